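# Fake-crystal generators: multivariate Gaussian sampling over reduced
# crystal parameters fitted to dataset statistics, and controlled
# distortion of existing crystals in standardized parameter space.

#' Reduce cell lengths to molecule-volume-invariant units
#'
#' `a' = a / (Z * V_mol)^(1/3)` (likewise b', c'): the unique power law that
#' makes the cell volume scale as `Z * V_mol`, so sampling in reduced space
#' is invariant to the number of molecules in the cell and to the molecular
#' volume (the packing coefficient distribution decouples from both).
#'
#' @param params A [crystal_params()] or a numeric 12-vector
#'   (see [params_vector()]).
#' @param Z Molecules per unit cell.
#' @param V_mol Molecular volume in cubic Angstrom.
#' @return Numeric 12-vector with reduced lengths in slots 1:3.
#' @export
reduce_lengths <- function(params, Z, V_mol) {
  if (Z < 1 || V_mol <= 0) stop("Z must be >= 1 and V_mol > 0")
  v <- if (inherits(params, "crystal_params")) params_vector(params) else {
    stopifnot(is.numeric(params), length(params) == 12)
    params
  }
  s <- (Z * V_mol)^(1 / 3)
  v[1:3] <- v[1:3] / s
  v
}

#' Expand reduced cell lengths back to Angstrom
#'
#' Exact inverse of [reduce_lengths()].
#'
#' @param reduced Numeric 12-vector in reduced-length space.
#' @param Z Molecules per unit cell.
#' @param V_mol Molecular volume in cubic Angstrom.
#' @return Numeric 12-vector with absolute lengths in slots 1:3.
#' @export
expand_lengths <- function(reduced, Z, V_mol) {
  if (Z < 1 || V_mol <= 0) stop("Z must be >= 1 and V_mol > 0")
  v <- as.numeric(reduced)
  v[1:3] <- v[1:3] * (Z * V_mol)^(1 / 3)
  v
}

#' Fit a 12-dimensional Gaussian to crystal parameter statistics
#'
#' Computes per-parameter means and standard deviations plus the full 12x12
#' covariance of a dataset of crystal parameter vectors, in reduced-length
#' space.  A small ridge keeps the covariance positive definite when the
#' dataset is degenerate.
#'
#' @param params_list List of [crystal_params()].
#' @param Z_list Integer vector of molecules per cell, one per entry.
#' @param V_mol_list Numeric vector of molecular volumes, one per entry.
#' @param ridge Diagonal regularizer added to the covariance (default 1e-8).
#' @return Object of class `param_stats` with fields `mean`, `sd`, `cov`,
#'   `n`.
#' @export
fit_param_gaussian <- function(params_list, Z_list, V_mol_list,
                               ridge = 1e-8) {
  n <- length(params_list)
  if (n == 0) stop("empty dataset")
  X <- t(mapply(function(p, Z, V) reduce_lengths(p, Z, V),
                params_list, Z_list, V_mol_list))
  mu <- colMeans(X)
  cv <- if (n > 1) stats::cov(X) else matrix(0, 12, 12)
  cv <- (cv + t(cv)) / 2 + ridge * diag(12)
  sdv <- sqrt(pmax(diag(cv), ridge))
  structure(list(mean = mu, sd = sdv, cov = cv, n = n),
            class = "param_stats")
}

#' @export
print.param_stats <- function(x, ...) {
  cat(sprintf("<param_stats fitted on %d entries (reduced-length space)>\n",
              x$n))
  invisible(x)
}

#' Serialize fitted parameter statistics to a text file
#'
#' @param stats A `param_stats` object.
#' @param path Output path (TSV: mean row, sd row, then 12 covariance rows).
#' @return Invisibly, `path`.
#' @export
write_param_stats <- function(stats, path) {
  m <- rbind(mean = stats$mean, sd = stats$sd, stats$cov)
  utils::write.table(cbind(what = c("mean", "sd", paste0("cov", 1:12)),
                           as.data.frame(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fitted parameter statistics from a text file
#'
#' @param path Path written by [write_param_stats()].
#' @return A `param_stats` object.
#' @export
read_param_stats <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  m <- as.matrix(tab[, -1])
  dimnames(m) <- NULL
  structure(list(mean = m[1, ], sd = m[2, ], cov = m[3:14, , drop = FALSE],
                 n = NA_integer_), class = "param_stats")
}

# wrap a raw 12-vector into the valid crystal-parameter domain:
# lengths reflected positive, angles reflected into (0, 180) with a
# positive-volume retry, fractional centroid wrapped into [0, 1),
# orientation left free (any rotation vector is valid).
wrap_params_vector <- function(v) {
  v[1:3] <- abs(v[1:3])
  v[1:3][v[1:3] < 1e-3] <- 1e-3
  refl <- function(x) {
    x <- x %% 360
    ifelse(x > 180, 360 - x, x)
  }
  v[4:6] <- pmin(pmax(refl(v[4:6]), 1), 179)
  vol_ok <- function(ang) {
    ca <- cos(ang * pi / 180)
    1 - sum(ca^2) + 2 * prod(ca) > 1e-6
  }
  if (!vol_ok(v[4:6])) v[4:6] <- 0.5 * (v[4:6] + 90)  # pull toward orthogonal
  if (!vol_ok(v[4:6])) v[4:6] <- c(90, 90, 90)
  v[7:9] <- v[7:9] %% 1
  v
}

vector_to_params <- function(v, sg) {
  crystal_params(v[1:6], v[7:9], v[10:12], sg)
}

#' Sample fake crystals from the fitted Gaussian
#'
#' Draws `n` crystal parameter sets from the multivariate Gaussian fitted in
#' reduced-length space, expands lengths using the conformer's molecular
#' volume and the space group's general-position multiplicity, and wraps
#' out-of-range draws (angles, fractional centroid) into valid ranges so
#' every sample is buildable.  Typical samples have reasonable density but
#' essentially random molecular orientations, so they rarely respect vdW
#' radii.
#'
#' @param stats A `param_stats` from [fit_param_gaussian()].
#' @param conformer A featurized [molecule_record()] (for its volume).
#' @param sg A [space_group()].
#' @param n Number of samples.
#' @param seed Integer seed; same seed, same output.
#' @return List of [crystal_params()].
#' @export
sample_gaussian_crystals <- function(stats, conformer, sg, n, seed = 1L) {
  if (is.null(conformer$mol_volume)) {
    conformer$mol_volume <- molecular_volume(conformer)
  }
  Z <- length(sg$ops)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  L <- chol_psd(stats$cov)
  draws <- matrix(stats::rnorm(n * 12), n, 12) %*% L
  draws <- sweep(draws, 2, stats$mean, "+")
  lapply(seq_len(n), function(i) {
    v <- expand_lengths(draws[i, ], Z, conformer$mol_volume)
    vector_to_params(wrap_params_vector(v), sg)
  })
}

# Cholesky factor tolerant of semidefinite input
chol_psd <- function(S) {
  tryCatch(chol(S), error = function(e) {
    eg <- eigen(S, symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    t(eg$vectors %*% (t(eg$vectors) * sqrt(vals)))
  })
}

#' Standardize crystal parameters against dataset statistics
#'
#' Per-parameter (diagonal) standardization in reduced-length space:
#' `(C' - mean) / sd`.
#'
#' @param params A [crystal_params()].
#' @param stats A `param_stats`.
#' @param Z,V_mol Molecules per cell and molecular volume used for the
#'   length reduction.
#' @return Numeric 12-vector of standardized parameters.
#' @export
standardize_params <- function(params, stats, Z, V_mol) {
  (reduce_lengths(params, Z, V_mol) - stats$mean) / stats$sd
}

#' Invert [standardize_params()]
#'
#' @param svec Standardized 12-vector.
#' @param stats A `param_stats`.
#' @param sg A [space_group()] for the rebuilt parameter object.
#' @param Z,V_mol Molecules per cell and molecular volume.
#' @param wrap Wrap the destandardized vector into the valid domain
#'   (default `TRUE`).
#' @return A [crystal_params()].
#' @export
destandardize_params <- function(svec, stats, sg, Z, V_mol, wrap = TRUE) {
  v <- expand_lengths(svec * stats$sd + stats$mean, Z, V_mol)
  if (wrap) v <- wrap_params_vector(v)
  vector_to_params(v, sg)
}

#' Distort an existing crystal's parameters
#'
#' Standardizes the 12 parameters against the dataset statistics, adds
#' isotropic Gaussian noise scaled by the distortion factor `c_dis`, then
#' destandardizes and re-wraps.  `c_dis = 0` returns the input exactly
#' (up to domain wrapping, which is the identity for valid input);
#' `c_dis` near 1 produces essentially random crystals.
#'
#' @param params A [crystal_params()].
#' @param stats A `param_stats`.
#' @param Z,V_mol Molecules per cell and molecular volume.
#' @param c_dis Non-negative distortion scale (default 0.1).
#' @param seed Optional integer seed for the noise draw.
#' @return A distorted [crystal_params()].
#' @export
distort_crystal <- function(params, stats, Z, V_mol, c_dis = 0.1,
                            seed = NULL) {
  if (c_dis < 0) stop("c_dis must be non-negative")
  if (c_dis == 0) return(params)  # exact identity, no float round trip
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  s <- standardize_params(params, stats, Z, V_mol)
  s <- s + c_dis * stats::rnorm(12)
  destandardize_params(s, stats, params$space_group, Z, V_mol,
                       wrap = c_dis > 0)
}
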