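# The 12-parameter crystal representation: cell geometry, standardized
# molecular orientation, parameter extraction, and the deterministic
# unit-cell / N x N x N supercell builders.
#
# Conventions (fixed throughout the package):
#   * lattice matrix rows are the cell vectors; a lies along +x, b in the
#     xy-plane; fractional coords convert by right-multiplication, X = F M.
#   * molecular orientation is stored as a rotation vector (axis-angle),
#     which is bijective on rotations with angle in [0, pi) and smooth away
#     from the angle-pi boundary.
#   * "center of geometry" is the unweighted atom mean.

#' Triclinic cell matrix
#'
#' Builds the 3x3 lattice matrix (rows = cell vectors, Angstrom) in the
#' standard crystallographic frame: a along x, b in the xy-plane.
#'
#' @param a,b,c Cell lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return 3x3 numeric matrix with positive determinant.
#' @export
cell_matrix <- function(a, b, c, alpha, beta, gamma) {
  al <- alpha * pi / 180; be <- beta * pi / 180; ga <- gamma * pi / 180
  ca <- cos(al); cb <- cos(be); cg <- cos(ga); sg <- sin(ga)
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (!is.finite(vfac) || vfac <= 0 || sg <= 0) {
    stop("cell angles give non-positive volume")
  }
  rbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(c * cb, c * (ca - cb * cg) / sg, c * sqrt(vfac) / sg)
  )
}

#' Unit cell volume
#'
#' Closed-form triclinic volume `abc * sqrt(1 - cos^2 - ... + 2cos cos cos)`.
#'
#' @param cell Numeric vector `c(a, b, c, alpha, beta, gamma)`.
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  ang <- cell[4:6] * pi / 180
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3])
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac <= 0) stop("cell angles give non-positive volume")
  prod(cell[1:3]) * sqrt(vfac)
}

#' Fractional to Cartesian coordinates
#'
#' @param frac `n x 3` fractional coordinates.
#' @param M Lattice matrix from [cell_matrix()].
#' @return `n x 3` Cartesian coordinates (Angstrom).
#' @export
frac_to_cart <- function(frac, M) {
  as.matrix(frac) %*% M
}

#' Cartesian to fractional coordinates
#'
#' @param cart `n x 3` Cartesian coordinates (Angstrom).
#' @param M Lattice matrix from [cell_matrix()].
#' @return `n x 3` fractional coordinates.
#' @export
cart_to_frac <- function(cart, M) {
  if (abs(det(M)) < 1e-12) stop("singular lattice matrix")
  as.matrix(cart) %*% solve(M)
}

# unit-mass moment-of-inertia eigenvalues of centered coordinates
inertia_moments <- function(Xc) {
  eigen(inertia_tensor(Xc), symmetric = TRUE, only.values = TRUE)$values
}

inertia_tensor <- function(Xc) {
  r2 <- rowSums(Xc^2)
  sum(r2) * diag(3) - crossprod(Xc)
}

# ---- space groups ---------------------------------------------------------

.sg_tables <- local({
  mk <- function(strs) lapply(strs, parse_symop)
  list(
    "P1" = list(ops = mk("x,y,z"), system = "triclinic"),
    "P-1" = list(ops = mk(c("x,y,z", "-x,-y,-z")), system = "triclinic"),
    "P21" = list(ops = mk(c("x,y,z", "-x,y+1/2,-z")), system = "monoclinic"),
    "P21/c" = list(ops = mk(c("x,y,z", "-x,y+1/2,-z+1/2",
                              "-x,-y,-z", "x,-y+1/2,z+1/2")),
                   system = "monoclinic"),
    "P212121" = list(ops = mk(c("x,y,z", "x+1/2,-y+1/2,-z",
                                "-x,y+1/2,-z+1/2", "-x+1/2,-y,z+1/2")),
                     system = "orthorhombic"),
    "C2/c" = list(ops = mk(c("x,y,z", "-x,y,-z+1/2", "-x,-y,-z", "x,-y,z+1/2",
                             "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z+1/2",
                             "-x+1/2,-y+1/2,-z", "x+1/2,-y+1/2,z+1/2")),
                  system = "monoclinic"),
    "Pbca" = list(ops = mk(c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2",
                             "x+1/2,-y+1/2,-z", "-x,-y,-z", "x+1/2,y,-z+1/2",
                             "x,-y+1/2,z+1/2", "-x+1/2,y+1/2,z")),
                  system = "orthorhombic"),
    "Pna21" = list(ops = mk(c("x,y,z", "-x,-y,z+1/2",
                              "x+1/2,-y+1/2,z", "-x+1/2,y+1/2,z+1/2")),
                   system = "orthorhombic")
  )
})

#' Supported space-group symbols
#'
#' @return Character vector of the bundled general-position tables.
#' @export
supported_space_groups <- function() names(.sg_tables)

#' Space group object
#'
#' A symbol plus its general-position operator set.  The eight groups that
#' dominate organic crystal data are bundled; any other group can be used by
#' supplying explicit `"x,y,z"`-style operator strings (e.g. read from a
#' CIF).  The identity operator is always placed first.
#'
#' @param symbol Hermann-Mauguin-style symbol (e.g. `"P21/c"`).
#' @param ops Optional list of parsed operators (from [parse_symop()]) or
#'   character vector of operator strings, overriding the bundled table.
#' @return Object of class `space_group` with fields `symbol`, `ops`,
#'   `system`.
#' @export
space_group <- function(symbol, ops = NULL) {
  system <- "unknown"
  if (is.null(ops)) {
    key <- normalize_sg_symbol(symbol)
    if (!key %in% names(.sg_tables)) {
      stop("no bundled operator table for space group '", symbol,
           "'; supply operator strings explicitly")
    }
    ops <- .sg_tables[[key]]$ops
    system <- .sg_tables[[key]]$system
    symbol <- key
  } else {
    if (is.character(ops)) ops <- lapply(ops, parse_symop)
    key <- normalize_sg_symbol(symbol)
    if (key %in% names(.sg_tables)) system <- .sg_tables[[key]]$system
  }
  if (!length(ops)) stop("operator set must be non-empty")
  is_ident <- vapply(ops, function(op) {
    all(abs(op$W - diag(3)) < 1e-9) && all(abs(op$t %% 1) < 1e-9)
  }, logical(1))
  if (!any(is_ident)) stop("operator set lacks the identity")
  ops <- c(ops[which(is_ident)[1]], ops[-which(is_ident)[1]])
  structure(list(symbol = symbol, ops = ops, system = system),
            class = "space_group")
}

normalize_sg_symbol <- function(symbol) {
  s <- gsub("[ _]", "", symbol)
  s <- sub("^P2\\(?1\\)?/c$", "P21/c", s)
  s <- sub("^P-?1bar$", "P-1", s)
  s
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("<space_group %s: %d operators (%s)>\n", x$symbol,
              length(x$ops), x$system))
  invisible(x)
}

# ---- standardized orientation --------------------------------------------

#' Standardize a conformer's orientation
#'
#' Rotates a molecule into the standardized pose in which its principal
#' inertial axes (unit masses, ascending moments) lie along the Cartesian
#' axes.  Axis directions are disambiguated by requiring positive overlap
#' with the vector from the centroid to the most distant atom; an axis whose
#' overlap is (near) zero — as happens for planar molecules — is fixed by
#' the right-hand rule, and a secondary covariant reference (the largest
#' perpendicular atom displacement) resolves cases where two overlaps
#' vanish.  If the sign-fixed axes come out left-handed, the third axis is
#' aligned with -z instead, so the returned rotation is always proper.
#' Near-degenerate inertia eigenvalues are handled by re-orienting the axes
#' inside the degenerate subspace against the same reference vectors, which
#' keeps the pose a covariant function of the geometry.
#'
#' @param coords `n x 3` Cartesian coordinates (n >= 3, not all collinear).
#' @return List with `rotation` (proper 3x3 matrix Q mapping standardized to
#'   original coordinates: `X = X_std %*% t(Q) + centroid`), `coords` (the
#'   standardized, centered coordinates) and `centroid`.
#' @export
standardize_orientation <- function(coords) {
  X <- as.matrix(coords)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 atoms for an orientation frame")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scale <- sqrt(mean(rowSums(Xc^2)))
  if (scale < 1e-12) stop("degenerate geometry: all atoms coincide")
  sv <- svd(Xc)
  if (sv$d[2] / sv$d[1] < 1e-8) stop("all atoms collinear: frame undefined")

  eg <- eigen(inertia_tensor(Xc), symmetric = TRUE)
  ord <- order(eg$values)
  vals <- eg$values[ord]
  A <- t(eg$vectors[, ord])  # rows = principal axes, ascending moment

  # covariant reference vectors
  d2 <- rowSums(Xc^2)
  v1 <- Xc[which.max(d2), ]
  u1 <- v1 / sqrt(sum(v1^2))
  proj <- as.vector(Xc %*% u1)
  perp <- Xc - outer(proj, u1)
  pn <- rowSums(perp^2)
  v2 <- if (max(pn) > (1e-6 * scale)^2) perp[which.max(pn), ] else c(0, 0, 0)

  # re-orient axes inside (near-)degenerate inertia subspaces
  tol_deg <- 1e-6 * max(abs(vals), 1)
  i <- 1
  while (i <= 3) {
    j <- i
    while (j < 3 && abs(vals[j + 1] - vals[j]) < tol_deg) j <- j + 1
    if (j > i) {
      B <- t(A[i:j, , drop = FALSE])          # orthonormal basis, 3 x b
      refs <- list(v1, v2)
      new_axes <- matrix(0, nrow = 0, ncol = 3)
      for (r in refs) {
        if (nrow(new_axes) == ncol(B)) break
        p <- as.vector(B %*% crossprod(B, r))
        for (k in seq_len(nrow(new_axes))) {
          p <- p - sum(p * new_axes[k, ]) * new_axes[k, ]
        }
        if (sqrt(sum(p^2)) > 1e-8 * max(scale, 1)) {
          new_axes <- rbind(new_axes, p / sqrt(sum(p^2)))
        }
      }
      if (nrow(new_axes) == ncol(B) - 1 && ncol(B) == 2) {
        # complete the 2D block with the in-subspace orthogonal direction
        co <- as.vector(crossprod(B, new_axes[1, ]))
        q <- as.vector(B %*% c(-co[2], co[1]))
        new_axes <- rbind(new_axes, q / sqrt(sum(q^2)))
      }
      if (nrow(new_axes) == ncol(B)) A[i:j, ] <- new_axes
    }
    i <- j + 1
  }

  tol_ov <- 1e-6 * scale
  determined <- logical(3)
  for (k in 1:3) {
    o <- sum(A[k, ] * v1)
    if (abs(o) > tol_ov) {
      if (o < 0) A[k, ] <- -A[k, ]
      determined[k] <- TRUE
    }
  }
  for (k in which(!determined)) {
    o <- sum(A[k, ] * v2)
    if (abs(o) > tol_ov) {
      if (o < 0) A[k, ] <- -A[k, ]
      determined[k] <- TRUE
    }
  }
  if (sum(!determined) == 1) {
    # right-hand rule in cyclic axis order: e1 = e2 x e3, e2 = e3 x e1, ...
    k <- which(!determined)
    A[k, ] <- cross3(A[k %% 3 + 1, ], A[(k + 1) %% 3 + 1, ])
    determined[k] <- TRUE
  }

  if (det(A) < 0) A[3, ] <- -A[3, ]  # align third axis with -z instead

  list(rotation = t(A), coords = Xc %*% t(A), centroid = ctr)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# ---- rotation-vector encoding --------------------------------------------

#' Rotation vector from rotation matrix
#'
#' Axis-angle (rotation-vector) encoding with angle in `[0, pi]`; at the
#' angle-pi boundary the axis sign is fixed lexicographically so the
#' encoding is single-valued.
#'
#' @param R Proper rotation matrix.
#' @return Length-3 rotation vector (radians).
#' @export
rotvec_encode <- function(R) {
  tr <- sum(diag(R))
  ct <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (pi - theta > 1e-6) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(theta))
  } else {
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    k <- which.max(ax)
    ax <- B[, k] / ax[k]
    ax <- ax / sqrt(sum(ax^2))
    nz <- which(abs(ax) > 1e-9)[1]
    if (ax[nz] < 0) ax <- -ax
  }
  ax * theta
}

#' Rotation matrix from rotation vector
#'
#' Rodrigues' formula; inverse of [rotvec_encode()].
#'
#' @param v Length-3 rotation vector (radians).
#' @return Proper 3x3 rotation matrix.
#' @export
rotvec_decode <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  ax <- v / theta
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# ---- crystal parameters ---------------------------------------------------

#' Crystal parameter vector
#'
#' The 12 generative coordinates of a Z' = 1 molecular crystal: cell lengths
#' and angles, the fractional centroid of the canonical conformer, and its
#' orientation (rotation vector) relative to the standardized pose — plus
#' the space-group identity.
#'
#' @param cell `c(a, b, c, alpha, beta, gamma)`.
#' @param frac_centroid Fractional centroid, each component in `[0, 1)`.
#' @param orientation Rotation vector (radians).
#' @param space_group A [space_group()].
#' @return Object of class `crystal_params`.
#' @export
crystal_params <- function(cell, frac_centroid, orientation, space_group) {
  cell <- as.numeric(cell); frac_centroid <- as.numeric(frac_centroid)
  orientation <- as.numeric(orientation)
  if (length(cell) != 6 || length(frac_centroid) != 3 ||
      length(orientation) != 3) {
    stop("crystal parameters must comprise exactly 12 reals")
  }
  if (cell_volume(cell) <= 0) stop("non-positive cell volume")
  if (any(frac_centroid < 0 | frac_centroid >= 1)) {
    stop("fractional centroid components must lie in [0, 1)")
  }
  structure(list(cell = cell, frac_centroid = frac_centroid,
                 orientation = orientation, space_group = space_group),
            class = "crystal_params")
}

#' @export
print.crystal_params <- function(x, ...) {
  cat(sprintf(
    "<crystal_params %s: a=%.3f b=%.3f c=%.3f al=%.2f be=%.2f ga=%.2f>\n",
    x$space_group$symbol, x$cell[1], x$cell[2], x$cell[3],
    x$cell[4], x$cell[5], x$cell[6]))
  invisible(x)
}

#' Flatten crystal parameters to a numeric 12-vector
#'
#' Order: a, b, c, alpha, beta, gamma, x, y, z, phi, psi, theta.
#'
#' @param params A [crystal_params()].
#' @return Named numeric vector of length 12.
#' @export
params_vector <- function(params) {
  v <- c(params$cell, params$frac_centroid, params$orientation)
  names(v) <- c("a", "b", "c", "alpha", "beta", "gamma",
                "x", "y", "z", "phi", "psi", "theta")
  v
}

#' Select the canonical conformer
#'
#' Returns the index of the molecule whose fractional-coordinate centroid
#' (wrapped to `[0, 1)`, no minimum-image convention) has the smallest
#' Euclidean norm; ties break to the lowest index.
#'
#' @param entry A [crystal_entry()].
#' @return Integer molecule index.
#' @export
select_canonical_conformer <- function(entry) {
  M <- do.call(cell_matrix, as.list(entry$cell))
  norms <- vapply(entry$unit_cell_coords, function(X) {
    f <- colMeans(cart_to_frac(X, M)) %% 1
    sqrt(sum(f^2))
  }, numeric(1))
  which.min(norms)  # which.min takes the first minimum: lowest index on ties
}

#' Canonical conformer in standardized orientation
#'
#' @param entry A [crystal_entry()].
#' @return A [molecule_record()] whose coordinates are the canonical
#'   conformer rotated into the standardized pose (centered at the origin).
#' @export
canonical_conformer <- function(entry) {
  k <- select_canonical_conformer(entry)
  std <- standardize_orientation(entry$unit_cell_coords[[k]])
  mol <- entry$molecule
  mol$coords <- std$coords
  mol
}

#' Extract the 12 crystal parameters from a crystal entry
#'
#' Inverse of [build_unit_cell()]: identifies the canonical conformer, takes
#' its wrapped fractional centroid and the rotation from the standardized
#' pose, and returns these with the cell parameters.  All unit-cell
#' molecules must be congruent to the canonical conformer (they are checked
#' against its sorted intramolecular distance multiset).
#'
#' @param entry A [crystal_entry()] with Z' = 1.
#' @return A [crystal_params()].
#' @export
extract_crystal_params <- function(entry) {
  M <- do.call(cell_matrix, as.list(entry$cell))
  k <- select_canonical_conformer(entry)
  X <- entry$unit_cell_coords[[k]]
  if (nrow(X) > 1) {
    ref <- sort(stats::dist(X))
    for (m in seq_along(entry$unit_cell_coords)) {
      if (max(abs(sort(stats::dist(entry$unit_cell_coords[[m]])) - ref)) > 1e-5) {
        stop("unit-cell molecules are not congruent symmetry images")
      }
    }
  }
  fc <- colMeans(cart_to_frac(X, M)) %% 1
  std <- standardize_orientation(X)
  crystal_params(entry$cell, fc, rotvec_encode(std$rotation),
                 entry$space_group)
}

#' Build a unit cell from crystal parameters and a conformer
#'
#' Places the standardized conformer by rotating it per the orientation
#' rotation vector and translating its centroid to the fractional centroid,
#' then generates the remaining Z - 1 molecule images by applying the
#' space-group operators in fractional coordinates.  Each image is wrapped
#' so its centroid lies in the home cell.  Every output coordinate is a
#' smooth function of the 12 parameters away from wrap boundaries.
#'
#' @param params A [crystal_params()].
#' @param conformer A [molecule_record()] in standardized orientation
#'   (as returned by [canonical_conformer()] or
#'   [standardize_orientation()]).
#' @param identifier Identifier for the built entry.
#' @return A [crystal_entry()]; molecule image 1 is the placed conformer.
#' @export
build_unit_cell <- function(params, conformer, identifier = "built") {
  ops <- params$space_group$ops
  if (!length(ops)) stop("space group operator set is empty")
  M <- do.call(cell_matrix, as.list(params$cell))
  R <- rotvec_decode(params$orientation)
  X0 <- conformer$coords %*% t(R)
  X0 <- sweep(X0, 2, as.vector(params$frac_centroid %*% M), "+")
  f0 <- cart_to_frac(X0, M)
  images <- lapply(ops, function(op) {
    f <- sweep(f0 %*% t(op$W), 2, op$t, "+")
    ctr <- colMeans(f)
    f <- sweep(f, 2, floor(ctr + 1e-9))  # guard against -eps at the origin
    frac_to_cart(f, M)
  })
  mol <- conformer
  mol$coords <- images[[1]]
  crystal_entry(mol, params$cell, params$space_group, images,
                identifier = identifier)
}

# ---- supercell ------------------------------------------------------------

#' Build a labeled N x N x N supercell
#'
#' Replicates the unit cell over centered lattice offsets and labels each
#' atom: 0 for atoms of the canonical conformer, 1 for other atoms within
#' `r_max + r_c` of the canonical centroid, 2 (discarded) beyond.  Each
#' retained atom carries its molecule-image index and a symmetry map to the
#' corresponding canonical-conformer atom.
#'
#' @param entry A [crystal_entry()].
#' @param N Odd supercell dimension (default 3).
#' @param r_c Convolution cutoff radius in Angstrom (default 6).
#' @return Object of class `supercell_structure` with fields `coords`,
#'   `atomic_numbers`, `labels` (0/1), `molecule_image`, `symmetry_map`,
#'   `canonical_centroid`, `r_max`, `r_c`, `N`, `cell`.
#' @export
build_supercell <- function(entry, N = 3, r_c = 6) {
  if (N < 1 || N %% 2 == 0) stop("N must be a positive odd integer")
  M <- do.call(cell_matrix, as.list(entry$cell))
  k <- select_canonical_conformer(entry)
  X_can <- entry$unit_cell_coords[[k]]
  ctr0 <- colMeans(X_can)
  r_max <- max(sqrt(rowSums(sweep(X_can, 2, ctr0)^2)))
  h <- (N - 1) / 2
  offsets <- as.matrix(expand.grid(-h:h, -h:h, -h:h))
  shifts <- offsets %*% M

  n_at <- nrow(X_can)
  z <- entry$molecule$atomic_numbers
  coords_list <- vector("list", entry$Z * nrow(offsets))
  meta <- vector("list", length(coords_list))
  idx <- 0
  for (o in seq_len(nrow(offsets))) {
    central <- all(offsets[o, ] == 0)
    for (m in seq_len(entry$Z)) {
      idx <- idx + 1
      Xi <- sweep(entry$unit_cell_coords[[m]], 2, shifts[o, ], "+")
      coords_list[[idx]] <- Xi
      meta[[idx]] <- list(canonical = central && m == k, image = as.integer(idx))
    }
  }
  coords <- do.call(rbind, coords_list)
  is_can <- rep(vapply(meta, `[[`, logical(1), "canonical"), each = n_at)
  image_idx <- rep(vapply(meta, `[[`, integer(1), "image"), each = n_at)
  within <- rep(seq_len(n_at), times = length(coords_list))

  d_ctr <- sqrt(rowSums(sweep(coords, 2, ctr0)^2))
  labels <- ifelse(is_can, 0L, ifelse(d_ctr <= r_max + r_c, 1L, 2L))
  keep <- labels != 2L
  coords <- coords[keep, , drop = FALSE]
  labels <- labels[keep]
  image_idx <- image_idx[keep]
  within <- within[keep]

  canonical_rows <- integer(n_at)
  canonical_rows[within[labels == 0L]] <- which(labels == 0L)
  symmetry_map <- canonical_rows[within]

  structure(list(
    coords = coords,
    atomic_numbers = z[within],
    labels = labels,
    molecule_image = image_idx,
    within_molecule = within,
    symmetry_map = symmetry_map,
    canonical_centroid = ctr0,
    r_max = r_max, r_c = r_c, N = N,
    cell = entry$cell,
    identifier = entry$identifier
  ), class = "supercell_structure")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' @export
print.supercell_structure <- function(x, ...) {
  cat(sprintf(
    "<supercell_structure '%s': N=%d, %d atoms retained (%d canonical)>\n",
    x$identifier, x$N, nrow(x$coords), sum(x$labels == 0L)))
  invisible(x)
}

#' Check that a supercell encloses the label-1 sphere
#'
#' `TRUE` iff every molecule that could contribute a label-1 atom has its
#' home cell inside the N x N x N supercell.  Because molecules are
#' replicated whole (wrapped by centroid) and an atom can stick out of its
#' home cell by up to `r_max`, the criterion is that the sphere of radius
#' `2 r_max + r_c` about the canonical centroid fits inside the supercell
#' parallelepiped: any molecule with an atom inside the label-1 sphere
#' (radius `r_max + r_c`) then has its centroid, and hence its cell,
#' inside the hull.
#'
#' @param entry A [crystal_entry()].
#' @param N Odd supercell dimension.
#' @param r_c Cutoff radius in Angstrom.
#' @return Logical.
#' @export
supercell_encloses_check <- function(entry, N = 3, r_c = 6) {
  M <- do.call(cell_matrix, as.list(entry$cell))
  k <- select_canonical_conformer(entry)
  X_can <- entry$unit_cell_coords[[k]]
  ctr0 <- colMeans(X_can)
  r_max <- max(sqrt(rowSums(sweep(X_can, 2, ctr0)^2)))
  f0 <- as.vector(cart_to_frac(rbind(ctr0), M))
  V <- abs(det(M))
  h <- (N - 1) / 2
  heights <- vapply(1:3, function(i) {
    jk <- setdiff(1:3, i)
    V / sqrt(sum(cross3(M[jk[1], ], M[jk[2], ])^2))
  }, numeric(1))
  slack <- pmin(f0 + h, h + 1 - f0) * heights
  all(slack >= 2 * r_max + r_c)
}
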