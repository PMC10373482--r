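# Deterministic synthetic molecules and crystals: rigid geometric
# conformers grown as connected clusters, crystals with known ground-truth
# parameters (cell lengths rescaled to hit a target packing coefficient),
# and labeled conformer datasets with a planted smooth structure whose
# achievable error floor is known exactly.
#
# Fixture molecules are geometric, not chemically exact: every contract
# they feed (graph construction, parametrization round trips, generator
# statistics, learning sanity) is geometric or statistical.  A small set
# of real rigid molecules with literature geometries (benzene, urea) is
# provided separately for the featurizer path.

#' Fixture generation specification
#'
#' @param seed Base seed; together with an index it determines every
#'   fixture exactly.
#' @param n_atoms_range Heavy-atom count range (default 4..30 capped to
#'   4..12 for crystals to keep supercells desk-sized).
#' @param elements Atomic-number palette (default C, N, O).
#' @param c_pack_range Target packing-coefficient range (default
#'   0.55..0.85).
#' @param space_groups Space-group symbols to cycle over.
#' @param n_entries Number of fixtures a dataset-level helper generates.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_atoms_range = c(4L, 12L),
                         elements = c(6L, 7L, 8L),
                         c_pack_range = c(0.55, 0.85),
                         space_groups = supported_space_groups(),
                         n_entries = 10L) {
  structure(list(seed = as.integer(seed), n_atoms_range = n_atoms_range,
                 elements = as.integer(elements),
                 c_pack_range = c_pack_range, space_groups = space_groups,
                 n_entries = as.integer(n_entries)),
            class = "fixture_spec")
}

fixture_seed <- function(spec, index, salt = 0L) {
  (spec$seed * 7919L + index * 104729L + salt * 131071L) %% 2147483629L
}

#' Generate a deterministic rigid conformer
#'
#' Grows a connected cluster: each new atom attaches at a bond-like
#' distance (1.4-1.6 Angstrom) from a random existing atom, rejecting
#' positions closer than 1.1 Angstrom to any other atom.  Same
#' `(spec, index)`, same molecule.
#'
#' @param spec A [fixture_spec()].
#' @param index Fixture index (determinism salt).
#' @param featurized Attach features before returning (default `TRUE`).
#' @param volume_points Monte Carlo points for the volume estimate; the
#'   default is reduced from the production 1e5 to keep fixture-heavy test
#'   suites fast (the label pipelines only need a consistent estimate).
#' @return A [molecule_record()].
#' @export
make_molecule <- function(spec = fixture_spec(), index = 1L,
                          featurized = TRUE, volume_points = 2e4) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(fixture_seed(spec, index))
  n <- sample(spec$n_atoms_range[1]:spec$n_atoms_range[2], 1)
  z <- sample(spec$elements, n, replace = TRUE)
  X <- matrix(stats::rnorm(3, sd = 0.01), 1, 3)
  while (nrow(X) < n) {
    # draw a few candidate attachments and keep the most compact one:
    # real rigid conformers are globular, and compactness is also what
    # lets crystals reach realistic packing coefficients without
    # intermolecular vdW overlap
    best <- NULL; best_d <- Inf
    for (k in 1:4) {
      anchor <- X[sample(nrow(X), 1), ]
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      cand <- anchor + dir * stats::runif(1, 1.4, 1.6)
      if (min(sqrt(rowSums(sweep(X, 2, cand)^2))) < 1.1) next
      dctr <- sum((cand - colMeans(X))^2)
      if (dctr < best_d) { best <- cand; best_d <- dctr }
    }
    if (!is.null(best)) X <- rbind(X, best)
  }
  mol <- molecule_record(z, X, identifier = sprintf("fix_mol_%d", index))
  if (featurized) mol <- featurize(mol, volume_points = volume_points)
  mol
}

#' Generate a crystal fixture with known ground-truth parameters
#'
#' Builds a crystal from a fixture conformer: the cell angles respect the
#' space group's crystal system, relative cell lengths are drawn around
#' plausible aspect ratios and then rescaled so the packing coefficient
#' hits a target inside the spec's range, and position/orientation are
#' random.  The returned parameters are the canonical extraction of the
#' built entry, so `extract(build(params))` is the identity on them by
#' construction.
#'
#' @param spec A [fixture_spec()].
#' @param index Fixture index.
#' @param space_group Optional symbol override (else cycles through the
#'   spec's list).
#' @param n_candidates Random placements searched for the least-overlap
#'   packing (default 24).
#' @return List with `params` ([crystal_params()]), `entry`
#'   ([crystal_entry()]), and `conformer` (the standardized molecule).
#' @export
make_crystal <- function(spec = fixture_spec(), index = 1L,
                         space_group = NULL, n_candidates = 24L) {
  mol <- make_molecule(spec, index)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(fixture_seed(spec, index, salt = 1L))
  if (is.null(space_group)) {
    sgs <- spec$space_groups
    space_group <- sgs[(index - 1L) %% length(sgs) + 1L]
  }
  sg <- space_group(space_group)
  Z <- length(sg$ops)

  ang <- switch(sg$system,
    triclinic = stats::runif(3, 70, 110),
    monoclinic = c(90, stats::runif(1, 95, 120), 90),
    orthorhombic = c(90, 90, 90),
    c(90, 90, 90))
  target_cp <- stats::runif(1, spec$c_pack_range[1], spec$c_pack_range[2])
  V_cell <- Z * mol$mol_volume / target_cp
  ratios <- exp(stats::rnorm(3, sd = 0.15))
  base <- cell_volume(c(ratios, ang))
  s <- (V_cell / base)^(1 / 3)
  cell <- c(ratios * s, ang)

  std <- standardize_orientation(mol$coords)
  conf <- mol; conf$coords <- std$coords

  # Experimental crystals are optimized packings: search candidate
  # placements for the least intermolecular vdW overlap, then relieve any
  # residual overlap by expanding the cell as far as the packing target
  # allows.  This is what separates "pristine" fixtures from generator
  # fakes, whose placements are random.
  draw_placement <- function() {
    fc <- stats::runif(3)
    orient <- stats::rnorm(3)
    orient <- orient / sqrt(sum(orient^2)) * stats::runif(1, 0, pi * 0.95)
    list(fc = fc, orient = orient)
  }
  best <- NULL; best_ratio <- -Inf
  for (k in seq_len(n_candidates)) {
    pl <- draw_placement()
    p <- crystal_params(cell, pl$fc, pl$orient, sg)
    e <- build_unit_cell(p, conf)
    ratio <- min_contact_ratio(e)
    if (ratio > best_ratio) { best_ratio <- ratio; best <- pl }
    if (best_ratio >= 1) break
  }
  # local refinement: accept random perturbations that relieve overlap,
  # annealing the step size as the packing improves
  for (k in seq_len(3 * n_candidates)) {
    if (best_ratio >= 1) break
    sd_fc <- 0.06 / (1 + k / n_candidates)
    sd_or <- 0.20 / (1 + k / n_candidates)
    cand <- list(fc = (best$fc + stats::rnorm(3, sd = sd_fc)) %% 1,
                 orient = best$orient + stats::rnorm(3, sd = sd_or))
    e <- build_unit_cell(crystal_params(cell, cand$fc, cand$orient, sg), conf)
    ratio <- min_contact_ratio(e)
    if (ratio > best_ratio) { best_ratio <- ratio; best <- cand }
  }
  # expand the cell (c_pack floor 0.552) until contacts respect vdW radii
  while (best_ratio < 0.98) {
    cand <- cell; cand[1:3] <- cand[1:3] * 1.03
    cp <- Z * mol$mol_volume / cell_volume(cand)
    if (cp <= 0.552) break
    cell <- cand
    e <- build_unit_cell(crystal_params(cell, best$fc, best$orient, sg), conf)
    best_ratio <- min_contact_ratio(e)
  }
  p0 <- crystal_params(cell, best$fc, best$orient, sg)
  e0 <- build_unit_cell(p0, conf,
                        identifier = sprintf("fix_xtal_%d", index))
  params <- extract_crystal_params(e0)
  entry <- build_unit_cell(params, canonical_conformer(e0),
                           identifier = e0$identifier)
  list(params = params, entry = entry, conformer = canonical_conformer(e0))
}

# minimum d / (r_vdw_i + r_vdw_j) over canonical-vs-image atom pairs within
# range; Inf when no intermolecular pair is in range.  By symmetry every
# intermolecular contact orbit touches the canonical molecule, so scanning
# canonical-vs-images over the 27 neighboring cells is exhaustive.
min_contact_ratio <- function(entry, range = 4.5) {
  M <- do.call(cell_matrix, as.list(entry$cell))
  k <- select_canonical_conformer(entry)
  n <- nrow(entry$unit_cell_coords[[1]])
  U <- do.call(rbind, entry$unit_cell_coords)
  r1 <- rep(vdw_radii(entry$molecule$atomic_numbers), entry$Z)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% M
  nz <- nrow(U)
  img <- U[rep(seq_len(nz), 27), ] + off[rep(1:27, each = nz), ]
  molid <- rep(rep(seq_len(entry$Z), each = n), 27)
  central <- rep(1:27, each = nz) == 14L  # offset (0,0,0) row of expand.grid
  keep <- !(central & molid == k)
  img <- img[keep, , drop = FALSE]
  Xc <- entry$unit_cell_coords[[k]]
  p <- pairs_within(img, Xc, range)
  if (!length(p$src)) return(Inf)
  rc <- vdw_radii(entry$molecule$atomic_numbers)
  min(p$dist / (rep(r1, 27)[keep][p$src] + rc[p$tgt]))
}

#' Planted-structure labeled conformer dataset
#'
#' Generates conformers and packing-coefficient labels that are a fixed
#' smooth deterministic function of molecule descriptors plus Gaussian
#' noise: `c_pack = 0.55 + 0.3 / (1 + exp(-(V_mol / n_atoms - 11) / 3)) +
#' N(0, sigma)`.  Because the descriptors are visible to the model, the
#' achievable mean absolute error has a known floor of
#' `sigma * sqrt(2 / pi)`.
#'
#' @param spec A [fixture_spec()].
#' @param sigma Label noise standard deviation (default 0.01).
#' @return List with `mols` (featurized molecules), `labels`, `truth` (the
#'   noiseless planted values), and `sigma`.
#' @export
make_density_dataset <- function(spec = fixture_spec(n_entries = 200L),
                                 sigma = 0.01) {
  mols <- lapply(seq_len(spec$n_entries), function(i) {
    make_molecule(spec, i, volume_points = 5e3)
  })
  truth <- vapply(mols, function(m) {
    v_per_atom <- m$mol_features[["volume"]] / m$mol_features[["n_atoms"]]
    0.55 + 0.3 / (1 + exp(-(v_per_atom - 11) / 3))
  }, numeric(1))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(fixture_seed(spec, 0L, salt = 2L))
  labels <- truth + stats::rnorm(length(truth), sd = sigma)
  list(mols = mols, labels = labels, truth = truth, sigma = sigma)
}

#' Reference rigid molecules with literature geometries
#'
#' Hand-built heavy-atom geometries for small rigid molecules used to
#' exercise the featurizer on chemically real input: benzene (planar
#' hexagon, C-C 1.39 Angstrom) and urea (planar, C=O 1.26, C-N 1.35).
#'
#' @param name `"benzene"` or `"urea"`.
#' @return A [molecule_record()] (not yet featurized).
#' @export
reference_molecule <- function(name = c("benzene", "urea")) {
  name <- match.arg(name)
  if (name == "benzene") {
    th <- (0:5) * pi / 3
    molecule_record(rep(6L, 6),
                    cbind(1.39 * cos(th), 1.39 * sin(th), 0),
                    identifier = "benzene")
  } else {
    molecule_record(
      c(6L, 8L, 7L, 7L),
      rbind(c(0, 0, 0), c(0, 1.26, 0),
            c(1.16, -0.66, 0), c(-1.16, -0.66, 0)),
      identifier = "urea",
      donor_flags = c(0, 0, 1, 1))
  }
}

#' Export a set of crystal fixtures as CIF files
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
export_fixture_cifs <- function(spec = fixture_spec(), dir = tempdir()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(seq_len(spec$n_entries), function(i) {
    fx <- make_crystal(spec, i)
    p <- file.path(dir, sprintf("%s.cif", fx$entry$identifier))
    write_crystal_cif(fx$entry, p)
    p
  }, "")
  invisible(paths)
}
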