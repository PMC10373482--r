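test_that("cell_matrix matches the crystallographic convention", {
  expect_equal(cell_matrix(1, 1, 1, 90, 90, 90), diag(3), tolerance = 1e-12)
  expect_equal(cell_matrix(2, 3, 4, 90, 90, 90), diag(c(2, 3, 4)),
               tolerance = 1e-12)

  M <- cell_matrix(1, 1, 1, 90, 90, 120)
  expect_equal(det(M), cell_volume(c(1, 1, 1, 90, 90, 120)),
               tolerance = 1e-12)

  # volume conservation on random valid parameters
  set.seed(5)
  for (i in 1:25) {
    cell <- c(stats::runif(3, 3, 15), stats::runif(3, 70, 110))
    M <- do.call(cell_matrix, as.list(cell))
    expect_equal(det(M), cell_volume(cell), tolerance = 1e-10 * det(M))
    expect_equal(sqrt(rowSums(M^2)), cell[1:3], tolerance = 1e-10)
    ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) *
      180 / pi
    expect_equal(c(ang(M[2, ], M[3, ]), ang(M[1, ], M[3, ]),
                   ang(M[1, ], M[2, ])), cell[4:6], tolerance = 1e-8)
  }
  expect_error(cell_matrix(1, 1, 1, 10, 10, 170), "volume")
})

test_that("frac/cart conversion is exact and invertible", {
  M <- diag(c(2, 3, 4))
  expect_equal(as.vector(frac_to_cart(rbind(c(0.5, 0.5, 0.5)), M)),
               c(1, 1.5, 2))
  set.seed(6)
  M2 <- cell_matrix(7, 8, 9, 80, 95, 100)
  F0 <- matrix(stats::runif(30), 10, 3)
  expect_equal(cart_to_frac(frac_to_cart(F0, M2), M2), F0,
               tolerance = 1e-10)
  expect_error(cart_to_frac(F0, matrix(0, 3, 3)), "singular")
})

test_that("canonical conformer selection uses wrapped fractional norms", {
  mol <- test_molecule(1)
  cell <- c(12, 12, 12, 90, 90, 90)
  M <- do.call(cell_matrix, as.list(cell))
  place <- function(fc) sweep(sweep(mol$coords, 2, colMeans(mol$coords)),
                              2, as.vector(rbind(fc) %*% M), "+")
  e1 <- crystal_entry(mol, cell, space_group("P1", "x,y,z"),
                      list(place(c(0.1, 0.1, 0.1)),
                           place(c(0.4, 0.4, 0.4))))
  expect_equal(select_canonical_conformer(e1), 1)

  # single molecule
  e0 <- crystal_entry(mol, cell, space_group("P1"),
                      list(place(c(0.7, 0.2, 0.9))))
  expect_equal(select_canonical_conformer(e0), 1)

  # no minimum-image convention: 0.95 stays at norm 0.95, so (0.2, 0, 0)
  # wins even though 0.95 is nearer the origin under minimum image
  e2 <- crystal_entry(mol, cell, space_group("P1", "x,y,z"),
                      list(place(c(0.95, 0, 0)), place(c(0.2, 0, 0))))
  expect_equal(select_canonical_conformer(e2), 2)
})

test_that("standardize_orientation fixes the frame covariantly", {
  mol <- test_molecule(2)
  std <- standardize_orientation(mol$coords)
  # standardized pose: re-standardizing returns the identity rotation
  again <- standardize_orientation(std$coords)
  expect_equal(again$rotation, diag(3), tolerance = 1e-8)
  expect_equal(again$coords, std$coords, tolerance = 1e-8,
               ignore_attr = TRUE)

  # a known rotation is recovered exactly
  for (s in 1:5) {
    R0 <- random_rotation(s)
    rot <- standardize_orientation(std$coords %*% t(R0) + s)
    expect_equal(rot$rotation, R0, tolerance = 1e-8)
    expect_equal(rot$coords, std$coords, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # planar molecule: out-of-plane axis has zero overlap with the farthest
  # atom; frame comes out proper (det = +1)
  planar <- rbind(c(2.2, 0, 0), c(-1, 0.8, 0), c(-0.5, -1.4, 0),
                  c(0.4, 1.9, 0))
  stdp <- standardize_orientation(planar)
  expect_equal(det(stdp$rotation), 1, tolerance = 1e-10)
  expect_equal(stdp$coords[, 3], rep(0, 4), tolerance = 1e-8,
               ignore_attr = TRUE)

  line <- cbind(seq(0, 3, by = 1), 0, 0)
  expect_error(standardize_orientation(line), "collinear")
})

test_that("rotation-vector encoding is bijective", {
  set.seed(11)
  for (i in 1:1000) {
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2)) * stats::runif(1, 1e-6, pi - 1e-6)
    R <- rotvec_decode(v)
    expect_equal(rotvec_encode(R), v, tolerance = 1e-9)
  }
  expect_equal(rotvec_decode(c(0, 0, 0)), diag(3))
  expect_equal(rotvec_encode(diag(3)), c(0, 0, 0))
})

test_that("extract/build round-trips across all bundled space groups", {
  for (sg in supported_space_groups()) {
    fx <- test_crystal(5, sg)
    p <- fx$params
    e <- build_unit_cell(p, fx$conformer)
    p2 <- extract_crystal_params(e)
    expect_equal(params_vector(p2), params_vector(p), tolerance = 1e-5)

    e2 <- build_unit_cell(p2, canonical_conformer(e))
    expect_equal(do.call(rbind, e2$unit_cell_coords),
                 do.call(rbind, e$unit_cell_coords), tolerance = 1e-5,
                 ignore_attr = TRUE)
    expect_equal(p2$cell, e$cell)  # cell header passes through exactly
  }
})

test_that("build_unit_cell places images by the operators", {
  # P1 with identity orientation and origin centroid reproduces the
  # standardized conformer (up to the wrap of its centroid)
  mol <- test_molecule(4)
  std <- standardize_orientation(mol$coords)
  conf <- mol; conf$coords <- std$coords
  p <- crystal_params(c(14, 15, 16, 90, 90, 90), c(0, 0, 0), c(0, 0, 0),
                      space_group("P1"))
  e <- build_unit_cell(p, conf)
  expect_equal(e$unit_cell_coords[[1]], conf$coords, tolerance = 1e-10,
               ignore_attr = TRUE)

  # P-1: the image equals -frac wrapped, checked by hand on 3 atoms
  tri <- molecule_record(c(6L, 7L, 8L),
                         rbind(c(0, 0, 0), c(1.4, 0, 0), c(0, 1.3, 0.5)))
  stdt <- standardize_orientation(tri$coords)
  trif <- tri; trif$coords <- stdt$coords
  p2 <- crystal_params(c(9, 10, 11, 90, 90, 90), c(0.25, 0.3, 0.35),
                       c(0, 0, 0), space_group("P-1"))
  e2 <- build_unit_cell(p2, trif)
  M <- do.call(cell_matrix, as.list(p2$cell))
  f1 <- cart_to_frac(e2$unit_cell_coords[[1]], M)
  fi <- -f1
  fi <- sweep(fi, 2, floor(colMeans(fi)))
  expect_equal(e2$unit_cell_coords[[2]], fi %*% M, tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(build_unit_cell(structure(list(
    cell = p2$cell, frac_centroid = p2$frac_centroid,
    orientation = p2$orientation,
    space_group = list(symbol = "empty", ops = list())),
    class = "crystal_params"), trif), "empty")
})

test_that("supercell labeling, congruence, and the symmetry map", {
  fx <- test_crystal(6, "P-1")
  e <- fx$entry

  # with a huge cutoff nothing is discarded: Z * N^3 molecule images
  sc_all <- build_supercell(e, 3, r_c = 1e4)
  expect_equal(length(unique(sc_all$molecule_image)), e$Z * 27)
  expect_equal(nrow(sc_all$coords),
               e$Z * 27 * length(e$molecule$atomic_numbers))

  sc <- build_supercell(e, 3, r_c = 6)
  can <- which(sc$labels == 0L)
  expect_equal(sc$symmetry_map[can], can)
  # every retained atom lies within r_max + r_c of the canonical centroid
  d <- sqrt(rowSums(sweep(sc$coords, 2, sc$canonical_centroid)^2))
  expect_true(all(d[sc$labels == 1L] <= sc$r_max + 6 + 1e-9))

  # congruence: each image's sorted distance multiset matches the conformer
  ref <- sort(dist(e$unit_cell_coords[[1]]))
  for (im in unique(sc$molecule_image)[1:10]) {
    rows <- which(sc$molecule_image == im)
    if (length(rows) == length(e$molecule$atomic_numbers)) {
      expect_equal(sort(dist(sc$coords[rows, ])), ref, tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  }

  expect_error(build_supercell(e, 2), "odd")
  expect_error(build_supercell(e, -1), "odd")
})

test_that("supercell enclosure check is a sharp geometric predicate", {
  fx <- test_crystal(7, "P1")
  e <- fx$entry
  big <- e; big$cell[1:3] <- big$cell[1:3] * 10
  big$unit_cell_coords <- lapply(big$unit_cell_coords, identity)
  expect_true(supercell_encloses_check(big, 3, 6))

  tiny <- e
  s <- 3 / min(e$cell[1:3])
  tiny$cell[1:3] <- e$cell[1:3] * s  # ~3 Angstrom cell
  tiny$unit_cell_coords <- lapply(e$unit_cell_coords, function(X) X * s)
  expect_false(supercell_encloses_check(tiny, 3, 6))
  # growing N eventually encloses
  N <- 3
  while (!supercell_encloses_check(tiny, N, 6) && N < 31) N <- N + 2
  expect_true(supercell_encloses_check(tiny, N, 6))
})

test_that("space-group operator tables are closed groups of isometries", {
  for (sgname in supported_space_groups()) {
    sg <- space_group(sgname)
    W <- lapply(sg$ops, `[[`, "W")
    tt <- lapply(sg$ops, `[[`, "t")
    n <- length(sg$ops)
    key <- function(Wm, tv) paste(c(round(Wm, 6), round(tv %% 1, 6)),
                                  collapse = ",")
    have <- vapply(seq_len(n), function(i) key(W[[i]], tt[[i]]), "")
    # closure modulo lattice translations
    for (i in seq_len(n)) for (j in seq_len(n)) {
      Wc <- W[[i]] %*% W[[j]]
      tc <- as.vector(W[[i]] %*% tt[[j]]) + tt[[i]]
      expect_true(key(Wc, tc) %in% have,
                  label = sprintf("%s closure (%d,%d)", sgname, i, j))
    }
    # proper/improper isometries only
    for (i in seq_len(n)) expect_equal(abs(det(W[[i]])), 1)
  }
})
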