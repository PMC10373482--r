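test_that("strip_hydrogens removes hydrogens and keeps annotations", {
  # methane-like: 1 C + 4 H
  ch4 <- molecule_record(c(6, 1, 1, 1, 1),
                         rbind(c(0, 0, 0), c(1, 1, 1), c(-1, -1, 1),
                               c(1, -1, -1), c(-1, 1, -1)) * 0.63)
  out <- strip_hydrogens(ch4)
  expect_equal(length(out$atomic_numbers), 1)
  expect_equal(out$atomic_numbers, 6L)

  hfree <- test_molecule(1)
  expect_identical(strip_hydrogens(hfree), hfree)

  # benzene-like ring with 6 H and annotated acceptors on two carbons
  benz <- reference_molecule("benzene")
  th <- (0:5) * pi / 3
  withH <- molecule_record(
    c(benz$atomic_numbers, rep(1L, 6)),
    rbind(benz$coords, cbind(2.48 * cos(th), 2.48 * sin(th), 0)),
    acceptor_flags = c(1, 1, 0, 0, 0, 0, rep(0, 6)))
  out <- strip_hydrogens(withH)
  expect_equal(length(out$atomic_numbers), 6)
  expect_equal(out$n_acceptors, 2)
  expect_equal(out$n_donors, 0)

  allH <- molecule_record(c(1, 1), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  expect_error(strip_hydrogens(allH), "only hydrogens")
})

test_that("featurize produces the 8 x n and 16-long feature contracts", {
  c1 <- featurize(molecule_record(6L, matrix(0, 1, 3)),
                  volume_points = 2e3)
  expect_equal(dim(c1$atom_features), c(1, 8))
  expect_equal(unname(c1$atom_features[1, 1]), 6)
  expect_length(c1$mol_features, 16)

  mol <- test_molecule(2)
  expect_equal(unname(mol$mol_features[["n_atoms"]]),
               length(mol$atomic_numbers))

  # congruent copies give identical molecule features
  R0 <- random_rotation(4)
  rot <- featurize(molecule_record(mol$atomic_numbers,
                                   mol$coords %*% t(R0) + 2),
                   volume_points = 5e3)
  expect_equal(rot$mol_features, mol$mol_features, tolerance = 1e-10)

  # permutation changes only the row order of atom features
  set.seed(9); perm <- sample(length(mol$atomic_numbers))
  pm <- featurize(molecule_record(mol$atomic_numbers[perm],
                                  mol$coords[perm, ]), volume_points = 5e3)
  expect_equal(pm$mol_features, mol$mol_features, tolerance = 1e-10)
  expect_equal(pm$atom_features, mol$atom_features[perm, ],
               ignore_attr = TRUE)

  expect_error(featurize(molecule_record(c(6L, 1L), matrix(0:5, 2, 3))),
               "strip hydrogens")
})

test_that("packing coefficient follows Z * V_mol / V_cell", {
  fx <- test_crystal(1, "P1")
  e <- fx$entry
  e$molecule$mol_volume <- cell_volume(e$cell)  # V_mol = V_cell, Z = 1
  expect_equal(packing_coefficient(e), 1.0)

  e$molecule$mol_volume <- 100
  e$cell <- c(e$cell[1:3] * (400 / cell_volume(e$cell))^(1 / 3) * 2^(1/3),
              e$cell[4:6])
  # V_cell is now 800; with Z = 1 and V_mol = 100 -> 0.125; use a direct
  # arithmetic case instead: V_mol 100, V_cell 400, Z 2
  cube <- crystal_entry(e$molecule, c(400^(1 / 3), 400^(1 / 3), 400^(1 / 3),
                                      90, 90, 90),
                        space_group("P-1"),
                        list(e$molecule$coords, e$molecule$coords + 2))
  cube$molecule$mol_volume <- 100
  expect_equal(packing_coefficient(cube), 0.5)

  # doubling all cell lengths divides c_pack by 8
  fx2 <- test_crystal(2, "P-1")
  base <- packing_coefficient(fx2$entry)
  big <- fx2$entry
  big$cell[1:3] <- big$cell[1:3] * 2
  expect_equal(packing_coefficient(big), base / 8, tolerance = 1e-12)
})

test_that("runtime filter cascade marks entries per predicate", {
  good <- test_crystal(3, "P-1")$entry

  too_big <- good
  set.seed(1)
  nn <- 101
  X <- matrix(0, nn, 3)
  for (i in 2:nn) {
    repeat {
      cand <- X[sample(i - 1, 1), ] + stats::rnorm(3) * 1.2
      if (min(sqrt(rowSums(sweep(X[1:(i - 1), , drop = FALSE], 2,
                                 cand)^2))) > 1.1) break
    }
    X[i, ] <- cand
  }
  big_mol <- featurize(molecule_record(rep(6L, nn), X),
                       volume_points = 2e3)
  too_big <- crystal_entry(big_mol, c(30, 30, 30, 90, 90, 90),
                           space_group("P1"), list(X),
                           identifier = "too_big")

  overlapping <- good
  overlapping$unit_cell_coords[[2]][1, ] <-
    overlapping$unit_cell_coords[[1]][1, ]
  overlapping$identifier <- "overlap"

  rep <- apply_filters(list(good, too_big, overlapping), "runtime")
  expect_true(all(unlist(rep[1, -1])))
  expect_false(rep$max_atoms[2])
  expect_false(rep$overlapping_atoms[3])
  expect_setdiff <- setdiff(attr(rep, "survivors"),
                            good$identifier)
  expect_length(expect_setdiff, 0)
})

test_that("CIF write/read round-trips in both serializations", {
  fx <- test_crystal(4, "P21/c")
  e <- fx$entry
  for (mode in c("asymmetric", "full")) {
    f <- withr::local_tempfile(fileext = ".cif")
    write_crystal_cif(e, f, mode = mode)
    e2 <- read_crystal_cif(f)
    expect_equal(e2$cell, e$cell, tolerance = 1e-6)
    expect_equal(e2$Z, e$Z)
    expect_equal(do.call(rbind, e2$unit_cell_coords),
                 do.call(rbind, e$unit_cell_coords), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }

  bad <- e
  bad$cell <- c(5, 5, 5, 1, 1, 178)  # degenerate angles, volume ~ 0
  expect_error(write_crystal_cif(bad, tempfile()), "volume")
})

test_that("reading a P-1 CIF expands the inversion image by hand", {
  # 3-atom asymmetric unit in a P-1 cell written directly as text
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_p1bar_fixture",
    "_cell_length_a 8", "_cell_length_b 9", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "_symmetry_space_group_name_H-M 'P-1'",
    "loop_", "_symmetry_equiv_pos_as_xyz", "'x,y,z'", "'-x,-y,-z'",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.10 0.20 0.30",
    "N1 N 0.15 0.20 0.35",
    "O1 O 0.10 0.25 0.28"), f)
  e <- read_crystal_cif(f)
  expect_equal(e$Z, 2)
  M <- cell_matrix(8, 9, 10, 90, 90, 90)
  frac <- rbind(c(0.10, 0.20, 0.30), c(0.15, 0.20, 0.35),
                c(0.10, 0.25, 0.28))
  inv <- -frac
  ctr <- colMeans(inv)
  inv <- sweep(inv, 2, floor(ctr))  # wrap image centroid into the cell
  expect_equal(e$unit_cell_coords[[2]], inv %*% M, tolerance = 1e-6,
               ignore_attr = TRUE)

  # P1 cubic single molecule
  f2 <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_cubic", "_cell_length_a 10", "_cell_length_b 10",
    "_cell_length_c 10", "_cell_angle_alpha 90", "_cell_angle_beta 90",
    "_cell_angle_gamma 90",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.1 0.1 0.1", "C2 C 0.2 0.1 0.1"), f2)
  e2 <- read_crystal_cif(f2)
  expect_equal(e2$Z, 1)
  expect_equal(e2$cell, c(10, 10, 10, 90, 90, 90))

  f3 <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_broken", "_cell_length_a 10"), f3)
  expect_error(read_crystal_cif(f3), "incomplete")
})

test_that("XYZ and SDF conformer input round-trips", {
  mol <- test_molecule(3)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(mol, f)
  back <- read_xyz(f)
  expect_equal(back$atomic_numbers, mol$atomic_numbers)
  expect_equal(back$coords, mol$coords, tolerance = 1e-6,
               ignore_attr = TRUE)

  f2 <- withr::local_tempfile(fileext = ".sdf")
  n <- length(mol$atomic_numbers)
  sym <- element_property(mol$atomic_numbers, "symbol")
  writeLines(c(
    "fixture", "  generated", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            mol$coords[, 1], mol$coords[, 2], mol$coords[, 3], sym),
    "M  END", "$$$$"), f2)
  sdf <- read_sdf_conformer(f2)
  expect_equal(sdf$atomic_numbers, mol$atomic_numbers)
  expect_equal(sdf$coords, mol$coords, tolerance = 1e-4,
               ignore_attr = TRUE)
})
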