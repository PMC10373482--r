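# Molecule and crystal containers, featurization, filter cascade, and
# standard-format input/output (CIF, XYZ, SDF).

#' Create a molecule record
#'
#' The basic conformer container: atomic numbers plus Cartesian coordinates,
#' with optional hydrogen-bond donor/acceptor annotations.  Feature matrices
#' are attached later by [featurize()].
#'
#' @param atomic_numbers Integer vector of atomic numbers.
#' @param coords Numeric matrix, `n_atoms` x 3, Cartesian Angstrom.
#' @param identifier Character identifier.
#' @param donor_flags,acceptor_flags Optional 0/1 vectors per atom marking
#'   hydrogen-bond donors/acceptors.  If `acceptor_flags` is `NULL`, N, O and
#'   F atoms are marked as acceptors; donors default to none (hydrogens are
#'   deleted upstream, so donor identity must be annotated to survive).
#' @return An object of class `molecule_record`.
#' @export
molecule_record <- function(atomic_numbers, coords, identifier = "mol",
                            donor_flags = NULL, acceptor_flags = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(atomic_numbers) != nrow(coords)) {
    stop("atomic_numbers and coords disagree on atom count")
  }
  if (nrow(coords) < 1) stop("molecule must contain at least one atom")
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  if (is.null(acceptor_flags)) {
    acceptor_flags <- as.numeric(atomic_numbers %in% c(7L, 8L, 9L))
  }
  if (is.null(donor_flags)) donor_flags <- numeric(length(atomic_numbers))
  structure(list(
    identifier = identifier,
    atomic_numbers = as.integer(atomic_numbers),
    coords = coords,
    donor_flags = as.numeric(donor_flags),
    acceptor_flags = as.numeric(acceptor_flags),
    atom_features = NULL,
    mol_features = NULL,
    n_donors = sum(donor_flags),
    n_acceptors = sum(acceptor_flags),
    mol_volume = NULL
  ), class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record '%s': %d atoms%s>\n", x$identifier,
              length(x$atomic_numbers),
              if (is.null(x$atom_features)) "" else ", featurized"))
  invisible(x)
}

#' Create a crystal entry
#'
#' A whole crystal: one reference conformer, cell parameters, a space group
#' (symbol plus general-position operators), and the explicit Cartesian
#' coordinates of all Z molecules in the unit cell.
#'
#' @param molecule A [molecule_record()] for the asymmetric-unit conformer.
#' @param cell Numeric vector `c(a, b, c, alpha, beta, gamma)` (Angstrom,
#'   degrees).
#' @param space_group A space-group object from [space_group()].
#' @param unit_cell_coords List of `n_atoms` x 3 Cartesian matrices, one per
#'   molecule in the unit cell; atom order must match `molecule`.
#' @param identifier Character identifier.
#' @return An object of class `crystal_entry`.
#' @export
crystal_entry <- function(molecule, cell, space_group, unit_cell_coords,
                          identifier = "xtal") {
  cell <- as.numeric(cell)
  if (length(cell) != 6) stop("cell must be c(a, b, c, alpha, beta, gamma)")
  if (any(cell[1:3] <= 0)) stop("cell lengths must be positive")
  if (any(cell[4:6] <= 0 | cell[4:6] >= 180)) {
    stop("cell angles must lie strictly between 0 and 180 degrees")
  }
  if (cell_volume(cell) <= 0) stop("cell parameters give non-positive volume")
  Z <- length(unit_cell_coords)
  if (Z < 1) stop("unit cell must contain at least one molecule")
  structure(list(
    identifier = identifier,
    molecule = molecule,
    cell = cell,
    space_group = space_group,
    Z = Z,
    z_prime = 1,
    unit_cell_coords = lapply(unit_cell_coords, function(m) {
      m <- as.matrix(m); storage.mode(m) <- "double"; m
    })
  ), class = "crystal_entry")
}

#' @export
print.crystal_entry <- function(x, ...) {
  cat(sprintf("<crystal_entry '%s': %s, Z=%d, %d atoms/molecule>\n",
              x$identifier, x$space_group$symbol, x$Z,
              length(x$molecule$atomic_numbers)))
  invisible(x)
}

#' Remove hydrogen atoms from a molecule
#'
#' Deletes all atoms with atomic number 1 while retaining donor/acceptor
#' annotations on the remaining heavy atoms (donor/acceptor counts enter the
#' featurization even though the hydrogens themselves are gone).
#'
#' @param mol A [molecule_record()].
#' @return The molecule with hydrogens removed; features are invalidated.
#' @export
strip_hydrogens <- function(mol) {
  keep <- mol$atomic_numbers != 1L
  if (!any(keep)) stop("molecule contains only hydrogens; entry rejected")
  if (all(keep)) return(mol)
  out <- molecule_record(mol$atomic_numbers[keep],
                         mol$coords[keep, , drop = FALSE],
                         identifier = mol$identifier,
                         donor_flags = mol$donor_flags[keep],
                         acceptor_flags = mol$acceptor_flags[keep])
  out
}

# bonds inferred geometrically: d <= 1.3 * (rcov_i + rcov_j)
infer_bonds <- function(mol) {
  n <- length(mol$atomic_numbers)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  d <- as.matrix(stats::dist(mol$coords))
  rc <- element_property(mol$atomic_numbers, "covalent_radius")
  thresh <- 1.3 * outer(rc, rc, "+")
  idx <- which(d <= thresh & upper.tri(d), arr.ind = TRUE)
  idx
}

count_rings <- function(mol) {
  # cyclomatic number of the inferred bond graph: E - V + components
  bonds <- infer_bonds(mol)
  n <- length(mol$atomic_numbers)
  if (nrow(bonds) == 0) return(0)
  comp <- seq_len(n)
  for (k in seq_len(nrow(bonds))) {
    a <- comp[bonds[k, 1]]; b <- comp[bonds[k, 2]]
    if (a != b) comp[comp == b] <- a
  }
  nrow(bonds) - n + length(unique(comp))
}

#' Monte Carlo molecular volume
#'
#' Volume of the union of atomic van der Waals spheres, estimated by Monte
#' Carlo integration over the bounding box with a fixed internal seed so the
#' estimate is a pure function of the structure.
#'
#' @param mol A [molecule_record()].
#' @param n_points Number of sample points (default 1e5).
#' @return Volume in cubic Angstrom.
#' @export
molecular_volume <- function(mol, n_points = 1e5) {
  r <- vdw_radii(mol$atomic_numbers)
  # canonicalize the pose so the estimate (sample box included) is exactly
  # invariant under rigid motion and atom permutation of the input
  X <- tryCatch(standardize_orientation(mol$coords)$coords,
                error = function(e) {
    sweep(mol$coords, 2, colMeans(mol$coords))
  })
  lo <- apply(X - r, 2, min)
  hi <- apply(X + r, 2, max)
  # a mirror image standardizes to the z-flipped pose; a z-symmetric box
  # plus averaging over +z/-z sample pairs makes the estimate exactly
  # inversion invariant as well
  zl <- max(hi[3], -lo[3]); lo[3] <- -zl; hi[3] <- zl
  box <- prod(hi - lo)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(982451653L)
  P <- cbind(stats::runif(n_points, lo[1], hi[1]),
             stats::runif(n_points, lo[2], hi[2]),
             stats::runif(n_points, lo[3], hi[3]))
  inside <- rep(FALSE, n_points); inside_m <- rep(FALSE, n_points)
  for (i in seq_len(nrow(X))) {
    dxy <- (P[, 1] - X[i, 1])^2 + (P[, 2] - X[i, 2])^2
    inside <- inside | (dxy + (P[, 3] - X[i, 3])^2 < r[i]^2)
    inside_m <- inside_m | (dxy + (P[, 3] + X[i, 3])^2 < r[i]^2)
  }
  box * (mean(inside) + mean(inside_m)) / 2
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Compute atom- and molecule-level input features
#'
#' Attaches the 8-column per-atom feature matrix and the 16-entry molecule
#' feature vector.  Atom features: atomic number (first column), period,
#' group, electronegativity, covalent radius, vdW radius, donor flag,
#' acceptor flag.  Molecule features: atom count, mass, vdW volume, the three
#' principal inertial moments, radius of gyration, ring count, rotatable-bond
#' count (0 for the rigid conformers handled here), donor and acceptor
#' counts, planarity, maximum centroid-atom distance, and the composition
#' fractions of C, N and O.
#'
#' All molecule descriptors are invariant under rigid motion and atom
#' permutation.
#'
#' @param mol A [molecule_record()] with hydrogens already stripped.
#' @param volume_points Monte Carlo sample count for [molecular_volume()].
#' @return The molecule with `atom_features`, `mol_features` and
#'   `mol_volume` filled in.
#' @export
featurize <- function(mol, volume_points = 1e5) {
  z <- mol$atomic_numbers
  if (any(z == 1L)) stop("strip hydrogens before featurizing")
  if (any(z > 100L)) stop("atomic numbers above 100 are not supported")
  n <- length(z)
  X <- mol$coords
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (n > 1 && min(stats::dist(X)) < 1e-8) {
    stop("molecule has exactly coincident atoms")
  }

  mol$atom_features <- cbind(
    z,
    element_property(z, "period"),
    element_property(z, "group"),
    element_property(z, "electronegativity"),
    element_property(z, "covalent_radius"),
    element_property(z, "vdw_radius"),
    mol$donor_flags,
    mol$acceptor_flags
  )
  colnames(mol$atom_features) <- c("z", "period", "group", "en",
                                   "r_cov", "r_vdw", "donor", "acceptor")

  Imom <- sort(inertia_moments(Xc))
  rgyr <- sqrt(mean(rowSums(Xc^2)))
  gyr_eig <- eigen(crossprod(Xc) / n, symmetric = TRUE, only.values = TRUE)$values
  planarity <- if (sum(gyr_eig) > 0) min(gyr_eig) / sum(gyr_eig) else 0
  r_max <- if (n > 1) max(sqrt(rowSums(Xc^2))) else 0
  if (is.null(mol$mol_volume)) {
    mol$mol_volume <- molecular_volume(mol, n_points = volume_points)
  }
  mol$mol_features <- c(
    n_atoms = n,
    mass = sum(element_property(z, "mass")),
    volume = mol$mol_volume,
    I1 = Imom[1], I2 = Imom[2], I3 = Imom[3],
    r_gyr = rgyr,
    n_rings = count_rings(mol),
    n_rot_bonds = 0,
    n_donors = mol$n_donors,
    n_acceptors = mol$n_acceptors,
    planarity = planarity,
    r_max = r_max,
    frac_C = mean(z == 6L),
    frac_N = mean(z == 7L),
    frac_O = mean(z == 8L)
  )
  mol
}

#' Crystal packing coefficient
#'
#' The fraction of the unit-cell volume occupied by molecular vdW volume,
#' `Z * V_mol / V_cell`.  Density is a mass-weighted trivial transform:
#' `rho = Z * M / (N_A * V_cell)`.
#'
#' @param entry A [crystal_entry()].
#' @return Unitless packing coefficient.
#' @export
packing_coefficient <- function(entry) {
  V_cell <- cell_volume(entry$cell)
  if (V_cell <= 0) stop("zero or negative cell volume")
  if (is.null(entry$molecule$mol_volume)) {
    entry$molecule$mol_volume <- molecular_volume(entry$molecule)
  }
  entry$Z * entry$molecule$mol_volume / V_cell
}

#' Crystal mass density
#'
#' `Z * M / (N_A * V_cell)` in g/cm^3 — a trivial mass-weighted transform of
#' the packing coefficient.
#'
#' @param entry A [crystal_entry()].
#' @return Density in g/cm^3.
#' @export
crystal_density <- function(entry) {
  M <- sum(element_property(entry$molecule$atomic_numbers, "mass"))
  V_cell <- cell_volume(entry$cell)  # A^3
  entry$Z * M / (0.6022140857 * V_cell)
}

# ---- filter cascade -------------------------------------------------------

runtime_filter_names <- c("z_prime", "max_atoms", "max_atomic_number",
                          "z_range", "z_multiplicity", "packing_coefficient",
                          "overlapping_atoms")
processing_filter_names <- c("entry_empty", "missing_atoms", "z_prime",
                             "cell_valid")

#' Apply the crystal filter cascade
#'
#' Marks each entry pass/fail for every filter of the requested stage;
#' filters never throw.  The runtime stage enforces: Z' = 1, at most 100
#' atoms per molecule, maximum atomic number 100, 0 < Z <= 18, Z equal to
#' the general-position multiplicity of the stated space group, packing
#' coefficient strictly inside (0.55, 0.85), and no exactly overlapping
#' atoms.  An entry survives iff every applicable filter passes, so the
#' cascade is order-independent by construction.
#'
#' @param entries List of [crystal_entry()] objects.
#' @param stage `"processing"` or `"runtime"`.
#' @return A `filter_report`: a data frame of logical flags (one row per
#'   entry, one column per filter) with attribute `survivors` holding the
#'   identifiers that pass everything.
#' @export
apply_filters <- function(entries, stage = c("runtime", "processing")) {
  stage <- match.arg(stage)
  fnames <- if (stage == "runtime") runtime_filter_names else processing_filter_names
  flags <- matrix(TRUE, nrow = length(entries), ncol = length(fnames),
                  dimnames = list(NULL, fnames))
  ids <- character(length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    ids[i] <- e$identifier
    n <- length(e$molecule$atomic_numbers)
    if (stage == "processing") {
      flags[i, "entry_empty"] <- n > 0
      flags[i, "missing_atoms"] <- n > 0 && !anyNA(e$molecule$coords)
      flags[i, "z_prime"] <- isTRUE(e$z_prime == 1)
      flags[i, "cell_valid"] <- tryCatch(cell_volume(e$cell) > 0,
                                         error = function(err) FALSE)
    } else {
      flags[i, "z_prime"] <- isTRUE(e$z_prime == 1)
      flags[i, "max_atoms"] <- n <= 100
      flags[i, "max_atomic_number"] <- max(e$molecule$atomic_numbers) <= 100
      flags[i, "z_range"] <- e$Z > 0 && e$Z <= 18
      flags[i, "z_multiplicity"] <- e$Z == length(e$space_group$ops)
      cp <- tryCatch(packing_coefficient(e), error = function(err) NA_real_)
      flags[i, "packing_coefficient"] <- !is.na(cp) && cp > 0.55 && cp < 0.85
      all_xyz <- do.call(rbind, e$unit_cell_coords)
      flags[i, "overlapping_atoms"] <-
        nrow(all_xyz) < 2 || min(stats::dist(all_xyz)) > 1e-8
    }
  }
  rep <- as.data.frame(flags)
  rep <- cbind(identifier = ids, rep, stringsAsFactors = FALSE)
  attr(rep, "survivors") <- ids[rowSums(!flags) == 0]
  class(rep) <- c("filter_report", class(rep))
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report: %d entries, %d survive>\n",
              nrow(x), length(attr(x, "survivors"))))
  NextMethod()
}

# ---- CIF ------------------------------------------------------------------

# parse one "x, -y+1/2, z" style operator component
parse_symop_component <- function(s) {
  s <- gsub("\\s", "", tolower(s))
  w <- c(0, 0, 0); t <- 0
  # tokenise into signed terms
  toks <- regmatches(s, gregexpr("[+-]?[^+-]+", s))[[1]]
  for (tok in toks) {
    sign <- if (startsWith(tok, "-")) -1 else 1
    body <- sub("^[+-]", "", tok)
    if (body %in% c("x", "y", "z")) {
      w[match(body, c("x", "y", "z"))] <- w[match(body, c("x", "y", "z"))] + sign
    } else if (grepl("^[0-9]+/[0-9]+$", body)) {
      pq <- as.numeric(strsplit(body, "/")[[1]])
      t <- t + sign * pq[1] / pq[2]
    } else if (grepl("^[0-9.]+$", body)) {
      t <- t + sign * as.numeric(body)
    } else {
      stop("cannot parse symmetry operator token: ", tok)
    }
  }
  list(w = w, t = t)
}

#' Parse a symmetry operator string
#'
#' Converts an `"x, -y+1/2, z+1/2"` style general-position string into the
#' affine pair (W, t) acting on fractional coordinates.
#'
#' @param s Operator string with three comma-separated components.
#' @return List with 3x3 matrix `W` and length-3 translation `t`.
#' @export
parse_symop <- function(s) {
  comps <- strsplit(s, ",")[[1]]
  if (length(comps) != 3) stop("operator must have three components: ", s)
  parsed <- lapply(comps, parse_symop_component)
  list(W = do.call(rbind, lapply(parsed, `[[`, "w")),
       t = vapply(parsed, `[[`, numeric(1), "t"))
}

format_symop <- function(op) {
  fmt_t <- function(tv) {
    if (abs(tv) < 1e-9) return("")
    fr <- c(`0.5` = "1/2", `0.25` = "1/4", `0.75` = "3/4",
            `0.333333333333333` = "1/3", `0.666666666666667` = "2/3")
    key <- as.character(abs(tv))
    body <- if (key %in% names(fr)) fr[[key]] else format(abs(tv))
    paste0(if (tv < 0) "-" else "+", body)
  }
  comps <- character(3)
  for (i in 1:3) {
    parts <- character(0)
    for (j in 1:3) {
      w <- op$W[i, j]
      if (abs(w) > 1e-9) {
        parts <- c(parts, paste0(if (w < 0) "-" else if (length(parts)) "+" else "",
                                 c("x", "y", "z")[j]))
      }
    }
    comps[i] <- paste0(paste(parts, collapse = ""), fmt_t(op$t[i]))
  }
  paste(comps, collapse = ",")
}

strip_su <- function(x) as.numeric(sub("\\(.*\\)", "", x))

# tokenize a CIF data line respecting quoted strings
cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)
  toks <- regmatches(line, m)[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

#' Read a crystal from CIF
#'
#' Minimal CIF ingestion supporting the subset this package writes plus
#' typical small-molecule files: cell block, symmetry operator loop, and a
#' fractional atom-site loop.  The unit cell is expanded from the asymmetric
#' unit by the file's operators; molecule images are wrapped so their
#' centroids lie in the home cell.  Files written by [write_crystal_cif()]
#' in full-cell mode tag atoms with a molecule suffix and are re-grouped
#' from those tags.
#'
#' @param path CIF file path.
#' @param identifier Optional identifier override (default: data block name).
#' @return A [crystal_entry()].
#' @export
read_crystal_cif <- function(path, identifier = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  txt <- trimws(lines)

  grab <- function(tag) {
    hit <- grep(paste0("^", tag, "\\b"), txt, value = TRUE)
    if (!length(hit)) return(NA_character_)
    toks <- cif_tokens(hit[1])
    if (length(toks) < 2) NA_character_ else toks[2]
  }

  block <- grab("data_")
  if (is.null(identifier)) {
    dl <- grep("^data_", txt, value = TRUE)
    identifier <- if (length(dl)) sub("^data_", "", dl[1]) else "cif_entry"
  }

  cell <- c(strip_su(grab("_cell_length_a")), strip_su(grab("_cell_length_b")),
            strip_su(grab("_cell_length_c")), strip_su(grab("_cell_angle_alpha")),
            strip_su(grab("_cell_angle_beta")), strip_su(grab("_cell_angle_gamma")))
  if (anyNA(cell)) stop("incomplete CIF entry: missing cell parameters")

  sg_symbol <- grab("_symmetry_space_group_name_H-M")
  if (is.na(sg_symbol)) sg_symbol <- grab("_space_group_name_H-M_alt")
  if (is.na(sg_symbol)) sg_symbol <- "P1"

  # loops
  loops <- list()
  i <- 1
  while (i <= length(txt)) {
    if (txt[i] == "loop_") {
      j <- i + 1
      tags <- character(0)
      while (j <= length(txt) && grepl("^_", txt[j])) {
        tags <- c(tags, cif_tokens(txt[j])[1]); j <- j + 1
      }
      rows <- list()
      while (j <= length(txt) && nzchar(txt[j]) &&
             !grepl("^(_|loop_|data_)", txt[j])) {
        rows[[length(rows) + 1]] <- cif_tokens(txt[j]); j <- j + 1
      }
      loops[[length(loops) + 1]] <- list(tags = tags, rows = rows)
      i <- j
    } else i <- i + 1
  }

  find_loop <- function(tag) {
    for (lp in loops) if (tag %in% lp$tags) return(lp)
    NULL
  }

  symloop <- find_loop("_symmetry_equiv_pos_as_xyz")
  if (is.null(symloop)) symloop <- find_loop("_space_group_symop_operation_xyz")
  ops <- if (!is.null(symloop)) {
    col <- which(symloop$tags %in% c("_symmetry_equiv_pos_as_xyz",
                                     "_space_group_symop_operation_xyz"))
    lapply(symloop$rows, function(r) {
      parse_symop(paste(r[col:length(r)], collapse = " "))
    })
  } else list(parse_symop("x,y,z"))

  siteloop <- find_loop("_atom_site_fract_x")
  if (is.null(siteloop)) stop("incomplete CIF entry: missing atom sites")
  tagidx <- function(tag) match(tag, siteloop$tags)
  il <- tagidx("_atom_site_label"); it <- tagidx("_atom_site_type_symbol")
  ix <- tagidx("_atom_site_fract_x"); iy <- tagidx("_atom_site_fract_y")
  iz <- tagidx("_atom_site_fract_z")
  labels <- vapply(siteloop$rows, function(r) r[if (is.na(il)) it else il], "")
  syms <- vapply(siteloop$rows, function(r) r[if (is.na(it)) il else it], "")
  frac <- t(vapply(siteloop$rows,
                   function(r) strip_su(r[c(ix, iy, iz)]), numeric(3)))
  if (anyNA(frac)) stop("incomplete CIF entry: unreadable atom sites")
  z <- symbol_to_z(syms)

  M <- cell_matrix(cell[1], cell[2], cell[3], cell[4], cell[5], cell[6])

  mol_tags <- sub("^.*_m([0-9]+)$", "\\1", labels)
  tagged <- grepl("_m[0-9]+$", labels)
  if (all(tagged) && length(unique(mol_tags)) > 1) {
    # full-cell serialization: molecules identified by label suffix
    groups <- split(seq_along(labels), as.integer(mol_tags))
    mols <- lapply(groups, function(idx) frac_to_cart(frac[idx, , drop = FALSE], M))
    zz <- z[groups[[1]]]
    sg <- space_group(sg_symbol, ops)
  } else {
    sg <- space_group(sg_symbol, ops)
    mols <- lapply(ops, function(op) {
      f <- sweep(frac %*% t(op$W), 2, op$t, "+")
      ctr <- colMeans(f)
      f <- sweep(f, 2, ctr - (ctr %% 1))  # wrap molecule centroid into cell
      frac_to_cart(f, M)
    })
    zz <- z
  }
  mol <- molecule_record(zz, mols[[1]], identifier = identifier)
  crystal_entry(mol, cell, sg, mols, identifier = identifier)
}

#' Write a crystal to CIF
#'
#' @param entry A [crystal_entry()].
#' @param path Output path.
#' @param mode `"asymmetric"` writes the first molecule plus the symmetry
#'   operator loop; `"full"` writes every molecule explicitly with identity
#'   symmetry and molecule-index labels.  Both serializations re-expand to
#'   the same unit cell under [read_crystal_cif()].
#' @return Invisibly, `path`.
#' @export
write_crystal_cif <- function(entry, path, mode = c("asymmetric", "full")) {
  mode <- match.arg(mode)
  if (cell_volume(entry$cell) <= 0) stop("refusing to write zero-volume cell")
  M <- do.call(cell_matrix, as.list(entry$cell))
  sym <- element_property(entry$molecule$atomic_numbers, "symbol")
  out <- c(
    sprintf("data_%s", gsub("\\s", "_", entry$identifier)),
    sprintf("_cell_length_a %.8f", entry$cell[1]),
    sprintf("_cell_length_b %.8f", entry$cell[2]),
    sprintf("_cell_length_c %.8f", entry$cell[3]),
    sprintf("_cell_angle_alpha %.8f", entry$cell[4]),
    sprintf("_cell_angle_beta %.8f", entry$cell[5]),
    sprintf("_cell_angle_gamma %.8f", entry$cell[6])
  )
  if (mode == "asymmetric") {
    out <- c(out,
             sprintf("_symmetry_space_group_name_H-M '%s'", entry$space_group$symbol),
             "loop_", "_symmetry_equiv_pos_as_xyz",
             vapply(entry$space_group$ops,
                    function(op) sprintf("'%s'", format_symop(op)), ""),
             "loop_", "_atom_site_label", "_atom_site_type_symbol",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
    f <- cart_to_frac(entry$unit_cell_coords[[1]], M)
    for (i in seq_len(nrow(f))) {
      out <- c(out, sprintf("%s%d %s %.8f %.8f %.8f", sym[i], i, sym[i],
                            f[i, 1], f[i, 2], f[i, 3]))
    }
  } else {
    out <- c(out,
             "_symmetry_space_group_name_H-M 'P1'",
             "loop_", "_symmetry_equiv_pos_as_xyz", "'x,y,z'",
             "loop_", "_atom_site_label", "_atom_site_type_symbol",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
    for (m in seq_along(entry$unit_cell_coords)) {
      f <- cart_to_frac(entry$unit_cell_coords[[m]], M)
      for (i in seq_len(nrow(f))) {
        out <- c(out, sprintf("%s%d_m%d %s %.8f %.8f %.8f", sym[i], i, m,
                              sym[i], f[i, 1], f[i, 2], f[i, 3]))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a bare conformer from an XYZ file
#'
#' @param path XYZ file path.
#' @return A [molecule_record()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  body <- lines[3:(2 + n)]
  toks <- strsplit(trimws(body), "\\s+")
  z <- symbol_to_z(vapply(toks, `[[`, "", 1))
  xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  molecule_record(z, xyz, identifier = trimws(lines[2]))
}

#' Write a conformer to an XYZ file
#'
#' @param mol A [molecule_record()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(mol, path) {
  sym <- element_property(mol$atomic_numbers, "symbol")
  writeLines(c(
    as.character(length(mol$atomic_numbers)),
    mol$identifier,
    sprintf("%s %.8f %.8f %.8f", sym, mol$coords[, 1], mol$coords[, 2],
            mol$coords[, 3])
  ), path)
  invisible(path)
}

#' Read a conformer from an SDF/MOL (V2000) file
#'
#' Only the atom block is used; bonds and properties are ignored because the
#' downstream models are purely geometric.
#'
#' @param path SDF file path.
#' @return A [molecule_record()].
#' @export
read_sdf_conformer <- function(path) {
  lines <- readLines(path, warn = FALSE)
  counts <- lines[4]
  n <- as.integer(substr(counts, 1, 3))
  if (is.na(n) || n < 1) stop("unreadable SDF counts line")
  body <- lines[5:(4 + n)]
  toks <- strsplit(trimws(body), "\\s+")
  xyz <- t(vapply(toks, function(tk) as.numeric(tk[1:3]), numeric(3)))
  z <- symbol_to_z(vapply(toks, `[[`, "", 4))
  molecule_record(z, xyz, identifier = trimws(lines[1]))
}
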