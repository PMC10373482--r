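# Element property tables covering atomic numbers 1..100.
#
# Values for common organic/organometallic elements are tabulated
# (Bondi-style vdW radii, Pauling electronegativities, Cordero-style
# covalent radii, standard atomic weights); rarer elements fall back to
# smooth defaults so the featurizer never fails for Z <= 100.  The vdW
# table here is the single source of truth shared by the molecular
# volume estimator and the vdW overlap score.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm"
)

.element_table <- local({
  z <- seq_len(100)
  period <- findInterval(z, c(1, 3, 11, 19, 37, 55, 87))
  # group number (1..18); lanthanides/actinides folded to group 3
  grp <- integer(100)
  grp[1] <- 1; grp[2] <- 18
  grp[3:10] <- c(1, 2, 13:18)
  grp[11:18] <- c(1, 2, 13:18)
  grp[19:36] <- c(1, 2, 3:12, 13:18)
  grp[37:54] <- c(1, 2, 3:12, 13:18)
  grp[55:86] <- c(1, 2, rep(3L, 15), 4:12, 13:18)
  grp[87:100] <- c(1, 2, rep(3L, 12))

  en <- rep(1.6, 100)  # default: typical metal electronegativity
  known_en <- c(
    `1` = 2.20, `3` = 0.98, `4` = 1.57, `5` = 2.04, `6` = 2.55,
    `7` = 3.04, `8` = 3.44, `9` = 3.98, `11` = 0.93, `12` = 1.31,
    `13` = 1.61, `14` = 1.90, `15` = 2.19, `16` = 2.58, `17` = 3.16,
    `19` = 0.82, `20` = 1.00, `26` = 1.83, `29` = 1.90, `30` = 1.65,
    `35` = 2.96, `53` = 2.66
  )
  en[as.integer(names(known_en))] <- known_en
  en[c(2, 10, 18, 36, 54, 86)] <- 0  # noble gases: undefined, set 0

  rcov <- rep(1.50, 100)
  known_rcov <- c(
    `1` = 0.31, `5` = 0.84, `6` = 0.76, `7` = 0.71, `8` = 0.66,
    `9` = 0.57, `14` = 1.11, `15` = 1.07, `16` = 1.05, `17` = 1.02,
    `26` = 1.32, `29` = 1.32, `30` = 1.22, `35` = 1.20, `53` = 1.39
  )
  rcov[as.integer(names(known_rcov))] <- known_rcov

  rvdw <- rep(2.00, 100)
  known_rvdw <- c(
    `1` = 1.20, `2` = 1.40, `5` = 1.92, `6` = 1.70, `7` = 1.55,
    `8` = 1.52, `9` = 1.47, `10` = 1.54, `11` = 2.27, `12` = 1.73,
    `14` = 2.10, `15` = 1.80, `16` = 1.80, `17` = 1.75, `18` = 1.88,
    `19` = 2.75, `29` = 1.40, `30` = 1.39, `35` = 1.85, `53` = 1.98,
    `54` = 2.16
  )
  rvdw[as.integer(names(known_rvdw))] <- known_rvdw

  mass <- 2.2 * z  # fallback trend; exact values below for common elements
  known_mass <- c(
    `1` = 1.008, `5` = 10.81, `6` = 12.011, `7` = 14.007, `8` = 15.999,
    `9` = 18.998, `14` = 28.085, `15` = 30.974, `16` = 32.06,
    `17` = 35.45, `26` = 55.845, `29` = 63.546, `30` = 65.38,
    `35` = 79.904, `53` = 126.904
  )
  mass[as.integer(names(known_mass))] <- known_mass

  data.frame(
    z = z, symbol = .element_symbols, period = period, group = grp,
    electronegativity = en, covalent_radius = rcov, vdw_radius = rvdw,
    mass = mass, stringsAsFactors = FALSE
  )
})

#' Element properties by atomic number
#'
#' Lookup of bundled element properties for atomic numbers 1..100.
#'
#' @param z Integer vector of atomic numbers (1..100).
#' @param what Column name: one of `"symbol"`, `"period"`, `"group"`,
#'   `"electronegativity"`, `"covalent_radius"`, `"vdw_radius"`, `"mass"`.
#' @return Vector of the requested property, same length as `z`.
#' @examples
#' element_property(6, "vdw_radius")
#' @export
element_property <- function(z, what) {
  if (!what %in% names(.element_table)) {
    stop("unknown element property: ", what)
  }
  if (any(z < 1 | z > 100 | z != as.integer(z))) {
    stop("atomic numbers must be integers in 1..100")
  }
  .element_table[[what]][z]
}

#' van der Waals radii table
#'
#' The bundled Bondi-style vdW radius for each element, used both in the
#' molecular volume estimator and in the vdW overlap score.
#'
#' @param z Integer vector of atomic numbers.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function(z) element_property(z, "vdw_radius")

# symbol -> atomic number (case-normalized)
symbol_to_z <- function(sym) {
  sym <- sub("[0-9+'\\-].*$", "", sym)  # strip trailing labels like "C1"
  idx <- match(toupper(sym), toupper(.element_symbols))
  if (anyNA(idx)) stop("unknown element symbol(s): ",
                       paste(unique(sym[is.na(idx)]), collapse = ", "))
  idx
}
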