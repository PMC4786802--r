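#' @keywords internal
"_PACKAGE"

# Standard atomic weights (abridged IUPAC 2021) for the elements that occur
# in protein/ligand work; used for mass-weighted centroids.
.atomic_weights <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904,
  Na = 22.990, K = 39.098, Mg = 24.305, Ca = 40.078, Zn = 65.38,
  Fe = 55.845, Mn = 54.938, Se = 78.971, B = 10.81, Si = 28.085
)

# Monoisotopic masses of the most abundant isotope (IUPAC/AME2020),
# the arithmetic behind "calcd" high-resolution MS values.
.monoisotopic_masses <- c(
  H = 1.00782503207, D = 2.01410177785, C = 12.0, N = 14.0030740048,
  O = 15.9949146196, S = 31.97207100, P = 30.97376163, F = 18.99840322,
  Cl = 34.96885268, Br = 78.9183371, I = 126.904473, Na = 22.9897692809,
  K = 38.96370668, Mg = 23.98504170, Ca = 39.96259098, Zn = 63.9291422,
  Fe = 55.9349375, Mn = 54.9380451, Se = 79.9165213, B = 11.0093054,
  Si = 27.9769265325
)

# van der Waals radii (Angstrom) used by the accessible-surface quadrature.
.default_vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Se = 1.90
)

#' Load a van der Waals radii table
#'
#' Radii drive the solvent-accessible surface quadrature. The built-in
#' defaults (C 1.70, N 1.55, O 1.52, S 1.80 A) can be overridden with a
#' JSON file mapping element symbols to radii in Angstrom.
#'
#' @param path Optional path to a JSON file of element-to-radius pairs.
#' @return Named numeric vector of radii (Angstrom).
#' @export
vdw_radii <- function(path = NULL) {
  r <- .default_vdw_radii
  if (!is.null(path)) {
    user <- unlist(jsonlite::fromJSON(path))
    if (!is.numeric(user) || is.null(names(user)))
      stop("radii file must map element symbols to numeric radii")
    r[names(user)] <- user
  }
  r
}

# Guess the element from a PDB atom name when columns 77-78 are blank.
# Two-letter elements among the common set are recognised; everything
# else falls back to the first alphabetic character.
.element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  known2 <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "SE")
  ifelse(nchar(nm) >= 2 & two %in% known2 & substr(name, 1, 1) != " ",
         paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))),
         substr(nm, 1, 1))
}

.normalise_element <- function(el) {
  el <- gsub("\\s", "", el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}
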