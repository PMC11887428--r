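## Element tables used across the package.
##
## masses: principal-isotope (monoisotopic) masses in Da.
## r_cov:  covalent radii (Cordero et al. 2008 consensus values), Angstrom;
##         used for distance-based bond perception and harmonic bond r0.
## r_vdw:  van der Waals radii (Bondi), Angstrom; used for the projection
##         approximation disks and intramolecular 12-6 terms.
## chi/eta: Mulliken electronegativity and hardness, eV, used by the
##         electronegativity-equalisation partial charge scheme.

.ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "P", "S", "Cl"),
  number = c(1, 6, 7, 8, 9, 15, 16, 17),
  mass = c(1.00782503, 12.0, 14.0030740, 15.9949146,
           18.9984032, 30.9737615, 31.9720707, 34.9688527),
  r_cov = c(0.31, 0.76, 0.71, 0.66, 0.57, 1.07, 1.05, 1.02),
  r_vdw = c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75),
  chi_eV = c(7.18, 6.26, 7.23, 7.54, 10.41, 5.62, 6.22, 8.30),
  eta_eV = c(6.42, 5.00, 7.27, 6.08, 7.01, 4.88, 4.14, 4.68),
  stringsAsFactors = FALSE
)

EV_TO_KCAL <- 23.0609

element_row <- function(symbol) {
  idx <- match(symbol, .ELEMENTS$symbol)
  if (anyNA(idx)) {
    bad <- unique(symbol[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  .ELEMENTS[idx, , drop = FALSE]
}

#' Element property table
#'
#' Returns the bundled element table (monoisotopic masses, covalent and
#' van der Waals radii, electronegativity-equalisation parameters) used
#' throughout the package.
#'
#' @return A data frame with one row per supported element.
#' @export
element_table <- function() .ELEMENTS
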