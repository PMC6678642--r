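#' Default atom-type vocabulary
#'
#' The 22 drug-relevant elements that occupy named slots of the 23-wide
#' atom-type one-hot block; any other element falls into the trailing
#' `"other"` slot. The membership is configurable wherever a `vocab`
#' argument is accepted, but the block width is fixed at 23.
#'
#' @return Character vector of 22 element symbols.
#' @export
default_element_vocab <- function() {
  c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "B", "Si",
    "Se", "Li", "Na", "K", "Mg", "Ca", "Zn", "Fe", "Cu", "Mn")
}

# van der Waals radii (Bondi 1964 / Mantina 2009 extensions) and single-bond
# covalent radii (Cordero 2008), in Angstrom. Elements missing from the table
# get the "other" defaults below.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10, Se = 1.90,
  Li = 1.82, Na = 2.27, K = 2.75, Mg = 1.73, Ca = 2.31, Zn = 1.39,
  Fe = 2.04, Cu = 1.40, Mn = 2.05)

.cov_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07, S = 1.05,
  Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84, Si = 1.11, Se = 1.20,
  Li = 1.28, Na = 1.66, K = 2.03, Mg = 1.41, Ca = 1.76, Zn = 1.22,
  Fe = 1.32, Cu = 1.32, Mn = 1.39)

.other_vdw <- 2.00
.other_cov <- 1.50

# typical heavy-atom valences used by the synthetic molecule generator
.valences <- c(H = 1, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
               Cl = 1, Br = 1, I = 1, B = 3, Si = 4, Se = 2)

#' Van der Waals and covalent radii lookup
#'
#' @param elements character vector of element symbols.
#' @return data.frame with columns `vdw` and `covalent` (Angstrom).
#' @export
element_radii <- function(elements) {
  vdw <- unname(.vdw_radii[elements])
  cov <- unname(.cov_radii[elements])
  vdw[is.na(vdw)] <- .other_vdw
  cov[is.na(cov)] <- .other_cov
  data.frame(vdw = vdw, covalent = cov)
}
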