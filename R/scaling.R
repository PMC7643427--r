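#' Monomer MSD exponent of a Rouse chain
#'
#' A connected polymer segment diffusing a distance must drag the
#' neighbouring segments along, which makes monomer motion subdiffusive.
#' The scaling argument gives an MSD exponent
#' \deqn{\alpha = \frac{2\nu}{1 + 2\nu}}
#' where nu is the Flory exponent governing how the chain's radius of
#' gyration grows with length (`R_g ~ N^nu`).  The ideal (phantom) chain
#' has nu = 1/2 and alpha = 1/2; excluded volume in good solvent swells
#' the chain (mean-field nu = 3/5, refined nu ~ 0.588) so fewer monomers
#' are dragged and alpha rises to about 0.54.
#'
#' @param nu Flory exponent, in (0, 1].
#' @return the MSD exponent alpha.
#' @examples
#' rouse_exponent(1/2)    # 0.5, ideal Rouse chain
#' rouse_exponent(3/5)    # 6/11 ~ 0.545
#' rouse_exponent(0.588)  # ~0.540
#' @export
rouse_exponent <- function(nu) {
  if (!is.numeric(nu) || any(!is.finite(nu)) || any(nu <= 0) || any(nu > 1))
    stop("nu must lie in (0, 1]")
  2 * nu / (1 + 2 * nu)
}

#' Reference monomer MSD exponents
#'
#' The standard anchors for interpreting fitted chromatin MSD exponents:
#' the ideal Rouse chain, the excluded-volume chain at the mean-field
#' and refined Flory exponents (both computed via [rouse_exponent()]),
#' and the semi-flexible polymer value alpha = 3/4, which is a literature
#' constant (its derivation involves bending rigidity, outside the
#' Rouse scaling argument) rather than a computed entry.
#'
#' @return data.frame with columns `label`, `nu`, `alpha`, `source`.
#' @export
reference_exponents <- function() {
  data.frame(
    label = c("ideal Rouse", "excluded volume (mean-field)",
              "excluded volume (refined)", "semi-flexible"),
    nu = c(1 / 2, 3 / 5, 0.588, NA_real_),
    alpha = c(rouse_exponent(1 / 2), rouse_exponent(3 / 5),
              rouse_exponent(0.588), 3 / 4),
    source = c("computed", "computed", "computed", "literature constant"),
    stringsAsFactors = FALSE)
}
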