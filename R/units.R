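# unit conversions

#' Concentration of one bead per cubic nanometre, in mM
#'
#' `1 / nm^3 = 1e27 / N_A mol/L`, i.e. about 1660.5 mM.  All conversions
#' between bead counts and molar concentrations go through this constant.
#' @keywords internal
.MM_PER_INV_NM3 <- 1e27 / 6.02214076e23

#' Convert a sticker count in a box to a molar concentration
#'
#' @param count number of stickers (non-negative).
#' @param box either a numeric vector of three box edge lengths in nm, or a
#'   single volume in nm^3.
#' @return concentration in mM.
#' @examples
#' stickers_to_mM(2500, c(250, 50, 50))  # 6.64 mM
#' @export
stickers_to_mM <- function(count, box) {
  if (any(count < 0)) stop("count must be >= 0")
  vol <- if (length(box) == 3L) prod(box) else box[[1L]]
  if (!is.finite(vol) || vol <= 0) stop("box volume must be positive")
  count / vol * .MM_PER_INV_NM3
}

#' Convert a molar concentration to a number density
#'
#' @param c_mM concentration in mM.
#' @return number density in beads / nm^3.
#' @keywords internal
mM_to_per_nm3 <- function(c_mM) c_mM / .MM_PER_INV_NM3
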