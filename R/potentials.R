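# pair potentials of the coarse-grained model
#
# Three interactions define the model:
#   cross_attract : finite-ranged attraction between beads of different type,
#                   U(r) = -U0 cos^2(pi r / (2 r_att)),  r < r_att.
#                   Smooth well of depth U0 at contact (r = 0), vanishing with
#                   zero slope at the cutoff r_att = 0.8 * sticker_diameter.
#   same_repel    : soft repulsion between beads of the same type,
#                   U(r) = (E_rep / 2) (1 + cos(pi r / r_rep)),  r < r_rep,
#                   with r_rep = 1.5 * sticker_diameter.  Its role is steric:
#                   it prevents a second A bead from reaching a B bead that is
#                   already bound (one-to-one binding).
#   harmonic_bond : linker between consecutive stickers of a chain,
#                   U(r) = 0.5 k (r - r0)^2 with r0 the mean linker length.
#
# The attraction cutoff 0.8 * sigma is a frozen calibration: with
# sigma = 2.5 nm it makes the two-particle dissociation constant at well depth
# 9 kT equal to 0.4 mM (see dissociation_constant_from_potential).

#' Pair potential of the coarse-grained model
#'
#' @param r separation in nm (scalar or vector, non-negative).
#' @param kind one of `"cross_attract"`, `"same_repel"`, `"harmonic_bond"`.
#' @param spec a [simulation_spec()] supplying the geometric parameters.
#' @return energy in kT, vectorised over `r`.
#' @examples
#' sp <- simulation_spec(valence_A = 2, valence_B = 2, count_A = 1, count_B = 1,
#'                       box = c(20, 20, 20), U0 = 9)
#' pair_potential(0, "cross_attract", sp)  # -9
#' @export
pair_potential <- function(r, kind = c("cross_attract", "same_repel",
                                       "harmonic_bond"), spec) {
  kind <- match.arg(kind)
  if (any(r < 0)) stop("separation r must be >= 0")
  switch(kind,
    cross_attract = {
      rc <- spec$r_att
      ifelse(r < rc, -spec$U0 * cos(pi * r / (2 * rc))^2, 0)
    },
    same_repel = {
      rr <- spec$r_rep
      ifelse(r < rr, 0.5 * spec$E_rep * (1 + cos(pi * r / rr)), 0)
    },
    harmonic_bond = 0.5 * spec$bond_stiffness * (r - spec$mean_linker_length)^2
  )
}

#' Geometric bond criterion
#'
#' The default distance cutoff used to call an A-B sticker pair "bound": the
#' outer inflection point of the attraction well, `r_att / 2`, where the well
#' is at half depth.  Inside this radius the same-type repulsion makes double
#' occupancy of a sticker prohibitively costly.
#'
#' @param spec a [simulation_spec()].
#' @return cutoff distance in nm.
#' @export
bond_cutoff <- function(spec) spec$r_att / 2

#' Sticker-sticker dissociation constant from the pair potential
#'
#' Computes the two-particle dissociation constant of the cross-type
#' attraction as the inverse of the bound-state configurational integral
#' \deqn{K_d^{-1} = \int_0^{r_{att}} e^{-U(r)} 4 \pi r^2 \, dr,}
#' converted to mM.  The bound region is the full attraction well (up to the
#' cutoff).  At the default geometry (`sticker_diameter = 2.5` nm, cutoff
#' `0.8 * sigma = 2` nm) a well depth of 9 kT gives 0.4 mM.
#'
#' @param spec a [simulation_spec()]; only the attraction geometry is used.
#' @param U0 well depth in kT; defaults to `spec$U0`.
#' @return dissociation constant in mM.
#' @examples
#' sp <- simulation_spec(valence_A = 1, valence_B = 1, count_A = 1, count_B = 1,
#'                       box = c(50, 50, 50), U0 = 9)
#' dissociation_constant_from_potential(sp)  # ~0.4 mM
#' @export
dissociation_constant_from_potential <- function(spec, U0 = spec$U0) {
  if (U0 < 0) stop("U0 must be >= 0")
  rc <- spec$r_att
  I <- stats::integrate(function(r) exp(U0 * cos(pi * r / (2 * rc))^2) *
                          4 * pi * r^2,
                        lower = 0, upper = rc, rel.tol = 1e-12)$value
  if (!is.finite(I) || I <= 0) stop("bound-state integral is not finite")
  .MM_PER_INV_NM3 / I
}
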