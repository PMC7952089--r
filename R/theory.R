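# Dimer-gel mean-field theory of two-component associative polymers.
#
# A chains carry L1 stickers, B chains L2 (L1 >= L2).  Stickers bind
# one-to-one.  Polymers associate either as whole-chain dimers (dissociation
# constant Kd, polymeric mM) or as independent sticker-sticker bonds
# (dissociation constant Kb, mM); nonspecific interactions enter through a
# two-body (vb_ns, 1/mM) and three-body (wb_ns, 1/mM^2) repulsion acting on
# the majority sticker concentration.  The free-energy density per kT
# (concentrations in mM) is F = F_ni + F_s + F_ns with
#
#   F_ni = (c1/L1) ln(c1/(e L1)) + (c2/L2) ln(c2/(e L2))
#
#   F_s  = -x(r1) - x(r2) + rd ln(e Kd rd) + x(r1 - rd) + x(r2 - rd)
#          - x(q1) - x(q2) + cb ln(e Kb cb) + x(h1) + x(h2)
#
# where x(t) = t ln t (continuous at 0), r_i = c_i / L_i, rd = cd1/L1 =
# cd2/L2 is the dimer concentration, q_i = c_i - cd_i, cb the independent
# bond concentration, h_i = q_i - cb, and
#
#   F_ns = (vb_ns/2) max(c1,c2)^2 + (wb_ns/6) max(c1,c2)^3.
#
# Minimising F_s over (rd, cb) yields the mass-action stationarity
# conditions; with bonds (dimers) switched off they reduce to the elementary
# dimer (bond) mass-action laws.

#' Dimer-gel theory parameters
#'
#' @param L1,L2 valences of the two species, `L1 >= L2 >= 1`.
#' @param Kb sticker-pair dissociation constant in mM (default 3.8e-3, the
#'   strong-binding value used for the reference phase diagrams).
#' @param Kd whole-dimer dissociation constant in polymeric mM.  Default is
#'   the synthetic zipping-model estimate [dimer_kd()] (the reference values
#'   extracted from simulation are not bundled with the package).
#' @param vb_ns,wb_ns two- and three-body nonspecific interaction parameters
#'   (1/mM, 1/mM^2); defaults 9e-2 and 7e-3.
#' @return object of class `theory_params`.
#' @export
theory_params <- function(L1, L2, Kb = 3.8e-3, Kd = dimer_kd(L1, L2, Kb),
                          vb_ns = 9e-2, wb_ns = 7e-3) {
  stopifnot(L1 >= L2, L2 >= 1, Kd > 0, Kb > 0, vb_ns >= 0, wb_ns >= 0)
  structure(list(L1 = L1, L2 = L2, Kd = Kd, Kb = Kb,
                 vb_ns = vb_ns, wb_ns = wb_ns),
            class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat(sprintf("dimer-gel theory: L1 = %g, L2 = %g, Kd = %.4g mM, Kb = %.4g mM, vb = %g /mM, wb = %g /mM^2\n",
              x$L1, x$L2, x$Kd, x$Kb, x$vb_ns, x$wb_ns))
  invisible(x)
}

#' Synthetic zipping-model estimate of the dimer dissociation constant
#'
#' Stand-in for dimer dissociation constants fitted from simulation.  A dimer
#' forms by one bimolecular sticker contact (constant `Kb`) followed by
#' `Lb - 1` intramolecular closures, each with equilibrium constant
#' `kappa / Kb` where `kappa` is the local concentration one tethered sticker
#' presents to its partner; a `g = L1 - L2 + 1` register multiplicity for
#' unequal valences:
#' \deqn{K_d = K_b^{L_b} / (g \, \kappa^{L_b - 1}), \quad L_b = \min(L_1, L_2).}
#'
#' @param L1,L2 valences.
#' @param Kb sticker-pair dissociation constant, mM.
#' @param kappa closure local concentration in mM; default
#'   [closure_local_concentration()] evaluated for the model geometry.
#' @return dimer dissociation constant in polymeric mM.
#' @export
dimer_kd <- function(L1, L2, Kb = 3.8e-3, kappa = closure_local_concentration()) {
  Lb <- min(L1, L2)
  g <- abs(L1 - L2) + 1
  exp(Lb * log(Kb) - (Lb - 1) * log(kappa) - log(g))
}

#' Closure local concentration of the zipping model
#'
#' Effective concentration at which the next sticker of a partially zipped
#' dimer sees its partner.  Both stickers sit at the end of a spacer of
#' length `r0` attached to the previously bound (co-located) pair; treating
#' the spacers as rigid and isotropic, the separation `d` of the two next
#' stickers has density `d / (2 r0^2)` on `[0, 2 r0]`, and the
#' Boltzmann-weighted closure constant relative to the bimolecular one is
#' \deqn{\kappa = C_0 \frac{\int_0^{r_c} e^{-U(d)} \, d/(2 r0^2)\, dd}
#'                        {\int_0^{r_c} e^{-U(d)} 4 \pi d^2 \, dd}}
#' with `C0` the 1/nm^3 concentration unit.  The spacer used is the
#' binding-correlation-length rescaled segment `ell_corr * linker` (1.8 x
#' 4.7 nm by default), matching the coarse-graining at which stickers bind
#' independently.
#'
#' @param linker bare linker length in nm (default 4.7).
#' @param ell_corr binding correlation length in stickers (default 1.8).
#' @param U0 well depth used for the weighting; default the depth equivalent
#'   to `Kb = 3.8e-3` mM (about 14.5 kT).
#' @param sticker_diameter bead diameter in nm (default 2.5).
#' @return local concentration in mM.
#' @export
closure_local_concentration <- function(linker = 4.7, ell_corr = 1.8,
                                        U0 = NULL, sticker_diameter = 2.5) {
  rc <- 0.8 * sticker_diameter
  if (is.null(U0)) {
    kd1 <- function(u) {
      I <- stats::integrate(function(r) exp(u * cos(pi * r / (2 * rc))^2) *
                              4 * pi * r^2, 0, rc, rel.tol = 1e-10)$value
      .MM_PER_INV_NM3 / I
    }
    U0 <- stats::uniroot(function(u) log(kd1(u)) - log(3.8e-3),
                         c(5, 30), tol = 1e-9)$root
  }
  r0 <- ell_corr * linker
  w <- function(d) exp(U0 * cos(pi * d / (2 * rc))^2)
  num <- stats::integrate(function(d) w(d) * d / (2 * r0^2), 0, rc,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(function(d) w(d) * 4 * pi * d^2, 0, rc,
                          rel.tol = 1e-10)$value
  .MM_PER_INV_NM3 * num / den
}

.xlx <- function(t) ifelse(t > 0, t * log(t), 0)

#' Non-interacting (ideal) free-energy density
#'
#' `(c1/L1) ln(c1/(e L1)) + (c2/L2) ln(c2/(e L2))`, continuous at zero
#' concentration.  Units kT * mM.
#'
#' @param c1,c2 sticker concentrations in mM (vectorised).
#' @param p a [theory_params()].
#' @return numeric.
#' @export
f_noninteracting <- function(c1, c2, p) {
  r1 <- c1 / p$L1; r2 <- c2 / p$L2
  # c/(e L) = rho/e, so F_ni = rho1 ln(rho1/e) + rho2 ln(rho2/e)
  .xlx(r1) - r1 + .xlx(r2) - r2
}

#' Association state of the dimer-gel free energy
#'
#' Minimises the specific free energy over the dimer concentration
#' `rho_d = cd1/L1 = cd2/L2` and the independent-bond concentration `cb`
#' inside the feasible simplex.  Newton iterations are run from a
#' dimer-leaning and a bond-leaning start (the landscape can be bistable in
#' the strong-binding regime) and the lower-free-energy solution is
#' returned; stationarity residuals of the two mass-action conditions are
#' reported.
#'
#' @param c1,c2 sticker concentrations in mM (scalars).
#' @param p a [theory_params()].
#' @return object of class `association_state`: list with `cd1`, `cd2`
#'   (stickers in dimers, mM), `cb` (independent bonds, mM), `rho_d`
#'   (dimers, polymeric mM), `fs` (specific free energy, kT mM), and
#'   `residuals` (the two stationarity residuals).
#' @export
solve_association <- function(c1, c2, p) {
  stopifnot(c1 >= 0, c2 >= 0)
  m <- .assoc_solve_cpp(c1, c2, p$L1, p$L2, p$Kd, p$Kb)
  if (m[1, "converged"] < 1)
    stop(sprintf(paste0("association solver did not converge at c1 = %g, ",
                        "c2 = %g (residuals %.3g, %.3g)"),
                 c1, c2, m[1, "res1"], m[1, "res2"]))
  rd <- unname(m[1, "rho_d"])
  structure(list(cd1 = rd * p$L1, cd2 = rd * p$L2, cb = unname(m[1, "cb"]),
                 rho_d = rd, fs = unname(m[1, "fs"]),
                 residuals = unname(c(m[1, "res1"], m[1, "res2"]))),
            class = "association_state")
}

#' Specific (associative) free-energy density
#'
#' Evaluates the specific free energy at an arbitrary feasible association
#' state (not necessarily the minimiser).
#'
#' @param c1,c2 sticker concentrations, mM.
#' @param state an [solve_association()] result, or a list with `rho_d` and
#'   `cb`.
#' @param p a [theory_params()].
#' @return free energy in kT * mM.
#' @export
f_specific <- function(c1, c2, state, p) {
  rd <- state$rho_d; cb <- state$cb
  r1 <- c1 / p$L1; r2 <- c2 / p$L2
  q1 <- c1 - p$L1 * rd; q2 <- c2 - p$L2 * rd
  h1 <- q1 - cb; h2 <- q2 - cb
  tol <- 1e-9 * max(c1, c2, 1)
  if (rd < 0 || cb < 0 || min(q1, q2, h1, h2) < -tol)
    stop("association state outside the feasible region")
  q1 <- max(q1, 0); q2 <- max(q2, 0); h1 <- max(h1, 0); h2 <- max(h2, 0)
  out <- -.xlx(r1) - .xlx(r2) +
    .xlx(r1 - max(rd, 0)) + .xlx(r2 - max(rd, 0)) -
    .xlx(q1) - .xlx(q2) + .xlx(h1) + .xlx(h2)
  if (rd > 0) out <- out + rd * log(p$Kd) + .xlx(rd) + rd
  if (cb > 0) out <- out + cb * log(p$Kb) + .xlx(cb) + cb
  out
}

#' Nonspecific free-energy density
#'
#' `(vb_ns/2) max(c1,c2)^2 + (wb_ns/6) max(c1,c2)^3`: repulsion among the
#' (majority-species) independent-bond solution.
#'
#' @param c1,c2 sticker concentrations, mM (vectorised).
#' @param p a [theory_params()].
#' @return numeric, kT * mM.
#' @export
f_nonspecific <- function(c1, c2, p) {
  cm <- pmax(c1, c2)
  p$vb_ns / 2 * cm^2 + p$wb_ns / 6 * cm^3
}

#' Total free-energy density
#'
#' `F = F_ni + F_s + F_ns` evaluated at the solved association state.
#'
#' @param c1,c2 sticker concentrations, mM (scalars).
#' @param p a [theory_params()].
#' @param components if TRUE return a named vector with the three components
#'   and the total.
#' @return numeric (kT * mM), or a named vector when `components = TRUE`.
#' @export
f_total <- function(c1, c2, p, components = FALSE) {
  st <- solve_association(c1, c2, p)
  ni <- f_noninteracting(c1, c2, p)
  ns <- f_nonspecific(c1, c2, p)
  tot <- ni + st$fs + ns
  if (components)
    c(ni = ni, s = st$fs, ns = ns, total = tot)
  else tot
}

#' Limiting specific free energies (all-dimer / all-bond)
#'
#' In the strong-binding limit polymers are either all paired up as dimers
#' (`rho_d = min(rho_1, rho_2)`, `cb = 0`) or as independent bonds
#' (`cb = min(c1, c2)`, `rho_d = 0`):
#' \deqn{F_s^{dim} = \rho_d \ln K_d + (\rho - \rho_d) \ln\frac{\rho-\rho_d}{e}
#'       - \rho \ln\frac{\rho}{e}}
#' with `rho = max(rho_1, rho_2)`, and the analogous `F_s^{ind}` with
#' `Kb`, `c = max(c1, c2)`.  The full specific free energy is well
#' approximated by the lower of the two in that regime.
#'
#' @param c1,c2 sticker concentrations, mM (vectorised).
#' @param p a [theory_params()].
#' @param mode `"dimer"` or `"independent"`.
#' @return numeric, kT * mM.
#' @export
limiting_f_specific <- function(c1, c2, p, mode = c("dimer", "independent")) {
  mode <- match.arg(mode)
  if (mode == "dimer") {
    r1 <- c1 / p$L1; r2 <- c2 / p$L2
    rd <- pmin(r1, r2); r <- pmax(r1, r2)
    rd * log(p$Kd) + .xlx(r - rd) - .xlx(r) + rd
  } else {
    cb <- pmin(c1, c2); cc <- pmax(c1, c2)
    cb * log(p$Kb) + .xlx(cc - cb) - .xlx(cc) + cb
  }
}

#' Dimer-gel transition concentration at equal stoichiometry
#'
#' For equal valences `L` at equal sticker stoichiometry the all-dimer and
#' all-bond free energies cross at
#' \deqn{c_0 = e \left(K_b^L / (K_d L)\right)^{1/(L-1)}.}
#'
#' @param L valence (> 1).
#' @param Kd dimer dissociation constant, polymeric mM.
#' @param Kb sticker-pair dissociation constant, mM.
#' @return concentration in mM.
#' @export
transition_concentration <- function(L, Kd, Kb) {
  if (L <= 1) stop("transition concentration is undefined for L = 1")
  exp(1 + (L * log(Kb) - log(Kd * L)) / (L - 1))
}

#' Skewed-stoichiometry transition concentration
#'
#' Away from equal stoichiometry (skew `s = max(c1,c2)/min(c1,c2) >= 1`) the
#' dimer-gel crossing moves down to
#' \deqn{c_s = c_0 (s-1)^{s-1} s^{-s},}
#' with `c_s -> c_0` as `s -> 1`.
#'
#' @param c0 equal-stoichiometry transition concentration, mM.
#' @param s stoichiometry skew, >= 1.
#' @return concentration in mM.
#' @export
skewed_transition <- function(c0, s) {
  if (any(s < 1)) stop("skew s must be >= 1 (use max/min convention)")
  f <- ifelse(s > 1, exp((s - 1) * log(pmax(s - 1, 1e-300)) - s * log(s)), 1)
  c0 * f
}

#' Fraction of stickers in dimers
#'
#' `(cd1 + cd2) / (c1 + c2)` at the solved association state.
#'
#' @param c1,c2 sticker concentrations, mM (scalars).
#' @param p a [theory_params()].
#' @return fraction in `[0, 1]`.
#' @export
dimer_fraction <- function(c1, c2, p) {
  if (c1 + c2 <= 0) stop("c1 + c2 must be positive")
  st <- solve_association(c1, c2, p)
  (st$cd1 + st$cd2) / (c1 + c2)
}

#' Effective theory valence from the binding correlation length
#'
#' Stickers tethered by short linkers do not bind independently; segments of
#' about 1.8 stickers do.  The simulation valence `L` maps to the theory
#' valence `L / ell_corr`.
#'
#' @param L simulation valence.
#' @param ell_corr binding correlation length in stickers (default 1.8).
#' @return effective (real-valued) valence.
#' @examples
#' effective_valence(14)  # ~7.8, i.e. theory valence 8
#' @export
effective_valence <- function(L, ell_corr = 1.8) {
  if (ell_corr <= 0) stop("ell_corr must be > 0")
  L / ell_corr
}
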