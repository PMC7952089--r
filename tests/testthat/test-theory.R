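# dimer-gel free energy, association solver, transition concentrations

p_unit <- theory_params(1, 1, Kd = 1, Kb = 1, vb_ns = 0, wb_ns = 0)

test_that("non-interacting free energy has the stated values and limits", {
  expect_equal(f_noninteracting(0, 0, p_unit), 0)
  p <- theory_params(3, 2, Kd = 1, Kb = 1)
  expect_equal(f_noninteracting(exp(1) * 3, exp(1) * 2, p), 0,
               tolerance = 1e-12)
  expect_equal(f_noninteracting(1, 0, p_unit), -1)
})

test_that("solver reproduces the dimer-only closed form and degenerate cases", {
  p <- theory_params(2, 2, Kd = 1, Kb = 1e9, vb_ns = 0, wb_ns = 0)
  st <- solve_association(2, 2, p)
  # closed form of the bond-free reduction; the residual bond channel at
  # Kb = 1e9 shifts the minimiser by O(1e-9)
  expect_equal(st$rho_d, (3 - sqrt(5)) / 2, tolerance = 1e-7)
  expect_equal(st$cd1, 2 * (3 - sqrt(5)) / 2, tolerance = 1e-7)
  expect_lt(st$cb, 1e-6)
  st0 <- solve_association(0, 5, p)
  expect_equal(c(st0$cd1, st0$cd2, st0$cb), c(0, 0, 0))
  # internal consistency cd1/L1 = cd2/L2
  p87 <- theory_params(8, 7)
  st87 <- solve_association(4, 3.5, p87)
  expect_equal(st87$cd1 / 8, st87$cd2 / 7, tolerance = 1e-12)
})

test_that("stationarity residuals and mass-action reductions hold", {
  # full solutions: residuals below 1e-8 (relative, log form)
  set.seed(42)
  for (k in 1:25) {
    L1 <- sample(2:9, 1); L2 <- sample(seq_len(L1), 1)
    p <- theory_params(L1, L2, Kd = 10^runif(1, -6, 1),
                       Kb = 10^runif(1, -3, 1))
    st <- solve_association(runif(1, 0.1, 20), runif(1, 0.1, 20), p)
    expect_lt(max(abs(st$residuals)), 1e-8)
  }
  # with bonds suppressed the dimer equation reduces to Kd rho_d =
  # (rho1 - rho_d)(rho2 - rho_d)
  p9 <- theory_params(3, 2, Kd = 0.7, Kb = Inf)
  st <- solve_association(4, 3, p9)
  lhs <- 0.7 * st$rho_d
  rhs <- (4 / 3 - st$rho_d) * (3 / 2 - st$rho_d)
  expect_lt(abs(lhs - rhs) / rhs, 1e-8)
  # with dimers suppressed the bond equation reduces to Kb cb = (c1-cb)(c2-cb)
  p10 <- theory_params(3, 2, Kd = Inf, Kb = 0.9)
  st2 <- solve_association(4, 3, p10)
  expect_lt(abs(0.9 * st2$cb - (4 - st2$cb) * (3 - st2$cb)), 1e-8)
})

test_that("solver matches the brute-force grid minimizer", {
  set.seed(7)
  for (k in 1:40) {
    L1 <- sample(1:6, 1); L2 <- sample(seq_len(L1), 1)
    Kd <- 10^runif(1, -4, 1); Kb <- 10^runif(1, -2, 1)
    c1 <- runif(1, 0.05, 12); c2 <- runif(1, 0.05, 12)
    p <- theory_params(L1, L2, Kd = Kd, Kb = Kb)
    st <- solve_association(c1, c2, p)
    gb <- oracle_grid_minimum(c1, c2, L1, L2, Kd, Kb, n = 150)
    expect_lt(st$fs, gb$fs + 1e-9 * (abs(gb$fs) + 1))  # solver at least as low
    expect_lt(abs(st$fs - gb$fs) / (abs(gb$fs) + 1e-6), 5e-3)
  }
})

test_that("specific free energy matches independent transcriptions", {
  set.seed(3)
  for (k in 1:30) {
    L1 <- sample(1:6, 1); L2 <- sample(seq_len(L1), 1)
    Kd <- 10^runif(1, -3, 1); Kb <- 10^runif(1, -2, 1)
    c1 <- runif(1, 0.2, 10); c2 <- runif(1, 0.2, 10)
    p <- theory_params(L1, L2, Kd = Kd, Kb = Kb)
    # random feasible interior state
    rd <- runif(1, 0, 1) * min(c1 / L1, c2 / L2) * 0.9
    cb <- runif(1, 0, 1) * min(c1 - L1 * rd, c2 - L2 * rd) * 0.9
    st <- list(rho_d = rd, cb = cb)
    v <- f_specific(c1, c2, st, p)
    expect_equal(v, oracle_fs(c1, c2, L1, L2, Kd, Kb, rd, cb),
                 tolerance = 1e-12)
    expect_equal(v, oracle_fs_printed(c1, c2, L1, L2, Kd, Kb, rd, cb),
                 tolerance = 1e-10)
  }
  # no-association state has zero specific free energy (Zs = 1)
  p <- theory_params(4, 3, Kd = 0.1, Kb = 0.1)
  expect_equal(f_specific(5, 3, list(rho_d = 0, cb = 0), p), 0)
  # all-dimer equal-valence state at equal stoichiometry: rho ln(Kd e / rho)
  pL <- theory_params(5, 5, Kd = 0.3, Kb = 1)
  cc <- 2; rho <- cc / 5
  v <- f_specific(cc, cc, list(rho_d = rho * (1 - 1e-12), cb = 0), pL)
  expect_equal(v, rho * log(0.3 * exp(1) / rho), tolerance = 1e-6)
  expect_error(f_specific(1, 1, list(rho_d = 10, cb = 0), pL), "feasible")
})

test_that("nonspecific free energy follows the majority-concentration rule", {
  p <- theory_params(2, 2, Kd = 1, Kb = 1, vb_ns = 9e-2, wb_ns = 7e-3)
  expect_equal(f_nonspecific(0, 0, p), 0)
  expect_equal(f_nonspecific(10, 10, p), 4.5 + 7 / 6, tolerance = 1e-12)
  expect_equal(f_nonspecific(4, 2, p), f_nonspecific(4, 4, p))
})

test_that("total free energy is additive, symmetric, and has the right limits", {
  p8 <- theory_params(8, 8)
  set.seed(12)
  for (k in 1:10) {
    c1 <- runif(1, 0.1, 20); c2 <- runif(1, 0.1, 20)
    comp <- f_total(c1, c2, p8, components = TRUE)
    expect_equal(comp[["total"]], sum(comp[c("ni", "s", "ns")]),
                 tolerance = 1e-10)
    expect_equal(f_total(c1, c2, p8), f_total(c2, c1, p8), tolerance = 1e-10)
  }
  # no association: F reduces to ideal + nonspecific
  pinf <- theory_params(4, 3, Kd = Inf, Kb = Inf)
  expect_equal(f_total(3, 2, pinf),
               f_noninteracting(3, 2, pinf) + f_nonspecific(3, 2, pinf),
               tolerance = 1e-12)
})

test_that("full specific free energy is sandwiched by the limiting forms", {
  p8 <- theory_params(8, 8)
  for (cc in c(0.5, 1, 3, 6, 10, 20)) {
    st <- solve_association(cc, cc, p8)
    lim <- min(limiting_f_specific(cc, cc, p8, "dimer"),
               limiting_f_specific(cc, cc, p8, "independent"))
    # the limiting states are feasible points of the minimisation, so the
    # full minimum lies at or below the lower limiting value ...
    expect_lte(st$fs, lim + 1e-9 * abs(lim))
    # ... and within 1% of it in the strong-binding regime (c >> Kd, Kb)
    if (cc >= 3)
      expect_lt(abs(st$fs - lim) / abs(lim), 0.01)
  }
  # off-diagonal too
  p87 <- theory_params(8, 7)
  st <- solve_association(8, 7, p87)
  lim <- min(limiting_f_specific(8, 7, p87, "dimer"),
             limiting_f_specific(8, 7, p87, "independent"))
  expect_lt(abs(st$fs - lim) / abs(lim), 0.01)
})

test_that("transition concentrations obey their defining identities", {
  expect_equal(transition_concentration(2, 0.5, 1), exp(1), tolerance = 1e-12)
  expect_error(transition_concentration(1, 0.5, 1))
  # F_s^dim(c0) = F_s^ind(c0) at equal stoichiometry
  for (L in c(4, 8)) {
    p <- theory_params(L, L)
    c0 <- transition_concentration(L, p$Kd, p$Kb)
    expect_lt(abs(limiting_f_specific(c0, c0, p, "dimer") -
                  limiting_f_specific(c0, c0, p, "independent")), 1e-10)
  }
  # Kb doubled at L = 3: c0 scales by 2^{3/2}
  expect_equal(transition_concentration(3, 0.2, 2) /
                 transition_concentration(3, 0.2, 1), 2^(3 / 2),
               tolerance = 1e-12)
  # skewed transition: limit and monotone decrease
  c0 <- 5
  expect_equal(skewed_transition(c0, 1), c0)
  expect_equal(skewed_transition(c0, 2), c0 / 4)
  s <- seq(1, 10, by = 0.05)
  expect_true(all(diff(skewed_transition(c0, s)) < 0))
  expect_error(skewed_transition(c0, 0.5))
})

test_that("dimer fraction behaves with dilution and concentration maps", {
  p8 <- theory_params(8, 8)
  # mass-action dilution: fraction -> 0 as c -> 0 for finite Kd
  pmono <- theory_params(1, 1, Kd = 1, Kb = 1e9)
  fr <- vapply(c(1, 0.1, 0.01, 0.001), function(cc)
    dimer_fraction(cc, cc, pmono), 0)
  expect_true(all(diff(fr) < 0))
  expect_lt(fr[4], 0.01)
  # strong binding below c_s: essentially fully dimerised
  c0 <- transition_concentration(8, p8$Kd, p8$Kb)
  expect_gt(dimer_fraction(c0 / 3, c0 / 3, p8), 0.9)
  # ridge of high dimer fraction along the diagonal, boundary tracked by c_s
  cc <- 0.75 * c0
  on_diag <- dimer_fraction(cc / 2, cc / 2, p8)
  s <- 2
  off_diag <- dimer_fraction(cc * s / (1 + s), cc / (1 + s), p8)
  expect_gt(on_diag, 0.9)
  expect_lt(off_diag, on_diag)
  expect_error(dimer_fraction(0, 0, p8))
})

test_that("effective valence is the correlation-length rescaling", {
  expect_equal(round(effective_valence(14, 1.8)), 8)
  expect_equal(effective_valence(14, 1.8), 14 / 1.8)
  expect_equal(effective_valence(5, 1), 5)
  expect_equal(effective_valence(8, 1.8), 4.44, tolerance = 1e-2)
  expect_error(effective_valence(8, 0))
})

test_that("species-swap symmetry holds for all free-energy components", {
  # for equal valences, swapping the two concentrations is an exact
  # relabelling of the species (general (c1, L1) <-> (c2, L2) swaps are
  # covered implicitly: the solver only sees min/max roles)
  p <- theory_params(5, 5, Kd = 1e-4, Kb = 0.01)
  st1 <- solve_association(5, 2, p)
  st2 <- solve_association(2, 5, p)
  expect_equal(st1$fs, st2$fs, tolerance = 1e-12)
  expect_equal(st1$cb, st2$cb, tolerance = 1e-12)
  expect_equal(st1$rho_d, st2$rho_d, tolerance = 1e-12)
  expect_equal(f_total(4, 1.5, p), f_total(1.5, 4, p), tolerance = 1e-12)
})
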