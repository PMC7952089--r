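# system construction and Langevin dynamics

test_that("planted mode places a single chain at the origin with rest spacing", {
  sp <- simulation_spec(valence_A = 2, valence_B = 1, count_A = 1, count_B = 1,
                        box = c(40, 40, 40), U0 = 0, init_mode = "planted")
  cfg <- build_system(sp)
  expect_equal(cfg$positions[1, ], c(0, 0, 0))
  expect_equal(sqrt(sum((cfg$positions[2, ] - cfg$positions[1, ])^2)),
               sp$mean_linker_length)
})

test_that("slab mode confines chain centres to the middle third of x", {
  sp <- simulation_spec(valence_A = 10, valence_B = 10, count_A = 12,
                        count_B = 12, box = c(250, 50, 50), U0 = 14,
                        init_mode = "slab", seed = 4)
  cfg <- build_system(sp)
  ctr <- tapply(cfg$positions[, 1], cfg$polymer, mean)
  expect_true(all(abs(ctr - 125) < 250 / 6 + 1e-9))
  # composition invariant under seed change, positions not
  cfg2 <- build_system(sp, seed = 99)
  expect_identical(table(cfg$species), table(cfg2$species))
  expect_false(identical(cfg$positions, cfg2$positions))
  # same-type core never violated
  d <- magicratio:::.same_type_min_dist_cpp(cfg$positions,
                                            magicratio:::.species_int(cfg),
                                            cfg$box)
  expect_gt(d, 0.4 * sp$r_rep - 1e-9)
})

test_that("trajectories are bit-identical for a fixed seed", {
  sp <- simulation_spec(2, 2, 2, 2, c(30, 30, 30), U0 = 9,
                        init_mode = "uniform", seed = 11)
  cfg <- build_system(sp)
  t1 <- run_langevin(cfg, sp, n_steps = 500, seed = 3, stride = 100)
  t2 <- run_langevin(cfg, sp, n_steps = 500, seed = 3, stride = 100)
  expect_identical(t1$frames[[5]]$positions, t2$frames[[5]]$positions)
  t3 <- run_langevin(cfg, sp, n_steps = 500, seed = 4, stride = 100)
  expect_false(identical(t1$frames[[5]]$positions, t3$frames[[5]]$positions))
})

test_that("overdamped T = 0 dynamics relaxes a stretched bond to rest length", {
  sp <- simulation_spec(2, 1, 1, 1, c(60, 60, 60), U0 = 0, friction = 30,
                        temperature = 0, init_mode = "planted")
  cfg <- build_system(sp)
  pos <- cfg$positions
  pos[2, 1] <- pos[2, 1] + 3  # stretch by 3 nm
  cfg <- configuration(pos, cfg$species, cfg$polymer, cfg$index, cfg$box, sp)
  tr <- run_langevin(cfg, sp, n_steps = 20000, seed = 1, stride = 200,
                     velocities = matrix(0, 3, 3))
  dev <- abs(bond_length_series(tr) - sp$mean_linker_length)
  expect_lt(dev[length(dev)], 1e-6)
  expect_true(all(diff(dev) <= 1e-8))
})

test_that("harmonic dimer samples the Boltzmann bond-length distribution", {
  sp <- simulation_spec(valence_A = 2, valence_B = 1, count_A = 1, count_B = 1,
                        box = c(60, 60, 60), U0 = 0, init_mode = "planted",
                        seed = 3)
  cfg <- build_system(sp)
  tr <- run_langevin(cfg, sp, n_steps = 2e5, seed = 11, stride = 250)
  r <- bond_length_series(tr)[-(1:100)]
  k <- sp$bond_stiffness; r0 <- sp$mean_linker_length
  # analytic moments of p(r) ~ r^2 exp(-k (r - r0)^2 / 2)
  mom <- function(j) integrate(function(x) x^(2 + j) * exp(-k / 2 * (x - r0)^2),
                               0, Inf)$value
  mu <- mom(1) / mom(0)
  v <- mom(2) / mom(0) - mu^2
  se <- blocked_se(r)
  expect_lt(abs(mean(r) - mu), 3 * se)
  expect_lt(abs(stats::var(r) - v) / v, 0.2)
})

test_that("the frictionless noiseless integrator conserves energy", {
  sp <- simulation_spec(2, 2, 1, 1, c(60, 60, 60), U0 = 9, friction = 0,
                        temperature = 0, timestep = 2 * pi / sqrt(10) / 500,
                        init_mode = "planted")
  cfg <- build_system(sp)
  pos <- cfg$positions
  pos[2, 1] <- pos[2, 1] + 2          # stretched bond
  pos[3, ] <- pos[1, ] + c(0.5, 0, 0) # A-B pair inside the well
  cfg <- configuration(pos, cfg$species, cfg$polymer, cfg$index, cfg$box, sp)
  tr <- run_langevin(cfg, sp, n_steps = 1e4, seed = 1, stride = 100,
                     velocities = matrix(0.3, 4, 3))
  E <- tr$epot + tr$ekin
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
})

test_that("diverging dynamics raises an integration-blow-up error", {
  sp <- simulation_spec(2, 1, 1, 1, c(40, 40, 40), U0 = 0,
                        init_mode = "planted")
  cfg <- build_system(sp)
  expect_error(run_langevin(cfg, sp, n_steps = 500, seed = 1, stride = 100,
                            velocities = matrix(1e200, 3, 3)),
               "blew up at step")
})

test_that("total energy matches construction-level expectations", {
  sp <- simulation_spec(2, 2, 1, 1, c(60, 60, 60), U0 = 9,
                        init_mode = "planted")
  cfg <- build_system(sp)   # chains far apart, bonds at rest
  expect_equal(total_energy(cfg), 0, tolerance = 1e-9)
  # bring one A-B pair to the attraction minimum (r = 0)
  pos <- cfg$positions
  pos[3, ] <- pos[1, ]
  pos[4, ] <- pos[3, ] + c(sp$mean_linker_length, 20, 0)  # keep B2 away
  cfg2 <- configuration(pos, cfg$species, cfg$polymer, cfg$index, cfg$box, sp)
  e <- total_energy(cfg2)
  bond_dev <- 0.5 * sp$bond_stiffness *
    (sqrt(sum((pos[4, ] - pos[3, ])^2)) - sp$mean_linker_length)^2
  expect_equal(e - bond_dev, -9, tolerance = 1e-6)
  # two same-type beads at core contact: energy equals the pair potential
  spA <- simulation_spec(1, 1, 2, 1, c(60, 60, 60), U0 = 0,
                         init_mode = "planted")
  cfgA <- build_system(spA)
  posA <- cfgA$positions
  posA[2, ] <- posA[1, ] + c(1.2, 0, 0)
  posA[3, ] <- posA[1, ] + c(0, 25, 0)
  cfgA <- configuration(posA, cfgA$species, cfgA$polymer, cfgA$index,
                        cfgA$box, spA)
  expect_equal(total_energy(cfgA),
               pair_potential(1.2, "same_repel", spA), tolerance = 1e-9)
})

test_that("one-to-one binding holds along an interacting trajectory", {
  sp <- simulation_spec(valence_A = 2, valence_B = 2, count_A = 6, count_B = 6,
                        box = c(30, 30, 30), U0 = 9, init_mode = "uniform",
                        seed = 8)
  cfg <- build_system(sp)
  tr <- run_langevin(cfg, sp, n_steps = 4e4, seed = 2, stride = 500)
  cut <- bond_cutoff(sp)
  viol <- vapply(tr$frames, function(f) {
    pr <- magicratio:::.cross_pairs_cpp(f$positions,
                                        magicratio:::.species_int(f),
                                        f$box, cut)
    if (nrow(pr) == 0) return(0L)
    max(0L, max(table(pr[, 2])) - 1L, max(table(pr[, 1])) - 1L)
  }, 0L)
  expect_identical(sum(viol), 0L)
})
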