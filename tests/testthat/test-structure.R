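# bond detection, clusters, profiles, coexistence, unit conversion

test_that("stickers_to_mM reproduces the published global concentration", {
  expect_equal(round(stickers_to_mM(2500, c(250, 50, 50)), 2), 6.64)
  expect_equal(stickers_to_mM(0, c(10, 10, 10)), 0)
  expect_equal(stickers_to_mM(1, 1e6), 1.66054e-3, tolerance = 1e-5)
  expect_error(stickers_to_mM(-1, 100))
  expect_error(stickers_to_mM(1, 0))
})

test_that("minimal fully-bonded oligomers and unpaired counts are exact", {
  expect_equal(minimal_fully_bonded_oligomer(14, 7), c(a = 1L, b = 2L))
  expect_equal(minimal_fully_bonded_oligomer(14, 6), c(a = 3L, b = 7L))
  expect_equal(minimal_fully_bonded_oligomer(14, 14), c(a = 1L, b = 1L))
  expect_equal(unpaired_stickers(c(1, 2), 14, 8), 2)
  expect_equal(unpaired_stickers(c(1, 1), 14, 13), 1)
  expect_equal(unpaired_stickers(c(1, 1), 9, 9), 0)
  # the minimal composition is fully bonded by construction
  for (m in c(3, 8, 14)) for (n in c(2, 7, 12)) {
    ab <- minimal_fully_bonded_oligomer(m, n)
    expect_equal(unpaired_stickers(ab, m, n), 0)
  }
})

test_that("detect_bonds pairs planted beads and breaks ties by lowest id", {
  # one A bead equidistant from two B beads
  pos <- rbind(c(10, 10, 10), c(10.5, 10, 10), c(9.5, 10, 10))
  cfg <- configuration(pos, c("A", "B", "B"), 1:3, c(1, 1, 1), c(40, 40, 40))
  bp <- detect_bonds(cfg, cutoff = 1)
  expect_identical(nrow(bp), 1L)
  expect_identical(unname(bp[1, "b"]), 2L)  # lowest B id wins the tie
  # planted pair just inside the cutoff
  cfg2 <- configuration(rbind(c(5, 5, 5), c(5.9, 5, 5)), c("A", "B"), 1:2,
                        c(1, 1), c(40, 40, 40))
  expect_identical(nrow(detect_bonds(cfg2, cutoff = 1)), 1L)
  expect_identical(nrow(detect_bonds(cfg2, cutoff = 0.5)), 0L)
})

test_that("greedy matching equals the exhaustive oracle on planted sets", {
  for (seed in 1:6) {
    rng <- magicratio:::.local_rng(seed)
    n <- 5L
    pos <- matrix(NA_real_, 2 * n, 3)
    # well-separated A-B pairs at random sub-cutoff offsets
    for (k in seq_len(n)) {
      base <- c(rng$unif(), rng$unif(), rng$unif()) * 20 + (k - 1) * 30
      off <- rng$sphere() * 0.8 * rng$unif()
      pos[2 * k - 1, ] <- base %% 200
      pos[2 * k, ] <- (base + off) %% 200
    }
    cfg <- configuration(pos, rep(c("A", "B"), n), seq_len(2 * n),
                         rep(1L, 2 * n), c(200, 200, 200))
    bp <- detect_bonds(cfg, cutoff = 1)
    or <- oracle_min_matching(cfg, cutoff = 1)
    expect_identical(nrow(bp), or$size)
    got <- bp[order(bp[, 1]), , drop = FALSE]
    want <- or$pairs[order(or$pairs[, 1]), , drop = FALSE]
    expect_equal(unname(got[, 1:2]), unname(want), ignore_attr = TRUE)
  }
})

test_that("find_clusters reports compositions, sizes, and bonding state", {
  # 5 fully bonded A14+B14 dimers
  pc <- make_planted_clusters(
    data.frame(n_A = rep(1, 5), n_B = rep(1, 5), pattern = "fully_bonded"),
    valence_A = 14, valence_B = 14)
  cl <- find_clusters(pc$config, detect_bonds(pc$config))
  expect_identical(nrow(cl), 5L)
  expect_true(all(cl$size == 28))
  expect_true(all(cl$fully_bonded))
  expect_identical(as.integer(attr(cl, "size_table")), 5L)
  # maximal trimer 1 A14 + 2 B8: two unpaired stickers
  pc2 <- make_planted_clusters(
    data.frame(n_A = 1, n_B = 2, pattern = "maximal"),
    valence_A = 14, valence_B = 8)
  cl2 <- find_clusters(pc2$config, detect_bonds(pc2$config))
  expect_identical(nrow(cl2), 1L)
  expect_identical(cl2$n_A, 1L)
  expect_identical(cl2$n_B, 2L)
  expect_identical(cl2$n_unpaired, 2L)
  expect_false(cl2$fully_bonded)
  # mass conservation: sticker sizes always sum to the bead count
  expect_identical(sum(cl2$size), nrow(pc2$config$positions))
})

test_that("planted cluster fixtures yield their ground-truth pairing", {
  # (3 A14, 7 B6) is the minimal fully-bonded oligomer of the 14:6 system;
  # B chains cross the A-chain boundaries, so it is a single cluster
  pc <- make_planted_clusters(
    data.frame(n_A = c(3, 1), n_B = c(7, 1),
               pattern = c("fully_bonded", "none")),
    valence_A = 14, valence_B = 6)
  bp <- detect_bonds(pc$config)
  want <- pc$pairing[order(pc$pairing[, 1]), , drop = FALSE]
  got <- bp[order(bp[, 1]), , drop = FALSE]
  expect_equal(unname(got[, 1:2]), unname(want[, 1:2]))
  cl <- find_clusters(pc$config, bp)
  expect_identical(nrow(cl), 3L)  # the "none" row contributes 2 clusters
  expect_true(cl$fully_bonded[cl$n_A == 3])
  expect_identical(cl$size[cl$n_A == 3], 3L * 14L + 7L * 6L)
})

test_that("density profile is flat for a uniform gas and normalised", {
  sp <- simulation_spec(4, 4, 100, 100, c(100, 50, 50), U0 = 0,
                        init_mode = "uniform", seed = 6)
  cfg <- build_system(sp)
  prof <- density_profile(cfg, bin_width = 20, align = FALSE)
  glob <- stickers_to_mM(n_beads(sp), sp$box)
  tot <- prof$c_A + prof$c_B
  expect_equal(mean(tot), glob, tolerance = 1e-9)  # exact normalisation
  # whole chains land in bins, so fluctuations are chain-level counting
  # noise: ~40 chains per bin, relative sd ~ 0.16
  expect_lt(max(abs(tot - glob)) / glob, 0.6)
})

test_that("alignment makes a shifted frame's profile identical", {
  sp <- simulation_spec(10, 10, 10, 10, c(250, 50, 50), U0 = 14,
                        init_mode = "slab", seed = 2)
  cfg <- build_system(sp)
  bw <- 2.5
  shift_bins <- 17L
  pos2 <- cfg$positions
  pos2[, 1] <- (pos2[, 1] + shift_bins * bw) %% cfg$box[1]
  cfg2 <- configuration(pos2, cfg$species, cfg$polymer, cfg$index, cfg$box,
                        sp)
  p1 <- density_profile(cfg, bin_width = bw, align = TRUE)
  p2 <- density_profile(cfg2, bin_width = bw, align = TRUE)
  expect_equal(p1$c_A, p2$c_A, tolerance = 1e-12)
  expect_equal(p1$c_B, p2$c_B, tolerance = 1e-12)
})

test_that("coexistence extraction recovers planted plateaus", {
  prof <- make_planted_profile(c_dilute = 0.2, c_dense = 12,
                               half_width = 30, width = 2)
  cx <- extract_coexistence(prof, dilute_window = 100, dense_window = 10)
  expect_equal(unname(sum(cx$dilute)), 0.2, tolerance = 1e-6)
  expect_equal(unname(sum(cx$dense)), 12, tolerance = 1e-6)
  # flat profile: dilute equals dense
  flat <- make_planted_profile(6.64, 6.64)
  cxf <- extract_coexistence(flat)
  expect_equal(sum(cxf$dilute), sum(cxf$dense), tolerance = 1e-12)
  expect_equal(unname(sum(cxf$dense)), 6.64, tolerance = 1e-9)
  expect_error(extract_coexistence(prof, dilute_window = 1e4),
               "empty analysis window")
})

test_that("noisy planted profiles are recovered within noise propagation", {
  for (seed in 1:5) {
    prof <- make_planted_profile(c_dilute = 0.5, c_dense = 12,
                                 half_width = 40, width = 2,
                                 noise_sd = 0.02, seed = seed)
    cx <- extract_coexistence(prof)
    nd <- sum(abs(prof$x) >= 100)
    tol <- 3 * 0.02 / sqrt(nd)  # 3 sigma of the window-mean noise
    expect_lt(abs(sum(cx$dilute) - 0.5) / 0.5, tol * 2)
    expect_lt(abs(sum(cx$dense) - 12) / 12, tol * 2)
  }
})

test_that("raising the planted dense plateau raises only the dense estimate", {
  p1 <- make_planted_profile(0.4, 8, half_width = 40, width = 2)
  p2 <- make_planted_profile(0.4, 14, half_width = 40, width = 2)
  c1 <- extract_coexistence(p1); c2 <- extract_coexistence(p2)
  expect_gt(sum(c2$dense), sum(c1$dense))
  expect_equal(sum(c2$dilute), sum(c1$dilute), tolerance = 1e-9)
})
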