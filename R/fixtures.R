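# planted synthetic fixtures
#
# Each generator emits the statistical structure a downstream analysis stage
# assumes, together with its exact ground truth, so the analysis chain can be
# tested without running long simulations.

#' Planted tanh slab density profile
#'
#' A symmetric slab: concentration `c_dense` inside `|x| < half_width`,
#' `c_dilute` outside, with tanh interfaces of width `width`, split between
#' A and B according to per-plateau stoichiometries, plus multiplicative
#' Gaussian noise.
#'
#' @param c_dilute,c_dense plateau total sticker concentrations, mM.
#' @param box numeric length-3 box in nm.
#' @param half_width slab half-width in nm (default `box[1]/6`).
#' @param width interface width in nm (default 5).
#' @param stoich_dilute,stoich_dense A:B concentration ratio in each plateau
#'   (default 1).
#' @param noise_sd relative (multiplicative) noise standard deviation
#'   (default 0).
#' @param bin_width profile bin width in nm (default 2.5).
#' @param seed integer seed for the noise.
#' @return a `density_profile` with attribute `truth` (the spec values).
#' @export
make_planted_profile <- function(c_dilute, c_dense, box = c(250, 50, 50),
                                 half_width = box[1] / 6, width = 5,
                                 stoich_dilute = 1, stoich_dense = 1,
                                 noise_sd = 0, bin_width = 2.5, seed = 1L) {
  stopifnot(c_dense >= c_dilute, c_dilute >= 0, width > 0)
  nb <- max(4L, round(box[1] / bin_width))
  bw <- box[1] / nb
  x <- (seq_len(nb) - 0.5) * bw - box[1] / 2
  tot <- c_dilute + (c_dense - c_dilute) * 0.5 *
    (tanh((x + half_width) / width) - tanh((x - half_width) / width))
  w_dense <- pmin(1, pmax(0, (tot - c_dilute) /
                            max(c_dense - c_dilute, 1e-300)))
  fA_dil <- stoich_dilute / (1 + stoich_dilute)
  fA_den <- stoich_dense / (1 + stoich_dense)
  fA <- fA_dil + (fA_den - fA_dil) * w_dense
  cA <- tot * fA
  cB <- tot * (1 - fA)
  if (noise_sd > 0) {
    rng <- .local_rng(seed)
    cA <- cA * (1 + noise_sd * .rng_gauss(rng, nb))
    cB <- cB * (1 + noise_sd * .rng_gauss(rng, nb))
  }
  structure(data.frame(x = x, c_A = cA, c_B = cB),
            box = box, frames = 1L, bin_width = bw,
            truth = list(c_dilute = c_dilute, c_dense = c_dense,
                         half_width = half_width, width = width,
                         noise_sd = noise_sd),
            class = c("density_profile", "data.frame"))
}

#' Planted bonded clusters with exact ground truth
#'
#' Builds a configuration containing the requested clusters, each with a
#' prescribed bonding pattern, clusters separated by more than twice the
#' bond cutoff.  Bound pairs are placed essentially on top of each other
#' (the attraction minimum); unbound stickers continue the chain contour and
#' sit beyond the cutoff from every opposite-type bead.
#'
#' Chains zig-zag along the x axis with the linker rest length, consecutive
#' B chains continuing where the previous one ended, which guarantees
#' geometric realisability of one-to-one bonding for valences up to ~16.
#'
#' @param compositions data frame (or list of rows) with columns `n_A`,
#'   `n_B`, `pattern` (`"fully_bonded"`, `"maximal"` or `"none"`).
#' @param valence_A,valence_B sticker counts per A / B chain.
#' @param box box lengths in nm; default sized to fit the clusters.
#' @param spec optional [simulation_spec()] template for geometry defaults.
#' @return list with `config` (a [configuration()]) and `pairing` (the
#'   ground-truth `bond_pairing`).
#' @export
make_planted_clusters <- function(compositions, valence_A, valence_B,
                                  box = NULL, spec = NULL) {
  comp <- as.data.frame(compositions)
  stopifnot(nrow(comp) >= 1, all(c("n_A", "n_B", "pattern") %in% names(comp)))
  if (is.null(spec))
    spec <- simulation_spec(valence_A = valence_A, valence_B = valence_B,
                            count_A = max(1, sum(comp$n_A)),
                            count_B = max(1, sum(comp$n_B)),
                            box = c(100, 100, 100), U0 = 14,
                            init_mode = "planted")
  r0 <- spec$mean_linker_length
  cutoff <- bond_cutoff(spec)
  offset <- 0.2  # bound-pair separation, deep inside the well
  row_pitch <- max(4 * cutoff, spec$r_rep + 1, 10)
  max_len <- max(comp$n_A * valence_A, comp$n_B * valence_B) * r0 + 10
  if (is.null(box)) box <- c(max_len + 20,
                             nrow(comp) * row_pitch + row_pitch, 20)
  pos <- NULL; species <- character(0); polymer <- integer(0)
  index <- integer(0); pair_a <- integer(0); pair_b <- integer(0)
  pol_id <- 0L
  for (k in seq_len(nrow(comp))) {
    nA <- comp$n_A[k]; nB <- comp$n_B[k]; pat <- as.character(comp$pattern[k])
    y0 <- (k - 0.5) * row_pitch
    # A stickers in one long row (chain after chain)
    a_ids <- integer(0)
    for (ca in seq_len(nA)) {
      pol_id <- pol_id + 1L
      for (b in seq_len(valence_A)) {
        pos <- rbind(pos, c(((ca - 1L) * valence_A + b - 1L) * r0, y0, 10))
        species <- c(species, "A"); polymer <- c(polymer, pol_id)
        index <- c(index, b)
        a_ids <- c(a_ids, nrow(pos))
      }
    }
    # B stickers: bound ones on top of successive A stickers, spares beyond
    n_bond <- switch(pat,
                     fully_bonded = ,
                     maximal = min(nA * valence_A, nB * valence_B),
                     none = 0L)
    if (pat == "fully_bonded" && nA * valence_A != nB * valence_B)
      stop("composition cannot be fully bonded")
    bcount <- 0L
    for (cb in seq_len(nB)) {
      pol_id <- pol_id + 1L
      for (b in seq_len(valence_B)) {
        bcount <- bcount + 1L
        if (bcount <= n_bond) {
          target <- a_ids[bcount]
          p <- pos[target, ] + c(0, 0, offset)
          pair_a <- c(pair_a, target)
        } else {
          # dangling: continue along the row, above the plane, out of reach
          p <- c((bcount - 1L) * r0, y0 + 2.5 * cutoff + 2, 10 + 2.5 * cutoff)
        }
        pos <- rbind(pos, p)
        species <- c(species, "B"); polymer <- c(polymer, pol_id)
        index <- c(index, b)
        if (bcount <= n_bond) pair_b <- c(pair_b, nrow(pos))
      }
    }
  }
  if (any(pos[, 1] >= box[1] | pos[, 2] >= box[2] | pos[, 3] >= box[3]) ||
      any(pos < 0))
    stop("infeasible packing: clusters do not fit in the box")
  config <- configuration(pos, species, polymer, index, box, spec)
  pairing <- structure(cbind(a = pair_a, b = pair_b),
                       r = rep(offset, length(pair_a)),
                       class = c("bond_pairing", "matrix", "array"))
  list(config = config, pairing = pairing)
}

#' Dilute gas of unbound chains
#'
#' Uniformly placed chains with no cross-type contact within the attraction
#' range: a valid, unbound starting state for oligomer-equilibration and
#' mass-action experiments.
#'
#' @param valences integer length-2: stickers per A and B chain.
#' @param counts integer length-2: number of A and B chains.
#' @param box box lengths in nm.
#' @param seed integer seed.
#' @param spec optional [simulation_spec()] template (overrides valences,
#'   counts, box).
#' @return a [configuration()].
#' @export
make_dilute_gas <- function(valences, counts, box, seed = 1L, spec = NULL) {
  if (is.null(spec))
    spec <- simulation_spec(valence_A = valences[1], valence_B = valences[2],
                            count_A = counts[1], count_B = max(0, counts[2]),
                            box = box, U0 = 14, seed = seed,
                            init_mode = "uniform")
  if (n_beads(spec) == 0)
    return(configuration(matrix(0, 0, 3), character(0), integer(0),
                         integer(0), spec$box, spec))
  for (attempt in 1:40) {
    config <- build_system(spec, seed = seed + (attempt - 1L) * 1000L)
    pr <- .cross_pairs_cpp(config$positions, .species_int(config),
                           config$box, spec$r_att)
    if (nrow(pr) == 0) return(config)
  }
  stop("infeasible density: could not place an unbound gas")
}
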