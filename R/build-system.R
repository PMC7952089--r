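# initial configuration builders

#' Build an initial configuration for a spec
#'
#' Three initialisation modes:
#' * `"slab"`: chain centres uniform in the middle third of the x axis and
#'   across the full y/z cross-section; chains grown as random walks with the
#'   linker rest length.  This is the standard starting state for coexistence
#'   (slab-method) runs.
#' * `"uniform"`: chain centres uniform over the whole box.
#' * `"planted"`: deterministic straight chains on a lattice (no randomness);
#'   useful for constructing exact test fixtures.
#'
#' Random modes reject bead placements that put two same-type beads within
#' the repulsive core (0.4 * repulsion range) and fail with an
#' infeasible-packing error when the density makes that impossible.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return a [configuration()].
#' @export
build_system <- function(spec, seed = spec$seed) {
  n_chain <- spec$count_A + spec$count_B
  valences <- c(rep(spec$valence_A, spec$count_A),
                rep(spec$valence_B, spec$count_B))
  species_chain <- c(rep("A", spec$count_A), rep("B", spec$count_B))
  r0 <- spec$mean_linker_length
  box <- spec$box

  if (spec$init_mode == "planted") {
    pos <- matrix(0, n_beads(spec), 3)
    k <- 0L
    # straight chains along x, laid out on a y/z lattice with generous pitch
    pitch <- max(spec$r_rep, r0) + spec$sticker_diameter
    ny <- max(1L, floor(box[2] / pitch))
    for (c_i in seq_len(n_chain)) {
      iy <- (c_i - 1L) %% ny
      iz <- (c_i - 1L) %/% ny
      for (b in seq_len(valences[c_i])) {
        k <- k + 1L
        pos[k, ] <- c((b - 1L) * r0, iy * pitch, iz * pitch)
      }
    }
    if (max(pos[, 3]) >= box[3]) stop("infeasible packing: planted lattice exceeds box")
  } else {
    rng <- .local_rng(seed)
    core <- 0.4 * spec$r_rep
    pos <- matrix(NA_real_, n_beads(spec), 3)
    spc <- rep(species_chain, valences)
    x_lo <- if (spec$init_mode == "slab") box[1] / 3 else 0
    x_hi <- if (spec$init_mode == "slab") 2 * box[1] / 3 else box[1]
    k <- 0L
    for (c_i in seq_len(n_chain)) {
      placed <- FALSE
      for (try_chain in 1:60) {
        start <- c(x_lo + rng$unif() * (x_hi - x_lo),
                   rng$unif() * box[2], rng$unif() * box[3])
        chain <- matrix(NA_real_, valences[c_i], 3)
        chain[1, ] <- start
        ok <- .placement_ok(chain[1, ], spc[k + 1L], pos[seq_len(k), , drop = FALSE],
                            spc[seq_len(k)], box, core)
        b <- 2L
        while (ok && b <= valences[c_i]) {
          grown <- FALSE
          for (try_bead in 1:200) {
            u <- rng$sphere()
            cand <- chain[b - 1L, ] + r0 * u
            if (spec$init_mode == "slab") {
              xr <- cand[1] %% box[1]
              if (xr < x_lo || xr > x_hi) next
            }
            if (.placement_ok(cand, spc[k + b], pos[seq_len(k), , drop = FALSE],
                              spc[seq_len(k)], box, core) &&
                .placement_ok(cand, spc[k + b], chain[seq_len(b - 1L), , drop = FALSE],
                              rep(spc[k + b], b - 1L), box, core)) {
              chain[b, ] <- cand
              grown <- TRUE
              break
            }
          }
          if (!grown) { ok <- FALSE }
          b <- b + 1L
        }
        if (ok) {
          pos[k + seq_len(valences[c_i]), ] <- chain
          k <- k + valences[c_i]
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("infeasible packing: could not place chain ", c_i)
    }
    pos <- pos %% matrix(box, nrow(pos), 3, byrow = TRUE)
  }

  configuration(positions = pos,
                species = rep(species_chain, valences),
                polymer = rep(seq_len(n_chain), valences),
                index = unlist(lapply(valences, seq_len)),
                box = box, spec = spec)
}

.placement_ok <- function(p, sp, other_pos, other_sp, box, core) {
  if (nrow(other_pos) == 0L) return(TRUE)
  same <- other_sp == sp
  if (!any(same)) return(TRUE)
  d <- sweep(other_pos[same, , drop = FALSE], 2, p)
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  min(rowSums(d^2)) > core^2
}

# Small deterministic RNG independent of R's global RNG state, so that
# configuration building is reproducible from (spec, seed) alone.
.local_rng <- function(seed) {
  state <- as.double((as.numeric(seed) %% 2147483647) + 1)
  unif <- function() {
    # Lehmer / Park-Miller minimal standard generator
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
  sphere <- function() {
    repeat {
      v <- c(2 * unif() - 1, 2 * unif() - 1, 2 * unif() - 1)
      s <- sum(v^2)
      if (s > 1e-4 && s <= 1) return(v / sqrt(s))
    }
  }
  list(unif = unif, sphere = sphere)
}
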