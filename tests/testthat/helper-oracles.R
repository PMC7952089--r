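# Independent oracles used across the suite.  These deliberately avoid the
# package's own solution paths.

# exhaustive minimum-weight one-to-one matching over cross-type pairs within
# cutoff (for <= ~12 beads); returns total weight and the matching
oracle_min_matching <- function(config, cutoff) {
  pos <- config$positions
  A <- which(config$species == "A")
  B <- which(config$species == "B")
  box <- config$box
  d <- function(i, j) {
    v <- pos[i, ] - pos[j, ]
    v <- v - box * round(v / box)
    sqrt(sum(v^2))
  }
  edges <- list()
  for (i in A) for (j in B) {
    w <- d(i, j)
    if (w < cutoff) edges[[length(edges) + 1]] <- c(i, j, w)
  }
  if (!length(edges)) return(list(weight = 0, pairs = matrix(0, 0, 2)))
  best <- list(weight = Inf, pairs = NULL, size = -1)
  em <- do.call(rbind, edges)
  recurse <- function(k, usedA, usedB, w, pairs) {
    if (k > nrow(em)) {
      size <- if (is.null(pairs)) 0 else nrow(pairs)
      # maximise cardinality first, then minimise weight
      if (size > best$size || (size == best$size && w < best$weight))
        best <<- list(weight = w, pairs = pairs, size = size)
      return(invisible())
    }
    recurse(k + 1, usedA, usedB, w, pairs)  # skip edge k
    i <- em[k, 1]; j <- em[k, 2]
    if (!(i %in% usedA) && !(j %in% usedB))
      recurse(k + 1, c(usedA, i), c(usedB, j), w + em[k, 3],
              rbind(pairs, em[k, 1:2]))
  }
  recurse(1, integer(0), integer(0), 0, NULL)
  best
}

# canonical specific free energy in plain R (mirror of the derivation, used
# to cross-check the C++ value path)
oracle_fs <- function(c1, c2, L1, L2, Kd, Kb, rd, cb) {
  xlx <- function(t) ifelse(t > 0, t * log(t), 0)
  r1 <- c1 / L1; r2 <- c2 / L2
  q1 <- c1 - L1 * rd; q2 <- c2 - L2 * rd
  h1 <- q1 - cb; h2 <- q2 - cb
  out <- -xlx(r1) - xlx(r2) +
    xlx(r1 - rd) + xlx(r2 - rd) - xlx(q1) - xlx(q2) + xlx(h1) + xlx(h2)
  if (rd > 0) out <- out + rd * log(Kd) + xlx(rd) + rd
  if (cb > 0) out <- out + cb * log(Kb) + xlx(cb) + cb
  out
}

# the published grouping of the specific free energy, transcribed literally
# term by term (fractions restored); independent of oracle_fs algebra
oracle_fs_printed <- function(c1, c2, L1, L2, Kd, Kb, rd, cb) {
  cd1 <- L1 * rd; cd2 <- L2 * rd
  lg <- function(x) if (x > 0) log(x) else 0
  -(c1 / L1) * lg(c1) + (1 - L1) / L1 * (c1 - cd1) * lg(c1 - cd1) +
    (c1 - cd1 - cb) * lg(c1 - cd1 - cb) -
    (c2 / L2) * lg(c2) + (1 - L2) / L2 * (c2 - cd2) * lg(c2 - cd2) +
    (c2 - cd2 - cb) * lg(c2 - cd2 - cb) +
    (if (cd1 > 0) (cd1 / L1) * lg(exp(1) * cd2 * L1 * Kd) else 0) +
    (if (cb > 0) cb * lg(exp(1) * cb * Kb) else 0)
}

# brute-force grid minimizer of the specific free energy over the feasible
# simplex (coarse grid + two rounds of local refinement)
oracle_grid_minimum <- function(c1, c2, L1, L2, Kd, Kb, n = 400) {
  r1 <- c1 / L1; r2 <- c2 / L2
  rdmax <- min(r1, r2)
  eval_grid <- function(rd_lo, rd_hi, n) {
    rd <- seq(rd_lo, rd_hi, length.out = n)
    best <- list(fs = Inf, rd = NA, cb = NA)
    for (r in rd) {
      cbmax <- min(c1 - L1 * r, c2 - L2 * r)
      if (cbmax < 0) next
      cb <- seq(0, cbmax * (1 - 1e-9), length.out = n)
      fs <- oracle_fs_vec(c1, c2, L1, L2, Kd, Kb, r, cb)
      k <- which.min(fs)
      if (fs[k] < best$fs) best <- list(fs = fs[k], rd = r, cb = cb[k])
    }
    best
  }
  b <- eval_grid(0, rdmax * (1 - 1e-9), n)
  span_rd <- rdmax / n
  for (round in 1:3) {
    lo <- max(0, b$rd - span_rd); hi <- min(rdmax * (1 - 1e-12), b$rd + span_rd)
    b2 <- eval_grid(lo, hi, 80)
    if (b2$fs < b$fs) b <- b2
    span_rd <- (hi - lo) / 80
  }
  b
}

oracle_fs_vec <- function(c1, c2, L1, L2, Kd, Kb, rd, cb) {
  xlx <- function(t) ifelse(t > 0, t * log(t), 0)
  r1 <- c1 / L1; r2 <- c2 / L2
  q1 <- c1 - L1 * rd; q2 <- c2 - L2 * rd
  h1 <- q1 - cb; h2 <- q2 - cb
  out <- -xlx(r1) - xlx(r2) +
    xlx(r1 - rd) + xlx(r2 - rd) - xlx(q1) - xlx(q2) + xlx(h1) + xlx(h2)
  out <- out + ifelse(rd > 0, rd * log(Kd) + xlx(rd) + rd, 0)
  out + ifelse(cb > 0, cb * log(Kb) + xlx(cb) + cb, 0)
}

# small helper: bond length series of a two-bead chain trajectory
bond_length_series <- function(traj, i = 1L, j = 2L) {
  vapply(traj$frames, function(f) {
    v <- f$positions[i, ] - f$positions[j, ]
    v <- v - f$box * round(v / f$box)
    sqrt(sum(v^2))
  }, 0)
}

# blocked standard error of the mean
blocked_se <- function(x, nblocks = 10) {
  b <- vapply(split(x, cut(seq_along(x), nblocks)), mean, 0)
  stats::sd(b) / sqrt(nblocks)
}
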