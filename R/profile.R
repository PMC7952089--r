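# slab density profiles and coexistence extraction

#' Sticker density profile along the slab axis
#'
#' Bins bead positions along x per frame, optionally aligns each frame so the
#' centre of the dense region sits at x = 0 (the shift is found by maximising
#' the boxcar-windowed total density via circular cross-correlation, window
#' width equal to the dense analysis window), averages over frames, and
#' converts counts to mM.  Profile coordinates are bin centres in
#' `[-Lx/2, Lx/2)`.
#'
#' @param traj a `trajectory` or a single [configuration()].
#' @param bin_width bin width in nm (default 2.5).
#' @param align logical; align frames before averaging (default TRUE).
#' @param window_frac width of the alignment window as a fraction of the box
#'   (default 0.08, i.e. 20 nm for a 250 nm box).
#' @return object of class `density_profile`: data frame with columns `x`,
#'   `c_A`, `c_B` (mM); attributes `box`, `frames`, `bin_width`.
#' @export
density_profile <- function(traj, bin_width = 2.5, align = TRUE,
                            window_frac = 0.08) {
  frames <- if (inherits(traj, "trajectory")) traj$frames else list(traj)
  stopifnot(length(frames) >= 1)
  box <- frames[[1]]$box
  if (bin_width > box[1]) stop("bin_width exceeds the box length")
  nb <- max(4L, round(box[1] / bin_width))
  bw <- box[1] / nb
  area <- box[2] * box[3]
  conv <- .MM_PER_INV_NM3 / (bw * area)  # counts -> mM per bin
  acc_A <- acc_B <- numeric(nb)
  win <- max(1L, round(window_frac * nb))
  for (fr in frames) {
    xb <- floor((fr$positions[, 1] %% box[1]) / bw)
    xb <- pmin(xb, nb - 1L) + 1L
    hA <- tabulate(xb[fr$species == "A"], nb)
    hB <- tabulate(xb[fr$species == "B"], nb)
    if (align) {
      tot <- hA + hB
      # circular boxcar sum of width `win` centred on each bin
      cs <- cumsum(c(tot, tot))
      half <- win %/% 2
      wsum <- vapply(seq_len(nb), function(i) {
        lo <- i - half; hi <- i + (win - half - 1L)
        if (lo < 1) { lo <- lo + nb; hi <- hi + nb }
        if (lo > 1) cs[hi] - cs[lo - 1] else cs[hi]
      }, 0)
      ctr <- which.max(wsum)
      shift <- (nb %/% 2 + 1L) - ctr
      hA <- .roll(hA, shift)
      hB <- .roll(hB, shift)
    }
    acc_A <- acc_A + hA
    acc_B <- acc_B + hB
  }
  nf <- length(frames)
  x <- (seq_len(nb) - 0.5) * bw - box[1] / 2
  structure(data.frame(x = x, c_A = acc_A / nf * conv, c_B = acc_B / nf * conv),
            box = box, frames = nf, bin_width = bw,
            class = c("density_profile", "data.frame"))
}

.roll <- function(v, k) {
  n <- length(v)
  k <- ((k %% n) + n) %% n
  if (k == 0) v else c(v[(n - k + 1):n], v[1:(n - k)])
}

#' Dilute- and dense-phase concentrations from a profile
#'
#' Averages the A and B sticker concentrations over a dilute window (the two
#' box ends) and a dense window (around the aligned slab centre).  Defaults
#' reproduce the windows `|x| >= 100 nm` and `|x| <= 10 nm` of a 250 nm box,
#' scaled by `box_x / 250`.
#'
#' @param profile a [density_profile()].
#' @param dilute_window x beyond which (in absolute value) bins count as
#'   dilute; default `100 * box_x / 250`.
#' @param dense_window x within which (absolute value) bins count as dense;
#'   default `10 * box_x / 250`.
#' @return object of class `coexistence_point`: list with `dilute` and
#'   `dense`, each `c(c_A, c_B)` in mM.
#' @export
extract_coexistence <- function(profile, dilute_window = NULL,
                                dense_window = NULL) {
  stopifnot(inherits(profile, "density_profile"))
  bx <- attr(profile, "box")[1]
  if (is.null(dilute_window)) dilute_window <- 100 * bx / 250
  if (is.null(dense_window)) dense_window <- 10 * bx / 250
  dil <- abs(profile$x) >= dilute_window
  den <- abs(profile$x) <= dense_window
  if (!any(dil) || !any(den)) stop("empty analysis window")
  structure(list(
    dilute = c(c_A = mean(profile$c_A[dil]), c_B = mean(profile$c_B[dil])),
    dense = c(c_A = mean(profile$c_A[den]), c_B = mean(profile$c_B[den]))),
    class = "coexistence_point")
}

#' @export
print.coexistence_point <- function(x, ...) {
  cat(sprintf("coexistence: dilute (%.4g, %.4g) mM, dense (%.4g, %.4g) mM\n",
              x$dilute[1], x$dilute[2], x$dense[1], x$dense[2]))
  invisible(x)
}
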