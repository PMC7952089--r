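# free-energy landscapes and convex-hull phase diagrams
#
# The binodal construction follows the standard common-tangent-plane logic in
# two-component composition space: compute F(c1, c2) on a grid, take the
# lower convex hull of the 3-D point cloud (c1, c2, F), and read coexistence
# off the hull facets.  Facets whose projected area is much larger than a
# grid cell bridge non-convex parts of the landscape: their vertices are
# coexisting compositions and their long edges are tie lines.  Nodes lying
# strictly above the hull are inside the two-phase region.

#' Free-energy landscape on a concentration grid
#'
#' Evaluates the total dimer-gel free energy at every node of a uniform
#' `(c1, c2)` grid on `[0, c_max]^2`.
#'
#' @param p a [theory_params()].
#' @param c_max grid maximum in mM (default 30).
#' @param n_grid nodes per axis (default 200, minimum 50).
#' @return object of class `free_energy_landscape`: list with `c1`, `c2`
#'   (axes), `F` (matrix, `F[i, j]` at `c1[i]`, `c2[j]`), `rho_d`, `cb`
#'   (association state per node), and `params`.
#' @export
build_landscape <- function(p, c_max = 30, n_grid = 200) {
  stopifnot(c_max > 0, n_grid >= 50)
  ax <- seq(0, c_max, length.out = n_grid)
  g <- expand.grid(c1 = ax, c2 = ax)
  m <- .assoc_solve_cpp(g$c1, g$c2, p$L1, p$L2, p$Kd, p$Kb)
  bad <- which(m[, "converged"] < 1)
  if (length(bad))
    stop(sprintf("association solver failed at node c1 = %g, c2 = %g",
                 g$c1[bad[1]], g$c2[bad[1]]))
  Fv <- f_noninteracting(g$c1, g$c2, p) + m[, "fs"] +
    f_nonspecific(g$c1, g$c2, p)
  if (!all(is.finite(Fv))) stop("non-finite free energy on the grid")
  structure(list(c1 = ax, c2 = ax,
                 F = matrix(Fv, n_grid, n_grid),
                 rho_d = matrix(m[, "rho_d"], n_grid, n_grid),
                 cb = matrix(m[, "cb"], n_grid, n_grid),
                 params = p),
            class = "free_energy_landscape")
}

#' Phase diagram from the lower convex hull of a landscape
#'
#' Computes the lower convex hull of the points `(c1, c2, F)`.  Facets whose
#' projected area exceeds `alpha` grid cells are coexistence facets; their
#' longest edge (in composition space) is kept as a tie line, with endpoints
#' ordered dilute first by total concentration.  A node is labelled
#' two-phase when the landscape lies above the hull by more than `tol` at
#' that node.
#'
#' @param ls a [build_landscape()] result.
#' @param alpha facet-area threshold in units of the grid cell area
#'   (default 1.5).
#' @param tol two-phase classification tolerance on `F - hull` relative to
#'   the free-energy range (default 1e-9).
#' @return object of class `phase_diagram`: list with `label` (matrix,
#'   `"one-phase"`/`"two-phase"`), `tie_lines` (data frame with dilute and
#'   dense endpoint compositions), `envelope` (hull value at the nodes),
#'   `degenerate` flag, and `params`/`grid` metadata.
#' @export
binodal_from_hull <- function(ls, alpha = 1.5, tol = 1e-9) {
  n1 <- length(ls$c1); n2 <- length(ls$c2)
  pts <- cbind(rep(ls$c1, n2), rep(ls$c2, each = n1), as.vector(ls$F))
  hull <- .convex_hull3_cpp(pts)
  empty_tl <- data.frame(dilute_c1 = numeric(0), dilute_c2 = numeric(0),
                         dense_c1 = numeric(0), dense_c2 = numeric(0))
  if (isTRUE(hull$degenerate)) {
    warning("degenerate (planar) free-energy landscape; all one-phase")
    return(structure(list(label = matrix("one-phase", n1, n2),
                          tie_lines = empty_tl, envelope = ls$F,
                          degenerate = TRUE, params = ls$params,
                          grid = list(c1 = ls$c1, c2 = ls$c2),
                          alpha = alpha),
                     class = "phase_diagram"))
  }
  fac <- hull$facets[hull$normal_z < -1e-9, , drop = FALSE]
  cell <- (ls$c1[2] - ls$c1[1]) * (ls$c2[2] - ls$c2[1])
  # projected areas and planes of the lower facets
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  a <- fac[, 1]; b <- fac[, 2]; cc <- fac[, 3]
  area <- 0.5 * abs((x[b] - x[a]) * (y[cc] - y[a]) -
                    (x[cc] - x[a]) * (y[b] - y[a]))
  env <- .hull_envelope(ls, pts, fac)
  frange <- diff(range(z))
  two <- (ls$F - env) > tol * max(frange, 1)
  big <- which(area > alpha * cell)
  tie <- empty_tl
  if (length(big)) {
    rows <- lapply(big, function(k) {
      v <- c(fac[k, 1], fac[k, 2], fac[k, 3])
      e <- rbind(v[c(1, 2)], v[c(2, 3)], v[c(1, 3)])
      len <- (x[e[, 1]] - x[e[, 2]])^2 + (y[e[, 1]] - y[e[, 2]])^2
      ed <- e[which.max(len), ]
      tot <- (x + y)[ed]
      ed <- ed[order(tot)]
      data.frame(dilute_c1 = x[ed[1]], dilute_c2 = y[ed[1]],
                 dense_c1 = x[ed[2]], dense_c2 = y[ed[2]])
    })
    tie <- unique(do.call(rbind, rows))
  }
  structure(list(label = matrix(ifelse(two, "two-phase", "one-phase"),
                                n1, n2),
                 tie_lines = tie, envelope = env, degenerate = FALSE,
                 params = ls$params, grid = list(c1 = ls$c1, c2 = ls$c2),
                 alpha = alpha,
                 facets = fac, facet_area_cells = area / cell),
            class = "phase_diagram")
}

# Evaluate the lower-hull envelope at every grid node by rasterising the
# facet planes over the nodes inside each facet's (c1, c2) triangle.
.hull_envelope <- function(ls, pts, fac) {
  n1 <- length(ls$c1); n2 <- length(ls$c2)
  env <- matrix(Inf, n1, n2)
  d1 <- ls$c1[2] - ls$c1[1]; d2 <- ls$c2[2] - ls$c2[1]
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  for (k in seq_len(nrow(fac))) {
    v <- fac[k, ]
    x1 <- x[v[1]]; y1 <- y[v[1]]; z1 <- z[v[1]]
    x2 <- x[v[2]]; y2 <- y[v[2]]; z2 <- z[v[2]]
    x3 <- x[v[3]]; y3 <- y[v[3]]; z3 <- z[v[3]]
    det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    if (abs(det) < 1e-14 * max(d1 * d2, 1)) next
    i_lo <- max(1L, floor(min(x1, x2, x3) / d1 - 1e-9) + 1L)
    i_hi <- min(n1, ceiling(max(x1, x2, x3) / d1 + 1e-9) + 1L)
    j_lo <- max(1L, floor(min(y1, y2, y3) / d2 - 1e-9) + 1L)
    j_hi <- min(n2, ceiling(max(y1, y2, y3) / d2 + 1e-9) + 1L)
    if (i_lo > i_hi || j_lo > j_hi) next
    ii <- i_lo:i_hi; jj <- j_lo:j_hi
    px <- ls$c1[ii]; py <- ls$c2[jj]
    PX <- matrix(px, length(ii), length(jj))
    PY <- matrix(py, length(ii), length(jj), byrow = TRUE)
    l1 <- ((y2 - y3) * (PX - x3) + (x3 - x2) * (PY - y3)) / det
    l2 <- ((y3 - y1) * (PX - x3) + (x1 - x3) * (PY - y3)) / det
    l3 <- 1 - l1 - l2
    eps <- 1e-9
    inside <- l1 >= -eps & l2 >= -eps & l3 >= -eps
    if (!any(inside)) next
    zz <- l1 * z1 + l2 * z2 + l3 * z3
    sub <- env[ii, jj, drop = FALSE]
    sub[inside] <- pmin(sub[inside], zz[inside])
    env[ii, jj] <- sub
  }
  env[!is.finite(env)] <- ls$F[!is.finite(env)]
  env
}

#' Tie line through a global composition
#'
#' Finds the coexistence facet containing `(c1, c2)` and returns its tie
#' line; `NULL` when the composition is in the one-phase region.
#'
#' @param pd a [binodal_from_hull()] result.
#' @param c1,c2 global composition, mM.
#' @return one-row data frame like `pd$tie_lines`, or `NULL`.
#' @export
tie_line_through <- function(pd, c1, c2) {
  if (pd$degenerate || nrow(pd$tie_lines) == 0) return(NULL)
  # node-level check first: nearest node must be two-phase
  i <- which.min(abs(pd$grid$c1 - c1))
  j <- which.min(abs(pd$grid$c2 - c2))
  if (pd$label[i, j] != "two-phase") return(NULL)
  fac <- pd$facets
  big <- which(pd$facet_area_cells > pd$alpha)
  pts1 <- rep(pd$grid$c1, length(pd$grid$c2))
  pts2 <- rep(pd$grid$c2, each = length(pd$grid$c1))
  for (k in big) {
    v <- fac[k, ]
    x1 <- pts1[v[1]]; y1 <- pts2[v[1]]
    x2 <- pts1[v[2]]; y2 <- pts2[v[2]]
    x3 <- pts1[v[3]]; y3 <- pts2[v[3]]
    det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    if (abs(det) < 1e-14) next
    l1 <- ((y2 - y3) * (c1 - x3) + (x3 - x2) * (c2 - y3)) / det
    l2 <- ((y3 - y1) * (c1 - x3) + (x1 - x3) * (c2 - y3)) / det
    l3 <- 1 - l1 - l2
    if (min(l1, l2, l3) >= -1e-9) {
      e <- rbind(v[c(1, 2)], v[c(2, 3)], v[c(1, 3)])
      len <- (pts1[e[, 1]] - pts1[e[, 2]])^2 + (pts2[e[, 1]] - pts2[e[, 2]])^2
      ed <- e[which.max(len), ]
      ed <- ed[order(pts1[ed] + pts2[ed])]
      return(data.frame(dilute_c1 = pts1[ed[1]], dilute_c2 = pts2[ed[1]],
                        dense_c1 = pts1[ed[2]], dense_c2 = pts2[ed[2]]))
    }
  }
  NULL
}

#' Dilute/dense branch scan over stoichiometries
#'
#' For each parameter set and each sticker stoichiometry ratio `c1/c2`, places
#' the global composition at total sticker concentration `c_total` and reads
#' the dilute- and dense-branch compositions from the tie line through it.
#'
#' @param p_list a [theory_params()] or list of them.
#' @param stoichiometries numeric vector of sticker-concentration ratios
#'   `c1 / c2`.
#' @param c_total total global sticker concentration in mM (default 6.64).
#' @param c_max,n_grid,alpha forwarded to [build_landscape()] /
#'   [binodal_from_hull()].
#' @return data frame with one row per (parameter set, stoichiometry):
#'   valences, the global composition, `coexists`, and the tie-line endpoint
#'   compositions and totals (NA when in the one-phase region).
#' @export
dilute_branch_scan <- function(p_list, stoichiometries, c_total = 6.64,
                               c_max = 30, n_grid = 200, alpha = 1.5) {
  if (inherits(p_list, "theory_params")) p_list <- list(p_list)
  stopifnot(length(p_list) >= 1)
  out <- list()
  for (p in p_list) {
    ls <- build_landscape(p, c_max = c_max, n_grid = n_grid)
    pd <- binodal_from_hull(ls, alpha = alpha)
    for (r in stoichiometries) {
      c1 <- c_total * r / (1 + r)
      c2 <- c_total / (1 + r)
      tl <- tie_line_through(pd, c1, c2)
      row <- data.frame(L1 = p$L1, L2 = p$L2, stoich = r,
                        c1_global = c1, c2_global = c2,
                        coexists = !is.null(tl),
                        dilute_c1 = NA_real_, dilute_c2 = NA_real_,
                        dilute_total = NA_real_,
                        dense_c1 = NA_real_, dense_c2 = NA_real_,
                        dense_total = NA_real_)
      if (!is.null(tl)) {
        row$dilute_c1 <- tl$dilute_c1; row$dilute_c2 <- tl$dilute_c2
        row$dilute_total <- tl$dilute_c1 + tl$dilute_c2
        row$dense_c1 <- tl$dense_c1; row$dense_c2 <- tl$dense_c2
        row$dense_total <- tl$dense_c1 + tl$dense_c2
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' @export
print.phase_diagram <- function(x, ...) {
  n2 <- sum(x$label == "two-phase")
  cat(sprintf("phase diagram: %d x %d grid, %d two-phase nodes, %d tie lines\n",
              nrow(x$label), ncol(x$label), n2, nrow(x$tie_lines)))
  invisible(x)
}

#' Plot a phase diagram
#' @param x a `phase_diagram`.
#' @param ... passed to [graphics::image()].
#' @export
plot.phase_diagram <- function(x, ...) {
  graphics::image(x$grid$c1, x$grid$c2, (x$label == "two-phase") * 1,
                  col = c("white", "darkseagreen2"),
                  xlab = "c1 (mM)", ylab = "c2 (mM)", ...)
  if (nrow(x$tie_lines))
    graphics::segments(x$tie_lines$dilute_c1, x$tie_lines$dilute_c2,
                       x$tie_lines$dense_c1, x$tie_lines$dense_c2,
                       col = "grey40")
  invisible(x)
}
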