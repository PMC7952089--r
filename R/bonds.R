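# bond detection and cluster analysis

#' Detect one-to-one sticker bonds
#'
#' Greedy nearest-distance matching over all cross-type bead pairs within
#' `cutoff`: pairs are visited in order of increasing distance (ties broken
#' by lowest A-bead id, then lowest B-bead id) and accepted when both beads
#' are still unmatched.  Each bead ends up with at most one partner.
#'
#' @param config a [configuration()].
#' @param cutoff bond distance criterion in nm; default [bond_cutoff()] of
#'   the configuration's spec (the attraction well's outer inflection).
#' @return an object of class `bond_pairing`: a two-column matrix
#'   (`a`, `b`) of bead indices, with the pair distances as attribute `r`.
#' @export
detect_bonds <- function(config, cutoff = NULL) {
  stopifnot(inherits(config, "configuration"))
  if (is.null(cutoff)) {
    if (is.null(config$spec)) stop("no cutoff given and no spec available")
    cutoff <- bond_cutoff(config$spec)
  }
  pr <- .cross_pairs_cpp(config$positions, .species_int(config), config$box,
                         cutoff)
  out <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("a", "b")))
  rr <- numeric(0)
  if (nrow(pr) > 0) {
    ord <- order(pr[, 3], pr[, 1], pr[, 2])
    pr <- pr[ord, , drop = FALSE]
    taken <- logical(nrow(config$positions))
    keep <- logical(nrow(pr))
    for (k in seq_len(nrow(pr))) {
      i <- pr[k, 1]; j <- pr[k, 2]
      if (!taken[i] && !taken[j]) {
        taken[i] <- TRUE; taken[j] <- TRUE; keep[k] <- TRUE
      }
    }
    out <- cbind(a = as.integer(pr[keep, 1]), b = as.integer(pr[keep, 2]))
    rr <- pr[keep, 3]
  }
  if (anyDuplicated(c(out))) stop("internal error: bead paired twice")
  structure(out, r = rr, class = c("bond_pairing", class(out)))
}

#' Cluster composition from a bond pairing
#'
#' Clusters are connected components over polymers, two polymers being linked
#' when at least one sticker bond joins them.  Composition is reported in
#' polymer counts; size in stickers.  A cluster is `fully_bonded` when none
#' of its stickers is unpaired.
#'
#' @param config a [configuration()].
#' @param pairing a `bond_pairing` from [detect_bonds()].
#' @return an object of class `cluster_stats`: a data frame with one row per
#'   cluster (`n_A`, `n_B`, `size`, `n_unpaired`, `fully_bonded`) plus the
#'   sticker-size histogram as attribute `size_table`.
#' @export
find_clusters <- function(config, pairing) {
  stopifnot(inherits(config, "configuration"))
  pol <- config$polymer
  n_pol <- max(pol)
  g <- igraph::make_empty_graph(n = n_pol, directed = FALSE)
  if (nrow(pairing) > 0) {
    e <- cbind(pol[pairing[, 1]], pol[pairing[, 2]])
    g <- igraph::add_edges(g, t(e))
  }
  comp <- igraph::components(g)$membership
  paired <- logical(nrow(config$positions))
  paired[c(pairing)] <- TRUE
  bead_comp <- comp[pol]
  ncl <- max(comp)
  n_A <- n_B <- size <- unp <- integer(ncl)
  pol_species <- vapply(seq_len(n_pol),
                        function(p) config$species[match(p, pol)], "")
  for (cl in seq_len(ncl)) {
    pols <- which(comp == cl)
    n_A[cl] <- sum(pol_species[pols] == "A")
    n_B[cl] <- sum(pol_species[pols] == "B")
    beads <- which(bead_comp == cl)
    size[cl] <- length(beads)
    unp[cl] <- sum(!paired[beads])
  }
  df <- data.frame(cluster = seq_len(ncl), n_A = n_A, n_B = n_B, size = size,
                   n_unpaired = unp, fully_bonded = unp == 0L)
  stopifnot(sum(df$size) == nrow(config$positions))
  structure(df, size_table = table(size), class = c("cluster_stats",
                                                    class(df)))
}
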