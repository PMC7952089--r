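# dilute-phase oligomer combinatorics
#
# In the strong-binding regime the dilute phase is dominated by the smallest
# oligomer in which all stickers can pair: a polymers of valence m and b of
# valence n with a*m = b*n.  When the valences do not divide evenly, the best
# small oligomer leaves |a*m - b*n| stickers unpaired.

#' Smallest fully-bonded oligomer composition
#'
#' The minimal `(a, b)` with `a * m = b * n`:
#' `a = n / gcd(m, n)`, `b = m / gcd(m, n)`.
#'
#' @param m valence of species A.
#' @param n valence of species B.
#' @return integer vector `c(a = ..., b = ...)` of polymer counts.
#' @examples
#' minimal_fully_bonded_oligomer(14, 7)  # 1 A + 2 B: the A14:B7 trimer
#' minimal_fully_bonded_oligomer(14, 6)  # 3 A + 7 B
#' @export
minimal_fully_bonded_oligomer <- function(m, n) {
  stopifnot(m >= 1, n >= 1, m == round(m), n == round(n))
  g <- .gcd(m, n)
  c(a = as.integer(n / g), b = as.integer(m / g))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Unpaired stickers of an oligomer composition
#'
#' Minimum number of unpaired stickers in an oligomer of `a` A-polymers of
#' valence `m` and `b` B-polymers of valence `n` under one-to-one pairing:
#' `|a * m - b * n|`.
#'
#' @param composition integer vector `c(a, b)` of polymer counts.
#' @param m,n valences of species A and B.
#' @return integer.
#' @examples
#' unpaired_stickers(c(1, 2), 14, 8)   # 2: the A14:(B8)2 trimer
#' unpaired_stickers(c(1, 1), 14, 13)  # 1: one dangling A sticker per dimer
#' @export
unpaired_stickers <- function(composition, m, n) {
  stopifnot(length(composition) == 2, all(composition >= 0))
  abs(composition[[1]] * m - composition[[2]] * n)
}
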