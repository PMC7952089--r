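# SimulationSpec: parameters of a two-component sticker-polymer system

#' Specify a two-component sticker-polymer simulation
#'
#' An `Am:Bn` system: `count_A` chains of `valence_A` stickers of type A and
#' `count_B` chains of `valence_B` stickers of type B in a periodic box.
#' Consecutive stickers are connected by harmonic linkers; unlike-type
#' stickers attract (well depth `U0`), like-type stickers repel softly.
#'
#' @param valence_A,valence_B stickers per A / B chain (integer >= 1).
#' @param count_A,count_B number of A / B chains (integer >= 1; `count_B = 0`
#'   is allowed for single-species systems used in tests).
#' @param box numeric length-3, box edge lengths in nm.
#' @param U0 depth of the cross-type attraction well, in kT.
#' @param sticker_diameter bead diameter in nm (default 2.5).  The attraction
#'   cutoff is `0.8 * sticker_diameter` and the same-type repulsion range is
#'   `1.5 * sticker_diameter`.
#' @param mean_linker_length harmonic-bond rest length in nm (default 4.7).
#' @param bond_stiffness harmonic-bond spring constant in kT/nm^2 (default 10).
#' @param E_rep height of the same-type soft repulsion at contact, kT
#'   (default 100).
#' @param friction Langevin friction in 1/time (default 1).
#' @param timestep integration timestep in reduced time; default is 1/50 of
#'   the harmonic-bond oscillation period `2 pi sqrt(m / k)`.
#' @param temperature thermal energy in kT (fixed at 1 for production use;
#'   0 switches the thermostat noise off).
#' @param seed integer seed for initial construction and dynamics.
#' @param init_mode `"slab"` (dense slab in the middle third of x),
#'   `"uniform"`, or `"planted"` (deterministic lattice of straight chains).
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(valence_A, valence_B, count_A, count_B, box, U0,
                            sticker_diameter = 2.5, mean_linker_length = 4.7,
                            bond_stiffness = 10, E_rep = 100, friction = 1,
                            timestep = NULL, temperature = 1, seed = 1L,
                            init_mode = c("slab", "uniform", "planted")) {
  init_mode <- match.arg(init_mode)
  stopifnot(valence_A >= 1, valence_B >= 1, count_A >= 1, count_B >= 0,
            length(box) == 3, all(box > 0), U0 >= 0, sticker_diameter > 0,
            mean_linker_length > 0, bond_stiffness > 0, friction >= 0,
            temperature >= 0)
  if (is.null(timestep)) timestep <- 2 * pi / sqrt(bond_stiffness) / 50
  if (timestep <= 0) stop("timestep must be > 0")
  r_att <- 0.8 * sticker_diameter
  r_rep <- 1.5 * sticker_diameter
  if (any(box <= 2 * max(r_att, r_rep)))
    stop("box lengths must exceed twice the largest interaction cutoff")
  structure(list(
    valence_A = as.integer(valence_A), valence_B = as.integer(valence_B),
    count_A = as.integer(count_A), count_B = as.integer(count_B),
    box = as.numeric(box), U0 = U0,
    sticker_diameter = sticker_diameter,
    mean_linker_length = mean_linker_length,
    bond_stiffness = bond_stiffness, E_rep = E_rep,
    r_att = r_att, r_rep = r_rep,
    friction = friction, timestep = timestep, temperature = temperature,
    seed = as.integer(seed), init_mode = init_mode
  ), class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("A%d:B%d system, %d + %d chains (%d stickers) in %g x %g x %g nm\n",
              x$valence_A, x$valence_B, x$count_A, x$count_B, n_beads(x),
              x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  U0 = %g kT, sigma = %g nm, linker %g nm (k = %g kT/nm^2)\n",
              x$U0, x$sticker_diameter, x$mean_linker_length,
              x$bond_stiffness))
  cat(sprintf("  global sticker concentration %.3f mM (A:B ratio %.3f)\n",
              stickers_to_mM(n_beads(x), x$box),
              (x$count_A * x$valence_A) / max(1, x$count_B * x$valence_B)))
  invisible(x)
}

#' Total bead count of a spec
#' @param spec a [simulation_spec()].
#' @return integer.
#' @export
n_beads <- function(spec) {
  spec$count_A * spec$valence_A + spec$count_B * spec$valence_B
}

# interaction parameter list handed to the C++ core
.cpp_pars <- function(spec) {
  list(U0 = spec$U0, r_att = spec$r_att, E_rep = spec$E_rep,
       r_rep = spec$r_rep, k_bond = spec$bond_stiffness,
       r0_bond = spec$mean_linker_length, mass = 1)
}

#' Construct a configuration object
#'
#' A `configuration` holds per-bead positions, species (`"A"`/`"B"`),
#' polymer id, and index within the chain, together with the periodic box.
#'
#' @param positions n x 3 matrix of positions in nm.
#' @param species character or factor, `"A"` or `"B"` per bead.
#' @param polymer integer polymer id per bead.
#' @param index integer index of the bead within its chain.
#' @param box numeric length-3 box edge lengths in nm.
#' @param spec optional [simulation_spec()] recorded for downstream defaults.
#' @return an object of class `configuration`.
#' @export
configuration <- function(positions, species, polymer, index, box,
                          spec = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(species),
            length(polymer) == length(species),
            length(index) == length(species), length(box) == 3)
  if (!all(is.finite(positions))) stop("positions must be finite")
  structure(list(positions = positions,
                 species = as.character(species),
                 polymer = as.integer(polymer),
                 index = as.integer(index),
                 box = as.numeric(box),
                 periodic = c(TRUE, TRUE, TRUE),
                 spec = spec),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("configuration: %d beads (%d A, %d B), %d polymers, box %g x %g x %g nm\n",
              nrow(x$positions), sum(x$species == "A"), sum(x$species == "B"),
              length(unique(x$polymer)), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

# bond table (i, j) of consecutive beads within each chain
.chain_bonds <- function(config) {
  ord <- order(config$polymer, config$index)
  ids <- seq_along(config$polymer)[ord]
  pol <- config$polymer[ord]
  same <- pol[-length(pol)] == pol[-1]
  cbind(ids[-length(ids)][same], ids[-1][same])
}

.species_int <- function(config) ifelse(config$species == "A", 1L, 2L)
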