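# Langevin dynamics driver

#' Run Langevin dynamics
#'
#' Integrates the system with a BAOAB splitting of Langevin dynamics at unit
#' bead mass.  With `spec$friction = 0` and `spec$temperature = 0` the
#' integrator reduces to velocity Verlet (used for energy-conservation
#' checks).  A fixed `(spec, seed)` pair gives a bit-identical trajectory.
#'
#' @param config starting [configuration()].
#' @param spec a [simulation_spec()]; `NULL` uses `config$spec`.
#' @param n_steps number of timesteps.
#' @param seed integer seed for the thermostat noise; defaults to `spec$seed`.
#' @param stride record every `stride`-th step (default: 100).
#' @param velocities optional n x 3 matrix of initial velocities; default
#'   draws from the Maxwell-Boltzmann distribution at `spec$temperature`
#'   (zero when `temperature = 0`).
#' @return a `trajectory` object: list with `times`, `frames` (list of
#'   [configuration()]), `epot`, `ekin` (energies per recorded frame, kT),
#'   `stride`, and the metadata needed to re-run (`spec`, `seed`,
#'   `friction`, `timestep`).
#' @export
run_langevin <- function(config, spec = config$spec, n_steps, seed = spec$seed,
                         stride = 100L, velocities = NULL) {
  stopifnot(inherits(config, "configuration"), n_steps >= 1, stride >= 1)
  if (is.null(spec)) stop("no simulation_spec available")
  # resolve timestep vs bond period: require >= 20 steps per period
  period <- 2 * pi / sqrt(spec$bond_stiffness)
  if (spec$timestep > period / 20)
    stop("timestep too large: need >= 20 steps per bond oscillation period")
  n <- nrow(config$positions)
  if (is.null(velocities)) {
    if (spec$temperature > 0) {
      rng <- .local_rng(seed + 7L)
      velocities <- matrix(sqrt(spec$temperature) *
                             .rng_gauss(rng, 3L * n), n, 3)
    } else velocities <- matrix(0, n, 3)
  }
  bonds <- .chain_bonds(config)
  res <- .run_langevin_cpp(config$positions, velocities, .species_int(config),
                           bonds, config$box, .cpp_pars(spec),
                           as.integer(n_steps), as.integer(stride),
                           spec$timestep, spec$friction, spec$temperature,
                           as.double(seed))
  frames <- lapply(res$frames, function(p) {
    configuration(p, config$species, config$polymer, config$index,
                  config$box, spec)
  })
  structure(list(times = res$times, frames = frames, epot = res$epot,
                 ekin = res$ekin, stride = as.integer(stride),
                 spec = spec, seed = as.integer(seed),
                 friction = spec$friction, timestep = spec$timestep,
                 velocities = res$velocities),
            class = "trajectory")
}

.rng_gauss <- function(rng, n) {
  # Box-Muller on the local generator
  m <- ceiling(n / 2)
  u1 <- vapply(seq_len(m), function(i) rng$unif(), 0)
  u2 <- vapply(seq_len(m), function(i) rng$unif(), 0)
  r <- sqrt(-2 * log(pmax(u1, 1e-300)))
  g <- c(r * cos(2 * pi * u2), r * sin(2 * pi * u2))
  g[seq_len(n)]
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, t in [%g, %g], %d beads\n",
              length(x$frames), x$times[1], x$times[length(x$times)],
              nrow(x$frames[[1]]$positions)))
  invisible(x)
}

#' Trajectory subscripting returns configurations
#' @param x a trajectory.
#' @param i frame index.
#' @param ... ignored.
#' @export
`[[.trajectory` <- function(x, i, ...) .subset2(x, "frames")[[i]]

#' Number of frames in a trajectory
#' @param x a trajectory.
#' @export
length.trajectory <- function(x) length(.subset2(x, "frames"))

#' Total potential energy of a configuration
#'
#' Sum of harmonic-bond terms and all non-bonded pair terms (cross-type
#' attraction, same-type repulsion) under the minimum-image convention.
#' Directly bonded pairs are excluded from the non-bonded sum.
#'
#' @param config a [configuration()].
#' @param spec a [simulation_spec()]; `NULL` uses `config$spec`.
#' @return energy in kT.
#' @export
total_energy <- function(config, spec = config$spec) {
  stopifnot(inherits(config, "configuration"))
  if (is.null(spec)) stop("no simulation_spec available")
  .total_energy_cpp(config$positions, .species_int(config),
                    .chain_bonds(config), config$box, .cpp_pars(spec))
}
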