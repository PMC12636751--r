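#' Advance a cell state by one overdamped Langevin step
#'
#' First-order Euler-Maruyama update of position-Langevin (Brownian)
#' dynamics: `x <- x + (F/gamma) * dt + sqrt(2 kT dt / gamma) * xi` with
#' independent standard-normal `xi` per coordinate.  Draws from the current
#' R RNG stream, so results are reproducible under [set.seed()].
#'
#' @param state a `cell_state`.
#' @param params a [sim_params()] object (`dt`, `kT`, `gamma` are used).
#' @param forces optional precomputed `n x 2` force matrix; computed from
#'   `state` via [total_forces()] when `NULL`.
#' @return The advanced `cell_state` (time incremented by `dt`).
#' @export
step_overdamped <- function(state, params, forces = NULL) {
  if (params$dt <= 0) stop("argument error: dt must be > 0", call. = FALSE)
  if (is.null(forces)) forces <- total_forces(state, params)
  if (any(!is.finite(forces))) {
    bad <- which(!is.finite(forces[, 1]) | !is.finite(forces[, 2]))[1L]
    stop("numerical instability: non-finite force on bead ", bad,
         call. = FALSE)
  }
  n <- nrow(state$positions)
  out <- state
  disp <- forces * (params$dt / params$gamma)
  if (params$kT > 0) {
    amp <- sqrt(2 * params$kT * params$dt / params$gamma)
    disp <- disp + matrix(amp * rnorm(2L * n), ncol = 2L, byrow = TRUE)
  }
  out$positions <- state$positions + disp
  out$time <- state$time + params$dt
  out$rng_state <- get0(".Random.seed", envir = globalenv())
  out
}

# indices (1-based, into state$bonds) of each filament's terminal bond and
# the cap on that bond's rest length implied by max_filament_length
terminal_bond_info <- function(state, params) {
  b <- state$bonds
  fil_ids <- sort(unique(state$filament_id[!is.na(state$filament_id)]))
  term <- integer(length(fil_ids))
  cap <- numeric(length(fil_ids))
  for (idx in seq_along(fil_ids)) {
    f <- fil_ids[idx]
    members <- which(state$filament_id == f)
    head_bead <- members[state$roles[members] == "actin_head"]
    rows <- which(b$kind == "filament" & (b$i %in% members | b$j %in% members))
    tb <- rows[b$i[rows] == head_bead | b$j[rows] == head_bead]
    stopifnot(length(tb) == 1L)
    term[idx] <- tb
    cap[idx] <- params$max_filament_length -
      (sum(b$rest_length[rows]) - b$rest_length[tb])
  }
  list(terminal = term, cap = cap)
}

#' Stochastic actin tip growth
#'
#' Independently for each filament, with probability `growth_rate` the
#' terminal (head-adjacent) bond's rest length is increased by
#' `growth_increment`, capped so the filament's total bond rest length never
#' exceeds `max_filament_length`.  This models polymerization at the tip as
#' an extending rest length; bead count is conserved.  Draws from the current
#' R RNG stream.
#'
#' @param state a `cell_state`.
#' @param params a [sim_params()] object.
#' @return The updated `cell_state` (positions untouched).
#' @export
grow_filaments <- function(state, params) {
  if (params$growth_rate < 0 || params$growth_rate > 1)
    stop("argument error: growth_rate must be in [0, 1]", call. = FALSE)
  info <- terminal_bond_info(state, params)
  if (length(info$terminal) == 0L || params$growth_rate == 0) return(state)
  out <- state
  grow <- runif(length(info$terminal)) < params$growth_rate
  for (idx in which(grow)) {
    tb <- info$terminal[idx]
    if (out$bonds$rest_length[tb] + params$growth_increment <= info$cap[idx])
      out$bonds$rest_length[tb] <- out$bonds$rest_length[tb] +
        params$growth_increment
  }
  out
}

#' Run a full simulation
#'
#' Builds the cell from `params`, applies the symmetry-breaking position
#' perturbation (`init_noise`, seeded from `params$seed`), then advances
#' `n_steps` of overdamped Langevin dynamics with stochastic tip growth in a
#' compiled loop, recording a snapshot every `record_every` steps (the
#' initial state is frame 1).  The whole pipeline is a deterministic function
#' of `params` (including `seed`): identical inputs give bitwise-identical
#' trajectories.
#'
#' Runs abort with a "numerical instability" error (naming the step and bead)
#' if positions become non-finite or any membrane bond stretches beyond 3x
#' its rest length.
#'
#' @param params a [sim_params()] object.
#' @return A `trajectory` object: list with `snapshots` (list of
#'   `cell_state`), `times`, `energies` (per-frame energy breakdown matrix),
#'   `record_every`, `params`, and `wall_metadata`.
#' @examples
#' traj <- run_simulation(fixture_params("small", n_steps = 500L,
#'                                       record_every = 250L))
#' length(traj$snapshots)
#' @export
run_simulation <- function(params) {
  validate_params(params)
  cell <- build_cell(params)
  withr_seed(params$seed, {
    if (params$init_noise > 0) {
      noise <- matrix(rnorm(2L * nrow(cell$positions), sd = params$init_noise),
                      ncol = 2L)
      cell$positions <- cell$positions + noise
    }
    info <- terminal_bond_info(cell, params)
    cs <- state_to_cpp(cell)
    res <- run_dynamics_cpp(
      cell$positions, cs$roles, cs$bonds, cs$angles, state_pairpars(params),
      as.integer(info$terminal) - 1L, as.numeric(info$cap),
      params$n_steps, params$dt, params$kT, params$gamma,
      params$record_every, params$growth_rate, params$growth_increment,
      params$verlet_skin, 25L, params$seed)
  })
  n_frames <- length(res$positions)
  snapshots <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    st <- cell
    st$positions <- res$positions[[fr]]
    st$bonds$rest_length <- as.numeric(res$rest_lengths[[fr]])
    st$time <- res$times[fr]
    st$rng_state <- NULL
    snapshots[[fr]] <- st
  }
  energies <- res$energies
  colnames(energies) <- c("spring", "bending", "attraction",
                          "excluded_volume", "total")
  traj <- list(snapshots = snapshots, times = as.numeric(res$times),
               energies = energies, record_every = params$record_every,
               params = params,
               wall_metadata = list(seed = params$seed,
                                    package_version =
                                      as.character(packageVersion("neuritesim"))))
  class(traj) <- "trajectory"
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames of %d beads, t in [%g, %g]\n",
              length(x$snapshots), nrow(x$snapshots[[1]]$positions),
              min(x$times), max(x$times)))
  cat(sprintf("  U3 = %g, kappa00 = %g, seed = %d\n", x$params$U3,
              x$params$kappa00, x$params$seed))
  invisible(x)
}
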