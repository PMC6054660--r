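# Synthetic fixtures: ground-truth single-particle trajectories (Brownian,
# corral-confined, switching) and pseudo coarse-grained multi-protein
# trajectories generated by running the engine with known parameters. These
# stand in for coarse-grained MD input when exercising the parameterization
# and analysis workflows.

tracer_traj <- function(x, y, dt, id = 1L, species = "tracer",
                        theta = NULL) {
  n <- length(x)
  tb <- tibble::tibble(
    frame = seq_len(n) - 1L,
    time_ns = (seq_len(n) - 1L) * dt,
    id = as.integer(id), species = species,
    x = x, y = y,
    theta = if (is.null(theta)) 0 else theta,
    wind_x = 0L, wind_y = 0L,
    cluster_id = as.integer(id)
  )
  structure(tb, boundary = "unbounded", step_duration = dt,
            class = c("meso_trajectory", class(tibble::tibble())))
}

#' Generate a free Brownian trajectory
#'
#' Per-axis Gaussian increments with std `sqrt(2 * D * dt)`, giving the exact
#' 2D ensemble law `MSD(t) = 4 D t`.
#'
#' @param n_steps number of steps (trajectory has `n_steps + 1` frames).
#' @param D diffusion coefficient in nm^2/ns (`D = 0` gives a constant
#'   trajectory).
#' @param dt frame interval in ns (default 10).
#' @param x0,y0 starting position (nm).
#' @param seed optional RNG seed.
#' @return a single-particle trajectory tibble.
#' @export
gen_brownian <- function(n_steps, D, dt = 10, x0 = 0, y0 = 0, seed = NULL) {
  if (D < 0) rlang::abort("`D` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(2 * D * dt)
  x <- x0 + cumsum(c(0, rnorm(n_steps, 0, s)))
  y <- y0 + cumsum(c(0, rnorm(n_steps, 0, s)))
  tracer_traj(x, y, dt)
}

corral_walk <- function(n_steps, s, radius, cx, cy, x0, y0) {
  x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
  x[1] <- x0; y[1] <- y0
  for (i in seq_len(n_steps)) {
    px <- x[i] + rnorm(1, 0, s)
    py <- y[i] + rnorm(1, 0, s)
    if ((px - cx)^2 + (py - cy)^2 <= radius^2) {
      x[i + 1] <- px; y[i + 1] <- py
    } else {
      x[i + 1] <- x[i]; y[i + 1] <- y[i] # proposal rejected: stay put
    }
  }
  list(x = x, y = y)
}

#' Generate a corral-confined trajectory
#'
#' Brownian proposal steps inside a hard disc: proposals leaving the disc of
#' radius `corral_radius` are rejected and the position repeats. Emulates a
#' protein corralled by surrounding slowly moving clusters; the long-time MSD
#' plateaus below `2 * corral_radius^2`.
#'
#' @inheritParams gen_brownian
#' @param corral_radius disc radius in nm (> 0), centred on the start.
#' @return a single-particle trajectory tibble.
#' @export
gen_corral <- function(n_steps, D, corral_radius, dt = 10,
                       x0 = 0, y0 = 0, seed = NULL) {
  if (corral_radius <= 0) rlang::abort("`corral_radius` must be positive")
  if (D < 0) rlang::abort("`D` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  w <- corral_walk(n_steps, sqrt(2 * D * dt), corral_radius, x0, y0, x0, y0)
  tracer_traj(w$x, w$y, dt)
}

#' Generate a trajectory that switches between free and confined motion
#'
#' Alternates Brownian and corral segments at the given switch frames
#' (starting Brownian), continuous at every switch; each corral is centred on
#' the position at its switch point. Ground truth for the "mixed" motion
#' class.
#'
#' @inheritParams gen_corral
#' @param switch_frames strictly increasing frame indices (within
#'   `1..n_steps`) at which the motion mode flips; empty for pure Brownian.
#' @return a single-particle trajectory tibble.
#' @export
gen_switching <- function(n_steps, D, corral_radius, switch_frames,
                          dt = 10, x0 = 0, y0 = 0, seed = NULL) {
  if (length(switch_frames)) {
    if (is.unsorted(switch_frames, strictly = TRUE)) {
      rlang::abort("`switch_frames` must be strictly increasing")
    }
    if (min(switch_frames) < 1 || max(switch_frames) > n_steps) {
      rlang::abort("`switch_frames` out of range")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(2 * D * dt)
  bounds <- c(0, switch_frames, n_steps)
  x <- x0; y <- y0
  for (seg in seq_len(length(bounds) - 1)) {
    len <- bounds[seg + 1] - bounds[seg]
    if (len == 0) next
    cx <- x[length(x)]; cy <- y[length(y)]
    if (seg %% 2 == 1) { # Brownian segment
      x <- c(x, cx + cumsum(rnorm(len, 0, s)))
      y <- c(y, cy + cumsum(rnorm(len, 0, s)))
    } else {             # corral segment centred at the switch position
      w <- corral_walk(len, s, corral_radius, cx, cy, cx, cy)
      x <- c(x, w$x[-1])
      y <- c(y, w$y[-1])
    }
  }
  tracer_traj(x, y, dt)
}

#' Generate a pseudo coarse-grained trajectory with known ground truth
#'
#' Runs the mesoscale engine with the supplied motion laws and patches,
#' recording every step (10 ns resolution by default), and tags the output
#' with the true parameters so parameter-recovery tests can compare against
#' them. This exercises the parameterization workflow against the exact
#' forward model it assumes.
#'
#' @param n_x,n_y,box_width,box_height,boundary,n_steps,seed see
#'   [sim_config()].
#' @param species a `species_params` holding the ground-truth laws/patches.
#' @return a `meso_trajectory` with a `truth` attribute (the
#'   `species_params` used).
#' @export
gen_pseudo_cg <- function(species = btub_species(trans_A = 0.3, rot_A = 3),
                          n_x = 8, n_y = 8, box_width = 80, box_height = 80,
                          boundary = "hard_wall", n_steps = 500,
                          seed = NULL) {
  cfg <- sim_config(box_width, box_height, n_x = n_x, n_y = n_y,
                    boundary = boundary, species = species,
                    n_steps = n_steps, save_interval = 1, seed = seed)
  traj <- run_mesoscale(cfg)
  attr(traj, "truth") <- species
  traj
}

#' Generate a random non-clashing configuration
#'
#' Places proteins uniformly at random at the requested surface density with
#' all pairwise distances at least the clash distance (rejection sampling),
#' random orientations, all singleton clusters.
#'
#' @param density proteins per um^2 (the crowded-membrane reference value is
#'   10,000 um^-2).
#' @param box_width,box_height box dimensions in nm.
#' @param config optional [sim_config()] supplying cutoffs, boundary and
#'   species (default: a BtuB-like box of the given size).
#' @param max_attempts placement attempts per protein.
#' @param seed optional RNG seed.
#' @return a state tibble (see [init_grid()]).
#' @export
gen_random_config <- function(density, box_width, box_height,
                              config = NULL, max_attempts = 10000,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(config)) {
    config <- sim_config(box_width, box_height, n_x = 1, n_y = 1,
                         species = btub_species(), n_steps = 0)
  }
  n <- round(density * box_width * box_height / 1e6) # nm^2 -> um^2
  empty <- new_state(integer(), character(), numeric(), numeric(),
                     numeric(), integer())
  if (n == 0) return(empty)
  insert_proteins(empty, n, config, max_attempts = max_attempts)
}
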