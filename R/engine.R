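# The mesoscale engine: grid initialization, interaction/clash predicates,
# cluster-size-dependent rigid moves, the per-step update with clash-cascade
# rejection, permanent re-clustering, protein insertion, and the run driver.
#
# States are tibbles (id, species, x, y, theta, cluster_id). Coordinates are
# absolute nm; in periodic mode a state's x/y are *unwrapped* so that rigid
# clusters stay geometrically consistent across the boundary. Trajectories
# store wrapped coordinates plus integer winding numbers.

new_state <- function(id, species, x, y, theta, cluster_id) {
  tibble::tibble(id = as.integer(id), species = as.character(species),
                 x = x, y = y, theta = wrap_angle(theta),
                 cluster_id = as.integer(cluster_id))
}

#' Initialize proteins on a centred square grid
#'
#' Proteins are placed on an `n_x` by `n_y` square grid at `grid_spacing`
#' nearest-neighbour distance, centred in the box, with orientations drawn
#' uniformly from the current RNG. All proteins start as singleton clusters
#' and, because the spacing exceeds the interaction cutoff, no pair clashes
#' or interacts.
#'
#' @param config a [sim_config()]. If `config$seed` is set the RNG is seeded
#'   first.
#' @return a state tibble with columns `id`, `species`, `x`, `y`, `theta`,
#'   `cluster_id`.
#' @export
init_grid <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_x * config$n_y
  off_x <- (config$box_width - (config$n_x - 1) * config$grid_spacing) / 2
  off_y <- (config$box_height - (config$n_y - 1) * config$grid_spacing) / 2
  gx <- rep(seq_len(config$n_x) - 1, times = config$n_y) * config$grid_spacing
  gy <- rep(seq_len(config$n_y) - 1, each = config$n_x) * config$grid_spacing
  new_state(seq_len(n), names(config$species)[1],
            off_x + gx, off_y + gy, runif(n) * 360, seq_len(n))
}

pose_fields <- function(p) {
  # accept a one-row data frame or a named list/vector as a protein pose
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1)
    p <- as.list(p)
  }
  list(x = as.numeric(p[["x"]]), y = as.numeric(p[["y"]]),
       theta = as.numeric(p[["theta"]] %||% 0))
}

pair_displacement <- function(p1, p2, config) {
  d <- c(p2$x - p1$x, p2$y - p1$y)
  if (!is.null(config$boundary) && config$boundary == "periodic") {
    L <- c(config$box_width, config$box_height)
    d <- d - L * round(d / L)
  }
  d
}

#' Are two proteins interacting?
#'
#' True iff the centre distance lies in the interaction band
#' `(clash_fraction * cutoff, cutoff]` and -- when `specific_interfaces` is on
#' -- the bearing from protein 1 to protein 2 minus `theta1` falls in one of
#' protein 1's patches, while the reverse bearing minus `theta2` falls in one
#' of protein 2's patches (all modulo 360).
#'
#' @param p1,p2 protein poses: one-row data frames or named lists with `x`,
#'   `y`, `theta`.
#' @param params a `species_params` applied to both proteins, or a list of
#'   two (`params[[1]]` for `p1`, `params[[2]]` for `p2`).
#' @param config a [sim_config()] (supplies cutoffs, boundary mode and the
#'   `specific_interfaces` switch).
#' @return logical scalar.
#' @export
are_interacting <- function(p1, p2, params, config) {
  p1 <- pose_fields(p1); p2 <- pose_fields(p2)
  if (inherits(params, "species_params")) params <- list(params, params)
  d <- pair_displacement(p1, p2, config)
  dist <- sqrt(sum(d^2))
  lo <- config$clash_fraction * config$interaction_cutoff
  if (!(dist > lo && dist <= config$interaction_cutoff)) return(FALSE)
  if (!isTRUE(config$specific_interfaces)) return(TRUE)
  bearing <- atan2(d[2], d[1]) * 180 / pi
  in_patch(bearing - p1$theta, params[[1]]$patches) &&
    in_patch(bearing + 180 - p2$theta, params[[2]]$patches)
}

#' Do two proteins clash?
#'
#' A clash is a centre distance strictly below
#' `clash_fraction * interaction_cutoff` (4.9 nm at the defaults); a distance
#' exactly at the threshold is clash-free, so the clash region and the
#' interaction band do not overlap.
#'
#' @inheritParams are_interacting
#' @return logical scalar.
#' @export
is_clash <- function(p1, p2, config) {
  p1 <- pose_fields(p1); p2 <- pose_fields(p2)
  d <- pair_displacement(p1, p2, config)
  sqrt(sum(d^2)) < config$clash_fraction * config$interaction_cutoff
}

#' Sample a rigid move for a cluster of a given size
#'
#' Translations per axis and the rotation are independent zero-mean Gaussians
#' whose standard deviations follow the species' power laws
#' `std(n) = A * n^(-b)`; sizes beyond the parameterization domain use the
#' same law (extrapolation), floored at `std_min`.
#'
#' @param cluster_size positive integer.
#' @param params a `species_params`.
#' @return a list with `dx`, `dy` (nm) and `dtheta` (degrees).
#' @export
sample_cluster_move <- function(cluster_size, params) {
  if (length(cluster_size) != 1 || cluster_size < 1) {
    rlang::abort("`cluster_size` must be a single integer >= 1")
  }
  st <- power_law_std(cluster_size, params$trans_law[["A"]],
                      params$trans_law[["b"]], params$std_min)
  sr <- power_law_std(cluster_size, params$rot_law[["A"]],
                      params$rot_law[["b"]], params$std_min)
  list(dx = rnorm(1, 0, st), dy = rnorm(1, 0, st), dtheta = rnorm(1, 0, sr))
}

#' Recompute the cluster partition of a state
#'
#' Connected components of the interaction graph, unioned with the existing
#' partition: association is permanent, so components only ever grow. Cluster
#' ids are the minimum member id of each component.
#'
#' @param state a state tibble.
#' @param config a [sim_config()].
#' @return the state with `cluster_id` updated.
#' @export
rebuild_clusters <- function(state, config) {
  n <- nrow(state)
  if (n == 0) return(state)
  edges <- integer(0)
  sp <- config$species
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pi <- state[i, ]; pj <- state[j, ]
      ok <- are_interacting(pi, pj,
                            list(sp[[pi$species]], sp[[pj$species]]), config)
      if (ok) edges <- c(edges, i, j)
    }
  }
  # permanence: members of an existing cluster stay connected
  prev <- split(seq_len(n), state$cluster_id)
  for (m in prev) {
    if (length(m) > 1) edges <- c(edges, rbind(m[-length(m)], m[-1]))
  }
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  minid <- tapply(state$id, comp, min)
  state$cluster_id <- as.integer(minid[as.character(comp)])
  state
}

engine_call <- function(state, config, n_steps, save_every) {
  sp_names <- names(config$species)
  sp_idx <- match(state$species, sp_names)
  if (anyNA(sp_idx)) rlang::abort("state contains species absent from config")
  A_t <- vapply(config$species, function(s) s$trans_law[["A"]], 0)
  b_t <- vapply(config$species, function(s) s$trans_law[["b"]], 0)
  A_r <- vapply(config$species, function(s) s$rot_law[["A"]], 0)
  b_r <- vapply(config$species, function(s) s$rot_law[["b"]], 0)
  s_min <- vapply(config$species, function(s) s$std_min, 0)
  patch_list <- lapply(config$species, function(s) {
    as.matrix(s$patches[, c("start", "end")])
  })
  .meso_run_cpp(state$x, state$y, state$theta,
                state$cluster_id, sp_idx - 1L,
                A_t, b_t, A_r, b_r, s_min, unname(patch_list),
                config$box_width, config$box_height,
                config$boundary == "periodic",
                config$interaction_cutoff, config$clash_fraction,
                isTRUE(config$specific_interfaces),
                as.integer(n_steps), as.integer(save_every))
}

engine_frames <- function(res, state, config, step_offset = 0) {
  n <- nrow(state)
  steps <- res$rec_step
  tibble::tibble(
    frame = rep(steps + step_offset, each = n),
    time_ns = rep((steps + step_offset) * config$step_duration, each = n),
    id = rep(state$id, times = length(steps)),
    species = rep(state$species, times = length(steps)),
    x = res$x, y = res$y, theta = res$theta,
    wind_x = res$wind_x, wind_y = res$wind_y,
    # engine cluster ids are positional (1..n); map to protein ids
    cluster_id = as.integer(state$id[res$cluster_id])
  )
}

engine_final_state <- function(res, state) {
  new_state(state$id, state$species, res$final_x, res$final_y,
            res$final_theta, state$id[res$final_cluster])
}

#' Advance a state by engine steps
#'
#' Runs the per-step update: every cluster is assigned a sampled rigid move
#' (translation + rotation about its centre of mass, each member's own
#' orientation incremented); in hard-wall mode whole-cluster moves that would
#' exit the box are rejected; clashing cluster pairs are reverted to their
#' start-of-step poses and the check iterated to a fixed point; finally the
#' cluster partition is re-derived (permanently).
#'
#' @param state a state tibble (clash-free).
#' @param config a [sim_config()].
#' @param n_steps number of steps to advance (default 1).
#' @return the updated state tibble. In periodic mode coordinates are
#'   unwrapped.
#' @export
step_state <- function(state, config, n_steps = 1) {
  res <- engine_call(state, config, n_steps, save_every = n_steps + 1L)
  engine_final_state(res, state)
}

#' Insert proteins at random non-clashing positions
#'
#' Mimics insertion of newly synthesized proteins by the BAM machinery:
#' `n_new` proteins are added one at a time at uniform-random positions that
#' are at least the clash distance from every existing protein, with uniform
#' random orientations, as singleton clusters. Existing poses are untouched.
#'
#' @param state a state tibble.
#' @param n_new number of proteins to insert.
#' @param config a [sim_config()] (the new proteins take the first species).
#' @param max_attempts rejection-sampling attempts per protein before failing.
#' @return the augmented state tibble.
#' @export
insert_proteins <- function(state, n_new, config, max_attempts = 10000) {
  if (n_new == 0) return(state)
  lo <- config$clash_fraction * config$interaction_cutoff
  periodic <- config$boundary == "periodic"
  L <- c(config$box_width, config$box_height)
  xs <- state$x; ys <- state$y
  if (periodic) { xs <- xs %% L[1]; ys <- ys %% L[2] }
  next_id <- if (nrow(state)) max(state$id) + 1L else 1L
  new_x <- new_y <- numeric(n_new)
  for (k in seq_len(n_new)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      px <- runif(1) * L[1]; py <- runif(1) * L[2]
      dx <- xs - px; dy <- ys - py
      if (periodic) {
        dx <- dx - L[1] * round(dx / L[1])
        dy <- dy - L[2] * round(dy / L[2])
      }
      if (!length(dx) || min(dx^2 + dy^2) >= lo^2) {
        new_x[k] <- px; new_y[k] <- py
        xs <- c(xs, px); ys <- c(ys, py)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rlang::abort(sprintf(
        "could not place inserted protein %d of %d after %d attempts (membrane too crowded)",
        k, n_new, max_attempts))
    }
  }
  ids <- next_id + seq_len(n_new) - 1L
  dplyr::bind_rows(
    state,
    new_state(ids, names(config$species)[1], new_x, new_y,
              runif(n_new) * 360, ids)
  )
}

new_meso_trajectory <- function(frames, config) {
  structure(
    frames,
    box = c(width = config$box_width, height = config$box_height),
    boundary = config$boundary,
    step_duration = config$step_duration,
    species = config$species,
    seed = config$seed,
    class = c("meso_trajectory", class(tibble::tibble()))
  )
}

#' Trajectory metadata
#' @param traj a `meso_trajectory`.
#' @return a list with `box`, `boundary`, `step_duration`, `species`, `seed`.
#' @export
traj_meta <- function(traj) {
  list(box = attr(traj, "box"), boundary = attr(traj, "boundary"),
       step_duration = attr(traj, "step_duration"),
       species = attr(traj, "species"), seed = attr(traj, "seed"))
}

#' Run a mesoscale simulation
#'
#' Initializes the grid (unless `state` is supplied), advances `n_steps`
#' engine steps of `step_duration` ns, and records a frame every
#' `save_interval` steps (plus the initial and final frames). Optionally
#' pauses at `insert_at_step` to add `insert_n` new proteins at random
#' non-clashing positions before continuing.
#'
#' @param config a [sim_config()]. `config$seed` (if non-`NULL`) seeds the RNG
#'   so the run is fully reproducible.
#' @param insert_n,insert_at_step optional mid-run protein insertion.
#' @param state optional starting state tibble (bypasses [init_grid()]).
#' @return a `meso_trajectory`: a tibble with columns `frame`, `time_ns`,
#'   `id`, `species`, `x`, `y`, `theta`, `wind_x`, `wind_y`, `cluster_id`
#'   and metadata attributes (see [traj_meta()]). In periodic mode `x`/`y`
#'   are wrapped into the box and `wind_x`/`wind_y` hold winding numbers;
#'   unwrapped coordinates are `x + wind_x * box_width` etc.
#' @export
run_mesoscale <- function(config, insert_n = 0, insert_at_step = NULL,
                          state = NULL) {
  if (is.null(state)) {
    state <- init_grid(config) # seeds the RNG if config$seed is set
  } else if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  if (insert_n > 0 && !is.null(insert_at_step)) {
    stopifnot(insert_at_step >= 0, insert_at_step <= config$n_steps)
    res1 <- engine_call(state, config, insert_at_step, config$save_interval)
    f1 <- engine_frames(res1, state, config)
    state1 <- engine_final_state(res1, state)
    state2 <- insert_proteins(state1, insert_n, config)
    res2 <- engine_call(state2, config, config$n_steps - insert_at_step,
                        config$save_interval)
    f2 <- engine_frames(res2, state2, config, step_offset = insert_at_step)
    # the post-insertion record replaces the pre-insertion one at that step
    f1 <- dplyr::filter(f1, .data$frame < insert_at_step)
    frames <- dplyr::bind_rows(f1, f2)
  } else {
    res <- engine_call(state, config, config$n_steps, config$save_interval)
    frames <- engine_frames(res, state, config)
  }
  new_meso_trajectory(frames, config)
}

#' Per-frame cluster summary of a trajectory
#'
#' @param traj a `meso_trajectory` (or any frame table with `frame` and
#'   `cluster_id`).
#' @return a tibble with one row per frame: `n_proteins`, `n_clusters`,
#'   `max_cluster_size`.
#' @export
cluster_summary <- function(traj) {
  traj |>
    dplyr::group_by(.data$frame, .data$time_ns) |>
    dplyr::summarise(
      n_proteins = dplyr::n(),
      n_clusters = dplyr::n_distinct(.data$cluster_id),
      max_cluster_size = max(table(.data$cluster_id)),
      .groups = "drop"
    )
}

#' Extract one frame of a trajectory
#' @param traj a `meso_trajectory`.
#' @param frame frame index; defaults to the last recorded frame.
#' @return a tibble of per-protein records for that frame.
#' @export
traj_frame <- function(traj, frame = NULL) {
  if (is.null(frame)) frame <- max(traj$frame)
  dplyr::filter(tibble::as_tibble(traj), .data$frame == !!frame)
}

#' Unwrapped coordinates of a trajectory
#'
#' Adds `xu`/`yu` columns: `x + wind_x * box_width` and
#' `y + wind_y * box_height` (identical to `x`/`y` when there is no box or in
#' hard-wall mode, where winding is zero).
#'
#' @param traj a `meso_trajectory` or compatible tibble.
#' @return the tibble with `xu` and `yu` columns appended.
#' @export
unwrap_coords <- function(traj) {
  box <- attr(traj, "box")
  wx <- if (is.null(traj[["wind_x"]])) 0L else traj$wind_x
  wy <- if (is.null(traj[["wind_y"]])) 0L else traj$wind_y
  if (is.null(box)) {
    traj$xu <- traj$x
    traj$yu <- traj$y
  } else {
    traj$xu <- traj$x + wx * box[["width"]]
    traj$yu <- traj$y + wy * box[["height"]]
  }
  traj
}
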