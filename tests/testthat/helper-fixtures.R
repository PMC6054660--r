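# Shared fixtures: species variants and hand-built trajectory tables.

# a species that never associates (no patches + specific interfaces on)
isolated_species <- function(trans_A = 0.2, rot_A = 2) {
  species_params("free", patches = NULL,
                 trans_law = c(A = trans_A, b = 0.5),
                 rot_law = c(A = rot_A, b = 0.5))
}

btub_test_config <- function(n_steps = 200, seed = 1, ...) {
  sim_config(120, 120, n_x = 12, n_y = 12, species = btub_species(),
             n_steps = n_steps, seed = seed, ...)
}

# wrap a plain frame table in trajectory metadata
as_test_traj <- function(df, box = NULL, boundary = "hard_wall", dt = 10) {
  structure(tibble::as_tibble(df),
            box = box, boundary = boundary, step_duration = dt,
            class = c("meso_trajectory", class(tibble::tibble())))
}

# single protein pose for predicate tests
pose <- function(x, y, theta = 0) list(x = x, y = y, theta = theta)

# minimum over frames of the minimum pairwise distance (hard-wall coords)
min_pair_distance <- function(traj) {
  min(vapply(split(traj, traj$frame), function(f) {
    if (nrow(f) < 2) return(Inf)
    d <- stats::dist(cbind(f$x, f$y))
    min(d)
  }, 0))
}

# pooled multi-replicate pseudo-CG fixture for parameter recovery
pseudo_cg_pool <- function(species, n_runs = 30, n_steps = 80, seed0 = 0) {
  runs <- lapply(seq_len(n_runs), function(s) {
    tr <- gen_pseudo_cg(species = species, n_x = 14, n_y = 14,
                        box_width = 140, box_height = 140,
                        n_steps = n_steps, seed = seed0 + s)
    tr$frame <- tr$frame + s * 100000L
    tr
  })
  pool <- dplyr::bind_rows(runs)
  attr(pool, "boundary") <- "hard_wall"
  pool
}
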