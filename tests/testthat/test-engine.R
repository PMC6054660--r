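# Engine: initialization, move sampling, the update step's contracts
# (rigidity, no overlap, irreversible association, boundaries, determinism)
# and protein insertion.

test_that("grid initialization places, spaces and centres proteins", {
  cfg <- btub_test_config(seed = 3)
  st <- init_grid(cfg)
  expect_equal(nrow(st), 144)
  expect_equal(st$cluster_id, st$id) # all singletons
  d <- as.matrix(dist(cbind(st$x, st$y)))
  diag(d) <- Inf
  expect_equal(min(d), 10) # nearest-neighbour spacing
  expect_true(all(st$theta >= 0 & st$theta < 360))

  # degenerate single-protein grid sits at the box centre
  cfg1 <- sim_config(50, 50, n_x = 1, n_y = 1, species = btub_species(),
                     n_steps = 0)
  st1 <- init_grid(cfg1)
  expect_equal(c(st1$x, st1$y), c(25, 25))
  expect_equal(st1$cluster_id, 1L)

  # a large patch is centred: 70x70 grid spans 690 nm inside a 1 um box
  cfg70 <- sim_config(1000, 1000, n_x = 70, n_y = 70,
                      species = btub_species(), n_steps = 0)
  st70 <- init_grid(cfg70)
  expect_equal(nrow(st70), 4900)
  expect_equal(range(st70$x), c(155, 845))
  expect_equal(diff(range(st70$y)), 690)

  # a grid that does not fit is a configuration error
  expect_error(sim_config(100, 100, n_x = 12, n_y = 12,
                          species = btub_species(), n_steps = 0),
               "does not fit")
})

test_that("cluster moves are zero-mean Gaussians with the power-law std", {
  sp <- btub_species(trans_A = 0.35, rot_A = 4)
  set.seed(42)
  draws <- replicate(1e5, unlist(sample_cluster_move(4, sp)))
  stds <- apply(draws, 1, sd)
  means <- apply(draws, 1, mean)
  # std(4) = A / 2 for b = 0.5, within Monte-Carlo tolerance
  expect_equal(unname(stds[c("dx", "dy")]), rep(0.35 / 2, 2), tolerance = 0.02)
  expect_equal(unname(stds["dtheta"]), 4 / 2, tolerance = 0.02)
  expect_true(all(abs(means) < 4 * c(0.175, 0.175, 2) / sqrt(1e5)))
  expect_error(sample_cluster_move(0, sp), ">= 1")
})

test_that("bonded pairs move rigidly and association is permanent", {
  # facing pair placed in the interaction band: bearing 45 gives 45 - 0 = 45
  # in [15, 80] for p1 and 45 + 180 - 160 = 65 in [15, 80] for p2
  st <- tibble::tibble(id = 1:2, species = "BtuB",
                       x = c(50, 50 + 4.95 * cos(pi / 4)),
                       y = c(50, 50 + 4.95 * sin(pi / 4)),
                       theta = c(0, 160), cluster_id = 1:2)
  # with a frozen motion law the poses persist and the bond must form
  frozen <- species_params("BtuB", patches = btub_species()$patches,
                           trans_law = c(A = 0, b = 0.5),
                           rot_law = c(A = 0, b = 0.5))
  cfg0 <- sim_config(120, 120, n_x = 2, n_y = 2, species = frozen,
                     n_steps = 1, seed = 7)
  st1 <- step_state(st, cfg0)
  expect_equal(st1$cluster_id, c(1L, 1L))
  # once bonded, the pair distance is conserved under full motion
  cfg <- btub_test_config(n_steps = 1, seed = 7)
  d0 <- 4.95
  for (k in 1:50) {
    st1 <- step_state(st1, cfg)
    d <- sqrt(diff(st1$x)^2 + diff(st1$y)^2)
    expect_equal(d, d0, tolerance = 1e-9)
    expect_equal(st1$cluster_id, c(1L, 1L))
  }
})

test_that("rebuild_clusters is transitive and never forgets an edge", {
  cfg <- btub_test_config(specific_interfaces = FALSE)
  # chain: A-B and B-C within 5 nm, A-C at ~9.9 nm
  st <- tibble::tibble(id = 1:3, species = "BtuB",
                       x = c(10, 14.95, 19.9), y = 10, theta = 0,
                       cluster_id = 1:3)
  out <- rebuild_clusters(st, cfg)
  expect_equal(out$cluster_id, c(1L, 1L, 1L))

  # far-apart proteins stay singletons
  st2 <- tibble::tibble(id = 1:3, species = "BtuB",
                        x = c(10, 30, 50), y = 10, theta = 0,
                        cluster_id = 1:3)
  expect_equal(rebuild_clusters(st2, cfg)$cluster_id, 1:3)

  # a dimer that has drifted apart stays one cluster (permanent association)
  st3 <- tibble::tibble(id = 1:2, species = "BtuB",
                        x = c(10, 15.4), y = 10, theta = 0,
                        cluster_id = c(1L, 1L))
  expect_equal(rebuild_clusters(st3, cfg)$cluster_id, c(1L, 1L))
})

test_that("hard walls confine every cluster member", {
  # a protein against the wall with huge steps: every recorded pose in box
  sp <- isolated_species(trans_A = 5)
  cfg <- sim_config(30, 30, n_x = 2, n_y = 2, species = sp,
                    grid_spacing = 20, n_steps = 500, save_interval = 1,
                    seed = 11)
  traj <- run_mesoscale(cfg)
  expect_true(all(traj$x >= 0 & traj$x <= 30))
  expect_true(all(traj$y >= 0 & traj$y <= 30))
  expect_true(all(traj$wind_x == 0L & traj$wind_y == 0L))
})

test_that("no pair ever comes closer than the clash distance", {
  cfg <- btub_test_config(n_steps = 400, save_interval = 20, seed = 2,
                          specific_interfaces = FALSE)
  traj <- run_mesoscale(cfg)
  expect_gte(min_pair_distance(traj), 4.9)
})

test_that("association is irreversible: growth curves are monotone", {
  cfg <- btub_test_config(n_steps = 1000, save_interval = 50, seed = 4)
  traj <- run_mesoscale(cfg)
  cs <- cluster_summary(traj)
  expect_true(all(diff(cs$max_cluster_size) >= 0))
  expect_true(all(diff(cs$n_clusters) <= 0))
  # partition invariant: sizes sum to N at every frame
  expect_true(all(cs$n_proteins == 144))
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- btub_test_config(n_steps = 200, seed = 9)
  expect_identical(run_mesoscale(cfg), run_mesoscale(cfg))
  # and a zero-step run records only the initial frame
  cfg0 <- btub_test_config(n_steps = 0, seed = 9)
  expect_equal(unique(run_mesoscale(cfg0)$frame), 0)
})

test_that("periodic runs stay rigid across the boundary and track winding", {
  sp <- species_params("BtuB", patches = NULL,
                       trans_law = c(A = 1, b = 0.5),
                       rot_law = c(A = 5, b = 0.5))
  cfg <- sim_config(60, 60, n_x = 2, n_y = 2, boundary = "periodic",
                    species = sp, grid_spacing = 30, n_steps = 3000,
                    save_interval = 10, specific_interfaces = FALSE, seed = 12)
  # pre-bonded pair straddling the seam; unwrapped coordinates are
  # cluster-consistent (p2 at -2.95 wraps to 57.05 with winding -1)
  st <- tibble::tibble(id = 1:2, species = "BtuB",
                       x = c(2, -2.95), y = 30, theta = 0,
                       cluster_id = c(1L, 1L))
  res <- run_mesoscale(cfg, state = st)
  # wrapped coordinates are always inside the box
  expect_true(all(res$x >= 0 & res$x < 60))
  # minimum-image pair distance is conserved once bonded
  wide <- tidyr::pivot_wider(res[, c("frame", "id", "x", "y")],
                             names_from = "id", values_from = c("x", "y"))
  dx <- wide$x_2 - wide$x_1; dx <- dx - 60 * round(dx / 60)
  dy <- wide$y_2 - wide$y_1; dy <- dy - 60 * round(dy / 60)
  d <- sqrt(dx^2 + dy^2)
  expect_equal(d, rep(4.95, length(d)), tolerance = 1e-9)
  # with 3000 large steps the pair has crossed the seam at least once
  expect_gt(max(abs(res$wind_x) + abs(res$wind_y)), 0)
})

test_that("insertion adds non-clashing singletons and errors when crowded", {
  cfg <- sim_config(200, 200, n_x = 10, n_y = 10, species = btub_species(),
                    n_steps = 0, grid_spacing = 20, seed = 21)
  st <- init_grid(cfg)
  set.seed(1)
  st2 <- insert_proteins(st, 25, cfg)
  expect_equal(nrow(st2), 125)
  expect_equal(st2$cluster_id[101:125], 101:125)
  d <- as.matrix(dist(cbind(st2$x, st2$y)))
  diag(d) <- Inf
  expect_gte(min(d[101:125, ]), 4.9)
  # untouched existing poses
  expect_equal(st2[1:100, ], st, ignore_attr = TRUE)
  expect_identical(insert_proteins(st, 0, cfg), st)

  tiny <- sim_config(20, 20, n_x = 1, n_y = 1, species = btub_species(),
                     n_steps = 0)
  expect_error(insert_proteins(init_grid(tiny), 50, tiny, max_attempts = 200),
               "could not place inserted protein")
})

test_that("a mid-run insertion enlarges the population downstream", {
  cfg <- sim_config(150, 150, n_x = 8, n_y = 8, species = btub_species(),
                    n_steps = 100, save_interval = 25, grid_spacing = 15,
                    seed = 30)
  traj <- run_mesoscale(cfg, insert_n = 10, insert_at_step = 50)
  counts <- dplyr::count(traj, frame)
  expect_equal(counts$n[counts$frame < 50], rep(64, 2))
  expect_equal(counts$n[counts$frame >= 50], rep(74, 3))
})

test_that("an isolated protein diffuses with the analytic coefficient", {
  # ensemble of isolated proteins: fitted D vs s^2 / (2 dt)
  sp <- isolated_species(trans_A = 0.2)
  cfg <- sim_config(5500, 5500, n_x = 5, n_y = 5, species = sp,
                    grid_spacing = 1000, n_steps = 4000, save_interval = 1,
                    seed = 5)
  traj <- run_mesoscale(cfg)
  Ds <- vapply(unique(traj$id),
               function(i) attr(compute_msd(traj, i, max_lag = 4), "D"), 0)
  expect_equal(mean(Ds), 0.2^2 / (2 * 10), tolerance = 0.05)
})
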