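# Parameterization: motion statistics by cluster size, power-law fitting,
# angular densities, patch calling, and end-to-end recovery.

test_that("motion statistics recover generator stds by cluster size", {
  # hand-built trajectory: 10 permanent monomers (per-axis std 0.3) and
  # 5 permanent dimers moving rigidly (per-axis std 0.2)
  set.seed(8)
  n_frames <- 600
  mono <- purrr::map(1:10, function(i) {
    tibble::tibble(frame = 0:(n_frames - 1), time_ns = (0:(n_frames - 1)) * 10,
                   id = i, species = "BtuB",
                   x = cumsum(c(0, rnorm(n_frames - 1, 0, 0.3))),
                   y = cumsum(c(0, rnorm(n_frames - 1, 0, 0.3))),
                   theta = 0, wind_x = 0L, wind_y = 0L, cluster_id = i)
  })
  dimer <- purrr::map(1:5, function(k) {
    dx <- cumsum(c(0, rnorm(n_frames - 1, 0, 0.2)))
    dy <- cumsum(c(0, rnorm(n_frames - 1, 0, 0.2)))
    purrr::map(1:2, function(m) {
      tibble::tibble(frame = 0:(n_frames - 1),
                     time_ns = (0:(n_frames - 1)) * 10,
                     id = 100 + 2 * k + m, species = "BtuB",
                     x = 1000 * k + 5 * m + dx, y = 1000 * k + dy,
                     theta = 0, wind_x = 0L, wind_y = 0L,
                     cluster_id = 100 + 2 * k + 1)
    }) |> purrr::list_rbind()
  })
  traj <- as_test_traj(dplyr::bind_rows(c(mono, dimer)))
  stats <- motion_stats_by_cluster_size(traj, interval = 10)
  expect_equal(stats$cluster_size, c(1L, 2L))
  expect_equal(stats$trans_std[1], 0.3, tolerance = 0.02)
  expect_equal(stats$trans_std[2], 0.2, tolerance = 0.02)
  expect_true(all(stats$n_samples > 1000))
  # the interval must be compatible with the frame spacing
  expect_error(motion_stats_by_cluster_size(traj, interval = 5), "shorter")
  expect_error(motion_stats_by_cluster_size(traj, interval = 15), "divide")
  single <- dplyr::filter(traj, frame == 0)
  expect_error(motion_stats_by_cluster_size(as_test_traj(single)),
               "at least two frames")
})

test_that("windows spanning a cluster-size change are discarded", {
  # two proteins that 'merge' at frame 5: windows across frame 5 must drop
  df <- purrr::map(1:2, function(i) {
    tibble::tibble(frame = 0:10, time_ns = (0:10) * 10, id = i,
                   species = "BtuB", x = seq(0, 10) * i, y = 0, theta = 0,
                   wind_x = 0L, wind_y = 0L,
                   cluster_id = ifelse(0:10 >= 5, 1L, i))
  }) |> purrr::list_rbind()
  stats <- motion_stats_by_cluster_size(as_test_traj(df), interval = 10)
  # sizes 1 (frames 0..3 starts) and 2 (frames 5..9 starts); the window
  # starting at frame 4 straddles the merge and is dropped
  expect_equal(sum(stats$n_samples), 2 * (4 + 5))
})

test_that("power-law fitting is exact, validated and scale-equivariant", {
  fit <- fit_power_law(c(1, 4, 16), c(2, 1, 0.5))
  expect_equal(fit$A, 2, tolerance = 1e-12)
  expect_equal(fit$b, 0.5, tolerance = 1e-12)
  expect_lt(fit$residual, 1e-12)
  expect_equal(predict(fit, 9), 2 / 3, tolerance = 1e-10)
  expect_equal(tidy(fit)$estimate, c(2, 0.5), tolerance = 1e-10)

  expect_error(fit_power_law(1, 0.3), "2 distinct")
  expect_error(fit_power_law(c(1, 1), c(0.3, 0.31)), "2 distinct")
  expect_error(fit_power_law(c(1, 2), c(0.3, 0)), "positive")

  # noisy recovery: b within 0.1 of the truth
  set.seed(13)
  sizes <- 1:20
  stds <- 0.35 * sizes^(-0.6) * exp(rnorm(20, 0, 0.05))
  noisy <- fit_power_law(sizes, stds)
  expect_lt(abs(noisy$b - 0.6), 0.1)

  # scale equivariance: A scales, b invariant
  sc <- fit_power_law(sizes, 3.7 * stds)
  expect_equal(sc$A, 3.7 * noisy$A, tolerance = 1e-9)
  expect_equal(sc$b, noisy$b, tolerance = 1e-12)
})

test_that("angular densities normalize, localize peaks and flatten nulls", {
  # pairs built so both orderings contribute body angles ~ Normal(30, 10)
  build_pairs <- function(n_frames, pairs_per_frame, angle_fun) {
    purrr::map(seq_len(n_frames), function(f) {
      k <- pairs_per_frame
      cx <- rep(seq_len(k) * 1000, each = 1)
      th1 <- runif(k) * 360
      a1 <- angle_fun(k)
      bearing <- th1 + a1
      a2 <- angle_fun(k)
      th2 <- bearing + 180 - a2
      tibble::tibble(
        frame = f, time_ns = f * 10,
        id = c(seq_len(k) * 2 - 1, seq_len(k) * 2),
        species = "BtuB",
        x = c(cx, cx + 4.95 * cospi(bearing / 180)),
        y = c(rep(0, k), 4.95 * sinpi(bearing / 180)),
        theta = c(th1, th2), wind_x = 0L, wind_y = 0L,
        cluster_id = rep(seq_len(k), 2))
    }) |> purrr::list_rbind()
  }
  set.seed(17)
  peaked <- as_test_traj(build_pairs(100, 20, function(k) rnorm(k, 30, 10)))
  dens <- neighbor_angular_density(peaked, interaction_range = 6, n_bins = 72)
  expect_equal(sum(dens$density) * 5, 1, tolerance = 1e-6)
  top <- dens[which.max(dens$density), ]
  expect_true(top$bin_start <= 30 && top$bin_end >= 30)

  flat <- as_test_traj(build_pairs(250, 100, function(k) runif(k) * 360))
  fd <- neighbor_angular_density(flat, interaction_range = 6, n_bins = 72)
  expect_lt(max(fd$density) / min(fd$density), 1.5)

  expect_error(neighbor_angular_density(peaked, n_bins = 50), "divide")
  expect_error(neighbor_angular_density(peaked[0, ]), "empty")
})

test_that("patch calling thresholds, merges across the seam and sorts", {
  mk_density <- function(density) {
    n <- length(density)
    width <- 360 / n
    structure(tibble::tibble(
      bin_start = (seq_len(n) - 1) * width, bin_end = seq_len(n) * width,
      mid = (seq_len(n) - 0.5) * width, count = density, density = density),
      n_bins = n, class = c("angular_density", class(tibble::tibble())))
  }
  # support only on [20, 60]
  d <- numeric(72); d[5:12] <- 1
  p <- derive_patches(mk_density(d))
  expect_equal(nrow(p), 1)
  expect_equal(c(p$start, p$end), c(20, 60))

  # wrapped support [350, 360) + [0, 10] merges into one patch
  d2 <- numeric(72); d2[c(71, 72, 1, 2)] <- 1
  p2 <- derive_patches(mk_density(d2))
  expect_equal(nrow(p2), 1)
  expect_equal(c(p2$start, p2$end), c(350, 10))

  # two peaks give two patches containing their peaks, sorted by start
  d3 <- dnorm(((1:72) - 0.5) * 5, 30, 10) + dnorm(((1:72) - 0.5) * 5, 200, 10)
  p3 <- derive_patches(mk_density(d3 / (sum(d3) * 5)))
  expect_equal(nrow(p3), 2)
  expect_true(in_patch(30, p3) && in_patch(200, p3))
  expect_true(!is.unsorted(p3$start))

  # nothing above threshold: empty patch list, not an error
  expect_equal(nrow(derive_patches(mk_density(rep(1, 72)), threshold = 2)), 0)
})

test_that("engine parameters round-trip through the parameterization", {
  truth <- btub_species(trans_A = 0.3, trans_b = 0.5, rot_A = 6, rot_b = 0.5)
  pool <- pseudo_cg_pool(truth, n_runs = 30, n_steps = 80, seed0 = 200)
  # cluster-mode statistics are the exact inverse of the forward model
  stats <- motion_stats_by_cluster_size(pool, interval = 10, per = "cluster")
  # only fit sizes whose spread is estimated from a reasonable sample
  stats <- dplyr::filter(stats, n_samples >= 100)
  tfit <- fit_power_law(stats$cluster_size, stats$trans_std)
  rfit <- fit_power_law(stats$cluster_size, stats$rot_std)
  expect_equal(tfit$A, 0.3, tolerance = 0.1)
  expect_lt(abs(tfit$b - 0.5), 0.1)
  expect_equal(rfit$A, 6, tolerance = 0.1)
  expect_lt(abs(rfit$b - 0.5), 0.1)

  dens <- neighbor_angular_density(pool, interaction_range = 5, n_bins = 36,
                                   bonded_only = TRUE)
  patches <- derive_patches(dens, threshold = mean(dens$density))
  expect_gte(patch_overlap(patches, truth$patches), 0.8)
})
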