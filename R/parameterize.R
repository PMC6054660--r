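# Parameterization workflow: derive the mesoscale motion laws and interface
# patches from a particle trajectory (in production use, a coarse-grained MD
# trajectory reduced to per-protein x, y, orientation; in tests, synthetic
# fixtures with known ground truth).

#' Per-cluster-size motion statistics from a trajectory
#'
#' For every protein and every overlapping window of length `interval`,
#' computes the orientation change and the per-axis displacements over the
#' window, groups them by the protein's cluster size at the window start, and
#' reports the per-size spread. Windows during which the protein's cluster
#' size changes are discarded. Displacement spreads are root-mean-square
#' values: the displacement distributions are zero-mean by construction of
#' the model, so the mean is reported for checking but not subtracted.
#'
#' @param traj a trajectory tibble with `frame`, `time_ns`, `id`, `theta`,
#'   coordinates and `cluster_id` (e.g. from [run_mesoscale()] or
#'   [gen_pseudo_cg()]).
#' @param interval window length in ns (default 10); must be a multiple of
#'   the frame spacing.
#' @param min_samples smallest number of windows for which a size is reported
#'   (default 2).
#' @param per `"protein"` (default) measures each molecule's own
#'   displacement, the convention used on finer-grained input; `"cluster"`
#'   measures the centre-of-mass displacement of each cluster and one
#'   rotation sample per cluster. For trajectories generated by the engine
#'   itself the cluster mode is the exact inverse of the forward model:
#'   per-molecule displacements of clustered proteins additionally contain
#'   the tangential motion induced by cluster rotation, which biases the
#'   translational spread upward for large clusters.
#' @return a tibble with one row per observed cluster size: `cluster_size`,
#'   `n_samples`, `trans_std` (nm, per axis), `rot_std` (degrees),
#'   `trans_mean`, `rot_mean`, `interval`.
#' @export
motion_stats_by_cluster_size <- function(traj, interval = 10,
                                         min_samples = 2,
                                         per = c("protein", "cluster")) {
  per <- match.arg(per)
  traj <- unwrap_coords(tibble::as_tibble(traj))
  frames <- sort(unique(traj$frame))
  if (length(frames) < 2) {
    rlang::abort("trajectory must contain at least two frames")
  }
  spacing <- unique(diff(sort(unique(traj$time_ns))))
  if (length(spacing) != 1) {
    rlang::abort("trajectory frames must be evenly spaced in time")
  }
  if (interval < spacing) {
    rlang::abort(sprintf(
      "interval (%g ns) is shorter than the frame spacing (%g ns)",
      interval, spacing))
  }
  k <- interval / spacing
  if (abs(k - round(k)) > 1e-9) {
    rlang::abort("frame spacing must divide the interval")
  }
  k <- as.integer(round(k))
  # smallest frame increment: windows must span k contiguous recordings
  # (pooled replicate trajectories have frame gaps between runs)
  fstep <- min(diff(sort(unique(traj$frame))))

  if (per == "cluster") {
    # one record per cluster and frame: centre of mass + a reference
    # member's orientation (all members rotate identically)
    traj <- traj |>
      dplyr::group_by(.data$frame, .data$time_ns, .data$cluster_id) |>
      dplyr::summarise(xu = mean(.data$xu), yu = mean(.data$yu),
                       theta = .data$theta[which.min(.data$id)],
                       csize = dplyr::n(), .groups = "drop") |>
      dplyr::rename(id = "cluster_id") |>
      dplyr::mutate(cluster_id = .data$id)
  } else {
    traj <- dplyr::add_count(traj, .data$frame, .data$cluster_id,
                             name = "csize")
  }

  traj |>
    dplyr::group_by(.data$id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      dx = dplyr::lead(.data$xu, k) - .data$xu,
      dy = dplyr::lead(.data$yu, k) - .data$yu,
      dth = signed_angle_diff(dplyr::lead(.data$theta, k), .data$theta),
      contiguous = dplyr::lead(.data$frame, k) == .data$frame + k * fstep,
      # permanent or cutoff clustering: a size change within the window is
      # detected by tracking the running count of size transitions
      n_chg = cumsum(c(0, diff(.data$csize) != 0)),
      stable = dplyr::lead(.data$n_chg, k) == .data$n_chg
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$dx), .data$stable, .data$contiguous) |>
    dplyr::group_by(cluster_size = .data$csize) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      trans_std = sqrt(mean(c(.data$dx, .data$dy)^2)),
      rot_std = sqrt(mean(.data$dth^2)),
      trans_mean = mean(c(.data$dx, .data$dy)),
      rot_mean = mean(.data$dth),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_samples >= min_samples) |>
    dplyr::mutate(interval = interval)
}

# orientation change a - b mapped to (-180, 180]
signed_angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[!is.na(d) & d > 180] <- d[!is.na(d) & d > 180] - 360
  d
}

#' Fit the mobility power law std(n) = A * n^(-b)
#'
#' Least-squares fit of `log(std)` on `log(size)`, which is exact on
#' noiseless power-law data and scale-equivariant (scaling all `stds` by `c`
#' scales `A` by `c` and leaves `b` unchanged).
#'
#' @param sizes cluster sizes (>= 2 distinct values required).
#' @param stds positive standard deviations (nm or degrees), same length.
#' @return an object of class `power_law_fit` with elements `A`, `b`,
#'   `residual` (sum of squared residuals on the original scale),
#'   `fit_domain` and the underlying `lm` fit. Supports [tidy()], [glance()]
#'   and `predict()`.
#' @examples
#' fit_power_law(c(1, 4, 16), c(2, 1, 0.5)) # A = 2, b = 0.5
#' @export
fit_power_law <- function(sizes, stds) {
  if (is.data.frame(sizes)) {
    stds <- sizes$trans_std %||% sizes$stds
    sizes <- sizes$cluster_size %||% sizes$sizes
  }
  if (length(sizes) != length(stds)) {
    rlang::abort("`sizes` and `stds` must have the same length")
  }
  keep <- !is.na(sizes) & !is.na(stds)
  sizes <- sizes[keep]; stds <- stds[keep]
  if (length(unique(sizes)) < 2) {
    rlang::abort("power-law fit needs at least 2 distinct cluster sizes")
  }
  if (any(stds <= 0)) {
    rlang::abort("power-law fit requires strictly positive std values")
  }
  fit <- lm(log(stds) ~ log(sizes))
  A <- exp(unname(coef(fit)[1]))
  b <- -unname(coef(fit)[2])
  pred <- A * sizes^(-b)
  structure(
    list(A = A, b = b, residual = sum((stds - pred)^2),
         fit_domain = sort(unique(sizes)), n = length(sizes), lm = fit),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> std(n) = %.5g * n^(-%.5g)  (SSR %.3g on %d points)\n",
              x$A, x$b, x$residual, x$n))
  invisible(x)
}

#' @export
predict.power_law_fit <- function(object, n, ...) {
  object$A * n^(-object$b)
}

#' @rdname fit_power_law
#' @param x a `power_law_fit`.
#' @param ... unused.
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "b"), estimate = c(x$A, x$b))
}

#' @rdname fit_power_law
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(A = x$A, b = x$b, residual = x$residual, n = x$n,
                 r.squared = summary(x$lm)$r.squared)
}

#' Angular density of interacting neighbours around a central protein
#'
#' For every ordered pair of proteins within `interaction_range` of one
#' another (minimum image in periodic trajectories), accumulates the bearing
#' of the neighbour in the central protein's body frame (bearing minus the
#' central protein's orientation, modulo 360) into equal-width bins, then
#' normalizes to a probability density per degree. Peaks of this density mark
#' the interface patches through which neighbours sit.
#'
#' @param traj a trajectory tibble.
#' @param interaction_range neighbour cutoff in nm (default 6, the BtuB-BtuB
#'   analysis cutoff).
#' @param n_bins number of bins; the bin width `360 / n_bins` must be a whole
#'   number of degrees (default 72 bins of 5 degrees).
#' @param bonded_only if `TRUE`, only count pairs that belong to the same
#'   cluster (requires a `cluster_id` column). Appropriate for
#'   engine-generated trajectories, where mere adjacency can persist without
#'   interaction; the default `FALSE` counts every neighbour within range,
#'   the convention for finer-grained input where adjacency within the
#'   cutoff is itself the interaction criterion.
#' @return an object of class `angular_density`: a tibble with `bin_start`,
#'   `bin_end`, `mid`, `count`, `density` (per degree; integrates to 1).
#' @export
neighbor_angular_density <- function(traj, interaction_range = 6,
                                     n_bins = 72, bonded_only = FALSE) {
  traj <- tibble::as_tibble(traj)
  if (nrow(traj) == 0) rlang::abort("empty trajectory")
  if (360 %% n_bins != 0) {
    rlang::abort("`n_bins` must divide 360 evenly")
  }
  box <- attr(traj, "box")
  periodic <- identical(attr(traj, "boundary"), "periodic")
  width <- 360 / n_bins
  counts <- numeric(n_bins)
  for (f in split(traj, traj$frame)) {
    n <- nrow(f)
    if (n < 2) next
    # dx[i, j] = x_j - x_i: displacement from central i to neighbour j
    dx <- outer(f$x, f$x, function(a, b) b - a)
    dy <- outer(f$y, f$y, function(a, b) b - a)
    if (periodic && !is.null(box)) {
      dx <- dx - box[["width"]] * round(dx / box[["width"]])
      dy <- dy - box[["height"]] * round(dy / box[["height"]])
    }
    d2 <- dx^2 + dy^2
    within <- d2 <= interaction_range^2 & d2 > 0
    if (bonded_only) {
      within <- within & outer(f$cluster_id, f$cluster_id, `==`)
    }
    near <- which(within, arr.ind = TRUE)
    if (nrow(near) == 0) next
    # row = central protein i, col = neighbour j; ordered pairs
    bearing <- atan2(dy[near], dx[near]) * 180 / pi
    body <- wrap_angle(bearing - f$theta[near[, 1]])
    idx <- pmin(floor(body / width) + 1, n_bins)
    tab <- tabulate(idx, nbins = n_bins)
    counts <- counts + tab
  }
  total <- sum(counts)
  if (total == 0) {
    rlang::abort("no neighbour pairs found within the interaction range")
  }
  structure(
    tibble::tibble(
      bin_start = (seq_len(n_bins) - 1) * width,
      bin_end = seq_len(n_bins) * width,
      mid = (seq_len(n_bins) - 0.5) * width,
      count = counts,
      density = counts / (total * width)
    ),
    n_bins = n_bins, total = total,
    class = c("angular_density", class(tibble::tibble()))
  )
}

#' Call interaction patches from an angular density
#'
#' Contiguous runs of bins whose density exceeds `threshold` become patches;
#' runs touching across the 0/360 seam are merged into one wrapped patch.
#'
#' @param density an `angular_density` from [neighbor_angular_density()].
#' @param threshold density level (per degree) above which a bin belongs to a
#'   patch; default is the mean bin density plus one standard deviation.
#' @return a patch tibble (see [interaction_patches()]) sorted by start
#'   angle; empty (zero rows) if no bin exceeds the threshold.
#' @export
derive_patches <- function(density, threshold = NULL) {
  d <- density$density
  n <- length(d)
  width <- 360 / n
  if (is.null(threshold)) threshold <- mean(d) + sd(d)
  above <- d > threshold
  if (!any(above)) return(interaction_patches(numeric(), numeric()))
  if (all(above)) {
    rlang::warn("all bins exceed the threshold; returning the full circle")
    return(tibble::tibble(start = 0, end = 360 - width))
  }
  r <- rle(above)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  runs <- which(r$values)
  starts <- vapply(runs, function(k) min(which(run_id == k)), 0L)
  ends <- vapply(runs, function(k) max(which(run_id == k)), 0L)
  ang_start <- (starts - 1) * width
  ang_end <- ends * width
  # circular merge: a run ending at 360 joins a run starting at 0
  if (length(runs) > 1 && above[1] && above[n]) {
    ang_start[1] <- ang_start[length(runs)]
    ang_start <- ang_start[-length(runs)]
    ang_end <- ang_end[-length(runs)]
  }
  out <- interaction_patches(ang_start, wrap_angle(ang_end))
  out[order(out$start), ]
}

#' One-shot parameterization of a species from a trajectory
#'
#' Convenience wrapper chaining [motion_stats_by_cluster_size()],
#' [fit_power_law()] (translation and rotation), and
#' [neighbor_angular_density()] + [derive_patches()].
#'
#' @param traj a trajectory tibble.
#' @param name species name for the resulting parameters.
#' @param diameter particle diameter (nm).
#' @param interval motion-statistics window (ns).
#' @param interaction_range neighbour cutoff for the angular density (nm).
#' @param n_bins angular density bins.
#' @param bonded_only see [neighbor_angular_density()].
#' @param per see [motion_stats_by_cluster_size()].
#' @return a list with `species` (a ready-to-simulate `species_params`),
#'   `stats`, `trans_fit`, `rot_fit`, `density`, `patches`.
#' @export
parameterize_species <- function(traj, name = "BtuB", diameter = 5,
                                 interval = 10, interaction_range = 6,
                                 n_bins = 72, bonded_only = FALSE,
                                 per = "protein") {
  stats <- motion_stats_by_cluster_size(traj, interval = interval, per = per)
  trans_fit <- fit_power_law(stats$cluster_size, stats$trans_std)
  rot_fit <- fit_power_law(stats$cluster_size, stats$rot_std)
  density <- neighbor_angular_density(traj, interaction_range, n_bins,
                                      bonded_only = bonded_only)
  patches <- derive_patches(density)
  list(
    species = species_params(
      name, diameter = diameter, patches = patches,
      trans_law = c(A = trans_fit$A, b = trans_fit$b),
      rot_law = c(A = rot_fit$A, b = rot_fit$b)
    ),
    stats = stats, trans_fit = trans_fit, rot_fit = rot_fit,
    density = density, patches = patches
  )
}
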