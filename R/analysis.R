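# Post-hoc trajectory analyses: frame-wise distance-cutoff clustering,
# MSD / diffusion-coefficient estimation (MSD(t) = 4Dt in 2D), sliding-window
# classification of Brownian vs confined motion, motion-fraction summaries,
# and order-of-magnitude binding kinetics estimates.

#' Species-pair clustering cutoffs
#'
#' Default centroid-distance cutoffs used when clustering analysis-style
#' trajectories: 6 nm for BtuB-BtuB, 8.8 nm for OmpF-OmpF and 7.3 nm for a
#' BtuB-OmpF pair.
#'
#' @return a tibble with columns `species1`, `species2`, `cutoff` (nm),
#'   symmetric under species exchange.
#' @export
default_cutoffs <- function() {
  tibble::tibble(
    species1 = c("BtuB", "OmpF", "BtuB"),
    species2 = c("BtuB", "OmpF", "OmpF"),
    cutoff = c(6.0, 8.8, 7.3)
  )
}

lookup_cutoff <- function(cutoffs, s1, s2) {
  if (is.numeric(cutoffs)) {
    return(rep(cutoffs[[1]], length(s1)))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  map <- setNames(cutoffs$cutoff, key(cutoffs$species1, cutoffs$species2))
  out <- unname(map[key(s1, s2)])
  if (anyNA(out)) {
    bad <- unique(paste(s1, s2)[is.na(out)])
    rlang::abort(sprintf("no clustering cutoff defined for species pair(s): %s",
                         paste(bad, collapse = ", ")))
  }
  out
}

#' Frame-wise cluster assignment by distance cutoff
#'
#' Connected components of the graph whose edges join protein pairs closer
#' than their species-pair cutoff. This is the *analysis* clustering: purely
#' geometric, no patch condition and no memory, unlike the engine's permanent
#' association.
#'
#' @param frame a single-frame tibble with `id`, `species`, `x`, `y`.
#' @param cutoffs a cutoff table as from [default_cutoffs()], or a single
#'   number applied to every pair.
#' @param box,boundary optional box (`c(width, height)`) and `"periodic"` for
#'   minimum-image distances; defaults taken from the frame's attributes when
#'   present.
#' @return the frame with `cluster_id` (minimum member id) and `cluster_size`
#'   columns replaced/added.
#' @export
assign_clusters <- function(frame, cutoffs = default_cutoffs(),
                            box = attr(frame, "box"),
                            boundary = attr(frame, "boundary")) {
  frame <- tibble::as_tibble(frame)
  n <- nrow(frame)
  if (n == 0) rlang::abort("empty frame")
  dx <- outer(frame$x, frame$x, `-`)
  dy <- outer(frame$y, frame$y, `-`)
  if (identical(boundary, "periodic") && !is.null(box)) {
    dx <- dx - box[["width"]] * round(dx / box[["width"]])
    dy <- dy - box[["height"]] * round(dy / box[["height"]])
  }
  d <- sqrt(dx^2 + dy^2)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  cut <- lookup_cutoff(cutoffs, frame$species[pairs[, 1]],
                       frame$species[pairs[, 2]])
  sel <- d[pairs] <= cut
  edges <- t(pairs[sel, , drop = FALSE])
  g <- igraph::make_graph(edges = as.vector(edges), n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  minid <- tapply(frame$id, comp, min)
  frame$cluster_id <- as.integer(minid[as.character(comp)])
  frame |>
    dplyr::add_count(.data$cluster_id, name = "cluster_size")
}

#' Per-protein cluster-size time series
#'
#' Applies [assign_clusters()] to every frame of a trajectory.
#'
#' @param traj a trajectory tibble.
#' @inheritParams assign_clusters
#' @return a tibble `frame`, `time_ns`, `id`, `cluster_id`, `cluster_size`.
#' @export
cluster_size_timeseries <- function(traj, cutoffs = default_cutoffs()) {
  box <- attr(traj, "box")
  boundary <- attr(traj, "boundary")
  tibble::as_tibble(traj) |>
    dplyr::group_split(.data$frame) |>
    purrr::map(function(f) {
      out <- assign_clusters(f, cutoffs, box = box, boundary = boundary)
      dplyr::select(out, "frame", "time_ns", "id", "cluster_id",
                    "cluster_size")
    }) |>
    purrr::list_rbind()
}

#' Cluster-size distribution at one frame
#' @param traj a trajectory tibble.
#' @param frame frame index (default: last).
#' @inheritParams assign_clusters
#' @return a tibble `cluster_size`, `n_clusters`, `n_proteins`.
#' @export
cluster_size_distribution <- function(traj, frame = NULL,
                                      cutoffs = default_cutoffs()) {
  f <- traj_frame(traj, frame)
  a <- assign_clusters(f, cutoffs, box = attr(traj, "box"),
                       boundary = attr(traj, "boundary"))
  a |>
    dplyr::distinct(.data$cluster_id, .data$cluster_size) |>
    dplyr::count(.data$cluster_size, name = "n_clusters") |>
    dplyr::mutate(n_proteins = .data$cluster_size * .data$n_clusters)
}

time_avg_msd <- function(x, y, lags) {
  n <- length(x)
  vapply(lags, function(k) {
    dx <- x[(k + 1):n] - x[1:(n - k)]
    dy <- y[(k + 1):n] - y[1:(n - k)]
    mean(dx^2 + dy^2)
  }, 0)
}

#' Mean squared displacement and diffusion coefficient
#'
#' Time-averaged MSD over all frame pairs at each lag (or ensemble-averaged
#' displacement from the first frame across proteins when
#' `ensemble = TRUE`). The diffusion coefficient follows the 2D relation
#' `MSD(t) = 4 D t`: `D` is a quarter of the least-squares slope (with
#' intercept, the usual localization-noise convention in single-particle
#' tracking) of the MSD against time over lag points 1-4.
#'
#' @param traj a trajectory tibble; periodic trajectories are unwrapped via
#'   their winding numbers.
#' @param protein_id which protein to analyse (default: the only one, or an
#'   error if several and `ensemble = FALSE`).
#' @param max_lag largest lag in frames (default `min(n_frames - 1, 100)`).
#' @param ensemble average displacements from the first frame over all
#'   proteins instead of time-averaging a single protein.
#' @return an object of class `msd_curve`: a tibble `lag`, `time_ns`, `msd`
#'   (nm^2) with attributes `D` (nm^2/ns), `D_um2_s` (um^2/s; 1 nm^2/ns =
#'   1000 um^2/s), `slope`, `intercept`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
compute_msd <- function(traj, protein_id = NULL, max_lag = NULL,
                        ensemble = FALSE) {
  traj <- unwrap_coords(traj)
  dt <- attr(traj, "step_duration")
  times <- sort(unique(traj$time_ns))
  n_frames <- length(times)
  if (n_frames < 5) {
    rlang::abort("trajectory must have at least 5 frames for an MSD fit")
  }
  frame_dt <- if (n_frames > 1) diff(times)[1] else dt %||% 1
  if (ensemble) {
    wide <- tibble::as_tibble(traj) |> dplyr::arrange(.data$id, .data$frame)
    ml <- min(n_frames - 1, max_lag %||% (n_frames - 1))
    msd <- vapply(seq_len(ml), function(k) {
      d <- wide |>
        dplyr::group_by(.data$id) |>
        dplyr::summarise(
          sq = (.data$xu[k + 1] - .data$xu[1])^2 +
               (.data$yu[k + 1] - .data$yu[1])^2, .groups = "drop")
      mean(d$sq)
    }, 0)
    lags <- seq_len(ml)
  } else {
    ids <- unique(traj$id)
    if (is.null(protein_id)) {
      if (length(ids) != 1) {
        rlang::abort("several proteins present: give `protein_id` or use ensemble = TRUE")
      }
      protein_id <- ids
    }
    tr <- traj |>
      dplyr::filter(.data$id == !!protein_id) |>
      dplyr::arrange(.data$frame)
    if (nrow(tr) < 5) {
      rlang::abort("trajectory must have at least 5 frames for an MSD fit")
    }
    ml <- min(nrow(tr) - 1, max_lag %||% 100)
    lags <- seq_len(ml)
    msd <- time_avg_msd(tr$xu, tr$yu, lags)
  }
  curve <- tibble::tibble(lag = c(0L, lags),
                          time_ns = c(0, lags) * frame_dt,
                          msd = c(0, msd))
  fitpts <- dplyr::filter(curve, .data$lag >= 1, .data$lag <= 4)
  fit <- lm(msd ~ time_ns, data = fitpts)
  slope <- unname(coef(fit)[2])
  D <- slope / 4
  structure(curve,
            D = D, D_um2_s = D * 1000, slope = slope,
            intercept = unname(coef(fit)[1]),
            protein_id = protein_id %||% NA, frame_dt = frame_dt,
            class = c("msd_curve", class(tibble::tibble())))
}

#' @rdname compute_msd
#' @param x an `msd_curve`.
#' @param ... unused.
#' @export
tidy.msd_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname compute_msd
#' @export
glance.msd_curve <- function(x, ...) {
  tibble::tibble(D_nm2_ns = attr(x, "D"), D_um2_s = attr(x, "D_um2_s"),
                 slope = attr(x, "slope"), intercept = attr(x, "intercept"),
                 n_lags = max(x$lag))
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags; D = %.4g nm^2/ns (%.4g um^2/s)\n",
              max(x$lag), attr(x, "D"), attr(x, "D_um2_s")))
  print(tibble::as_tibble(x))
  invisible(x)
}

window_motion_stats <- function(x, y) {
  m <- time_avg_msd(x, y, 1:4)
  if (any(m <= 0)) {
    alpha <- 0
    D_local <- 0
  } else {
    lx <- log(1:4); ly <- log(m)
    alpha <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
    k <- 1:4
    D_local <- (sum((k - mean(k)) * (m - mean(m))) / sum((k - mean(k))^2)) / 4
  }
  maxd2 <- max((x - x[1])^2 + (y - y[1])^2)
  c(alpha = alpha, D_local = D_local, maxd2 = maxd2)
}

#' Classify a protein's motion as Brownian, confined or mixed
#'
#' A deterministic sliding-window classifier standing in for neural-network
#' based single-particle-tracking classifiers. Each window of `window` frames
#' gets (a) the MSD scaling exponent `alpha` (log-log slope of the
#' within-window time-averaged MSD over lags 1-4; `MSD ~ t^alpha`, with
#' `alpha = 1` for free diffusion and `alpha -> 0` at a confinement plateau)
#' and (b) a confinement ratio
#' `R = max displacement^2 / (4 * D_local * t_window)`, comparing the ground
#' actually covered with free-diffusion expectation at the window's own local
#' diffusion coefficient. A window is *confined* if `alpha < alpha_conf` or
#' `R < R_conf`, *Brownian* if `alpha >= alpha_brown` and `R >= R_conf`, else
#' unclassified. The per-protein label is *mixed* iff both Brownian and
#' confined windows occur. Frames not covered by any complete window (the
#' trajectory edges) remain unclassified.
#'
#' The thresholds are calibration constants of this surrogate classifier
#' (chosen for high accuracy on synthetic free/corral fixtures), not
#' physically derived values; all are configurable.
#'
#' @param traj a trajectory tibble.
#' @param protein_id protein to classify (default: the only one).
#' @param window window length in frames (>= 16; default 128).
#' @param stride window start spacing (default `window`: non-overlapping).
#' @param alpha_conf,alpha_brown,R_conf classification thresholds.
#' @return an object of class `motion_classification` with `windows` (tibble
#'   `start_frame`, `end_frame`, `alpha`, `R`, `label`), `overall` (one of
#'   `"brownian"`, `"confined"`, `"mixed"`, `"unclassified"`), `protein_id`,
#'   `window`. Supports [tidy()] and [glance()].
#' @export
classify_motion <- function(traj, protein_id = NULL, window = 128,
                            stride = window, alpha_conf = 0.5,
                            alpha_brown = 0.8, R_conf = 0.2) {
  if (window < 16) rlang::abort("`window` must be at least 16 frames")
  traj <- unwrap_coords(traj)
  ids <- unique(traj$id)
  if (is.null(protein_id)) {
    if (length(ids) != 1) rlang::abort("several proteins present: give `protein_id`")
    protein_id <- ids
  }
  tr <- traj |>
    dplyr::filter(.data$id == !!protein_id) |>
    dplyr::arrange(.data$frame)
  n <- nrow(tr)
  if (window > n) {
    rlang::abort(sprintf("window (%d) longer than trajectory (%d frames)",
                         window, n))
  }
  starts <- seq(1, n - window + 1, by = stride)
  rows <- purrr::map(starts, function(s) {
    idx <- s:(s + window - 1)
    st <- window_motion_stats(tr$xu[idx], tr$yu[idx])
    R <- if (st[["D_local"]] <= 0) 0 else {
      st[["maxd2"]] / (4 * st[["D_local"]] * window)
    }
    label <- if (st[["alpha"]] < alpha_conf || R < R_conf) {
      "confined"
    } else if (st[["alpha"]] >= alpha_brown && R >= R_conf) {
      "brownian"
    } else {
      "unclassified"
    }
    tibble::tibble(start_frame = tr$frame[s],
                   end_frame = tr$frame[s + window - 1],
                   alpha = st[["alpha"]], R = R, label = label)
  }) |> purrr::list_rbind()
  has_b <- any(rows$label == "brownian")
  has_c <- any(rows$label == "confined")
  overall <- if (has_b && has_c) "mixed"
             else if (has_b) "brownian"
             else if (has_c) "confined"
             else "unclassified"
  structure(
    list(windows = rows, overall = overall, protein_id = protein_id,
         window = window),
    class = "motion_classification"
  )
}

#' @export
print.motion_classification <- function(x, ...) {
  cat(sprintf("<motion_classification> protein %s: %s (%d windows of %d frames)\n",
              format(x$protein_id), x$overall, nrow(x$windows), x$window))
  invisible(x)
}

#' @rdname classify_motion
#' @param x a `motion_classification`.
#' @param ... unused.
#' @export
tidy.motion_classification <- function(x, ...) {
  dplyr::mutate(x$windows, protein_id = x$protein_id)
}

#' @rdname classify_motion
#' @export
glance.motion_classification <- function(x, ...) {
  tibble::tibble(protein_id = x$protein_id, overall = x$overall,
                 n_windows = nrow(x$windows),
                 n_brownian = sum(x$windows$label == "brownian"),
                 n_confined = sum(x$windows$label == "confined"))
}

#' Classify every protein in a trajectory
#'
#' @inheritParams classify_motion
#' @return a tibble `id`, `overall` (one row per protein).
#' @export
classify_motion_all <- function(traj, window = 128, stride = window,
                                alpha_conf = 0.5, alpha_brown = 0.8,
                                R_conf = 0.2) {
  purrr::map(unique(traj$id), function(i) {
    cl <- classify_motion(traj, i, window = window, stride = stride,
                          alpha_conf = alpha_conf,
                          alpha_brown = alpha_brown, R_conf = R_conf)
    tibble::tibble(id = i, overall = cl$overall)
  }) |> purrr::list_rbind()
}

#' Fractions of Brownian / confined / mixed motion
#'
#' Fractions are taken over classified proteins (overall labels other than
#' `"unclassified"`) and sum to 1. For large systems, a random subsample of
#' `sample_size` proteins can be drawn `n_resamples` times to give a mean and
#' standard deviation per class, the convention used for mesoscale systems of
#' thousands of proteins.
#'
#' @param classifications a tibble `id`, `overall` (from
#'   [classify_motion_all()]) or a list of `motion_classification` objects.
#' @param sample_size,n_resamples optional resampling scheme (e.g. 100
#'   proteins, 5 resamples).
#' @return a tibble `label`, `fraction` (and `sd` when resampling).
#' @export
motion_fractions <- function(classifications, sample_size = NULL,
                             n_resamples = 5) {
  if (is.list(classifications) && !is.data.frame(classifications)) {
    classifications <- purrr::map(classifications, function(cl) {
      tibble::tibble(id = cl$protein_id, overall = cl$overall)
    }) |> purrr::list_rbind()
  }
  labs <- classifications$overall[classifications$overall != "unclassified"]
  if (length(labs) == 0) rlang::abort("no classified proteins")
  levels <- c("brownian", "confined", "mixed")
  frac_of <- function(v) {
    unname(vapply(levels, function(l) mean(v == l), 0))
  }
  if (is.null(sample_size)) {
    return(tibble::tibble(label = levels, fraction = frac_of(labs)))
  }
  sample_size <- min(sample_size, length(labs))
  draws <- replicate(n_resamples, frac_of(sample(labs, sample_size)))
  tibble::tibble(label = levels,
                 fraction = unname(rowMeans(draws)),
                 sd = unname(apply(draws, 1, sd)))
}

#' Order-of-magnitude binding kinetics from a free energy of association
#'
#' Converts a standard free energy of association into an equilibrium
#' dissociation constant, `Kd = exp(dG / (R T))` with
#' R = 8.314 J mol^-1 K^-1, and combines it with an assumed association-rate
#' range to bound the dissociation rate, `koff = kon * Kd`. With
#' dG = -50 kJ/mol (the coarse-grained estimate for an OMP-OMP contact) this
#' gives Kd of order 1 nM and koff between 1e-3 and 1 per second -- contact
#' lifetimes of seconds or longer, which is why mesoscale association is
#' modelled as permanent on the millisecond timescale.
#'
#' @param delta_G free energy of association in kJ/mol (negative = binding).
#' @param temperature temperature in K (default 298).
#' @param kon_range assumed association rate range in 1/(M s)
#'   (default `c(1e6, 1e9)`).
#' @return a one-row tibble: `Kd_M`, `koff_lo_s`, `koff_hi_s`.
#' @examples
#' kinetics_estimates(-50) # Kd ~ 1.7e-9 M
#' @export
kinetics_estimates <- function(delta_G, temperature = 298,
                               kon_range = c(1e6, 1e9)) {
  if (temperature <= 0) rlang::abort("temperature must be positive")
  R_gas <- 8.314 # J / (mol K)
  Kd <- exp(delta_G * 1000 / (R_gas * temperature))
  koff <- sort(kon_range * Kd)
  tibble::tibble(Kd_M = Kd, koff_lo_s = koff[1], koff_hi_s = koff[2])
}
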