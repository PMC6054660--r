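# Trajectory file formats and rendering.
#
# Two encodings with identical logical content, selected by extension:
#   .csv      plain text, '#'-prefixed JSON header, one record per line
#   .parquet  Arrow/Parquet binary container, header in file metadata
# Coordinates: origin at the lower-left box corner, x rightward, y upward,
# nm units; unwrapped coordinate = wrapped + winding * box length (winding is
# identically zero outside periodic mode).

TRAJ_FORMAT_VERSION <- "1"
TRAJ_COLUMNS <- c("frame", "time_ns", "id", "species", "x", "y", "theta",
                  "wind_x", "wind_y", "cluster_id")

traj_header <- function(traj) {
  meta <- traj_meta(traj)
  list(
    format = "mesomp-trajectory",
    version = TRAJ_FORMAT_VERSION,
    box = if (is.null(meta$box)) NULL else as.list(meta$box),
    boundary = meta$boundary,
    step_duration = meta$step_duration,
    seed = meta$seed,
    species = if (is.null(meta$species)) NULL else {
      lapply(unname(meta$species), species_to_list)
    }
  )
}

apply_header <- function(frames, h) {
  if (!identical(h$format, "mesomp-trajectory")) {
    rlang::abort("malformed header: not a mesomp trajectory file")
  }
  if (!identical(as.character(h$version), TRAJ_FORMAT_VERSION)) {
    rlang::abort(sprintf("trajectory format version mismatch: file has %s, reader supports %s",
                         h$version, TRAJ_FORMAT_VERSION))
  }
  species <- NULL
  if (!is.null(h$species)) {
    species <- lapply(h$species, species_from_list)
    names(species) <- vapply(species, `[[`, "", "name")
  }
  structure(frames,
            box = if (is.null(h$box)) NULL else unlist(h$box),
            boundary = h$boundary, step_duration = h$step_duration,
            seed = h$seed, species = species,
            class = c("meso_trajectory", class(tibble::tibble())))
}

validate_frames <- function(frames, path) {
  missing <- setdiff(TRAJ_COLUMNS, names(frames))
  if (length(missing)) {
    rlang::abort(sprintf("parse error in %s: missing column(s) %s",
                         path, paste(missing, collapse = ", ")))
  }
  if (anyNA(frames[TRAJ_COLUMNS])) {
    bad <- which(rowSums(is.na(frames[TRAJ_COLUMNS])) > 0)[1]
    rlang::abort(sprintf("parse error in %s: incomplete record %d (truncated file?)",
                         path, bad))
  }
  if (is.unsorted(frames$frame)) {
    rlang::abort(sprintf("parse error in %s: non-monotonic frame indices", path))
  }
  frames
}

#' Write / read a trajectory file
#'
#' The encoding follows the file extension: `.csv` writes a text file whose
#' first lines are a `#`-prefixed JSON header followed by a standard CSV
#' table; `.parquet` writes an Arrow/Parquet container with the same header
#' stored in the file's key-value metadata. Both encodings round-trip every
#' field and the trajectory metadata losslessly.
#'
#' @param traj a `meso_trajectory`.
#' @param path output path ending in `.csv` or `.parquet`.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the `meso_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  frames <- tibble::as_tibble(traj)[TRAJ_COLUMNS]
  header <- traj_header(traj)
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA,
                            null = "null")
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    con <- file(path, "w")
    writeLines(c("# mesomp-trajectory", paste0("# ", hjson)), con)
    close(con)
    readr::write_csv(frames, path, append = TRUE, col_names = TRUE)
  } else if (ext == "parquet") {
    tbl <- arrow::arrow_table(frames)
    tbl$metadata$mesomp_header <- as.character(hjson)
    arrow::write_parquet(tbl, path)
  } else {
    rlang::abort(sprintf("unsupported trajectory extension '.%s' (use .csv or .parquet)",
                         ext))
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("trajectory file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    head2 <- readLines(path, n = 2)
    if (length(head2) < 2 || head2[1] != "# mesomp-trajectory") {
      rlang::abort(sprintf("parse error in %s: missing trajectory header (line 1)",
                           path))
    }
    h <- jsonlite::fromJSON(sub("^# ", "", head2[2]),
                            simplifyVector = FALSE)
    frames <- suppressWarnings(
      readr::read_csv(path, comment = "#", show_col_types = FALSE,
                      progress = FALSE))
    probs <- readr::problems(frames)
    if (nrow(probs)) {
      rlang::abort(sprintf("parse error in %s: row %d (%s)", path,
                           probs$row[1], probs$expected[1]))
    }
  } else if (ext == "parquet") {
    tbl <- arrow::read_parquet(path, as_data_frame = FALSE)
    hjson <- tbl$metadata$mesomp_header
    if (is.null(hjson)) {
      rlang::abort(sprintf("parse error in %s: missing trajectory header metadata",
                           path))
    }
    h <- jsonlite::fromJSON(hjson, simplifyVector = FALSE)
    frames <- tibble::as_tibble(as.data.frame(tbl))
  } else {
    rlang::abort(sprintf("unsupported trajectory extension '.%s'", ext))
  }
  frames <- validate_frames(tibble::as_tibble(frames), path)
  frames$id <- as.integer(frames$id)
  frames$frame <- as.integer(frames$frame)
  frames$wind_x <- as.integer(frames$wind_x)
  frames$wind_y <- as.integer(frames$wind_y)
  frames$cluster_id <- as.integer(frames$cluster_id)
  apply_header(frames, h)
}

#' Export one frame as an XYZ coordinate file
#'
#' One pseudo-atom per protein at (x, y, 0), with the species encoded in the
#' atom-name column, for inspection in standard molecular viewers.
#'
#' @param frame a single-frame tibble (`species`, `x`, `y`).
#' @param path output path (conventionally `.xyz`).
#' @param comment second-line comment string.
#' @return `path`, invisibly.
#' @export
export_positions <- function(frame, path, comment = "mesomp frame") {
  atom <- toupper(substr(frame$species, 1, 3))
  if (nrow(frame) == 0) atom <- character()
  lines <- c(
    as.character(nrow(frame)),
    comment,
    sprintf("%s %.3f %.3f %.3f", atom, frame$x, frame$y, 0)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Render a trajectory as a fluorescence-style image stack
#'
#' Emulates TIRF-microscopy observation of an under-labelled sample: a subset
#' of proteins (drawn once per run with probability `labelled_fraction`) each
#' contribute a 2D Gaussian point-spread function at their position, Poisson
#' shot noise and background are added, and frames are written as a
#' multi-page 16-bit TIFF. The labelled-emitter ground truth is written as a
#' CSV sidecar (`<path>.emitters.csv`) for tracking-evaluation use.
#'
#' @param traj a `meso_trajectory` with a box.
#' @param path output TIFF path.
#' @param pixel_size nm per pixel (default 100).
#' @param psf_sigma Gaussian PSF width in nm (default 130).
#' @param labelled_fraction probability a protein carries a label
#'   (default 0.1).
#' @param intensity expected photon count per emitter per frame.
#' @param background Poisson background mean per pixel.
#' @param seed optional RNG seed for label assignment and shot noise.
#' @return invisibly, a list with `path`, `labelled_ids`, `n_frames`,
#'   `dim` (pixels).
#' @export
render_frames <- function(traj, path, pixel_size = 100, psf_sigma = 130,
                          labelled_fraction = 0.1, intensity = 5000,
                          background = 5, seed = NULL) {
  stopifnot(pixel_size > 0, psf_sigma > 0,
            labelled_fraction > 0, labelled_fraction <= 1)
  box <- attr(traj, "box")
  if (is.null(box)) rlang::abort("trajectory has no box; cannot render")
  npx <- ceiling(box[["width"]] / pixel_size)
  npy <- ceiling(box[["height"]] / pixel_size)
  if (npx < 4 || npy < 4) {
    rlang::abort("degenerate pixel geometry: box maps to fewer than 4x4 pixels")
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- sort(unique(traj$id))
  labelled <- ids[runif(length(ids)) < labelled_fraction]
  if (length(labelled) == 0) labelled <- ids[1] # keep at least one emitter
  frames <- sort(unique(traj$frame))
  # PSF evaluated at pixel centres, normalized off-grid so total intensity is
  # conserved; emitters clipped at the field edge lose the clipped part
  px_centers_x <- (seq_len(npx) - 0.5) * pixel_size
  px_centers_y <- (seq_len(npy) - 0.5) * pixel_size
  imgs <- vector("list", length(frames))
  emit <- vector("list", length(frames))
  maxval <- 0
  for (fi in seq_along(frames)) {
    f <- dplyr::filter(tibble::as_tibble(traj), .data$frame == frames[fi],
                       .data$id %in% labelled)
    img <- matrix(0, nrow = npy, ncol = npx)
    for (r in seq_len(nrow(f))) {
      gx <- exp(-(px_centers_x - f$x[r])^2 / (2 * psf_sigma^2))
      gy <- exp(-(px_centers_y - f$y[r])^2 / (2 * psf_sigma^2))
      norm <- (pixel_size / (psf_sigma * sqrt(2 * pi)))^2
      img <- img + intensity * norm * outer(gy, gx)
    }
    counts <- matrix(rpois(npx * npy, lambda = img + background),
                     nrow = npy, ncol = npx)
    imgs[[fi]] <- counts
    maxval <- max(maxval, counts)
    emit[[fi]] <- tibble::tibble(frame = frames[fi], id = f$id,
                                 x = f$x, y = f$y,
                                 px = f$x / pixel_size, py = f$y / pixel_size)
  }
  scale <- max(maxval, 1)
  tiff::writeTIFF(lapply(imgs, function(m) m / 65535), path,
                  bits.per.sample = 16, reduce = FALSE)
  readr::write_csv(purrr::list_rbind(emit), paste0(path, ".emitters.csv"))
  invisible(list(path = path, labelled_ids = labelled,
                 n_frames = length(frames), dim = c(npy, npx),
                 max_count = maxval, scale = scale))
}
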