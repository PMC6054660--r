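# Simulation configuration: box geometry, boundary mode, cutoffs, the species
# table, grid initialization and run length. Serialized to/from YAML so a run
# is fully described by one file plus a seed.

#' Build a simulation configuration
#'
#' @param box_width,box_height box dimensions in nm.
#' @param n_x,n_y initial square-grid dimensions (the grid is centred in the
#'   box at `grid_spacing`).
#' @param boundary `"hard_wall"` (moves that would take any cluster member
#'   outside the box are rejected) or `"periodic"` (minimum-image distances,
#'   coordinates wrapped with winding numbers).
#' @param species a `species_params` object or named list of them; grid
#'   proteins are all of the first species.
#' @param n_steps number of engine steps.
#' @param step_duration physical duration of one step in ns (default 10).
#' @param interaction_cutoff association cutoff in nm (default 5).
#' @param clash_fraction fraction of the cutoff below which two centres clash
#'   (default 0.98, i.e. a 4.9 nm excluded-distance for a 5 nm cutoff).
#' @param grid_spacing initial nearest-neighbour spacing in nm (default 10;
#'   must exceed the cutoff so the starting grid is interaction-free).
#' @param specific_interfaces if `FALSE`, proteins in the interaction band
#'   associate regardless of orientation (the no-specific-interfaces control).
#' @param save_interval record a frame every this many steps (default 10).
#' @param seed integer RNG seed; `NULL` leaves the RNG state untouched.
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config(120, 120, n_x = 12, n_y = 12, species = btub_species(),
#'                   n_steps = 100, seed = 1)
#' @export
sim_config <- function(box_width, box_height, n_x, n_y,
                       boundary = c("hard_wall", "periodic"),
                       species = btub_species(),
                       n_steps = 1000,
                       step_duration = 10,
                       interaction_cutoff = 5,
                       clash_fraction = 0.98,
                       grid_spacing = 10,
                       specific_interfaces = TRUE,
                       save_interval = 10,
                       seed = NULL) {
  boundary <- match.arg(boundary)
  if (inherits(species, "species_params")) {
    species <- setNames(list(species), species$name)
  }
  stopifnot(length(species) >= 1, box_width > 0, box_height > 0,
            n_x >= 1, n_y >= 1, n_steps >= 0, step_duration > 0,
            interaction_cutoff > 0, save_interval >= 1)
  if (!(clash_fraction > 0 && clash_fraction < 1)) {
    rlang::abort("`clash_fraction` must lie in (0, 1)")
  }
  if (grid_spacing <= interaction_cutoff) {
    rlang::abort("`grid_spacing` must exceed `interaction_cutoff`")
  }
  patch_extent <- c((n_x - 1) * grid_spacing, (n_y - 1) * grid_spacing)
  if (patch_extent[1] > box_width || patch_extent[2] > box_height) {
    rlang::abort(sprintf(
      "configuration error: %d x %d grid at %g nm spacing (%g x %g nm) does not fit in the %g x %g nm box",
      n_x, n_y, grid_spacing, patch_extent[1], patch_extent[2],
      box_width, box_height))
  }
  structure(
    list(box_width = box_width, box_height = box_height,
         n_x = n_x, n_y = n_y, boundary = boundary, species = species,
         n_steps = n_steps, step_duration = step_duration,
         interaction_cutoff = interaction_cutoff,
         clash_fraction = clash_fraction, grid_spacing = grid_spacing,
         patch_extent = patch_extent,
         specific_interfaces = specific_interfaces,
         save_interval = save_interval, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_x, "x", x$n_y, " grid in ", x$box_width, "x",
      x$box_height, " nm box (", x$boundary, ")\n", sep = "")
  cat("  ", x$n_steps, " steps of ", x$step_duration,
      " ns; cutoff ", x$interaction_cutoff, " nm, clash below ",
      x$clash_fraction * x$interaction_cutoff, " nm; interfaces ",
      if (x$specific_interfaces) "specific" else "isotropic", "\n", sep = "")
  invisible(x)
}

species_to_list <- function(sp) {
  list(name = sp$name, diameter = sp$diameter,
       patches = list(start = sp$patches$start, end = sp$patches$end),
       trans_law = as.list(sp$trans_law), rot_law = as.list(sp$rot_law),
       std_min = sp$std_min)
}

species_from_list <- function(l) {
  species_params(
    name = l$name, diameter = l$diameter,
    patches = interaction_patches(unlist(l$patches$start),
                                  unlist(l$patches$end)),
    trans_law = c(A = l$trans_law$A, b = l$trans_law$b),
    rot_law = c(A = l$rot_law$A, b = l$rot_law$b),
    std_min = l$std_min %||% 0
  )
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a `sim_config`.
#' @param path file path (conventionally `.yaml`).
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  l <- unclass(config)
  l$species <- lapply(l$species, species_to_list)
  l$patch_extent <- NULL # derived
  yaml::write_yaml(l, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("config file not found: %s", path))
  }
  l <- yaml::read_yaml(path)
  sim_config(
    box_width = l$box_width, box_height = l$box_height,
    n_x = l$n_x, n_y = l$n_y, boundary = l$boundary,
    species = setNames(lapply(l$species, species_from_list),
                       vapply(l$species, `[[`, "", "name")),
    n_steps = l$n_steps, step_duration = l$step_duration,
    interaction_cutoff = l$interaction_cutoff,
    clash_fraction = l$clash_fraction, grid_spacing = l$grid_spacing,
    specific_interfaces = l$specific_interfaces,
    save_interval = l$save_interval, seed = l$seed
  )
}
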