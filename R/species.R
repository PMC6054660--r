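# Species geometry and motion laws.
#
# A species is a rigid disc of given diameter carrying zero or more "sticky
# patch" angular intervals on its perimeter (body frame, degrees,
# counter-clockwise from the orientation axis; intervals may wrap across 360).
# Its mobility is a cluster-size-dependent Gaussian step law
# std(n) = A * n^(-b), one law for per-axis translation and one for rotation.

#' Define an interaction patch set
#'
#' Patches are angular intervals on a protein's perimeter, in its body frame
#' (degrees counter-clockwise from the orientation axis). Intervals may wrap
#' across 360 (e.g. `start = 350, end = 10`). Membership is tested modulo 360.
#'
#' @param start,end numeric vectors of interval endpoints in degrees.
#' @return a tibble with columns `start` and `end`, normalized to `[0, 360)`.
#' @examples
#' interaction_patches(c(15, 180), c(80, 230)) # the BtuB interface geometry
#' @export
interaction_patches <- function(start, end) {
  if (length(start) != length(end)) {
    rlang::abort("`start` and `end` must have the same length")
  }
  start <- wrap_angle(start)
  end <- wrap_angle(end)
  width <- wrap_angle(end - start)
  if (length(start) && any(width == 0)) {
    rlang::abort("patch width must be strictly between 0 and 360 degrees")
  }
  tibble::tibble(start = start, end = end)
}

#' Angular interval membership, modulo 360
#'
#' @param angle numeric vector of angles in degrees (any range).
#' @param patches a tibble of patch intervals from [interaction_patches()].
#' @return logical vector: does each angle fall inside any patch (endpoints
#'   inclusive)?
#' @export
in_patch <- function(angle, patches) {
  a <- wrap_angle(angle)
  if (is.null(patches) || nrow(patches) == 0L) {
    return(rep(FALSE, length(a)))
  }
  hit <- rep(FALSE, length(a))
  for (k in seq_len(nrow(patches))) {
    s <- patches$start[k]
    e <- patches$end[k]
    hit <- hit | if (s <= e) a >= s & a <= e else a >= s | a <= e
  }
  hit
}

#' Normalize angles to [0, 360)
#' @param a numeric vector, degrees.
#' @return angles wrapped onto `[0, 360)`.
#' @export
wrap_angle <- function(a) {
  w <- a %% 360
  w[w == 360] <- 0
  w
}

#' Per-step Gaussian standard deviation for a cluster of size n
#'
#' Evaluates the power law `std(n) = A * n^(-b)`, the mobility model in which
#' larger rigid clusters make smaller moves; for clusters larger than the
#' sizes observed during parameterization the same law is extrapolated, with
#' an optional floor `std_min`.
#'
#' @param n cluster size(s), positive integers.
#' @param A amplitude (nm for translation, degrees for rotation).
#' @param b dimensionless exponent.
#' @param std_min lower floor for the returned std (default 0).
#' @return numeric vector of standard deviations.
#' @examples
#' power_law_std(c(1, 4), A = 0.35, b = 0.5) # 0.35, 0.175
#' @export
power_law_std <- function(n, A, b, std_min = 0) {
  if (any(n < 1)) rlang::abort("cluster size must be >= 1")
  pmax(A * n^(-b), std_min)
}

#' Define a protein species
#'
#' @param name species label (e.g. `"BtuB"`).
#' @param diameter particle diameter in nm (BtuB is modelled as 5 nm).
#' @param patches a tibble from [interaction_patches()]; `NULL` for a species
#'   with no specific interfaces.
#' @param trans_law,rot_law numeric `c(A = , b = )`: per-step Gaussian std
#'   power laws for per-axis translation (nm) and rotation (degrees).
#' @param std_min floor applied to both laws when extrapolating to very large
#'   clusters (default 0).
#' @return an object of class `species_params`.
#' @examples
#' btub_species(trans_A = 0.2, rot_A = 2)
#' @export
species_params <- function(name, diameter = 5,
                           patches = interaction_patches(numeric(), numeric()),
                           trans_law = c(A = 0.2, b = 0.5),
                           rot_law = c(A = 2, b = 0.5),
                           std_min = 0) {
  stopifnot(diameter > 0, trans_law[["A"]] >= 0, rot_law[["A"]] >= 0,
            std_min >= 0)
  if (is.null(patches)) patches <- interaction_patches(numeric(), numeric())
  structure(
    list(name = name, diameter = diameter, patches = patches,
         trans_law = c(A = unname(trans_law[["A"]]), b = unname(trans_law[["b"]])),
         rot_law = c(A = unname(rot_law[["A"]]), b = unname(rot_law[["b"]])),
         std_min = std_min),
    class = "species_params"
  )
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params> ", x$name, " (diameter ", x$diameter, " nm)\n", sep = "")
  cat("  trans std(n) = ", x$trans_law[["A"]], " * n^-", x$trans_law[["b"]],
      " nm;  rot std(n) = ", x$rot_law[["A"]], " * n^-", x$rot_law[["b"]],
      " deg\n", sep = "")
  if (nrow(x$patches)) {
    cat("  patches: ",
        paste(sprintf("[%g, %g]", x$patches$start, x$patches$end),
              collapse = ", "), "\n", sep = "")
  } else {
    cat("  patches: none (isotropic)\n")
  }
  invisible(x)
}

#' BtuB-like species with the canonical interface geometry
#'
#' Convenience constructor for the vitamin B12 transporter BtuB as modelled at
#' the mesoscale: a 5 nm disc with two sticky patches at 15-80 and 180-230
#' degrees.
#'
#' @param trans_A,rot_A monomer per-step stds (nm per axis, degrees).
#' @param trans_b,rot_b power-law exponents.
#' @param std_min extrapolation floor.
#' @return a `species_params` object named `"BtuB"`.
#' @export
btub_species <- function(trans_A = 0.2, trans_b = 0.5,
                         rot_A = 2, rot_b = 0.5, std_min = 0) {
  species_params(
    "BtuB", diameter = 5,
    patches = interaction_patches(c(15, 180), c(80, 230)),
    trans_law = c(A = trans_A, b = trans_b),
    rot_law = c(A = rot_A, b = rot_b),
    std_min = std_min
  )
}

#' Circular Jaccard overlap between two patch sets
#'
#' Measures agreement between two sets of angular intervals as the Jaccard
#' index of their union supports on the circle, evaluated on a fine grid.
#'
#' @param p1,p2 patch tibbles from [interaction_patches()].
#' @param resolution grid step in degrees (default 0.1).
#' @return Jaccard overlap in `[0, 1]` (1 if both are empty).
#' @export
patch_overlap <- function(p1, p2, resolution = 0.1) {
  grid <- seq(0, 360 - resolution, by = resolution)
  a <- in_patch(grid, p1)
  b <- in_patch(grid, p2)
  if (!any(a) && !any(b)) return(1)
  sum(a & b) / sum(a | b)
}
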