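#' Extract a trephine rim loop, optionally deformed
#'
#' Pulls a named closed node cycle out of the mesh and returns its vertex
#' coordinates, displaced by `u` when a solved field is supplied. The
#' orientation is normalised to counter-clockwise about the loop's mean
#' (Newell) normal, with the normal's sign fixed to point towards the
#' outward/protrusion side (positive component along the through-thickness
#' axis, estimated from the loop itself).
#'
#' @param mesh a [tet_mesh()].
#' @param loop_name name of a loop, e.g. `"trephine_inner_loop"`.
#' @param u optional [solve_displacements()] result or N x 3 matrix (mm).
#' @return Closed polyline: an n x 3 matrix (mm), one row per vertex, the
#'   first vertex not repeated.
#' @export
extract_trephine_loop <- function(mesh, loop_name, u = NULL) {
  if (!loop_name %in% names(mesh$loops)) {
    stop("unknown loop '", loop_name, "'; available: ",
         if (length(mesh$loops)) paste(names(mesh$loops), collapse = ", ")
         else "(none)")
  }
  ids <- mesh$loops[[loop_name]]
  pts <- mesh$nodes[ids, , drop = FALSE]
  if (!is.null(u)) {
    if (inherits(u, "displacement_field")) u <- u$u
    u <- as.matrix(u)
    if (nrow(u) != nrow(mesh$nodes)) stop("displacement field size mismatch")
    pts <- pts + u[ids, , drop = FALSE]
  }
  nrm <- newell_vector(pts)
  ref <- c(0, 0, 1)
  s <- sum(nrm * ref)
  if (abs(s) < 1e-12 * sqrt(sum(nrm^2))) s <- nrm[which.max(abs(nrm))]
  if (s < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  pts
}

# Newell vector area: 0.5 * sum r_i x r_{i+1}; norm = loop area, direction =
# mean normal. Robust for closed, possibly non-planar polygons.
newell_vector <- function(pts) {
  nxt <- c(2:nrow(pts), 1L)
  0.5 * colSums(cross3(pts, pts[nxt, , drop = FALSE]))
}

#' Measure a closed trephine loop
#'
#' Computes the morphometric quantities reported for stoma incisions:
#' perimeter (sum of segment lengths), area (magnitude of the Newell vector
#' area, which equals the projected planar area for a near-planar loop) and
#' the loop's extents along two body axes — "axial" (horizontal, default
#' global x) and "sagittal" (antero-posterior protrusion direction, default
#' global z). Input coordinates are mm; results are reported in cm / cm^2.
#'
#' @param loop closed polyline, an n x 3 matrix in mm (n >= 8, simple).
#' @param axial_axis,sagittal_axis unit direction vectors of the two
#'   diameter measurements.
#' @return A one-row tibble of class `"trephine_measurement"`: columns
#'   `perimeter_cm`, `area_cm2`, `axial_diameter_cm`, `sagittal_diameter_cm`
#'   plus (filled by [enlargement()]) `percent_area_increase` and
#'   `percent_perimeter_increase`.
#' @export
measure_loop <- function(loop, axial_axis = c(1, 0, 0),
                         sagittal_axis = c(0, 0, 1)) {
  loop <- as.matrix(loop)
  if (nrow(loop) >= 2L &&
      sqrt(sum((loop[1L, ] - loop[nrow(loop), ])^2)) < 1e-12) {
    loop <- loop[-nrow(loop), , drop = FALSE]   # tolerate repeated endpoint
  }
  if (nrow(loop) < 8L) stop("loop must have at least 8 vertices")
  # Simplicity is checked via the best-fit-plane projection, but only for
  # near-planar loops: a strongly warped deformed rim can self-cross in
  # projection while the space curve itself is perfectly fine, and the
  # Newell area remains the right area measure there.
  nrm <- newell_vector(loop)
  nhat <- nrm / max(sqrt(sum(nrm^2)), 1e-300)
  q <- sweep(loop, 2L, colMeans(loop))
  out_of_plane <- max(abs(q %*% nhat))
  diam <- max(sqrt(rowSums(q^2))) * 2
  if (out_of_plane < 0.05 * diam && polyline_self_intersects(loop)) {
    stop("non-simple loop")
  }
  nxt <- c(2:nrow(loop), 1L)
  per <- sum(sqrt(rowSums((loop[nxt, , drop = FALSE] - loop)^2)))
  area <- sqrt(sum(newell_vector(loop)^2))
  if (area <= 1e-12 * per^2) stop("degenerate (zero-area) loop")
  pa <- loop %*% (axial_axis / sqrt(sum(axial_axis^2)))
  ps <- loop %*% (sagittal_axis / sqrt(sum(sagittal_axis^2)))
  out <- tibble::tibble(
    perimeter_cm = per / 10,
    area_cm2 = area / 100,
    axial_diameter_cm = (max(pa) - min(pa)) / 10,
    sagittal_diameter_cm = (max(ps) - min(ps)) / 10,
    percent_area_increase = NA_real_,
    percent_perimeter_increase = NA_real_)
  class(out) <- c("trephine_measurement", class(out))
  out
}

#' Percent enlargement of a deformed trephine
#'
#' Fills the percent-increase fields of a deformed measurement relative to
#' the reference (undeformed) one:
#' `100 * (deformed - reference) / reference`.
#'
#' @param reference,deformed [measure_loop()] results.
#' @return The deformed measurement with `percent_area_increase` and
#'   `percent_perimeter_increase` filled.
#' @examples
#' ref <- tibble::tibble(perimeter_cm = 6.28, area_cm2 = 3.14)
#' def <- tibble::tibble(perimeter_cm = 9.05, area_cm2 = 5.82)
#' enlargement(ref, def)   # 85% area, 44% perimeter (as rounded in print)
#' @export
enlargement <- function(reference, deformed) {
  stopifnot(reference$area_cm2 > 0, reference$perimeter_cm > 0)
  out <- deformed
  out$percent_area_increase <-
    100 * (deformed$area_cm2 - reference$area_cm2) / reference$area_cm2
  out$percent_perimeter_increase <-
    100 * (deformed$perimeter_cm - reference$perimeter_cm) / reference$perimeter_cm
  if (!inherits(out, "trephine_measurement")) {
    class(out) <- c("trephine_measurement", class(out))
  }
  out
}

#' Mean trephine enlargement per stoma-position group
#'
#' Averages the percent increases over the position groups of the labelling
#' scheme: the midline stoma `"s0"` is reported alone and the lateral
#' columns are grouped by their `i` index (`s1j`, `s2j`, `s3j`), mirroring
#' how enlargement is compared between stomas crossing the rectus abdominis
#' and stomas lateral to it.
#'
#' @param measurements a tibble with a `position` label column and the
#'   percent-increase columns of [measure_loop()] rows (e.g. several
#'   [enlargement()] results bound together).
#' @return A tibble with one row per group: `group`, `n`,
#'   `mean_percent_area_increase`, `mean_percent_perimeter_increase`.
#'   Empty groups are omitted.
#' @export
summarize_by_position <- function(measurements) {
  stopifnot("position" %in% names(measurements))
  lab <- measurements$position
  known <- stoma_position_labels()
  bad <- setdiff(unique(lab), known)
  if (length(bad)) {
    stop("unknown position label(s): ", paste(bad, collapse = ", "))
  }
  measurements |>
    dplyr::mutate(group = ifelse(lab == "s0", "s0",
                                 paste0("s", substr(lab, 2L, 2L), "j"))) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_percent_area_increase = mean(.data$percent_area_increase),
      mean_percent_perimeter_increase = mean(.data$percent_perimeter_increase),
      .groups = "drop")
}
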