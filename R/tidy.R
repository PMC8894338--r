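#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for wallfem result objects
#'
#' `tidy()` returns the per-case results of a sweep (one row per position x
#' pressure), per-element stress rows for a `stress_state`, or per-node
#' displacement rows for a `displacement_field`. `glance()` condenses a
#' sweep into a one-row summary.
#'
#' @param x a `wall_experiment`, `stress_state` or `displacement_field`.
#' @param ... unused.
#' @return A tibble.
#' @name wallfem-tidiers
NULL

#' @rdname wallfem-tidiers
#' @method tidy wall_experiment
#' @export
tidy.wall_experiment <- function(x, ...) x$results

#' @rdname wallfem-tidiers
#' @method glance wall_experiment
#' @export
glance.wall_experiment <- function(x, ...) {
  res <- x$results[x$results$status == "ok", ]
  pmax <- max(res$pressure_kPa)
  top <- res[res$pressure_kPa == pmax, ]
  tibble::tibble(
    n_positions = length(unique(x$results$position)),
    n_pressures = length(unique(x$results$pressure_kPa)),
    n_failed = length(x$failures),
    pressure_max_kPa = pmax,
    max_displacement_mm = max(top$max_displacement_mm),
    vm_max_MPa = max(top$vm_max_MPa),
    max_percent_area_increase = if ("percent_area_increase" %in% names(top))
      max(top$percent_area_increase, na.rm = TRUE) else NA_real_)
}

#' @rdname wallfem-tidiers
#' @method tidy stress_state
#' @export
tidy.stress_state <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$stress))
  out$region <- x$regions
  out$von_mises <- x$von_mises
  out$element <- seq_len(nrow(out))
  dplyr::relocate(out, "element", "region")
}

#' @rdname wallfem-tidiers
#' @method tidy displacement_field
#' @export
tidy.displacement_field <- function(x, ...) {
  tibble::tibble(node = seq_len(nrow(x$u)),
                 ux = x$u[, 1], uy = x$u[, 2], uz = x$u[, 3],
                 magnitude = sqrt(rowSums(x$u^2)))
}

#' Plot trephine enlargement across stoma positions
#'
#' Bar chart of the percent area (and optionally perimeter) increase per
#' stoma position at the largest simulated pressure, the headline
#' comparison of a placement sweep.
#'
#' @param object a [run_experiment()] result.
#' @param metric `"area"`, `"perimeter"` or `"both"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot wall_experiment
#' @export
autoplot.wall_experiment <- function(object, metric = c("both", "area",
                                                        "perimeter"), ...) {
  metric <- match.arg(metric)
  res <- tidy(object)
  pmax <- max(res$pressure_kPa)
  dat <- res |>
    dplyr::filter(.data$pressure_kPa == pmax, .data$position != "none",
                  .data$status == "ok") |>
    dplyr::mutate(position = factor(.data$position,
                                    levels = stoma_position_labels())) |>
    tidyr::pivot_longer(dplyr::all_of(c("percent_area_increase",
                                        "percent_perimeter_increase")),
                        names_to = "metric", values_to = "percent") |>
    dplyr::mutate(metric = ifelse(.data$metric == "percent_area_increase",
                                  "area", "perimeter"))
  if (metric != "both") dat <- dat[dat$metric == metric, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$percent,
                                    fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "stoma position",
                  y = sprintf("%% increase at %g kPa", pmax),
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a reference and a deformed trephine loop
#'
#' Projects both loops on the axial/sagittal plane used for the diameter
#' measurements, visualising the elliptic shape the incision adopts under
#' load.
#'
#' @param reference,deformed closed polylines from
#'   [extract_trephine_loop()] (mm).
#' @return A ggplot object.
#' @export
plot_trephine_loops <- function(reference, deformed) {
  mk <- function(p, which) {
    p <- rbind(p, p[1L, , drop = FALSE])
    tibble::tibble(x = p[, 1], z = p[, 3], loop = which)
  }
  dat <- dplyr::bind_rows(mk(reference, "reference"), mk(deformed, "deformed"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$z, colour = .data$loop)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "axial position (mm)", y = "sagittal position (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
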