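#' Configuration of a stoma-position sweep
#'
#' Bundles everything one experiment needs: the wall phantom (or a path to
#' an external `.msh` mesh), the material table, the intraabdominal
#' pressure levels (kPa) and the stoma positions to simulate. The default
#' protocol solves the no-stoma reference wall plus all 17 labelled
#' trephine positions at five equally spaced pressure levels up to 20 kPa,
#' the pressure reached when coughing or jumping.
#'
#' @param phantom a [phantom_spec()], or a path to a Gmsh `.msh` file (in
#'   which case `positions` is ignored and the mesh is solved as-is).
#' @param materials a [material_table()].
#' @param iap_levels_kPa non-negative, ascending pressure levels in kPa.
#' @param positions character vector of stoma labels; `"none"` is the
#'   reference wall without incision.
#' @param outdir output directory for `summary.csv`, per-case `.vtu` files
#'   and `run.log`, or `NULL` to keep results in memory only.
#' @param linearity_shortcut solve once per geometry at the largest
#'   pressure and scale to the other levels (exact in the linear model); a
#'   scaling self-check against an independent solve is run on the first
#'   geometry. Set `FALSE` to solve every level.
#' @param vtu which cases get a `.vtu` export when `outdir` is set:
#'   `"max"` (largest pressure only), `"all"`, or `"none"`.
#' @param solver `"direct"` or `"cg"`, see [solve_displacements()].
#' @param verbose print progress messages.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(phantom = phantom_spec(),
                              materials = default_materials(),
                              iap_levels_kPa = c(4, 8, 12, 16, 20),
                              positions = c("none", stoma_position_labels()),
                              outdir = NULL,
                              linearity_shortcut = TRUE,
                              vtu = c("max", "all", "none"),
                              solver = c("direct", "cg"),
                              verbose = FALSE) {
  stopifnot(is.numeric(iap_levels_kPa), length(iap_levels_kPa) >= 1L,
            all(iap_levels_kPa >= 0), !is.unsorted(iap_levels_kPa))
  valid <- c("none", stoma_position_labels())
  bad <- setdiff(positions, valid)
  if (length(bad)) stop("invalid position label(s): ", paste(bad, collapse = ", "))
  structure(list(phantom = phantom, materials = materials,
                 iap_levels_kPa = as.double(iap_levels_kPa),
                 positions = positions, outdir = outdir,
                 linearity_shortcut = isTRUE(linearity_shortcut),
                 vtu = match.arg(vtu), solver = match.arg(solver),
                 verbose = isTRUE(verbose)),
            class = "experiment_config")
}

#' Run a stoma-position / pressure sweep
#'
#' For every requested position the wall phantom is meshed (with or without
#' its trephine), solved under the largest pressure and post-processed at
#' every pressure level: maximum displacement magnitude, global and
#' per-region maximum von Mises stress and — when a trephine exists — the
#' deformed-loop morphometry of the innermost rim with percent enlargement
#' against the reference configuration. In the linear model displacements
#' and stresses scale exactly with pressure, so one factorisation per
#' geometry suffices; the trephine measures are re-evaluated at each scaled
#' displacement because perimeter and area are nonlinear in the
#' displacement.
#'
#' Failures in one case are caught, logged and reported in the `status`
#' column without aborting the sweep.
#'
#' @param config an [experiment_config()].
#' @return An object of class `"wall_experiment"`: list with `results` (one
#'   tibble row per position x pressure), `config`, `failures`, and
#'   `reference` (per-position reference loop measurements).
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  t_start <- Sys.time()
  log_lines <- c(sprintf("wallfem sweep started %s", format(t_start)),
                 sprintf("R %s, Matrix %s", getRversion(),
                         as.character(utils::packageVersion("Matrix"))),
                 "config:", yaml::as.yaml(config_as_list(config)))
  external <- is.character(config$phantom)
  positions <- if (external) "external" else config$positions
  pk <- config$iap_levels_kPa
  pmax <- max(pk)
  rows <- list(); refs <- list(); failures <- character(0)
  lin_checked <- FALSE

  for (pos in positions) {
    res <- tryCatch(
      run_one_position(config, pos, pmax, pk, check_linearity =
                         config$linearity_shortcut && !lin_checked),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, pos)
      log_lines <- c(log_lines,
                     sprintf("case %s FAILED: %s", pos, conditionMessage(res)))
      rows[[pos]] <- tibble::tibble(position = pos, pressure_kPa = pk,
                                    status = "failed")
      next
    }
    lin_checked <- lin_checked || !is.null(res$linearity)
    if (!is.null(res$linearity)) {
      log_lines <- c(log_lines,
                     sprintf("linearity self-check (%s): max deviation %.3e mm",
                             pos, res$linearity))
    }
    rows[[pos]] <- res$rows
    refs[[pos]] <- res$reference
    log_lines <- c(log_lines, sprintf(
      "case %s: %d nodes, %d tets, solve residual %.2e",
      pos, res$n_nodes, res$n_tets, res$residual))
    if (config$verbose) message("case ", pos, " done")
  }
  results <- dplyr::bind_rows(rows)
  out <- structure(list(results = results, config = config,
                        failures = failures,
                        reference = dplyr::bind_rows(refs)),
                   class = "wall_experiment")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(config$outdir, "summary.csv"),
                     row.names = FALSE)
    log_lines <- c(log_lines, sprintf("finished %s (%.1f s)",
                                      format(Sys.time()),
                                      as.numeric(difftime(Sys.time(), t_start,
                                                          units = "secs"))))
    writeLines(log_lines, file.path(config$outdir, "run.log"))
  }
  if (length(failures)) {
    warning("cases failed: ", paste(failures, collapse = ", "))
  }
  out
}

run_one_position <- function(config, pos, pmax, pk, check_linearity = FALSE) {
  mesh <- position_mesh(config, pos)
  mats <- config$materials
  vrep <- validate_mesh(mesh, mats)
  if (nrow(vrep)) stop("invalid mesh for case ", pos, ": ", vrep$problem[1L])
  has_hole <- "trephine_inner_loop" %in% names(mesh$loops)
  p_MPa <- pmax / 1000
  lc <- load_case(p_MPa)
  K <- assemble_stiffness(mesh, mats)
  f <- assemble_pressure_load(mesh, lc$group, lc$pressure)
  sol <- if (pmax > 0) {
    solve_linear_system(mesh, K, f, lc, method = config$solver)
  } else {
    zero_field(mesh, lc)
  }
  lin_dev <- NULL
  if (check_linearity && pmax > 0) {
    p2 <- max(pk[pk > 0][1L], pmax / 4)
    sol2 <- solve_linear_system(mesh, K, f * (p2 / pmax), lc,
                                method = config$solver)
    lin_dev <- max(abs(sol2$u - (p2 / pmax) * sol$u))
  }
  ss <- if (pmax > 0) compute_strain_stress(mesh, mats, sol) else NULL
  ref_meas <- if (has_hole) {
    measure_loop(extract_trephine_loop(mesh, "trephine_inner_loop"))
  } else NULL

  region_names <- sort(unique(mesh$regions))
  mag <- sqrt(rowSums(sol$u^2))
  rows <- purrr::map_dfr(pk, function(p) {
    s <- if (pmax > 0) p / pmax else 0
    row <- tibble::tibble(
      position = pos, pressure_kPa = p, status = "ok",
      max_displacement_mm = max(mag) * s,
      vm_max_MPa = if (!is.null(ss)) max(ss$von_mises) * s else 0)
    for (rg in region_names) {
      row[[paste0("vm_max_", rg)]] <-
        if (!is.null(ss)) max(ss$von_mises[ss$regions == rg]) * s else 0
    }
    if (has_hole) {
      loop <- extract_trephine_loop(mesh, "trephine_inner_loop",
                                    u = sol$u * s)
      meas <- enlargement(ref_meas, measure_loop(loop))
      row <- dplyr::bind_cols(row, meas)
    }
    row
  })
  if (!is.null(config$outdir) && config$vtu != "none" && pmax > 0) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    plevels <- if (config$vtu == "max") pmax else pk
    for (p in plevels) {
      s <- p / pmax
      write_vtk(mesh,
                node_fields = list(
                  displacement = sol$u * s,
                  von_mises_nodal = nodal_average(mesh, ss$von_mises) * s),
                cell_fields = list(von_mises = ss$von_mises * s),
                path = file.path(config$outdir,
                                 sprintf("case_%s_P%g.vtu", pos, p)))
    }
  }
  list(rows = rows,
       reference = if (has_hole) {
         dplyr::bind_cols(tibble::tibble(position = pos), ref_meas)
       } else NULL,
       residual = sol$residual, linearity = lin_dev,
       n_nodes = nrow(mesh$nodes), n_tets = nrow(mesh$tets))
}

position_mesh <- function(config, pos) {
  if (is.character(config$phantom)) return(read_gmsh(config$phantom))
  args <- unclass(config$phantom)
  args$hole_position <- if (identical(pos, "none")) NULL else pos
  build_wall_phantom(do.call(phantom_spec, args))
}

zero_field <- function(mesh, lc) {
  structure(list(u = matrix(0, nrow(mesh$nodes), 3L),
                 fixed_dofs = integer(0),
                 reactions = matrix(0, nrow(mesh$nodes), 3L),
                 residual = 0),
            class = "displacement_field")
}

config_as_list <- function(config) {
  out <- unclass(config)
  if (inherits(out$phantom, "phantom_spec")) out$phantom <- unclass(out$phantom)
  out$materials <- as.data.frame(out$materials)
  out
}

#' @export
print.wall_experiment <- function(x, ...) {
  cat(sprintf("<wall_experiment> %d cases x %d pressure levels, %d failed\n",
              length(unique(x$results$position)),
              length(unique(x$results$pressure_kPa)), length(x$failures)))
  print(x$results, n = 10)
  invisible(x)
}

#' Table of deformed-stoma dimensions at one pressure
#'
#' Formats the sweep results at a single pressure level the way such
#' results are conventionally tabulated: one row per stoma position in
#' label order, deformed area (cm^2, 2 decimals), percent area increase
#' (integer), deformed perimeter (cm, 2 decimals) and percent perimeter
#' increase (integer). The reference (no-stoma) case carries no trephine
#' and is excluded.
#'
#' @param experiment a [run_experiment()] result.
#' @param pressure_kPa one of the pressure levels of the sweep.
#' @return A tibble with columns `position`, `area_cm2`,
#'   `pct_area_increase`, `perimeter_cm`, `pct_perimeter_increase`.
#' @export
report_table <- function(experiment, pressure_kPa) {
  res <- experiment$results
  levels <- unique(res$pressure_kPa)
  if (!pressure_kPa %in% levels) {
    stop("pressure ", pressure_kPa, " kPa not in results; available: ",
         paste(levels, collapse = ", "))
  }
  res |>
    dplyr::filter(.data$pressure_kPa == !!pressure_kPa,
                  .data$position != "none",
                  .data$status == "ok") |>
    dplyr::mutate(position = factor(.data$position,
                                    levels = stoma_position_labels())) |>
    dplyr::arrange(.data$position) |>
    dplyr::transmute(
      position = as.character(.data$position),
      area_cm2 = round(.data$area_cm2, 2L),
      pct_area_increase = round(.data$percent_area_increase),
      perimeter_cm = round(.data$perimeter_cm, 2L),
      pct_perimeter_increase = round(.data$percent_perimeter_increase))
}

#' Read or write an experiment configuration as YAML
#'
#' The whole configuration — phantom parameters, material table, pressure
#' levels, positions, solver options — round-trips through one
#' human-readable YAML file, which the sweep echoes into its run log so
#' every reported number can be reproduced from the log alone.
#'
#' @param path YAML file path.
#' @return `read_experiment_config()`: an [experiment_config()];
#'   `write_experiment_config()`: `path`, invisibly.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  phantom <- if (is.character(raw$phantom)) raw$phantom else {
    do.call(phantom_spec, raw$phantom[lengths(raw$phantom) > 0])
  }
  materials <- if (is.null(raw$materials)) default_materials() else {
    mt <- as.data.frame(do.call(rbind, lapply(raw$materials, as.data.frame)))
    material_table(mt$region, mt$E, mt$nu)
  }
  experiment_config(
    phantom = phantom, materials = materials,
    iap_levels_kPa = raw$iap_levels_kPa %||% c(4, 8, 12, 16, 20),
    positions = raw$positions %||% c("none", stoma_position_labels()),
    outdir = raw$outdir,
    linearity_shortcut = raw$linearity_shortcut %||% TRUE,
    vtu = raw$vtu %||% "max",
    solver = raw$solver %||% "direct",
    verbose = raw$verbose %||% FALSE)
}

#' @rdname read_experiment_config
#' @param config an [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  lst <- config_as_list(config)
  lst$materials <- unname(apply(lst$materials, 1L, function(r) {
    list(region = unname(r[["region"]]), E = as.numeric(r[["E"]]),
         nu = as.numeric(r[["nu"]]))
  }))
  yaml::write_yaml(lst, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
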