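#' Run the full morphometric analysis pipeline
#'
#' For every input volume of every condition (e.g. `"fast"` / `"slow"`
#' freezing): segmentation with ice localization (grey inputs; label
#' volumes are used as-is), phase volume fractions, vertical fraction
#' profiles, interface specific surface areas, local-thickness
#' distributions of the ice phases and, optionally, the mean-curvature
#' occurrence distribution of the ice surface. Condition-level scalars
#' are aggregated as arithmetic mean +/- sd over the per-volume fractions
#' (sd absent for a single volume). The run is fully deterministic given
#' its inputs; with `out_dir` set, CSV tables and a JSON summary are
#' written and identical reruns produce bit-identical files.
#'
#' @param conditions Named list of conditions; each element is a list of
#'   [grey_volume()], [label_volume()] or `phantom_volume` objects
#'   (phantoms contribute their grey volume).
#' @param thresholds `"auto"` or numeric `c(t_air_ice, t_ice_starch)`.
#' @param closing_radius Matrix closing radius, voxels.
#' @param slab_vx Slab thickness for vertical profiles, voxels.
#' @param profile_fractions Which fraction profiles to compute.
#' @param ssa_interfaces List of phase pairs for SSA (default: air vs ice
#'   outside, and ice inside vs starch).
#' @param thickness_phases Phases whose local thickness is measured.
#' @param curvature_phase Phase selector for curvature, or `NULL` to skip.
#' @param curvature_sigma_vx Smoothing sigma for the curvature estimator.
#' @param out_dir Optional output directory for CSV/JSON reports.
#' @return A `condition_report`: list of tibbles `fractions` (per
#'   volume), `summary` (condition mean/sd per fraction), `ssa`,
#'   `ssa_summary`, `profiles`, `thickness`, `curvature` (or `NULL`),
#'   and `failed` (volumes whose analysis aborted).
#' @export
run_pipeline <- function(conditions,
                         thresholds = "auto",
                         closing_radius = 16L,
                         slab_vx = 16L,
                         profile_fractions = c("porosity", "ice_in_solid",
                                               "ice_inside_in_solid"),
                         ssa_interfaces = list(c("air", "ice_outside"),
                                               c("ice_inside", "starch")),
                         thickness_phases = c("ice_inside", "ice_outside"),
                         curvature_phase = "ice",
                         curvature_sigma_vx = 2,
                         out_dir = NULL) {
  if (!is.list(conditions) || !length(conditions))
    abort("conditions must be a non-empty named list of volume lists",
          class = "icemorph_validation_error")
  if (is.null(names(conditions)) || anyDuplicated(names(conditions)) ||
      any(names(conditions) == ""))
    abort("condition labels must be unique and non-empty",
          class = "icemorph_validation_error")
  if (any(!vapply(conditions, length, integer(1))))
    abort("every condition needs at least one volume",
          class = "icemorph_validation_error")

  fr_rows <- list(); ssa_rows <- list(); prof_rows <- list()
  th_rows <- list(); cv_rows <- list(); failed <- list()
  for (cond in names(conditions)) {
    vols <- conditions[[cond]]
    for (i in seq_along(vols)) {
      vid <- names(vols)[i] %||% ""
      if (vid == "") vid <- paste0(cond, "_", i)
      res <- tryCatch(
        analyse_volume(vols[[i]], thresholds, closing_radius, slab_vx,
                       profile_fractions, ssa_interfaces, thickness_phases,
                       curvature_phase, curvature_sigma_vx),
        error = function(e) {
          warn(sprintf("volume '%s' failed: %s", vid, conditionMessage(e)))
          NULL
        })
      if (is.null(res)) {
        failed[[length(failed) + 1L]] <- tibble(condition = cond, volume = vid)
        next
      }
      fr_rows[[length(fr_rows) + 1L]] <-
        mutate(res$fractions, condition = cond, volume = vid, .before = 1)
      ssa_rows[[length(ssa_rows) + 1L]] <-
        mutate(res$ssa, condition = cond, volume = vid, .before = 1)
      prof_rows[[length(prof_rows) + 1L]] <-
        mutate(res$profiles, condition = cond, volume = vid, .before = 1)
      if (!is.null(res$thickness))
        th_rows[[length(th_rows) + 1L]] <-
          mutate(res$thickness, condition = cond, volume = vid, .before = 1)
      if (!is.null(res$curvature))
        cv_rows[[length(cv_rows) + 1L]] <-
          mutate(res$curvature, condition = cond, volume = vid, .before = 1)
    }
  }
  fractions <- bind_rows(fr_rows)
  if (!nrow(fractions))
    abort("all volumes failed", class = "icemorph_error")
  phicols <- grep("^phi_", names(fractions), value = TRUE)
  summary <- fractions |>
    group_by(.data$condition) |>
    summarise(n = n(),
              across(dplyr::all_of(phicols),
                     list(mean = ~mean(.x),
                          sd = ~if (n() > 1L) sd(.x) else NA_real_)),
              .groups = "drop")
  ssa <- bind_rows(ssa_rows)
  ssa_summary <- ssa |>
    group_by(.data$condition, .data$interface) |>
    summarise(n = n(), ssa_mm_mean = mean(.data$ssa_mm),
              ssa_mm_sd = if (n() > 1L) sd(.data$ssa_mm) else NA_real_,
              .groups = "drop")
  report <- structure(list(fractions = fractions, summary = summary,
                           ssa = ssa, ssa_summary = ssa_summary,
                           profiles = bind_rows(prof_rows),
                           thickness = if (length(th_rows)) bind_rows(th_rows) else NULL,
                           curvature = if (length(cv_rows)) bind_rows(cv_rows) else NULL,
                           failed = if (length(failed)) bind_rows(failed) else NULL),
                      class = "condition_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

analyse_volume <- function(vol, thresholds, closing_radius, slab_vx,
                           profile_fractions, ssa_interfaces,
                           thickness_phases, curvature_phase,
                           curvature_sigma_vx) {
  if (inherits(vol, "phantom_volume")) vol <- vol$grey
  labels <- if (inherits(vol, "label_volume")) vol
            else segment(vol, thresholds, closing_radius)$labels
  fractions <- volume_fractions(labels)
  ssa <- bind_rows(lapply(ssa_interfaces, function(p)
    specific_surface_area(labels, p[[1]], p[[2]])))
  profiles <- bind_rows(lapply(profile_fractions, function(f) {
    pr <- vertical_profile(labels, f, slab_vx)
    mutate(as_tibble(pr), fraction = f, .before = 1)
  }))
  thickness <- NULL
  if (length(thickness_phases)) {
    th <- list()
    for (ph in thickness_phases) {
      m <- array(labels$data %in% resolve_phase(ph), dim(labels$data))
      if (!any(m)) next
      d <- thickness_distribution(local_thickness(m, labels$voxel_size))
      th[[length(th) + 1L]] <- mutate(as_tibble(d), phase = ph, .before = 1)
    }
    if (length(th)) thickness <- bind_rows(th)
  }
  curvature <- NULL
  if (!is.null(curvature_phase)) {
    m <- array(labels$data %in% resolve_phase(curvature_phase),
               dim(labels$data))
    if (any(m) && !all(m)) {
      cf <- mean_curvature_field(m, labels$voxel_size, curvature_sigma_vx)
      curvature <- as_tibble(curvature_distribution(cf))
    }
  }
  list(fractions = fractions, ssa = ssa, profiles = profiles,
       thickness = thickness, curvature = curvature)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) if (!is.null(x))
    write.csv(x, file.path(out_dir, f), row.names = FALSE)
  wr(report$fractions, "fractions.csv")
  wr(report$summary, "summary.csv")
  wr(report$ssa, "ssa.csv")
  for (f in unique(report$profiles$fraction))
    wr(filter(report$profiles, .data$fraction == f),
       paste0("profiles_", f, ".csv"))
  if (!is.null(report$thickness))
    for (p in unique(report$thickness$phase))
      wr(filter(report$thickness, .data$phase == p),
         paste0("thickness_", p, ".csv"))
  wr(report$curvature, "curvature.csv")
  jsonlite::write_json(list(summary = report$summary,
                            ssa = report$ssa_summary),
                       file.path(out_dir, "summary.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.condition_report <- function(x, ...) {
  cat("<condition_report>\n")
  print(x$summary)
  print(x$ssa_summary)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `condition_report`.
#' @param ... Unused.
#' @export
tidy.condition_report <- function(x, ...) x$fractions

#' @rdname run_pipeline
#' @export
glance.condition_report <- function(x, ...) x$summary

#' Headline percentage ratio between two phase fractions
#'
#' `100 * numerator / denominator`, rounded to the nearest integer
#' percent for headline reporting (e.g. the share of total ice that
#' formed inside the matrix). The default method takes two numbers (such
#' as condition-mean fractions from a published table); the
#' `condition_report` method takes two phase names and uses the
#' condition-mean solid-basis fractions.
#'
#' @param x A numeric numerator, or a `condition_report`.
#' @param ... Method arguments.
#' @return Integer percent (`NA` for a zero denominator).
#' @export
#' @examples
#' derived_ratio(43, 62)  # 69
derived_ratio <- function(x, ...) UseMethod("derived_ratio")

#' @rdname derived_ratio
#' @param denominator Denominator value.
#' @export
derived_ratio.default <- function(x, denominator, ...) {
  if (length(denominator) != 1L || denominator == 0) return(NA_integer_)
  as.integer(round(100 * x / denominator))
}

#' @rdname derived_ratio
#' @param numerator_phase,denominator_phase Phase names: `"ice"`,
#'   `"ice_inside"`, `"ice_outside"` or `"starch"` (solid-basis fractions).
#' @param condition Condition label to extract.
#' @export
derived_ratio.condition_report <- function(x, numerator_phase,
                                           denominator_phase, condition, ...) {
  col <- function(ph) switch(ph,
    ice = "phi_ice_in_solid_mean",
    ice_inside = "phi_ice_inside_in_solid_mean",
    ice_outside = "phi_ice_outside_in_solid_mean",
    starch = "phi_starch_in_solid_mean",
    abort(paste("no solid-basis fraction for phase", ph),
          class = "icemorph_error"))
  row <- filter(x$summary, .data$condition == !!condition)
  if (!nrow(row)) abort("unknown condition", class = "icemorph_error")
  derived_ratio(row[[col(numerator_phase)]], row[[col(denominator_phase)]])
}
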