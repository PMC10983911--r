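# Multiverse orchestration: the analytic decision grid, specification-curve
# tables and percentile selection.
#
# The package never executes first-level GLMs; it enumerates the decision
# grid and consumes per-permutation summary estimates or map sets (real or
# synthetic) keyed by permutation id.

#' Define an analytic decision grid
#'
#' Four decision categories drive the multiverse: smoothing kernel FWHM (mm),
#' motion-correction strategy, task-model parameterization and task contrast.
#' Each option list must be nonempty with unique entries.
#'
#' @param fwhm Numeric vector of smoothing kernels in mm.
#' @param motion Character vector of motion-correction labels.
#' @param model Character vector of model-parameterization labels.
#' @param contrast Character vector of contrast labels.
#' @return An object of class `decision_grid`.
#' @export
decision_grid <- function(fwhm, motion, model, contrast) {
  opts <- list(fwhm = fwhm, motion = motion, model = model,
               contrast = contrast)
  for (nm in names(opts)) {
    if (length(opts[[nm]]) == 0) abort(sprintf("empty option list: %s", nm))
    if (anyDuplicated(opts[[nm]])) {
      abort(sprintf("duplicate entries in option list: %s", nm))
    }
  }
  structure(opts, class = "decision_grid")
}

#' @export
print.decision_grid <- function(x, ...) {
  cat(sprintf(
    "<decision_grid> %d fwhm x %d motion x %d model x %d contrast = %d permutations\n",
    length(x$fwhm), length(x$motion), length(x$model), length(x$contrast),
    prod(lengths(x))
  ))
  invisible(x)
}

#' The default realized decision grid
#'
#' Five smoothing kernels (1.5x-3.5x a 2.4 mm voxel), four motion options,
#' three task-model parameterizations and four contrasts: 240 permutations.
#' Passing `motion_options = 6` adds the two high-motion-exclusion options
#' of the full proposed grid (360 permutations).
#'
#' @param voxel_mm Acquisition voxel size in mm (default 2.4).
#' @param weight Multiplier applied to all kernels (default 1).
#' @param motion_options 4 (realized) or 6 (proposed).
#' @return A [decision_grid()].
#' @export
default_decision_grid <- function(voxel_mm = 2.4, weight = 1,
                                  motion_options = 4) {
  if (!motion_options %in% c(4, 6)) abort("motion_options must be 4 or 6")
  motion <- sprintf("opt%d", seq_len(motion_options))
  decision_grid(
    fwhm = build_smoothing_grid(voxel_mm, weight = weight),
    motion = motion,
    model = c("CueMod", "FixMod", "AntMod"),
    contrast = c("LgainNeut", "LgainBase", "SgainNeut", "SgainBase")
  )
}

#' Enumerate all permutations of a decision grid
#'
#' Cartesian product in deterministic order — `fwhm` varies slowest
#' (outermost), `contrast` fastest (innermost) — with ids `1..R`.
#'
#' @param grid A [decision_grid()].
#' @return Tibble with columns `id`, `fwhm`, `motion`, `model`, `contrast`.
#' @export
enumerate_permutations <- function(grid) {
  stopifnot(inherits(grid, "decision_grid"))
  out <- tidyr::expand_grid(
    fwhm = grid$fwhm, motion = grid$motion,
    model = grid$model, contrast = grid$contrast
  )
  dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
}

#' Build a smoothing-kernel grid from voxel size
#'
#' Kernels are `multiplier * voxel_mm * weight`, rounded to one decimal (mm).
#' The default multipliers 1.5-3.5 in steps of 0.5 give five kernels; a
#' weight below 1 compensates for acquisitions whose larger voxels carry more
#' inherent smoothness.
#'
#' @param voxel_mm Positive voxel size in mm.
#' @param multipliers Positive numeric vector of voxel-size multiples.
#' @param weight Positive scalar weight.
#' @return Numeric vector of kernel FWHMs in mm.
#' @examples
#' build_smoothing_grid(2.4)             # 3.6 4.8 6.0 7.2 8.4
#' build_smoothing_grid(4, weight = 0.5) # 3.0 4.0 5.0 6.0 7.0
#' @export
build_smoothing_grid <- function(voxel_mm, multipliers = seq(1.5, 3.5, by = 0.5),
                                 weight = 1) {
  if (voxel_mm <= 0 || weight <= 0 || any(multipliers <= 0)) {
    abort("voxel_mm, multipliers and weight must be positive")
  }
  round(multipliers * voxel_mm * weight, 1)
}

#' Collect per-permutation estimates into a specification-curve table
#'
#' Input is a long tibble of summary estimates, one row per (permutation,
#' sample). Per permutation the point estimate is the mean across samples
#' and the interval is `mean +/- 1.96 SE` of the across-sample dispersion
#' (`NA` with a single sample). Rows are ranked ascending by point estimate
#' (ties broken by permutation id) and annotated with `percentile =
#' rank / R`.
#'
#' @param estimates Tibble with columns `id`, `sample`, `estimate`.
#' @param grid Optional [decision_grid()]; when given, every enumerated
#'   permutation must appear in `estimates` (missing ids are an error, never
#'   silently dropped) and the decision columns are joined onto the output.
#' @return A `spec_curve_table` tibble: `id`, decision columns (if `grid`),
#'   `n_samples`, `estimate`, `ci_lower`, `ci_upper`, `rank`, `percentile`.
#' @export
collect_estimates <- function(estimates, grid = NULL) {
  estimates <- tibble::as_tibble(estimates)
  need <- c("id", "sample", "estimate")
  if (!all(need %in% names(estimates))) {
    abort("estimates needs columns id, sample, estimate")
  }
  agg <- estimates |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      ci_half = 1.96 * sd(.data$estimate) / sqrt(dplyr::n()),
      estimate = mean(.data$estimate),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_lower = .data$estimate - .data$ci_half,
      ci_upper = .data$estimate + .data$ci_half,
      ci_half = NULL
    )
  if (!is.null(grid)) {
    perms <- enumerate_permutations(grid)
    missing <- setdiff(perms$id, agg$id)
    if (length(missing) > 0) {
      abort(sprintf("missing estimates for %d permutation(s): %s",
                    length(missing),
                    paste(utils::head(missing, 10), collapse = ", ")))
    }
    agg <- dplyr::left_join(perms, agg, by = "id")
  }
  out <- agg |>
    dplyr::arrange(.data$estimate, .data$id) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  percentile = .data$rank / dplyr::n()) |>
    dplyr::arrange(.data$id)
  class(out) <- c("spec_curve_table", class(out))
  out
}

#' Select the permutation at a given percentile of the spec curve
#'
#' Nearest-rank selection: the row with rank `ceiling(p * R)` (at least 1).
#'
#' @param spec_table A [collect_estimates()] result.
#' @param p Percentile in (0, 1], e.g. 0.25 or 0.75.
#' @return The selected one-row tibble.
#' @export
percentile_select <- function(spec_table, p) {
  stopifnot(p > 0, p <= 1)
  r <- max(1L, as.integer(ceiling(p * nrow(spec_table))))
  spec_table[spec_table$rank == r, ]
}

#' Supra/subthreshold medians per permutation
#'
#' Applies [median_within_mask()] to each permutation's map under both
#' partitions of the analysis mask.
#'
#' @param maps Named list of [labeled_volume()]s keyed by permutation id.
#' @param supra,sub [brain_mask()]s (e.g. from [partition_by_reference()]).
#' @return Tibble with columns `id`, `median_supra`, `median_sub`.
#' @export
permutation_medians <- function(maps, supra, sub) {
  ids <- names(maps)
  if (is.null(ids)) ids <- as.character(seq_along(maps))
  purrr::map_dfr(seq_along(maps), function(i) {
    tibble::tibble(
      id = ids[[i]],
      median_supra = median_within_mask(maps[[i]], supra),
      median_sub = median_within_mask(maps[[i]], sub)
    )
  })
}

#' Read a decision grid from a YAML config
#'
#' Recognised keys: either `fwhm_options` directly, or `voxel_mm` +
#' optional `multipliers` + optional `weight` (fed to
#' [build_smoothing_grid()]); plus `motion_options`, `model_options`,
#' `contrast_options`. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A [decision_grid()].
#' @export
read_decision_grid <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("fwhm_options", "voxel_mm", "multipliers", "weight",
             "motion_options", "model_options", "contrast_options")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  fwhm <- if (!is.null(cfg$fwhm_options)) {
    as.numeric(cfg$fwhm_options)
  } else if (!is.null(cfg$voxel_mm)) {
    build_smoothing_grid(
      cfg$voxel_mm,
      multipliers = if (is.null(cfg$multipliers)) seq(1.5, 3.5, by = 0.5)
                    else as.numeric(cfg$multipliers),
      weight = if (is.null(cfg$weight)) 1 else cfg$weight
    )
  } else {
    abort("config needs fwhm_options or voxel_mm")
  }
  decision_grid(fwhm, cfg$motion_options, cfg$model_options,
                cfg$contrast_options)
}
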