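# Bootstrap stability of the median ICC and its variance components as a
# function of sample size.

#' Bootstrap sample-size stability of voxelwise reliability summaries
#'
#' For each `n` in `n_grid` and each iteration, draws `n` subjects (with
#' replacement by default), recomputes the voxelwise ICC on the subsample and
#' records the in-mask medians of the ICC, MSBS and MSWS maps. Per-`n`
#' summaries report the mean and a 95% percentile interval (2.5/97.5 across
#' iterations). A master seed spawns one substream per (n, iteration) draw,
#' so results are fully reproducible and order-independent.
#'
#' @param stack A [measurement_stack()].
#' @param mask A [brain_mask()] on the stack's grid.
#' @param n_grid Strictly increasing integer vector of subsample sizes;
#'   default 25 to 525 in steps of 50.
#' @param iterations Bootstrap iterations per `n` (default 100).
#' @param icc_type,alpha As in [voxelwise_icc()].
#' @param seed Integer master seed.
#' @param replace Draw with replacement (default `TRUE`). `FALSE` requires
#'   `n <=` available subjects and makes `n = n_subjects` reproduce the
#'   full-sample analysis exactly.
#' @return An object of class `stability_curve`: `draws` (tibble `n`,
#'   `iteration`, `median_icc`, `median_msbs`, `median_msws`), `summary`
#'   (tibble `n`, `metric`, `mean`, `ci_lower`, `ci_upper`), `full`
#'   (full-sample medians), `seed`, `n_subjects`.
#' @export
bootstrap_stability <- function(stack, mask, n_grid = seq(25, 525, by = 50),
                                iterations = 100,
                                icc_type = c("icc_3", "icc_2", "icc_1"),
                                alpha = 0.05, seed = 1, replace = TRUE) {
  icc_type <- match.arg(icc_type)
  if (length(n_grid) == 0) abort("empty n_grid")
  if (is.unsorted(n_grid, strictly = TRUE)) {
    abort("n_grid must be strictly increasing")
  }
  if (iterations < 1) abort("iterations must be >= 1")
  if (!replace && max(n_grid) > stack$n) {
    abort("without replacement, max(n_grid) must not exceed available subjects")
  }
  flat <- stack_to_matrix(stack, mask)
  n_avail <- stack$n

  # one substream seed per (n, iteration), derived from the master seed
  set.seed(seed)
  sub_seeds <- matrix(
    sample.int(.Machine$integer.max, length(n_grid) * iterations),
    nrow = length(n_grid)
  )

  masked_medians <- function(idx) {
    mats <- lapply(flat$matrices, function(m) m[idx, , drop = FALSE])
    res <- icc_matrix_stack(mats, icc_type, alpha)
    med <- function(v) {
      v <- v[is.finite(v)]
      if (length(v) == 0) NaN else median(v)
    }
    c(med(res$estimate), med(res$msbs), med(res$msws))
  }

  draws <- purrr::map_dfr(seq_along(n_grid), function(gi) {
    n <- n_grid[gi]
    purrr::map_dfr(seq_len(iterations), function(it) {
      set.seed(sub_seeds[gi, it])
      idx <- sample.int(n_avail, n, replace = replace)
      m <- masked_medians(idx)
      tibble::tibble(n = n, iteration = it, median_icc = m[1],
                     median_msbs = m[2], median_msws = m[3])
    })
  })

  summary <- draws |>
    tidyr::pivot_longer(dplyr::starts_with("median_"),
                        names_to = "metric", names_prefix = "median_",
                        values_to = "value") |>
    dplyr::group_by(.data$n, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      ci_lower = quantile(.data$value, 0.025, names = FALSE),
      ci_upper = quantile(.data$value, 0.975, names = FALSE),
      .groups = "drop"
    )

  full <- masked_medians(seq_len(n_avail))
  structure(
    list(
      draws = draws, summary = summary,
      full = c(median_icc = full[1], median_msbs = full[2],
               median_msws = full[3]),
      seed = seed, n_subjects = n_avail, icc_type = icc_type,
      iterations = iterations
    ),
    class = "stability_curve"
  )
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf(
    "<stability_curve> %s, %d n-levels x %d iterations (seed %d)\n  full-sample median ICC = %.4f\n",
    x$icc_type, length(unique(x$draws$n)), x$iterations, x$seed,
    x$full["median_icc"]
  ))
  invisible(x)
}

#' @rdname bootstrap_stability
#' @param x A `stability_curve` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-draw tibble; `glance()` the per-n
#'   summary in wide form with CI widths.
#' @export
tidy.stability_curve <- function(x, ...) x$draws

#' @rdname bootstrap_stability
#' @export
glance.stability_curve <- function(x, ...) {
  x$summary |>
    dplyr::mutate(ci_width = .data$ci_upper - .data$ci_lower)
}

#' Write a stability curve to TSV files
#'
#' @param curve A [bootstrap_stability()] result.
#' @param prefix Output path prefix; writes `<prefix>_draws.tsv` and
#'   `<prefix>_summary.tsv`.
#' @return Paths, invisibly.
#' @export
write_stability_curve <- function(curve, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  p1 <- paste0(prefix, "_draws.tsv")
  p2 <- paste0(prefix, "_summary.tsv")
  readr::write_tsv(curve$draws, p1)
  readr::write_tsv(curve$summary, p2)
  invisible(c(draws = p1, summary = p2))
}
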