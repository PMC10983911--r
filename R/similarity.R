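# Similarity between statistical maps: Jaccard/Dice on thresholded binary
# maps, Spearman rank correlation on continuous maps, and the t -> Cohen's d
# conversion used to put group maps from different sample sizes on one
# effect-size scale.

SIM_METRICS <- c("jaccard", "dice", "spearman")

#' Threshold and binarize a map within a mask
#'
#' A voxel enters the output mask iff it lies in `mask` and its value is
#' strictly greater than `threshold`. The result may be empty (no voxel
#' passes); downstream similarity on two empty masks is `NaN`.
#'
#' @param map A [labeled_volume()].
#' @param mask A [brain_mask()] on the same grid.
#' @param threshold Numeric cut (e.g. `z = 3.1` or Cohen's d = 0.4).
#' @return A `brain_mask` (possibly empty).
#' @export
binarize_map <- function(map, mask, threshold) {
  check_grids(map, mask, "map and mask")
  new_mask((map$data > threshold) & (mask$data != 0), mask$affine,
           paste0(map$label, "_bin"))
}

#' Jaccard similarity of two binary masks
#'
#' `|A intersect B| / |A union B|`; two empty masks give `NaN`.
#'
#' @param a,b [brain_mask()]s on one grid.
#' @return Numeric scalar in `[0, 1]` (or `NaN`).
#' @export
jaccard_coefficient <- function(a, b) {
  check_grids(a, b, "masks")
  inter <- sum(a$data != 0 & b$data != 0)
  union <- sum(a$data != 0 | b$data != 0)
  if (union == 0) return(NaN)
  inter / union
}

#' Dice similarity of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks give `NaN`.
#'
#' @inheritParams jaccard_coefficient
#' @return Numeric scalar in `[0, 1]` (or `NaN`).
#' @export
dice_coefficient <- function(a, b) {
  check_grids(a, b, "masks")
  na <- sum(a$data != 0)
  nb <- sum(b$data != 0)
  if (na + nb == 0) return(NaN)
  2 * sum(a$data != 0 & b$data != 0) / (na + nb)
}

#' Spearman rank correlation between two maps within a mask
#'
#' Rank correlation over in-mask voxels with average ranks for ties
#' (equivalent to the product-moment correlation of ranks; reduces to the
#' classical `1 - 6 sum(d^2) / (n (n^2 - 1))` form when no ties occur).
#'
#' @param a,b [labeled_volume()]s on one grid.
#' @param mask A [brain_mask()] with at least 3 voxels.
#' @return Numeric scalar in `[-1, 1]`; `NaN` when either map has zero rank
#'   variance within the mask.
#' @export
spearman_similarity <- function(a, b, mask) {
  check_grids(a, b, "maps")
  check_grids(a, mask, "map and mask")
  sel <- mask$data != 0
  if (sum(sel) < 3) abort("need at least 3 masked voxels")
  x <- a$data[sel]
  y <- b$data[sel]
  if (var(rank(x)) == 0 || var(rank(y)) == 0) return(NaN)
  stats::cor(x, y, method = "spearman")
}

#' Similarity between two maps
#'
#' Dispatches on `metric`: `"jaccard"`/`"dice"` binarize both maps at
#' `threshold` inside `mask` first; `"spearman"` correlates the continuous
#' in-mask values (no thresholding).
#'
#' @param a,b [labeled_volume()]s on one grid.
#' @param mask A [brain_mask()]; defaults to all voxels.
#' @param threshold Binarization threshold for jaccard/dice (default 0);
#'   ignored for spearman.
#' @param metric One of `"jaccard"`, `"dice"`, `"spearman"`.
#' @return One-row tibble: `image_a`, `image_b`, `metric`, `threshold`,
#'   `coefficient`.
#' @export
image_similarity <- function(a, b, mask = NULL, threshold = 0,
                             metric = c("jaccard", "dice", "spearman")) {
  metric <- match.arg(metric)
  if (is.null(mask)) {
    mask <- new_mask(array(1, dim(a$data)), a$affine, "full")
  }
  coef <- switch(metric,
    jaccard = jaccard_coefficient(binarize_map(a, mask, threshold),
                                  binarize_map(b, mask, threshold)),
    dice = dice_coefficient(binarize_map(a, mask, threshold),
                            binarize_map(b, mask, threshold)),
    spearman = spearman_similarity(a, b, mask)
  )
  tibble::tibble(
    image_a = a$label, image_b = b$label, metric = metric,
    threshold = if (metric == "spearman") NA_real_ else threshold,
    coefficient = coef
  )
}

#' Pairwise similarity over a set of maps
#'
#' One row per unordered pair (`i < j` in input order), `choose(m, 2)` rows
#' for `m` images.
#'
#' @param images List of two or more [labeled_volume()]s on one grid.
#' @inheritParams image_similarity
#' @return Tibble of [image_similarity()] rows.
#' @export
pairwise_similarity <- function(images, mask = NULL, threshold = 0,
                                metric = c("jaccard", "dice", "spearman")) {
  metric <- match.arg(metric)
  if (length(images) < 2) abort("need at least 2 images")
  pairs <- combn(length(images), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    image_similarity(images[[i]], images[[j]], mask, threshold, metric)
  })
}

#' Convert a t-statistic map to Cohen's d
#'
#' `d = t / sqrt(N)` per voxel: a monotone, sign-preserving rescaling that
#' makes thresholds comparable across group maps computed at different
#' sample sizes.
#'
#' @param tmap A [labeled_volume()] of t-statistics.
#' @param n Positive integer group size underlying the t-map.
#' @return A [labeled_volume()] of Cohen's d values with attribute
#'   `source_n`.
#' @examples
#' vol <- labeled_volume(array(3.2, c(2, 2, 2)))
#' t_to_cohens_d(vol, 64)$data[1]  # 0.4
#' @export
t_to_cohens_d <- function(tmap, n) {
  if (length(n) != 1 || n < 1 || n %% 1 != 0) {
    abort("n must be a positive integer")
  }
  out <- labeled_volume(tmap$data / sqrt(n), tmap$affine,
                        paste0(tmap$label, "_d"))
  attr(out, "source_n") <- as.integer(n)
  out
}
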