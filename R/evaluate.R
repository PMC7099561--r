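# Segmentation metrics, the threshold sweep and per-B/C-group reporting.

#' Pixelwise confusion counts between a predicted and reference mask
#'
#' @param pred,gt Binary 0/1 masks of identical size (foreground = sFAZ).
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`
#'   (`tp + fp + tn + fn = H * W`).
#' @export
#' @examples
#' confusion_counts(matrix(c(1L, 0L), 1), matrix(c(1L, 1L), 1))
confusion_counts <- function(pred, gt) {
  assert_mask(pred, "pred"); assert_mask(gt, "gt")
  assert_same_dim(pred, gt, "pred and gt")
  tibble::tibble(
    tp = sum(pred == 1L & gt == 1L),
    fp = sum(pred == 1L & gt == 0L),
    tn = sum(pred == 0L & gt == 0L),
    fn = sum(pred == 0L & gt == 1L)
  )
}

# Degenerate-denominator convention shared by the three metrics: when a
# denominator is zero the masks carry no information about that class;
# return 1 when they agree on it (e.g. both empty), else 0, and flag it.
degenerate <- function(agree) structure(as.numeric(agree), degenerate = TRUE)

#' Dice similarity coefficient from confusion counts
#'
#' `DSC = 2*TP / (FP + 2*TP + FN)`. When both masks are empty the
#' denominator vanishes and 1 is returned (flagged with attribute
#' `degenerate`).
#'
#' @param c A [confusion_counts()] row (or any list with `tp`, `fp`, `tn`,
#'   `fn`).
#' @return DSC in \[0, 1\].
#' @export
dsc <- function(c) {
  den <- c$fp + 2 * c$tp + c$fn
  if (den == 0) return(degenerate(TRUE))
  2 * c$tp / den
}

#' @rdname dsc
#' @details `sensitivity = TP / (TP + FN)`; with an empty reference mask the
#'   convention returns 1 iff the prediction is also empty.
#' @export
sensitivity <- function(c) {
  den <- c$tp + c$fn
  if (den == 0) return(degenerate(c$fp == 0))
  c$tp / den
}

#' @rdname dsc
#' @details `specificity = TN / (TN + FP)`; with no reference background the
#'   convention returns 1 iff the prediction has no background either.
#' @export
specificity <- function(c) {
  den <- c$tn + c$fp
  if (den == 0) return(degenerate(c$fn == 0))
  c$tn / den
}

#' Pearson correlation with p-value
#'
#' `R = cov(x, y) / (sd(x) * sd(y))`, with a two-sided p-value from the
#' usual t transform with `n - 2` degrees of freedom. Used to compare
#' predicted against reference sFAZ areas.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A one-row tibble with `r`, `p_value`, `n`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 observations.")
  if (var(x) == 0 || var(y) == 0) abort("Zero variance in `x` or `y`.")
  r <- stats::cov(x, y) / (sd(x) * sd(y))
  n <- length(x)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  tibble::tibble(r = r, p_value = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' Mean-DSC threshold sweep
#'
#' For every threshold on the grid, binarises (and by default
#' morphologically refines) each probability map, computes the per-image
#' DSC against its reference mask, and records the mean and SD. The
#' reported optimum is the smallest grid point attaining the maximal mean.
#'
#' @param probmaps List of probability matrices.
#' @param gts List of matching reference masks.
#' @param grid Increasing thresholds in \[0, 1\] (default 0 to 1 by 0.01,
#'   which contains the reference optimum 0.44 as a grid point).
#' @param refine_first If `TRUE` (default) apply
#'   largest-component/hole-fill refinement before scoring, matching the
#'   full pipeline; `FALSE` scores the raw binarisation.
#' @return A `faz_sweep` object: tibble `curve` (threshold, mean_dsc,
#'   sd_dsc) plus `argmax_threshold` and `max_mean_dsc`.
#' @export
threshold_sweep <- function(probmaps, gts, grid = seq(0, 1, by = 0.01),
                            refine_first = TRUE) {
  if (!length(probmaps) || length(probmaps) != length(gts)) {
    abort("`probmaps` and `gts` must be non-empty lists of equal length.")
  }
  if (is.unsorted(grid) || any(grid < 0 | grid > 1)) {
    abort("`grid` must be increasing and within [0, 1].")
  }
  stats <- vapply(grid, function(th) {
    d <- vapply(seq_along(probmaps), function(i) {
      m <- if (refine_first) refine(probmaps[[i]], th)
           else binarize(probmaps[[i]], th)
      as.numeric(dsc(confusion_counts(m, gts[[i]])))
    }, numeric(1))
    c(mean(d), sd(d))
  }, numeric(2))
  curve <- tibble::tibble(threshold = grid, mean_dsc = stats[1, ],
                          sd_dsc = stats[2, ])
  best <- grid[which.max(stats[1, ])]  # which.max: first (smallest) argmax
  structure(list(curve = curve, argmax_threshold = best,
                 max_mean_dsc = max(stats[1, ])),
            class = "faz_sweep")
}

#' @export
print.faz_sweep <- function(x, ...) {
  cat(sprintf("<faz_sweep> %d thresholds; max mean DSC %.4f at %.2f\n",
              nrow(x$curve), x$max_mean_dsc, x$argmax_threshold))
  invisible(x)
}

#' @rdname threshold_sweep
#' @param x,object A `faz_sweep`.
#' @param ... Unused.
#' @export
tidy.faz_sweep <- function(x, ...) x$curve

#' @rdname threshold_sweep
#' @export
autoplot.faz_sweep <- function(object, ...) {
  cv <- object$curve
  ggplot2::ggplot(cv, ggplot2::aes(.data$threshold, .data$mean_dsc)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_dsc - .data$sd_dsc,
                   ymax = .data$mean_dsc + .data$sd_dsc),
      fill = "grey80") +
    ggplot2::geom_line(colour = "red") +
    ggplot2::geom_vline(xintercept = object$argmax_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "binarisation threshold", y = "mean DSC")
}

#' Per-image metrics for a set of predictions
#'
#' Refines each probability map at `threshold`, scores it against its
#' reference mask and computes both areas, yielding one metrics row per
#' image.
#'
#' @param probmaps List of probability matrices.
#' @param gts List of reference masks.
#' @param meta Data frame with one row per image; columns `subject_id` and
#'   `group_id` are carried through.
#' @param threshold Binarisation threshold (default 0.44, the reference
#'   optimum).
#' @param scan_mm Physical scan width in mm.
#' @return Tibble with `subject_id`, `group_id`, `dsc`, `sensitivity`,
#'   `specificity`, `area_pred`, `area_gt`.
#' @export
evaluate_images <- function(probmaps, gts, meta, threshold = 0.44,
                            scan_mm = 3) {
  stopifnot(length(probmaps) == length(gts),
            nrow(meta) == length(probmaps))
  rows <- lapply(seq_along(probmaps), function(i) {
    m <- refine(probmaps[[i]], threshold)
    cc <- confusion_counts(m, gts[[i]])
    tibble::tibble(
      subject_id = meta$subject_id[i],
      group_id = meta$group_id[i],
      dsc = as.numeric(dsc(cc)),
      sensitivity = as.numeric(sensitivity(cc)),
      specificity = as.numeric(specificity(cc)),
      area_pred = compute_area(m, scan_mm)$area_mm2,
      area_gt = compute_area(gts[[i]], scan_mm)$area_mm2
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-B/C-group performance report
#'
#' Summarises per-image metrics rows into the per-group table (mean and SD
#' of DSC, sensitivity, specificity, and the Pearson R between predicted
#' and reference areas with its p-value), plus a pooled all-groups row.
#' Groups with fewer than 3 rows report `NA` for R rather than erroring.
#'
#' @param rows Tibble from [evaluate_images()].
#' @return Tibble with one row per group plus a pooled `"all"` row.
#' @export
group_report <- function(rows) {
  if (!all(rows$group_id %in% 1:9)) {
    abort("Every row must have `group_id` in 1-9.")
  }
  summarise_rows <- function(d, label) {
    rp <- if (nrow(d) >= 3 && var(d$area_pred) > 0 && var(d$area_gt) > 0) {
      pearson_r(d$area_pred, d$area_gt)
    } else {
      tibble::tibble(r = NA_real_, p_value = NA_real_, n = nrow(d))
    }
    tibble::tibble(
      group = label, n = nrow(d),
      dsc_mean = mean(d$dsc), dsc_sd = sd(d$dsc),
      sensitivity_mean = mean(d$sensitivity),
      sensitivity_sd = sd(d$sensitivity),
      specificity_mean = mean(d$specificity),
      specificity_sd = sd(d$specificity),
      area_r = rp$r, area_r_p = rp$p_value
    )
  }
  per_group <- rows |>
    dplyr::group_by(.data$group_id) |>
    dplyr::group_map(~ summarise_rows(.x, paste0("G", .y$group_id))) |>
    dplyr::bind_rows()
  dplyr::bind_rows(per_group, summarise_rows(rows, "all"))
}
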