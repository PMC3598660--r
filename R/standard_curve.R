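#' Amplification efficiency from a standard-curve slope
#'
#' For a calibration curve of Cq against log10 template amount with slope
#' `m` (cycles per 10-fold dilution, negative for a working assay), the
#' per-cycle amplification factor is `10^(-1/m)` and the efficiency in
#' percent is
#' \deqn{E = (10^{-1/\mathrm{slope}} - 1) \times 100.}
#' A slope of \eqn{-1/\log_{10} 2 \approx -3.3219} corresponds to perfect
#' doubling (E = 100\%). The value is returned unclamped; summaries
#' conventionally report it to one decimal.
#'
#' @param slope Standard-curve slope, strictly negative and finite.
#' @return Efficiency in percent. Strictly decreasing in `|slope|`.
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.numeric(slope) || length(slope) != 1 || !is.finite(slope)) {
    stop("slope must be a single finite number", call. = FALSE)
  }
  if (slope >= 0) {
    stop("efficiency is undefined for non-negative slope (got ", slope, ")",
         call. = FALSE)
  }
  (10^(-1 / slope) - 1) * 100
}

dilution_points_for_fit <- function(points) {
  stopifnot(is.data.frame(points))
  if (length(unique(points$gene)) > 1) {
    stop("fit_standard_curve expects points for a single gene", call. = FALSE)
  }
  mean_cq <- vapply(points$cq_replicates, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  tibble::tibble(gene = points$gene, amount = points$amount,
                 mean_cq = mean_cq)
}

#' Fit a per-gene standard curve
#'
#' Replicate Cq values are averaged per dilution amount (amounts whose
#' replicates are all missing are dropped), then ordinary least squares of
#' mean Cq on log10(amount) gives the slope and intercept; efficiency
#' follows via [efficiency_from_slope()]. Efficiencies outside the
#' conventional 90--110\% window are reported with a warning, never clamped:
#' a real assay can legitimately sit outside it.
#'
#' @param points A `dilution_series` (or compatible data frame) for one
#'   gene: columns `gene`, `amount`, list-column `cq_replicates`.
#' @return Object of class `standard_curve_fit`: list with `gene`, `slope`,
#'   `intercept`, `r_squared`, `efficiency_percent`, `range_used`
#'   (min/max amount actually fitted), `n_points`, and the per-amount `data`.
#' @export
fit_standard_curve <- function(points) {
  pts <- dilution_points_for_fit(points)
  usable <- pts[!is.na(pts$mean_cq), ]
  if (length(unique(usable$amount)) < 3) {
    stop("fit_standard_curve: need >= 3 distinct amounts with usable Cq (",
         length(unique(usable$amount)), " available)", call. = FALSE)
  }
  x <- log10(usable$amount)
  if (stats::sd(x) == 0) {
    stop("fit_standard_curve: zero variance in log10(amount)", call. = FALSE)
  }
  fit <- stats::lm(usable$mean_cq ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # r.squared from summary() is NaN when the response is constant; a flat
  # (saturated) series explains nothing, so report 0
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 0
  eff <- if (slope < 0) efficiency_from_slope(slope) else NA_real_
  if (is.na(eff)) {
    warning("non-negative slope (", signif(slope, 4),
            "): efficiency undefined", call. = FALSE)
  } else if (eff < 90 || eff > 110) {
    warning("efficiency ", round(eff, 1),
            "% outside the conventional 90-110% window", call. = FALSE)
  }
  structure(list(
    gene = unique(usable$gene),
    slope = slope,
    intercept = intercept,
    r_squared = r2,
    efficiency_percent = eff,
    range_used = c(min = min(usable$amount), max = max(usable$amount)),
    n_points = nrow(usable),
    data = usable
  ), class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<standard_curve_fit> %s: slope %.3f, intercept %.2f, E = %.1f%%, R2 = %.3f (%d points, %g-%g)\n",
    x$gene, x$slope, x$intercept, x$efficiency_percent, x$r_squared,
    x$n_points, x$range_used["min"], x$range_used["max"]))
  invisible(x)
}

#' Select the best linear sub-range of a dilution series
#'
#' Dilution series often fail at the extremes: the most dilute points drop
#' below the detection limit and the most concentrated ones saturate the
#' reaction. Amounts whose Cq is entirely missing are dropped, then every
#' contiguous sub-range (in amount order) with at least `min_points` usable
#' amounts is fitted and the sub-range with the highest R-squared wins. Ties
#' are resolved toward the wider range, then the range containing larger
#' amounts, to preserve dynamic range.
#'
#' @inheritParams fit_standard_curve
#' @param min_points Minimum number of usable amounts per candidate range.
#' @return List with `points` (the winning sub-series) and `fit` (its
#'   [fit_standard_curve()] result).
#' @export
select_linear_range <- function(points, min_points = 4) {
  pts <- dilution_points_for_fit(points)
  usable <- pts[!is.na(pts$mean_cq), ]
  usable <- usable[order(usable$amount), ]
  n <- nrow(usable)
  if (n < min_points) {
    stop("select_linear_range: only ", n, " usable amounts; need >= ",
         min_points, call. = FALSE)
  }
  best <- NULL
  for (i in seq_len(n - min_points + 1)) {
    for (j in seq(i + min_points - 1, n)) {
      sub <- usable[i:j, ]
      fit <- stats::lm(sub$mean_cq ~ log10(sub$amount))
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (!is.finite(r2)) r2 <- 0
      cand <- list(i = i, j = j, r2 = r2, width = j - i + 1,
                   top_amount = sub$amount[nrow(sub)])
      if (is.null(best) ||
          cand$r2 > best$r2 + 1e-12 ||
          (abs(cand$r2 - best$r2) <= 1e-12 &&
           (cand$width > best$width ||
            (cand$width == best$width &&
             cand$top_amount > best$top_amount)))) {
        best <- cand
      }
    }
  }
  keep_amounts <- usable$amount[best$i:best$j]
  sub_points <- points[points$amount %in% keep_amounts, , drop = FALSE]
  list(points = sub_points, fit = fit_standard_curve(sub_points))
}

#' Standard-curve table for several genes
#'
#' Convenience wrapper fitting one curve per gene of a dilution series,
#' optionally after [select_linear_range()] adaptation.
#'
#' @param series A `dilution_series` covering one or more genes.
#' @param adapt_range If `TRUE`, each gene's range is adapted with
#'   [select_linear_range()] before the final fit.
#' @param min_points Passed to [select_linear_range()].
#' @return Tibble with one row per gene: slope, intercept, efficiency
#'   (percent), R-squared and the dilution range used.
#' @export
standard_curve_table <- function(series, adapt_range = FALSE,
                                 min_points = 4) {
  stopifnot(is.data.frame(series))
  rows <- lapply(split(series, series$gene), function(pts) {
    fit <- if (adapt_range) select_linear_range(pts, min_points)$fit
           else fit_standard_curve(pts)
    tibble::tibble(gene = fit$gene, slope = fit$slope,
                   intercept = fit$intercept,
                   efficiency_percent = fit$efficiency_percent,
                   r_squared = fit$r_squared,
                   amount_min = fit$range_used["min"],
                   amount_max = fit$range_used["max"],
                   n_points = fit$n_points)
  })
  dplyr::bind_rows(rows)
}
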