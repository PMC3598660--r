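new_stability_result <- function(algorithm, values, ranks, details = NULL) {
  structure(list(algorithm = algorithm, values = values, ranks = ranks,
                 details = details),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  ord <- order(x$ranks)
  cat("<stability_result> ", x$algorithm, " (lower value = more stable)\n",
      sep = "")
  print(tibble::tibble(gene = names(x$values)[ord],
                       value = unname(x$values)[ord],
                       rank = unname(x$ranks)[ord]), n = Inf)
  invisible(x)
}

fractional_ranks <- function(values) {
  r <- rank(values, ties.method = "average")
  names(r) <- names(values)
  r
}

#' Convert mean Cq to log2 relative quantities
#'
#' Each gene's Cq row is anchored at its own minimum (the sample with the
#' most template), so quantities are relative within gene:
#' \deqn{logq[g,s] = (\min_u Cq[g,u] - Cq[g,s]) \cdot \log_2 E_g}
#' with `E_g` the gene's amplification factor (2 for a perfectly doubling
#' assay; `1 + efficiency_percent/100` when standard-curve efficiencies are
#' supplied). The anchor cancels in every downstream stability statistic;
#' it merely keeps values in a tame range (all `logq <= 0`, per-gene max 0).
#'
#' @param matrix A `cq_matrix` from [aggregate_replicates()].
#' @param efficiencies Optional named vector of per-gene amplification
#'   factors (> 1), e.g. `1 + efficiency_percent/100` from
#'   [standard_curve_table()]. Default: exactly 2 for every gene.
#' @return Object of class `logq_matrix`: genes x samples grid `logq` plus
#'   the per-gene factors and the sample group map.
#' @export
to_log_quantities <- function(matrix, efficiencies = NULL) {
  stopifnot(inherits(matrix, "cq_matrix"))
  cq <- matrix$mean_cq
  if (any(rowSums(!is.na(cq)) < 2)) {
    bad <- matrix$genes[rowSums(!is.na(cq)) < 2]
    stop("to_log_quantities: gene(s) with < 2 non-missing samples: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  eff <- rep(2, length(matrix$genes))
  names(eff) <- matrix$genes
  if (!is.null(efficiencies)) {
    eff[names(efficiencies)] <- efficiencies
  }
  if (any(!is.finite(eff)) || any(eff <= 1)) {
    stop("amplification factors must be finite and > 1", call. = FALSE)
  }
  row_min <- apply(cq, 1, min, na.rm = TRUE)
  logq <- (row_min - cq) * log2(eff)
  structure(list(genes = matrix$genes, samples = matrix$samples,
                 logq = logq, efficiency_factor = eff,
                 group_of = matrix$group_of),
            class = "logq_matrix")
}

# SD of the difference of two rows over pairwise-complete samples;
# also used on raw Cq rows by the comparative delta-Ct method
pair_sd <- function(a, b, min_overlap = 3) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_overlap) {
    stop("fewer than ", min_overlap, " pairwise-complete samples for a ",
         "gene pair", call. = FALSE)
  }
  stats::sd(a[ok] - b[ok])
}

pairwise_sd_matrix <- function(X, min_overlap = 3) {
  g <- nrow(X)
  V <- matrix(0, g, g, dimnames = list(rownames(X), rownames(X)))
  for (j in seq_len(g - 1)) {
    for (k in seq(j + 1, g)) {
      V[j, k] <- V[k, j] <- pair_sd(X[j, ], X[k, ], min_overlap)
    }
  }
  V
}

#' geNorm expression-stability ranking
#'
#' For genes j, k the pairwise variation `V_jk` is the standard deviation
#' over samples of the log2 expression ratio `logq[j, ] - logq[k, ]`; the
#' stability measure `M_j` is the mean of `V_jk` over all other genes. The
#' gene with the largest M (least stable) is removed and M is recomputed
#' among the survivors, down to the final pair, which the algorithm cannot
#' separate and which therefore shares rank 1.5. Each gene's reported value
#' is its M at the iteration of its removal (final pair: the final M).
#'
#' @param lq A [to_log_quantities()] result.
#' @param min_overlap Minimum pairwise-complete samples per gene pair.
#' @return A `stability_result` (algorithm `"genorm"`); `details` holds the
#'   removal order with the M value at each iteration.
#' @export
genorm <- function(lq, min_overlap = 3) {
  stopifnot(inherits(lq, "logq_matrix"))
  X <- lq$logq
  g <- nrow(X)
  if (g < 3) stop("genorm: need >= 3 genes", call. = FALSE)

  active <- rownames(X)
  values <- stats::setNames(rep(NA_real_, g), rownames(X))
  removal <- tibble::tibble(iteration = integer(), gene = character(),
                            m_value = numeric())
  iter <- 0L
  repeat {
    iter <- iter + 1L
    V <- pairwise_sd_matrix(X[active, , drop = FALSE], min_overlap)
    M <- rowSums(V) / (length(active) - 1)
    if (length(active) == 2) {
      values[active] <- M
      removal <- dplyr::bind_rows(removal, tibble::tibble(
        iteration = iter, gene = active, m_value = unname(M)))
      break
    }
    worst <- names(M)[which.max(M)]
    values[worst] <- M[worst]
    removal <- dplyr::bind_rows(removal, tibble::tibble(
      iteration = iter, gene = worst, m_value = unname(M[worst])))
    active <- setdiff(active, worst)
  }

  # ranks follow the removal order (first removed = least stable); the
  # surviving pair ties at 1.5; genes with identical values share the
  # average of their order-based ranks (degenerate all-equal input ties
  # everything)
  order_rank <- stats::setNames(rep(1.5, g), rownames(X))
  removed <- removal$gene[seq_len(g - 2)]
  order_rank[removed] <- seq(g, 3)
  ranks <- stats::ave(order_rank, values, FUN = mean)
  names(ranks) <- names(order_rank)
  new_stability_result("genorm", values, ranks, details = removal)
}

#' geNorm pairwise variation V(n/n+1)
#'
#' Companion statistic for choosing how many reference genes suffice: for
#' the top-n genes in geNorm order, the log2 normalization factor of sample
#' s is the mean logq over those genes (the log of their geometric mean);
#' `V_n` is the SD over samples of the difference between the n-gene and
#' (n+1)-gene factors. The conventional reading is that the smallest n with
#' `V_n` below 0.15 is enough.
#'
#' @inheritParams genorm
#' @param threshold Flagging threshold on V (conventional 0.15).
#' @return Tibble with columns `n` and `v` (length G-2); attribute
#'   `"recommended_n"` is the smallest n with `v < threshold` (NA if none).
#' @export
genorm_pairwise_variation <- function(lq, threshold = 0.15,
                                      min_overlap = 3) {
  stopifnot(inherits(lq, "logq_matrix"))
  res <- genorm(lq, min_overlap)
  ord <- names(sort(res$ranks))  # ties resolved by gene order, recorded
  X <- lq$logq[ord, , drop = FALSE]
  g <- nrow(X)
  v <- vapply(seq(2, g - 1), function(n) {
    nf_n <- colMeans(X[seq_len(n), , drop = FALSE])
    nf_n1 <- colMeans(X[seq_len(n + 1), , drop = FALSE])
    stats::sd(nf_n - nf_n1)
  }, numeric(1))
  out <- tibble::tibble(n = seq(2, g - 1), v = v)
  rec <- out$n[out$v < threshold]
  attr(out, "recommended_n") <- if (length(rec)) min(rec) else NA_integer_
  attr(out, "gene_order") <- ord
  out
}

#' Comparative delta-Ct stability ranking
#'
#' For every gene pair (j, k) the per-sample difference
#' `dCq_jk[s] = Cq[j,s] - Cq[k,s]` is formed; a gene's stability value is
#' the mean over partners of the SD of these differences. A gene whose
#' expression tracks every other gene (constant ratios) scores 0. Works
#' directly on Cq, so with a common amplification factor of 2 it coincides
#' exactly with the first-pass geNorm M.
#'
#' @param matrix A `cq_matrix`.
#' @inheritParams genorm
#' @return A `stability_result` (algorithm `"delta_ct"`).
#' @export
delta_ct_stability <- function(matrix, min_overlap = 3) {
  stopifnot(inherits(matrix, "cq_matrix"))
  cq <- matrix$mean_cq
  if (nrow(cq) < 3) stop("delta_ct_stability: need >= 3 genes",
                         call. = FALSE)
  V <- pairwise_sd_matrix(cq, min_overlap)
  values <- rowSums(V) / (nrow(cq) - 1)
  new_stability_result("delta_ct", values, fractional_ranks(values),
                       details = tibble::as_tibble(V, rownames = "gene"))
}

#' BestKeeper descriptive-statistics ranking
#'
#' Per gene: arithmetic and geometric mean, min, max of Cq; the dispersion
#' "SD (+/- Cq)" is by the original tool's convention the mean absolute
#' deviation from the arithmetic mean (switch `dispersion = "sd"` for the
#' n-1 sample SD); CV\% = 100 * dispersion / mean. The BestKeeper index is
#' the per-sample geometric mean of all genes' Cq, and each gene is
#' correlated (Pearson) against the index. Stability value = dispersion,
#' ranked ascending; genes with dispersion > 1 cycle are flagged
#' inconsistent.
#'
#' @param matrix A `cq_matrix`; all Cq must be positive.
#' @param dispersion `"mad"` (mean absolute deviation, the tool's
#'   convention) or `"sd"`.
#' @return A `stability_result` (algorithm `"bestkeeper"`); `details` holds
#'   the full descriptive table and the per-sample index as attribute
#'   `"index"`.
#' @export
bestkeeper <- function(matrix, dispersion = c("mad", "sd")) {
  stopifnot(inherits(matrix, "cq_matrix"))
  dispersion <- match.arg(dispersion)
  cq <- matrix$mean_cq
  if (nrow(cq) < 2 || ncol(cq) < 3) {
    stop("bestkeeper: need >= 2 genes and >= 3 samples", call. = FALSE)
  }
  if (any(cq <= 0, na.rm = TRUE)) {
    stop("bestkeeper: non-positive Cq; geometric mean undefined",
         call. = FALSE)
  }
  index <- apply(cq, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v) == 0) NA_real_ else exp(mean(log(v)))
  })
  desc <- lapply(rownames(cq), function(g) {
    v <- cq[g, ]
    ok <- !is.na(v)
    m <- mean(v[ok])
    disp <- if (dispersion == "mad") mean(abs(v[ok] - m))
            else stats::sd(v[ok])
    both <- ok & !is.na(index)
    ct <- if (sum(both) >= 3 && stats::sd(v[both]) > 0 &&
              stats::sd(index[both]) > 0) {
      stats::cor.test(v[both], index[both])
    } else NULL
    tibble::tibble(
      gene = g, n = sum(ok),
      mean_cq = m, geo_mean_cq = exp(mean(log(v[ok]))),
      min_cq = min(v[ok]), max_cq = max(v[ok]),
      dispersion = disp, cv_percent = 100 * disp / m,
      r_with_index = if (is.null(ct)) NA_real_ else unname(ct$estimate),
      p_value = if (is.null(ct)) NA_real_ else ct$p.value,
      inconsistent = disp > 1
    )
  })
  details <- dplyr::bind_rows(desc)
  attr(details, "index") <- index
  values <- stats::setNames(details$dispersion, details$gene)
  new_stability_result("bestkeeper", values, fractional_ranks(values),
                       details = details)
}

# two-way (gene + sample) variance decomposition on a complete log-quantity
# block; returns the per-gene variance estimates of the model-based approach
normfinder_var <- function(Y) {
  k <- nrow(Y)
  n <- ncol(Y)
  R <- Y - rowMeans(Y) - rep(colMeans(Y), each = k) + mean(Y)
  u <- rowSums(R^2) / (n - 1)
  sig2 <- (k / (k - 2)) * (u - sum(u) / (k * (k - 1)))
  sig2[sig2 < 0] <- 0
  sig2
}

#' NormFinder model-based stability ranking
#'
#' Models log2 quantities as gene effect + sample effect + noise and
#' estimates each gene's own noise variance, correcting the naive two-way
#' residual sum of squares for the leakage of the other genes' noise into
#' the per-sample mean: with k genes, `u_g = sum_s r_gs^2 / (n-1)` has
#' expectation `sigma_g^2 (1 - 2/k) + sum(sigma^2)/k^2`, and
#' \deqn{\hat\sigma^2_g = \max(0, \tfrac{k}{k-2}(u_g - U/(k(k-1)))), \quad
#'   U = \sum_g u_g}
#' is unbiased for `sigma_g^2`. Ungrouped stability value = `sigma_g`
#' (an SD, log2 units). With `use_groups = TRUE`, the variance is estimated
#' within each sample group and combined with the gene's inter-group
#' expression deviation `d_(g,grp)` as
#' `mean over groups of (|d| + sqrt(sigma^2_grp / n_grp))`, so a gene that
#' is quiet within groups but shifted between them is penalised.
#'
#' @param matrix A complete `cq_matrix` (no missing cells; subset to
#'   complete samples first if needed).
#' @param use_groups Use the `group_of` labels for the grouped estimator.
#' @param efficiencies Passed to [to_log_quantities()].
#' @return A `stability_result` (algorithm `"normfinder"`).
#' @export
normfinder <- function(matrix, use_groups = FALSE, efficiencies = NULL) {
  stopifnot(inherits(matrix, "cq_matrix"))
  if (anyNA(matrix$mean_cq)) {
    stop("normfinder: matrix has missing cells; the two-way decomposition ",
         "needs a complete matrix (subset to complete samples first)",
         call. = FALSE)
  }
  k <- nrow(matrix$mean_cq)
  if (k < 4) stop("normfinder: need >= 4 genes", call. = FALSE)
  lq <- to_log_quantities(matrix, efficiencies)
  Y <- lq$logq

  if (!use_groups) {
    sig2 <- normfinder_var(Y)
    values <- sqrt(sig2)
    details <- tibble::tibble(gene = names(values),
                              variance = unname(sig2))
  } else {
    grp <- matrix$group_of
    if (anyNA(grp)) {
      stop("normfinder: use_groups = TRUE but some samples have no group",
           call. = FALSE)
    }
    sizes <- table(grp)
    if (any(sizes < 3)) {
      stop("normfinder: group(s) with fewer than 3 samples: ",
           paste(names(sizes)[sizes < 3], collapse = ", "), call. = FALSE)
    }
    Z <- Y - rep(colMeans(Y), each = k)  # gene profile relative to sample mean
    groups <- unique(grp)
    per_group <- sapply(groups, function(g2) {
      idx <- which(grp == g2)
      sig2 <- normfinder_var(Y[, idx, drop = FALSE])
      d <- rowMeans(Z[, idx, drop = FALSE]) - rowMeans(Z)
      abs(d) + sqrt(sig2 / length(idx))
    })
    values <- rowMeans(per_group)
    details <- tibble::as_tibble(per_group, rownames = "gene")
  }
  new_stability_result("normfinder", values, fractional_ranks(values),
                       details = details)
}
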