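check_same_genes <- function(results) {
  gene_sets <- lapply(results, function(r) sort(names(r$values)))
  ref <- gene_sets[[1]]
  for (i in seq_along(gene_sets)[-1]) {
    if (!identical(gene_sets[[i]], ref)) {
      diff <- union(setdiff(ref, gene_sets[[i]]), setdiff(gene_sets[[i]], ref))
      stop("gene sets differ across stability results: ",
           paste(diff, collapse = ", "), call. = FALSE)
    }
  }
  names(results[[1]]$values)
}

#' RefFinder-style geometric-mean aggregation of four base rankings
#'
#' Each gene's weight in a base method is its (fractional) rank there; the
#' aggregate stability value is the geometric mean of the four ranks, and
#' the aggregate ranking orders genes by that value. Because ranks are
#' >= 1 the geometric mean is always defined, and it necessarily lies
#' between the smallest and largest of the four input ranks.
#'
#' @param base_results List of exactly 4 `stability_result` objects
#'   (geNorm, NormFinder, BestKeeper, comparative delta-Ct) over the same
#'   gene set.
#' @return A `stability_result` with algorithm `"reffinder"`.
#' @export
reffinder_aggregate <- function(base_results) {
  if (length(base_results) != 4) {
    stop("reffinder_aggregate: need exactly 4 base results (got ",
         length(base_results), ")", call. = FALSE)
  }
  genes <- check_same_genes(base_results)
  rank_mat <- sapply(base_results, function(r) r$ranks[genes])
  values <- stats::setNames(apply(rank_mat, 1, function(v)
    exp(mean(log(v)))), genes)
  colnames(rank_mat) <- vapply(base_results, `[[`, "", "algorithm")
  details <- tibble::as_tibble(rank_mat)
  details <- dplyr::mutate(details, gene = genes, .before = 1)
  new_stability_result("reffinder", values, fractional_ranks(values),
                       details = details)
}

#' Five-algorithm rank-sum consensus
#'
#' Sums each gene's ranks across the five stability results (four base
#' algorithms plus the RefFinder aggregate — the aggregate is deliberately
#' double-counted, mirroring common practice of treating it as a fifth
#' voter). The lowest rank sum is the most stably expressed gene. Ties in
#' the rank sum are broken by the RefFinder geometric-mean rank, then by
#' gene id; the tie-break used is recorded per gene.
#'
#' @param all_results List of 5 `stability_result` objects on one gene set,
#'   including one with algorithm `"reffinder"`.
#' @return Object of class `consensus_report`: `table` (per-gene ranks,
#'   rank sum, geometric-mean rank, consensus rank, tie-break note),
#'   `final_order`, `correlation` (see [algorithm_correlation()]),
#'   `results` (the inputs), `genes`.
#' @export
rank_sum_consensus <- function(all_results) {
  if (length(all_results) != 5) {
    stop("rank_sum_consensus: need exactly 5 results (4 base + reffinder), ",
         "got ", length(all_results), call. = FALSE)
  }
  algs <- vapply(all_results, `[[`, "", "algorithm")
  if (!"reffinder" %in% algs) {
    stop("rank_sum_consensus: no result with algorithm 'reffinder'",
         call. = FALSE)
  }
  if (anyDuplicated(algs)) {
    stop("rank_sum_consensus: duplicate algorithm(s): ",
         paste(algs[duplicated(algs)], collapse = ", "), call. = FALSE)
  }
  genes <- check_same_genes(all_results)
  rank_mat <- sapply(all_results, function(r) r$ranks[genes])
  colnames(rank_mat) <- algs
  rank_sum <- rowSums(rank_mat)
  reff <- all_results[[which(algs == "reffinder")]]
  geo <- reff$values[genes]

  ord <- order(rank_sum, geo, genes)
  tie <- duplicated(rank_sum) | duplicated(rank_sum, fromLast = TRUE)
  tab <- tibble::as_tibble(rank_mat) |>
    dplyr::mutate(gene = genes, .before = 1) |>
    dplyr::mutate(rank_sum = unname(rank_sum),
                  reffinder_geomean = unname(geo),
                  tie_break = ifelse(tie, "reffinder_geomean_then_gene_id",
                                     "none"))
  tab <- tab[ord, ]
  tab$consensus_rank <- seq_along(genes)

  correlation <- algorithm_correlation(all_results)
  structure(list(table = tab, final_order = tab$gene,
                 correlation = correlation, results = all_results,
                 genes = genes),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report> ", length(x$genes),
      " genes, 5 algorithms; most stable first:\n", sep = "")
  print(x$table, n = Inf)
  invisible(x)
}

#' Pearson correlation among algorithm rankings
#'
#' Correlates the (fractional) rank vectors of each pair of algorithms;
#' because the inputs are ranks this is numerically a Spearman-type
#' agreement measure between methods. Two-sided p-values come from the
#' t-transform with G - 2 degrees of freedom. A constant rank vector (all
#' genes tied) has no defined correlation; such pairs are reported missing
#' with a warning.
#'
#' @param all_results List of >= 2 `stability_result` objects on one gene
#'   set covering >= 4 genes.
#' @param on `"ranks"` (default) correlates rank vectors; `"values"`
#'   correlates raw stability values (sensitivity analysis).
#' @return List with matrices `r`, `abs_r`, `p` (algorithms x algorithms).
#' @export
algorithm_correlation <- function(all_results, on = c("ranks", "values")) {
  on <- match.arg(on)
  genes <- check_same_genes(all_results)
  if (length(genes) < 4) {
    stop("algorithm_correlation: need >= 4 genes", call. = FALSE)
  }
  algs <- vapply(all_results, `[[`, "", "algorithm")
  vec_mat <- sapply(all_results, function(r)
    if (on == "ranks") r$ranks[genes] else r$values[genes])
  colnames(vec_mat) <- algs
  a <- length(algs)
  r <- matrix(NA_real_, a, a, dimnames = list(algs, algs))
  p <- r
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(a - 1)) {
    for (j in seq(i + 1, a)) {
      if (stats::sd(vec_mat[, i]) == 0 || stats::sd(vec_mat[, j]) == 0) {
        warning("constant vector for '", algs[if (stats::sd(vec_mat[, i]) == 0) i else j],
                "': correlation undefined, reported as missing",
                call. = FALSE)
        next
      }
      ct <- stats::cor.test(vec_mat[, i], vec_mat[, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, abs_r = abs(r), p = p)
}

#' Run the full reference-gene stability pipeline
#'
#' Replicate aggregation and filtering, the four base stability algorithms,
#' the RefFinder aggregate and the five-algorithm rank-sum consensus, in one
#' call. Samples with a missing aggregated Cq in any gene are dropped before
#' the stability stage (with a message) so that all five algorithms see the
#' same complete gene-by-sample block.
#'
#' @param table A [cq_table()].
#' @param max_cq Replicate filter threshold, cycles.
#' @param use_groups Use sample group labels in NormFinder.
#' @param efficiencies Optional per-gene amplification factors for the
#'   Cq-to-quantity transform (default: 2 for every gene).
#' @param dispersion BestKeeper dispersion convention, `"mad"` or `"sd"`.
#' @return A `consensus_report` (see [rank_sum_consensus()]); the QC flags
#'   from aggregation are attached as attribute `"qc_flags"`.
#' @export
rank_reference_genes <- function(table, max_cq = 35, use_groups = FALSE,
                                 efficiencies = NULL,
                                 dispersion = c("mad", "sd")) {
  agg <- aggregate_replicates(table, max_cq = max_cq)
  m <- agg$matrix
  complete <- colSums(is.na(m$mean_cq)) == 0
  if (!all(complete)) {
    message("dropping ", sum(!complete),
            " sample(s) with missing aggregated Cq: ",
            paste(m$samples[!complete], collapse = ", "))
    m$mean_cq <- m$mean_cq[, complete, drop = FALSE]
    m$n_used <- m$n_used[, complete, drop = FALSE]
    m$samples <- m$samples[complete]
    m$group_of <- m$group_of[complete]
  }
  lq <- to_log_quantities(m, efficiencies)
  base <- list(
    genorm(lq),
    normfinder(m, use_groups = use_groups, efficiencies = efficiencies),
    bestkeeper(m, dispersion = dispersion),
    delta_ct_stability(m)
  )
  reff <- reffinder_aggregate(base)
  report <- rank_sum_consensus(c(base, list(reff)))
  attr(report, "qc_flags") <- agg$flags
  report
}
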