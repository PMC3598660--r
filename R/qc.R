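#' @importFrom rlang .data
NULL

#' Aggregate replicate Cq values into a gene-by-sample matrix
#'
#' Applies the replicate-level exclusion rule — any replicate with Cq above
#' `max_cq` (default 35 cycles) or a missing (non-detect) Cq is removed —
#' and then averages the surviving replicates arithmetically for each
#' (gene, sample) cell. Filtering happens before averaging so a single
#' failed well cannot bias the cell mean. Every exclusion is logged with a
#' reason; a cell with no surviving replicate is reported as missing, and a
#' gene left without any usable value in any sample is kept as an all-missing
#' row with a warning rather than silently dropped.
#'
#' @param table A [cq_table()].
#' @param max_cq Replicates with Cq strictly above this threshold are
#'   excluded (cycles).
#' @return A list with components:
#'   \describe{
#'     \item{matrix}{`cq_matrix`: gene x sample `mean_cq` and `n_used` grids
#'       plus a `group_of` map.}
#'     \item{flags}{`qc_flags`: tibble `excluded` with one row per excluded
#'       replicate (reason `cq_above_cutoff` or `missing`), and `warnings`.}
#'   }
#' @export
aggregate_replicates <- function(table, max_cq = 35) {
  stopifnot(inherits(table, "cq_table"))
  if (!is.numeric(max_cq) || max_cq <= 0 || max_cq > table$total_cycles) {
    stop("max_cq must be in (0, ", table$total_cycles, "]", call. = FALSE)
  }
  obs <- table$observations[table$observations$role == "sample", ]
  if (nrow(obs) == 0) stop("no sample wells in table", call. = FALSE)

  genes <- unique(obs$gene)
  samples <- unique(obs$sample)

  reason <- rep(NA_character_, nrow(obs))
  reason[is.na(obs$cq)] <- "missing"
  reason[!is.na(obs$cq) & obs$cq > max_cq] <- "cq_above_cutoff"
  excluded <- tibble::tibble(
    gene = obs$gene[!is.na(reason)],
    sample = obs$sample[!is.na(reason)],
    replicate = obs$replicate[!is.na(reason)],
    run = obs$run[!is.na(reason)],
    cq = obs$cq[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  keep <- obs[is.na(reason), ]

  mean_cq <- matrix(NA_real_, length(genes), length(samples),
                    dimnames = list(genes, samples))
  n_used <- matrix(0L, length(genes), length(samples),
                   dimnames = list(genes, samples))
  if (nrow(keep) > 0) {
    agg <- keep %>%
      dplyr::group_by(.data$gene, .data$sample) %>%
      dplyr::summarise(m = mean(.data$cq), n = dplyr::n(), .groups = "drop")
    mean_cq[cbind(agg$gene, agg$sample)] <- agg$m
    n_used[cbind(agg$gene, agg$sample)] <- agg$n
  }

  warnings <- character(0)
  empty_genes <- genes[rowSums(!is.na(mean_cq)) == 0]
  if (length(empty_genes) > 0) {
    msg <- paste0("gene(s) with no surviving Cq value in any sample: ",
                  paste(empty_genes, collapse = ", "))
    warnings <- c(warnings, msg)
    warning(msg, call. = FALSE)
  }

  group_of <- stats::setNames(table$sample_meta$group,
                              table$sample_meta$sample)[samples]
  m <- structure(list(genes = genes, samples = samples, mean_cq = mean_cq,
                      n_used = n_used, group_of = group_of,
                      max_cq = max_cq),
                 class = "cq_matrix")
  flags <- structure(list(excluded = excluded, warnings = warnings),
                     class = "qc_flags")
  list(matrix = m, flags = flags)
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat("<cq_matrix> ", length(x$genes), " genes x ", length(x$samples),
      " samples; ", sum(is.na(x$mean_cq)), " missing cell(s); max_cq = ",
      x$max_cq, "\n", sep = "")
  invisible(x)
}

#' Flag possible contamination from negative-control wells
#'
#' Inspects no-template and no-RT control wells per gene. No amplification
#' (missing Cq) raises no flag; amplification above `max_cq` is recorded as
#' `negligible` (too late to matter relative to 1 ng template reactions);
#' amplification at or below `max_cq` is a `fail`. A fail never auto-excludes
#' the gene — judgement is left to the caller, since late-amplifying
#' contamination is routinely tolerated in practice.
#'
#' @inheritParams aggregate_replicates
#' @return `qc_flags` with tibble `contamination`
#'   (gene, control_type, replicate, cq, verdict).
#' @export
flag_contamination <- function(table, max_cq = 35) {
  stopifnot(inherits(table, "cq_table"))
  ctrl <- table$observations[table$observations$role != "sample", ]
  warnings <- character(0)
  if (nrow(ctrl) == 0) {
    warnings <- "no negative-control wells present in table"
    warning(warnings, call. = FALSE)
  }
  amp <- ctrl[!is.na(ctrl$cq), ]
  contamination <- tibble::tibble(
    gene = amp$gene,
    control_type = amp$role,
    replicate = amp$replicate,
    cq = amp$cq,
    verdict = ifelse(amp$cq > max_cq, "negligible", "fail")
  )
  structure(list(contamination = contamination, warnings = warnings),
            class = "qc_flags")
}

#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1 denominator) standard
#' deviation. The CV is scale-invariant (unchanged by multiplying all values
#' by a positive constant) but not shift-invariant.
#'
#' @param values Numeric vector, at least 2 finite values, non-zero mean.
#' @return CV as a percentage.
#' @export
cv_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values) || any(!is.finite(values))) {
    stop("cv_percent: need at least 2 finite values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) stop("cv_percent: undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Intra- or inter-assay variability per gene
#'
#' Intra-assay: the CV over replicate Cq values within each
#' (gene, sample, run) well group, averaged per gene — the repeatability of
#' pipetting and detection within one plate. Inter-assay: per (gene, sample),
#' the CV over per-run mean Cq across runs (e.g. the same samples assayed on
#' different days), averaged per gene — run-to-run reproducibility.
#'
#' @param table A [cq_table()].
#' @param mode `"intra"` or `"inter"`.
#' @return Tibble with columns `gene`, `cv_percent` (mean CV for the gene)
#'   and `n_units` (well groups or sample series contributing).
#' @export
assay_variability <- function(table, mode = c("intra", "inter")) {
  stopifnot(inherits(table, "cq_table"))
  mode <- match.arg(mode)
  obs <- table$observations[table$observations$role == "sample" &
                              !is.na(table$observations$cq), ]

  if (mode == "intra") {
    per_unit <- obs %>%
      dplyr::group_by(.data$gene, .data$sample, .data$run) %>%
      dplyr::summarise(n = dplyr::n(),
                       cv = if (dplyr::n() >= 2) cv_percent(.data$cq)
                            else NA_real_,
                       .groups = "drop") %>%
      dplyr::filter(!is.na(.data$cv))
  } else {
    per_run <- obs %>%
      dplyr::group_by(.data$gene, .data$sample, .data$run) %>%
      dplyr::summarise(run_mean = mean(.data$cq), .groups = "drop")
    per_unit <- per_run %>%
      dplyr::group_by(.data$gene, .data$sample) %>%
      dplyr::summarise(n = dplyr::n(),
                       cv = if (dplyr::n() >= 2) cv_percent(.data$run_mean)
                            else NA_real_,
                       .groups = "drop") %>%
      dplyr::filter(!is.na(.data$cv))
  }
  if (nrow(per_unit) == 0) {
    stop("assay_variability: no unit with the replication required for ",
         mode, "-assay CV (", if (mode == "intra")
           ">=2 replicates within a run" else
           "the same (gene, sample) in >=2 runs", ")", call. = FALSE)
  }
  per_unit %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(cv_percent = mean(.data$cv), n_units = dplyr::n(),
                     .groups = "drop")
}
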