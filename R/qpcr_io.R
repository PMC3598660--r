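#' @importFrom stats sd cor.test lm setNames complete.cases pt
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% arrange group_by summarise mutate filter select ungroup
NULL

CQ_ROLES <- c("sample", "no_template_control", "no_rt_control")

#' Construct a replicate-level Cq table
#'
#' The canonical raw input of the pipeline: one row per well, in long format,
#' so that replicate- and run-level structure (needed for CV computations and
#' replicate filtering) is preserved. Wide gene-by-sample matrices are only
#' ever produced internally, by [aggregate_replicates()].
#'
#' @param observations Data frame with columns `gene`, `sample`, `replicate`
#'   (positive integer), `run`, `cq` (non-negative cycles, `NA` for a
#'   non-detect) and `role` (one of `"sample"`, `"no_template_control"`,
#'   `"no_rt_control"`).
#' @param sample_meta Data frame with columns `sample` and `group` (and
#'   optionally `description`). Every sample-well `sample` id must appear
#'   here. If `NULL`, a metadata table with missing group labels is derived
#'   from the observations.
#' @param total_cycles Number of PCR cycles run; Cq values cannot exceed it.
#'
#' @return An object of class `cq_table`: a list with tibbles `observations`
#'   and `sample_meta`.
#' @export
cq_table <- function(observations, sample_meta = NULL, total_cycles = 40) {
  obs <- as_tibble(observations)
  required <- c("gene", "sample", "replicate", "run", "cq", "role")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0) {
    stop("cq_table: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs <- obs[required]
  obs$gene <- as.character(obs$gene)
  obs$sample <- as.character(obs$sample)
  obs$run <- as.character(obs$run)
  obs$role <- as.character(obs$role)

  if (any(!obs$role %in% CQ_ROLES)) {
    bad <- unique(obs$role[!obs$role %in% CQ_ROLES])
    stop("cq_table: unknown well role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rep_ok <- is.finite(obs$replicate) & obs$replicate >= 1 &
    obs$replicate == round(obs$replicate)
  if (any(!rep_ok)) {
    stop("cq_table: replicate indices must be positive integers",
         call. = FALSE)
  }
  obs$replicate <- as.integer(obs$replicate)
  cq_bad <- !is.na(obs$cq) &
    (!is.finite(obs$cq) | obs$cq < 0 | obs$cq > total_cycles)
  if (any(cq_bad)) {
    stop("cq_table: cq values must be finite, >= 0 and <= ", total_cycles,
         " cycles (or NA for non-detects); offending row(s): ",
         paste(utils::head(which(cq_bad), 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(obs$gene, obs$sample, obs$replicate, obs$run, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- obs[duplicated(key), c("gene", "sample", "replicate", "run")]
    stop("cq_table: duplicate (gene, sample, replicate, run) tuple(s), e.g. (",
         paste(unlist(dup[1, ]), collapse = ", "), ")", call. = FALSE)
  }

  sample_ids <- unique(obs$sample[obs$role == "sample"])
  if (is.null(sample_meta)) {
    sample_meta <- tibble(sample = sample_ids, group = NA_character_,
                          description = NA_character_)
  } else {
    sample_meta <- as_tibble(sample_meta)
    if (!all(c("sample", "group") %in% names(sample_meta))) {
      stop("cq_table: sample_meta needs columns 'sample' and 'group'",
           call. = FALSE)
    }
    if (!"description" %in% names(sample_meta)) {
      sample_meta$description <- NA_character_
    }
    sample_meta <- sample_meta[c("sample", "group", "description")]
    sample_meta$sample <- as.character(sample_meta$sample)
    sample_meta$group <- as.character(sample_meta$group)
    orphans <- setdiff(sample_ids, sample_meta$sample)
    if (length(orphans) > 0) {
      stop("cq_table: sample(s) missing from sample_meta: ",
           paste(orphans, collapse = ", "), call. = FALSE)
    }
  }

  structure(list(observations = obs, sample_meta = sample_meta,
                 total_cycles = total_cycles),
            class = "cq_table")
}

#' @export
print.cq_table <- function(x, ...) {
  obs <- x$observations
  cat("<cq_table> ", nrow(obs), " observations: ",
      length(unique(obs$gene)), " genes x ",
      length(unique(obs$sample[obs$role == "sample"])), " samples, ",
      length(unique(obs$run)), " run(s); ",
      sum(obs$role != "sample"), " control wells; ",
      sum(is.na(obs$cq)), " non-detects\n", sep = "")
  invisible(x)
}

parse_cq_column <- function(raw) {
  raw <- trimws(raw)
  out <- rep(NA_real_, length(raw))
  is_nd <- is.na(raw) | raw == "" | toupper(raw) == "ND" | raw == "NA"
  parsed <- suppressWarnings(as.numeric(raw[!is_nd]))
  if (anyNA(parsed)) {
    bad_row <- which(!is_nd)[which(is.na(parsed))[1]]
    stop("invalid Cq literal '", raw[!is_nd][which(is.na(parsed))[1]],
         "' in data row ", bad_row, call. = FALSE)
  }
  out[!is_nd] <- parsed
  out
}

#' Read a long-format Cq table from CSV
#'
#' Expects a UTF-8, comma-delimited file with header columns
#' `gene,sample,replicate,run,cq,role`. Missing (non-detect) Cq values are
#' encoded on disk as an empty field or the literal `ND`; they are preserved
#' as missing, never imputed as 0 or the cycle limit.
#'
#' @param path Path to the Cq CSV.
#' @param meta_path Optional path to a sample-metadata CSV with columns
#'   `sample,group`.
#' @inheritParams cq_table
#' @return A validated [cq_table()].
#' @export
read_cq_table <- function(path, meta_path = NULL, total_cycles = 40) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  required <- c("gene", "sample", "replicate", "run", "cq", "role")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$cq <- parse_cq_column(raw$cq)
  raw$replicate <- suppressWarnings(as.numeric(raw$replicate))
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- readr::read_csv(meta_path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
  }
  cq_table(raw, sample_meta = meta, total_cycles = total_cycles)
}

#' Write a Cq table (and optionally its sample metadata) to CSV
#'
#' Written with full double precision so that a write/read round trip is the
#' identity. Non-detect Cq values are written as `ND`.
#'
#' @param x A [cq_table()].
#' @param path Output path for the observation CSV.
#' @param meta_path Optional output path for the sample-metadata CSV.
#' @export
write_cq_table <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "cq_table"))
  obs <- x$observations
  obs$cq <- ifelse(is.na(obs$cq), "ND", format(obs$cq, digits = 17,
                                               scientific = FALSE,
                                               trim = TRUE))
  readr::write_csv(obs, path, progress = FALSE)
  if (!is.null(meta_path)) {
    readr::write_csv(x$sample_meta, meta_path, progress = FALSE)
  }
  invisible(path)
}

#' Read a serial-dilution series from CSV
#'
#' Expects columns `gene`, `amount_ng` (or `amount`), and replicate Cq
#' columns `cq1..cqR`. Within each gene the points are ordered by descending
#' input amount (highest template first, as a dilution series is pipetted).
#'
#' @param path Path to the dilution CSV.
#' @return A tibble of class `dilution_series` with columns `gene`, `amount`
#'   (ng of RNA-equivalent before RT) and list-column `cq_replicates`. Genes
#'   with fewer than 3 distinct amounts are flagged in the
#'   `"too_few_points"` attribute (and a warning is raised).
#' @export
read_dilution_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  if ("amount_ng" %in% names(raw) && !"amount" %in% names(raw)) {
    names(raw)[names(raw) == "amount_ng"] <- "amount"
  }
  cq_cols <- grep("^cq[0-9]+$", names(raw), value = TRUE)
  if (!all(c("gene", "amount") %in% names(raw)) || length(cq_cols) == 0) {
    stop("malformed dilution header: need columns gene, amount (or ",
         "amount_ng) and cq1..cqR", call. = FALSE)
  }
  amount <- suppressWarnings(as.numeric(raw$amount))
  if (anyNA(amount) || any(amount <= 0)) {
    stop("dilution amounts must be positive numbers", call. = FALSE)
  }
  cq_mat <- sapply(cq_cols, function(cc) parse_cq_column(raw[[cc]]))
  cq_mat <- matrix(cq_mat, nrow = nrow(raw))
  out <- tibble(
    gene = as.character(raw$gene),
    amount = amount,
    cq_replicates = lapply(seq_len(nrow(raw)), function(i) cq_mat[i, ])
  )
  new_dilution_series(out)
}

new_dilution_series <- function(out) {
  dup <- out %>% group_by(.data$gene) %>%
    summarise(dup = anyDuplicated(.data$amount) > 0)
  if (any(dup$dup)) {
    stop("duplicate dilution amount(s) within gene(s): ",
         paste(dup$gene[dup$dup], collapse = ", "), call. = FALSE)
  }
  out <- out %>% arrange(.data$gene, dplyr::desc(.data$amount))
  n_amounts <- out %>% group_by(.data$gene) %>% summarise(n = dplyr::n())
  short <- n_amounts$gene[n_amounts$n < 3]
  if (length(short) > 0) {
    warning("fewer than 3 distinct dilution amounts for gene(s): ",
            paste(short, collapse = ", "), call. = FALSE)
  }
  attr(out, "too_few_points") <- short
  class(out) <- c("dilution_series", class(out))
  out
}

#' Write per-algorithm stability tables, the consensus table and a summary
#'
#' Emits one CSV per stability algorithm (gene, stability value, rank), a
#' consensus CSV (rank sums, geometric-mean ranks, final order), a
#' correlation CSV, and a key-value JSON summary. All numeric columns are
#' written at full double precision so re-reading reproduces the values
#' exactly.
#'
#' @param report A [rank_sum_consensus()] result (`consensus_report`).
#' @param dir Output directory; created if absent.
#' @param extra Named list merged into the JSON summary (e.g. seed, filter
#'   settings).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, extra = list()) {
  stopifnot(inherits(report, "consensus_report"))
  if (length(report$genes) == 0) {
    stop("write_report: empty gene list, nothing to write", call. = FALSE)
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)

  paths <- character(0)
  for (res in report$results) {
    tab <- tibble(gene = names(res$values),
                  value = unname(res$values),
                  rank = unname(res$ranks[names(res$values)]))
    p <- file.path(dir, paste0("stability_", res$algorithm, ".csv"))
    readr::write_csv(tab, p, progress = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "consensus.csv")
  readr::write_csv(report$table, p, progress = FALSE)
  paths <- c(paths, p)

  cor_long <- as.data.frame(as.table(report$correlation$r),
                            stringsAsFactors = FALSE)
  names(cor_long) <- c("algorithm_a", "algorithm_b", "r")
  cor_long$abs_r <- abs(cor_long$r)
  cor_long$p_value <- as.vector(report$correlation$p)
  p <- file.path(dir, "correlation.csv")
  readr::write_csv(as_tibble(cor_long), p, progress = FALSE)
  paths <- c(paths, p)

  summary <- c(list(
    package = "refstab",
    package_version = as.character(utils::packageVersion("refstab")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_genes = length(report$genes),
    algorithms = vapply(report$results, `[[`, "", "algorithm"),
    final_order = report$final_order
  ), extra)
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
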