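#' Configuration for the synthetic Cq generator
#'
#' The defaults emulate a typical reference-gene screening panel: 12
#' candidate genes profiled in triplicate across 25 cell lines falling into
#' three biological subgroups ("ovarian" 11, "colon" 9, "other" 5). Three
#' genes are planted as genuinely stable (biological noise SD 0.1 log2
#' units, no group effect); eight span a noise gradient from 0.5 to 1.5;
#' one is group-confounded (quiet within groups, +1 log2 shifted in the
#' colon subgroup) — the failure mode that only a grouped analysis can
#' attribute correctly. A shared per-sample loading shift (SD 1 log2 unit,
#' i.e. about one Cq cycle of common input variation) affects all genes
#' alike, and replicate-level technical noise of 0.15 cycles matches
#' intra-assay CVs well under 1\% at Cq around 20.
#'
#' @param n_genes,n_samples,replicates Panel dimensions.
#' @param group_labels Character vector of length `n_samples` assigning
#'   each sample to a biological subgroup.
#' @param gene_noise_sd Per-gene biological noise SD, log2 units.
#' @param sample_shift_sd SD of the shared per-sample loading shift, log2
#'   units.
#' @param group_offsets `n_genes` x n-groups matrix of log2 expression
#'   offsets (gene rows, group columns); default all zero except the
#'   confounded gene.
#' @param base_cq Per-gene baseline Cq at nominal input (cycles).
#' @param efficiency_factor Per-gene amplification factor (> 1; 2 = perfect
#'   doubling).
#' @param replicate_noise_sd Technical replicate noise SD on the Cq scale
#'   (cycles).
#' @param dropout_cq Replicates with Cq above this are emitted as
#'   non-detects (missing), mimicking the detection limit.
#' @param seed Integer seed; same config (including seed) means
#'   byte-identical output.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 12, n_samples = 25, replicates = 3,
                              group_labels = NULL,
                              gene_noise_sd = NULL,
                              sample_shift_sd = 1.0,
                              group_offsets = NULL,
                              base_cq = NULL,
                              efficiency_factor = 2.0,
                              replicate_noise_sd = 0.15,
                              dropout_cq = 35, seed = 1L) {
  if (is.null(group_labels)) {
    group_labels <- rep(c("ovarian", "colon", "other"),
                        times = round(n_samples * c(11, 9, 5) / 25))
    group_labels <- rep_len(group_labels, n_samples)
  }
  genes <- sprintf("G%02d", seq_len(n_genes))
  samples <- sprintf("S%02d", seq_len(n_samples))
  groups <- unique(group_labels)

  if (is.null(gene_noise_sd)) {
    gene_noise_sd <- c(rep(0.1, min(3, n_genes)),
                       seq(0.5, 1.5,
                           length.out = max(0, n_genes - 4)),
                       if (n_genes >= 4) 0.2)[seq_len(n_genes)]
  }
  gene_noise_sd <- rep_len(gene_noise_sd, n_genes)
  if (is.null(group_offsets)) {
    group_offsets <- matrix(0, n_genes, length(groups),
                            dimnames = list(genes, groups))
    if (n_genes >= 4 && "colon" %in% groups) {
      group_offsets[n_genes, "colon"] <- 1.0  # the confounded gene
    }
  } else {
    group_offsets <- as.matrix(group_offsets)
    dimnames(group_offsets) <- list(genes, groups)
  }
  if (is.null(base_cq)) base_cq <- seq(18, 28, length.out = n_genes)
  base_cq <- rep_len(base_cq, n_genes)
  efficiency_factor <- rep_len(efficiency_factor, n_genes)

  cfg <- list(n_genes = n_genes, n_samples = n_samples,
              replicates = as.integer(replicates),
              genes = genes, samples = samples,
              group_labels = as.character(group_labels),
              gene_noise_sd = gene_noise_sd,
              sample_shift_sd = sample_shift_sd,
              group_offsets = group_offsets,
              base_cq = base_cq,
              efficiency_factor = efficiency_factor,
              replicate_noise_sd = replicate_noise_sd,
              dropout_cq = dropout_cq,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$n_samples >= 1, cfg$replicates >= 1)
  if (length(cfg$group_labels) != cfg$n_samples) {
    stop("group_labels must have one entry per sample", call. = FALSE)
  }
  if (any(cfg$gene_noise_sd < 0) || cfg$sample_shift_sd < 0 ||
      cfg$replicate_noise_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (any(cfg$base_cq <= 0) || any(cfg$base_cq >= 40)) {
    stop("base_cq must lie in (0, 40) cycles", call. = FALSE)
  }
  if (any(cfg$efficiency_factor <= 1)) {
    stop("efficiency factors must be > 1", call. = FALSE)
  }
  if (cfg$dropout_cq <= 0 || cfg$dropout_cq > 40) {
    stop("dropout_cq must lie in (0, 40]", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a replicate-level Cq dataset with known ground truth
#'
#' The latent log2 expression of gene g in sample s is additive:
#' \deqn{x[g,s] = -(\beta_s + d_{g,grp(s)} + \epsilon_{g,s})}
#' with loading shift `beta_s ~ N(0, sample_shift_sd^2)` shared by all
#' genes, per-group offsets `d`, and biological noise
#' `epsilon ~ N(0, gene_noise_sd_g^2)`. It maps to the Cq scale through the
#' gene's amplification factor, `Cq[g,s] = base_cq_g + x[g,s] /
#' log2(E_g)`, and each of the `replicates` wells adds independent
#' technical noise `N(0, replicate_noise_sd^2)` in cycles. Replicates
#' landing above `dropout_cq` are emitted as non-detects. All draws flow
#' from one seeded generator in a fixed order (shifts, then biological
#' noise, then replicate noise), so identical configs give identical
#' tables.
#'
#' @param config A [simulation_config()].
#' @return List with `table` (a [cq_table()]) and `truth`: the realized
#'   `beta`, `epsilon`, `expected_cq`, the `planted_stable_set` (genes
#'   with the minimal noise SD and no group offset), and the config.
#' @export
simulate_cq_dataset <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  g <- cfg$n_genes
  n <- cfg$n_samples

  draws <- withr::with_seed(cfg$seed, {
    beta <- stats::rnorm(n, 0, cfg$sample_shift_sd)
    eps <- matrix(stats::rnorm(g * n, 0, rep(cfg$gene_noise_sd, times = n)),
                  nrow = g, dimnames = list(cfg$genes, cfg$samples))
    tech <- array(stats::rnorm(g * n * cfg$replicates, 0,
                               cfg$replicate_noise_sd),
                  dim = c(g, n, cfg$replicates))
    list(beta = beta, eps = eps, tech = tech)
  })
  beta <- stats::setNames(draws$beta, cfg$samples)
  d <- cfg$group_offsets[, cfg$group_labels, drop = FALSE]
  x <- -(rep(beta, each = g) + d + draws$eps)
  expected_cq <- cfg$base_cq + x / log2(cfg$efficiency_factor)
  dimnames(expected_cq) <- list(cfg$genes, cfg$samples)

  obs <- expand.grid(replicate = seq_len(cfg$replicates),
                     gene = cfg$genes, sample = cfg$samples,
                     stringsAsFactors = FALSE)
  cq <- expected_cq[cbind(obs$gene, obs$sample)] +
    draws$tech[cbind(match(obs$gene, cfg$genes),
                     match(obs$sample, cfg$samples),
                     obs$replicate)]
  cq[cq > cfg$dropout_cq] <- NA_real_
  obs <- tibble::tibble(gene = obs$gene, sample = obs$sample,
                        replicate = obs$replicate, run = "run1",
                        cq = cq, role = "sample")
  meta <- tibble::tibble(sample = cfg$samples, group = cfg$group_labels,
                         description = NA_character_)

  no_offset <- rowSums(abs(cfg$group_offsets)) == 0
  planted <- cfg$genes[cfg$gene_noise_sd == min(cfg$gene_noise_sd) &
                         no_offset]
  truth <- list(beta = beta, epsilon = draws$eps,
                group_offsets = cfg$group_offsets,
                expected_cq = expected_cq,
                planted_stable_set = planted,
                config = cfg)
  list(table = cq_table(obs, meta), truth = truth)
}

#' Simulate a noisy serial-dilution series for one gene
#'
#' Replicate Cq values follow the standard-curve line
#' `Cq = intercept + slope * log10(amount)` plus independent Gaussian
#' noise in cycles. With `noise_sd = 0` the series refits exactly.
#'
#' @param gene_id Gene label carried on the output.
#' @param true_slope Standard-curve slope (cycles per 10-fold dilution,
#'   < 0).
#' @param true_intercept Cq at 1 unit of template (cycles).
#' @param amounts Distinct positive template amounts (e.g. ng).
#' @param noise_sd Technical noise SD, cycles.
#' @param replicates Wells per dilution point.
#' @param seed Integer seed.
#' @return A `dilution_series` tibble (gene, amount, cq_replicates),
#'   ordered by descending amount.
#' @export
simulate_dilution_series <- function(gene_id, true_slope, true_intercept,
                                     amounts, noise_sd = 0, replicates = 3,
                                     seed = 1L) {
  if (!is.numeric(true_slope) || true_slope >= 0) {
    stop("true_slope must be negative", call. = FALSE)
  }
  if (any(amounts <= 0)) stop("amounts must be positive", call. = FALSE)
  if (anyDuplicated(amounts)) {
    stop("amounts must be distinct", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  cq_mat <- withr::with_seed(seed, {
    mu <- true_intercept + true_slope * log10(amounts)
    matrix(stats::rnorm(length(amounts) * replicates, mean = mu,
                        sd = noise_sd),
           nrow = length(amounts))
  })
  out <- tibble::tibble(
    gene = as.character(gene_id),
    amount = as.numeric(amounts),
    cq_replicates = lapply(seq_along(amounts), function(i) cq_mat[i, ])
  )
  new_dilution_series(out)
}
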