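# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# wrap a plain gene x sample Cq matrix in the container the stability
# algorithms consume
make_cq_matrix <- function(cq, groups = NULL, max_cq = 35) {
  genes <- rownames(cq)
  samples <- colnames(cq)
  if (is.null(genes) || any(genes == "")) {
    genes <- sprintf("g%02d", seq_len(nrow(cq)))
  }
  if (is.null(samples) || any(samples == "")) {
    samples <- sprintf("s%02d", seq_len(ncol(cq)))
  }
  dimnames(cq) <- list(genes, samples)
  if (is.null(groups)) groups <- rep(NA_character_, length(samples))
  structure(list(genes = genes, samples = samples, mean_cq = cq,
                 n_used = matrix(1L, nrow(cq), ncol(cq),
                                 dimnames = dimnames(cq)),
                 group_of = stats::setNames(groups, samples),
                 max_cq = max_cq),
            class = "cq_matrix")
}

random_cq_matrix <- function(n_genes = 5, n_samples = 8, seed = 1,
                             base = 22, sd = 1) {
  withr::with_seed(seed, {
    cq <- matrix(stats::rnorm(n_genes * n_samples, base, sd),
                 n_genes, n_samples)
  })
  make_cq_matrix(cq)
}

# long-format replicate-level table: one run, all sample wells
make_cq_table <- function(cq_by_rep, groups = NULL) {
  # cq_by_rep: list of gene -> list of sample -> numeric replicate vector
  rows <- list()
  for (g in names(cq_by_rep)) {
    for (s in names(cq_by_rep[[g]])) {
      v <- cq_by_rep[[g]][[s]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = g, sample = s, replicate = seq_along(v), run = "run1",
        cq = v, role = "sample")
    }
  }
  obs <- dplyr::bind_rows(rows)
  samples <- unique(obs$sample)
  if (is.null(groups)) groups <- rep(NA_character_, length(samples))
  cq_table(obs, tibble::tibble(sample = samples, group = groups))
}

# the worked 3-gene example used by both the geNorm and delta-Ct tests:
# A and B differ by a constant, C wobbles
abc_matrix <- function() {
  make_cq_matrix(matrix(c(20, 21, 22, 23,
                          22, 23, 24, 25,
                          20, 22, 21, 24),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(c("A", "B", "C"),
                                        paste0("s", 1:4))))
}

# a 4-result list of stability_result objects from given rank vectors
results_from_ranks <- function(rank_list, genes) {
  lapply(names(rank_list), function(alg) {
    v <- stats::setNames(rank_list[[alg]], genes)
    structure(list(algorithm = alg, values = v,
                   ranks = stats::setNames(rank(v), genes),
                   details = NULL),
              class = "stability_result")
  })
}
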