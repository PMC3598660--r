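test_that("to_log_quantities anchors each gene at its minimum Cq", {
  m <- make_cq_matrix(rbind(ga = c(20, 21, 23), gb = c(22, 22, 22)))
  lq <- to_log_quantities(m)
  expect_equal(unname(lq$logq["ga", ]), c(0, -1, -3))
  expect_equal(unname(lq$logq["gb", ]), c(0, 0, 0))
  expect_equal(unname(apply(lq$logq, 1, max)), c(0, 0))

  # an imperfect assay compresses the log scale by log2(E)
  lq2 <- to_log_quantities(m, efficiencies = c(ga = 1.9313))
  expect_equal(unname(lq2$logq["ga", 2]), -log2(1.9313), tolerance = 1e-12)

  expect_error(to_log_quantities(m, efficiencies = c(ga = 1)), "> 1")
})

test_that("geNorm reproduces the hand-computed 3-gene example", {
  lq <- to_log_quantities(abc_matrix())
  res <- genorm(lq)
  # pairwise log-ratio SDs: V_AB = 0, V_AC = V_BC = sd(c(0,1,-1,1)) = 0.9574
  v_ac <- sd(c(0, 1, -1, 1))
  expect_equal(res$values[["C"]], v_ac, tolerance = 1e-12)
  expect_equal(res$details$gene[1], "C")       # C removed first
  expect_equal(res$details$m_value[1], v_ac, tolerance = 1e-12)
  # surviving pair shares rank 1.5 and the final M (= V_AB = 0)
  expect_equal(unname(res$ranks[c("A", "B")]), c(1.5, 1.5))
  expect_equal(unname(res$values[c("A", "B")]), c(0, 0))
  expect_equal(unname(res$ranks[["C"]]), 3)
})

test_that("geNorm degenerates gracefully", {
  m <- make_cq_matrix(matrix(20, 4, 5))
  res <- genorm(to_log_quantities(m))
  expect_equal(unname(res$values), rep(0, 4))
  expect_equal(unname(res$ranks), rep(2.5, 4))  # all tied

  m2 <- make_cq_matrix(matrix(c(20, 21, 22, 23), 2, byrow = TRUE))
  expect_error(genorm(to_log_quantities(m2)), ">= 3 genes")
})

test_that("pairwise variation V(n/n+1) matches a brute-force
           normalization-factor computation", {
  m <- random_cq_matrix(n_genes = 5, n_samples = 10, seed = 21)
  lq <- to_log_quantities(m)
  pv <- genorm_pairwise_variation(lq)
  expect_equal(nrow(pv), 3)  # G - 2 steps

  ord <- attr(pv, "gene_order")
  Q <- 2^lq$logq  # linear-scale relative quantities
  for (idx in seq_len(nrow(pv))) {
    n <- pv$n[idx]
    nf_n <- apply(Q[ord[1:n], , drop = FALSE], 2,
                  function(v) prod(v)^(1 / length(v)))
    nf_n1 <- apply(Q[ord[1:(n + 1)], , drop = FALSE], 2,
                   function(v) prod(v)^(1 / length(v)))
    expect_equal(pv$v[idx], sd(log2(nf_n / nf_n1)), tolerance = 1e-10)
  }
})

test_that("adding an exact copy of a top gene gives a zero V step", {
  base <- withr::with_seed(9, rnorm(8, 22, 1))
  cq <- rbind(A = base, B = base + 1, D = base + 2,
              C = base + withr::with_seed(10, rnorm(8, 0, 0.8)))
  pv <- genorm_pairwise_variation(to_log_quantities(make_cq_matrix(cq)))
  # A, B, D are copies up to a constant: the step adding the third copy to
  # the top-2 set cannot change the normalization factor profile
  expect_equal(pv$v[pv$n == 2], 0, tolerance = 1e-12)
})

test_that("comparative delta-Ct equals first-pass geNorm M at E = 2", {
  m <- abc_matrix()
  res <- delta_ct_stability(m)
  expect_equal(res$values[["A"]], mean(c(0, sd(c(0, 1, -1, 1)))),
               tolerance = 1e-12)
  for (seed in 1:10) {
    mr <- random_cq_matrix(n_genes = 6, n_samples = 9, seed = seed)
    first_pass_m <- {
      lq <- to_log_quantities(mr)
      V <- sapply(seq_len(6), function(j) sapply(seq_len(6), function(k)
        if (j == k) 0 else sd(lq$logq[j, ] - lq$logq[k, ])))
      colSums(V) / 5
    }
    expect_equal(unname(delta_ct_stability(mr)$values), first_pass_m,
                 tolerance = 1e-10)
  }
})

test_that("delta-Ct sees through constant offsets and global shifts", {
  base <- withr::with_seed(3, rnorm(8, 24, 1.5))
  cq <- rbind(A = base, B = base + 2,
              C = base + withr::with_seed(4, rnorm(8, 0, 1)))
  res <- delta_ct_stability(make_cq_matrix(cq))
  # A and B have a constant difference: their pair contributes SD 0
  expect_equal(res$values[["A"]], res$values[["B"]], tolerance = 1e-12)

  shift <- withr::with_seed(5, rnorm(8, 0, 2))
  shifted <- sweep(cq, 2, shift, `+`)  # per-sample loading shift
  res2 <- delta_ct_stability(make_cq_matrix(shifted))
  expect_equal(unname(res2$values), unname(res$values), tolerance = 1e-10)
})

test_that("BestKeeper statistics match a direct evaluation", {
  cq <- withr::with_seed(31, matrix(rnorm(24, 25, 1.2), 4, 6))
  rownames(cq) <- paste0("g", 1:4)
  m <- make_cq_matrix(cq)
  res <- bestkeeper(m)

  idx_oracle <- apply(m$mean_cq, 2, function(v) prod(v)^(1 / length(v)))
  expect_equal(unname(attr(res$details, "index")), unname(idx_oracle),
               tolerance = 1e-10)
  for (g in m$genes) {
    v <- m$mean_cq[g, ]
    expect_equal(res$values[[g]], mean(abs(v - mean(v))), tolerance = 1e-12)
    expect_equal(res$details$r_with_index[res$details$gene == g],
                 cor(v, idx_oracle), tolerance = 1e-10)
  }

  # constant gene: zero dispersion, most stable
  cq2 <- rbind(cq, konst = 20)
  res2 <- bestkeeper(make_cq_matrix(cq2))
  expect_equal(res2$values[["konst"]], 0)
  expect_equal(unname(res2$ranks[["konst"]]), 1)

  # proportional genes correlate perfectly with their index
  cq3 <- rbind(a = cq[1, ], b = 1.1 * cq[1, ])
  res3 <- bestkeeper(make_cq_matrix(cq3))
  expect_equal(res3$details$r_with_index, c(1, 1), tolerance = 1e-10)

  expect_error(bestkeeper(make_cq_matrix(matrix(c(-1, 2, 3, 4, 5, 6),
                                                2, 3))),
               "non-positive")
})

test_that("BestKeeper can switch to the n-1 sample SD convention", {
  m <- random_cq_matrix(4, 6, seed = 8)
  res <- bestkeeper(m, dispersion = "sd")
  expect_equal(unname(res$values), unname(apply(m$mean_cq, 1, sd)),
               tolerance = 1e-12)
})

test_that("NormFinder returns zero for exactly additive data and spots a
           group-confounded gene", {
  alpha <- c(0, 1, 2, 3.5)
  beta <- withr::with_seed(41, rnorm(12, 0, 1))
  y <- outer(alpha, rep(1, 12)) + outer(rep(1, 4), beta)
  m <- make_cq_matrix(30 - y)  # map back to a Cq scale
  res <- normfinder(m)
  expect_equal(unname(res$values), rep(0, 4), tolerance = 1e-10)

  # plant d = +1 in group 1, -1 in group 2 for one gene, tiny noise
  groups <- rep(c("grp1", "grp2"), each = 6)
  eps <- withr::with_seed(42, matrix(rnorm(48, 0, 0.05), 4, 12))
  y2 <- y + eps
  y2[4, groups == "grp1"] <- y2[4, groups == "grp1"] + 1
  y2[4, groups == "grp2"] <- y2[4, groups == "grp2"] - 1
  m2 <- make_cq_matrix(30 - y2, groups = groups)
  res2 <- normfinder(m2, use_groups = TRUE)
  expect_equal(names(which.max(res2$values)), "g04")
  expect_gt(min(res2$values[["g04"]] / res2$values[c("g01", "g02", "g03")]),
            2)
})

test_that("NormFinder enforces its preconditions", {
  expect_error(normfinder(random_cq_matrix(3, 6, seed = 1)), ">= 4 genes")
  m <- random_cq_matrix(4, 6, seed = 2)
  m$mean_cq[1, 1] <- NA
  expect_error(normfinder(m), "complete")
  m2 <- random_cq_matrix(4, 7, seed = 3)
  m2$group_of[] <- c(rep("a", 5), rep("b", 2))
  expect_error(normfinder(m2, use_groups = TRUE), "fewer than 3.*b")
})

test_that("the NormFinder variance estimator is unbiased for sigma^2 away
           from the zero-truncation boundary", {
  # with every sigma well above the estimator's sampling noise the
  # truncation at zero is inactive and sigma^2-hat is exactly unbiased
  sds <- c(0.3, 0.4, 0.5, 0.8, 1.0, 1.2)
  k <- 6; n <- 100; n_rep <- 200
  est2 <- matrix(NA_real_, n_rep, k)
  withr::with_seed(77, {
    for (r in seq_len(n_rep)) {
      beta <- rnorm(n)
      y <- matrix(rnorm(k * n, 0, rep(sds, n)), k) + rep(beta, each = k)
      m <- make_cq_matrix(28 - y)
      est2[r, ] <- normfinder(m)$values^2
    }
  })
  bias <- colMeans(est2) - sds^2
  se <- apply(est2, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(bias) < 3 * se))
  # and the total variance budget is conserved in expectation
  expect_equal(mean(rowSums(est2)), sum(sds^2),
               tolerance = 4 * sd(rowSums(est2)) / sqrt(n_rep) / sum(sds^2))
})

test_that("stability values are non-negative and ranks are valid
           fractional rankings", {
  for (seed in 1:5) {
    m <- random_cq_matrix(6, 10, seed = seed)
    lq <- to_log_quantities(m)
    for (res in list(genorm(lq), delta_ct_stability(m), bestkeeper(m),
                     normfinder(m))) {
      expect_true(all(res$values >= 0))
      expect_equal(sum(res$ranks), sum(seq_len(6)))
      expect_true(all(res$ranks >= 1 & res$ranks <= 6))
    }
  }
})

test_that("pairwise algorithms tolerate missing cells; sparse overlap errors", {
  m <- random_cq_matrix(4, 8, seed = 13)
  m$mean_cq[1, 1:2] <- NA
  m$mean_cq[2, 3] <- NA
  expect_silent(delta_ct_stability(m))
  expect_silent(genorm(to_log_quantities(m)))
  m$mean_cq[1, 1:6] <- NA
  expect_error(delta_ct_stability(m), "pairwise-complete")
})
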