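write_fixture_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_cq_table parses a long CSV, counting every row", {
  header <- "gene,sample,replicate,run,cq,role"
  rows <- expand.grid(gene = c("ga", "gb", "gc"), sample = c("s1", "s2"),
                      replicate = 1:3, stringsAsFactors = FALSE)
  lines <- c(header, sprintf("%s,%s,%d,run1,%.2f,sample",
                             rows$gene, rows$sample, rows$replicate,
                             20 + seq_len(nrow(rows)) / 10))
  tab <- read_cq_table(write_fixture_csv(lines))
  expect_s3_class(tab, "cq_table")
  expect_equal(nrow(tab$observations), 18)
  expect_setequal(unique(tab$observations$gene), c("ga", "gb", "gc"))
})

test_that("non-detects survive as missing; bad literals fail with the row", {
  lines <- c("gene,sample,replicate,run,cq,role",
             "ga,s1,1,run1,21.5,sample",
             "ga,s1,2,run1,ND,sample",
             "ga,s1,3,run1,,sample")
  tab <- read_cq_table(write_fixture_csv(lines))
  expect_equal(tab$observations$cq, c(21.5, NA, NA))

  bad <- c("gene,sample,replicate,run,cq,role",
           "ga,s1,1,run1,21.5,sample",
           "ga,s1,2,run1,abc,sample")
  expect_error(read_cq_table(write_fixture_csv(bad)), "abc.*row 2")
})

test_that("malformed headers and duplicate keys are rejected by name", {
  lines <- c("gene,sample,replicate,cq,role",  # no run column
             "ga,s1,1,21.5,sample")
  expect_error(read_cq_table(write_fixture_csv(lines)), "run")

  dup <- c("gene,sample,replicate,run,cq,role",
           "ga,s1,1,run1,21.5,sample",
           "ga,s1,1,run1,21.6,sample")
  expect_error(read_cq_table(write_fixture_csv(dup)), "duplicate.*ga, s1, 1")
})

test_that("cq_table validates ranges, roles and metadata coverage", {
  obs <- tibble::tibble(gene = "ga", sample = "s1", replicate = 1,
                        run = "r", cq = 41, role = "sample")
  expect_error(cq_table(obs), "<= 40")
  obs$cq <- 30
  obs$role <- "blank"
  expect_error(cq_table(obs), "unknown well role")
  obs$role <- "sample"
  expect_error(cq_table(obs, tibble::tibble(sample = "s2", group = "x")),
               "missing from sample_meta")
})

test_that("write then read round-trips a Cq table exactly", {
  sim <- simulate_cq_dataset(simulation_config(n_genes = 4, n_samples = 5,
                                               seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".csv")
  write_cq_table(sim$table, path, meta)
  back <- read_cq_table(path, meta)
  expect_equal(back$observations, sim$table$observations)
  expect_equal(back$sample_meta, sim$table$sample_meta)
})

test_that("dilution series reader orders points and flags short series", {
  lines <- c("gene,amount_ng,cq1,cq2,cq3",
             sprintf("ga,%g,%.2f,%.2f,%.2f", 10^(2:-3),
                     25 + 3.3 * (0:5), 25.1 + 3.3 * (0:5),
                     24.9 + 3.3 * (0:5)))
  series <- read_dilution_series(write_fixture_csv(lines))
  expect_equal(nrow(series), 6)
  expect_equal(series$amount, sort(series$amount, decreasing = TRUE))
  expect_length(series$cq_replicates[[1]], 3)

  dup <- c("gene,amount_ng,cq1", "ga,100,20", "ga,100,21", "ga,10,24")
  expect_error(read_dilution_series(write_fixture_csv(dup)),
               "duplicate dilution amount")

  neg <- c("gene,amount_ng,cq1", "ga,-1,20")
  expect_error(read_dilution_series(write_fixture_csv(neg)), "positive")

  short <- c("gene,amount_ng,cq1", "ga,100,20", "ga,10,23.3")
  expect_warning(s2 <- read_dilution_series(write_fixture_csv(short)),
                 "fewer than 3")
  expect_equal(attr(s2, "too_few_points"), "ga")
})

test_that("a 9-step ten-fold series from 1 pg to 100 ng reads as 9 points", {
  amounts <- 10^seq(-3, 2, length.out = 9)  # ng: 1 pg up to 100 ng
  lines <- c("gene,amount_ng,cq1",
             sprintf("ga,%.6g,%.3f", amounts, 20.09 - 3.25 * log10(amounts)))
  series <- read_dilution_series(write_fixture_csv(lines))
  expect_equal(nrow(series), 9)
  expect_equal(max(series$amount), 100)
  expect_equal(min(series$amount), 1e-3)
})

test_that("write_report emits per-algorithm, consensus and correlation CSVs
           that round-trip ranks exactly", {
  sim <- simulate_cq_dataset(simulation_config(seed = 3))
  report <- suppressMessages(rank_reference_genes(sim$table))
  dir <- withr::local_tempdir()
  paths <- write_report(report, dir, extra = list(seed = 3, max_cq = 35))
  expect_true(all(file.exists(file.path(
    dir, c("stability_genorm.csv", "stability_normfinder.csv",
           "stability_bestkeeper.csv", "stability_delta_ct.csv",
           "stability_reffinder.csv", "consensus.csv", "correlation.csv",
           "summary.json")))))
  for (res in report$results) {
    back <- readr::read_csv(
      file.path(dir, paste0("stability_", res$algorithm, ".csv")),
      show_col_types = FALSE)
    expect_equal(nrow(back), length(report$genes))
    expect_equal(back$rank, unname(res$ranks[back$gene]))
    expect_equal(back$value, unname(res$values[back$gene]))
  }
  cons <- readr::read_csv(file.path(dir, "consensus.csv"),
                          show_col_types = FALSE)
  expect_equal(cons$gene, report$final_order)
  expect_equal(cons$rank_sum, report$table$rank_sum)
  smry <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(smry$seed, 3)

  empty <- structure(list(genes = character(0)), class = "consensus_report")
  expect_error(write_report(empty, dir), "empty gene list")
})
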