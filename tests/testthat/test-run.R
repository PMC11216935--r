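sim_to_disk <- function(dir, cfg = synthetic_config(n_genomes = 4,
                                                    n_planted = 8,
                                                    n_decoys = 1),
                        seed = 9) {
  run_simulate(dir, seed = seed, config = cfg)
}

test_that("simulate writes gene, hit and manifest tables that read back", {
  dir <- withr::local_tempdir()
  sim <- sim_to_disk(dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genes.tsv", "hits.tsv", "manifest_genomes.tsv",
    "manifest_planted.tsv", "manifest_decoys.tsv",
    "manifest_hit_truth.tsv", "run.log"
  )))))
  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  expect_equal(genes, sim$genes)
})

test_that("census run writes the three tables and is deterministic", {
  dir <- withr::local_tempdir()
  sim_to_disk(dir)
  out1 <- file.path(dir, "out1"); out2 <- file.path(dir, "out2")
  res <- run_census(file.path(dir, "genes.tsv"), file.path(dir, "hits.tsv"),
                    out1)
  run_census(file.path(dir, "genes.tsv"), file.path(dir, "hits.tsv"), out2)
  tsvs <- c("architecture_table.tsv", "copy_number_table.tsv",
            "taxonomy_phylum.tsv")
  expect_true(all(file.exists(file.path(out1, tsvs))))
  for (f in tsvs) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  expect_s3_class(res$architecture, "pul_frequency_table")
  log <- readLines(file.path(out1, "run.log"))
  expect_true(any(grepl("md5=", log)))
  expect_true(any(grepl("param cutoff=1e-04", log)))
})

test_that("census of an absent domain yields empty tables, not an error", {
  dir <- withr::local_tempdir()
  sim_to_disk(dir)
  out <- file.path(dir, "out")
  expect_message(
    res <- run_census(file.path(dir, "genes.tsv"),
                      file.path(dir, "hits.tsv"), out,
                      target_domain = "BACON_2"),
    "BACON_2"
  )
  expect_equal(nrow(res$architecture), 0)
  expect_true(file.exists(file.path(out, "architecture_table.tsv")))
})

test_that("vicinity run reproduces the manifest's planted fraction", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_genomes = 5, n_planted = 9, n_decoys = 1)
  sim <- sim_to_disk(dir, cfg, seed = 14)
  out <- file.path(dir, "vout")
  scan <- run_vicinity(file.path(dir, "genes.tsv"),
                       file.path(dir, "hits.tsv"), out)
  expect_equal(scan$summary$fraction, 0.9) # 9 planted / 10 targets
  per_target <- readr::read_tsv(file.path(out, "vicinity_targets.tsv"),
                                comment = "#", show_col_types = FALSE)
  expect_equal(nrow(per_target), 10)
  expect_true(all(c("architecture_label", "susd_tier", "position_class")
                  %in% names(per_target)))
  summ <- readr::read_tsv(file.path(out, "vicinity_summary.tsv"),
                          comment = "#", show_col_types = FALSE)
  expect_equal(summ$n_pul_positive, 9)
})

test_that("a zero window finds nothing", {
  dir <- withr::local_tempdir()
  sim_to_disk(dir)
  scan <- run_vicinity(file.path(dir, "genes.tsv"),
                       file.path(dir, "hits.tsv"),
                       file.path(dir, "w0"), w = 0)
  expect_equal(scan$summary$n_pul_positive, 0L)
})

test_that("generalized markers replace the SusD definition", {
  genes <- make_genes("g01", 1:12)
  genes$ko[5] <- "K00001"
  hits <- hit_row(genes$gene_id[7], "DUF1735", 25, 140)
  dir <- withr::local_tempdir()
  write_gene_table(genes, file.path(dir, "genes.tsv"))
  write_domain_hits(hits, file.path(dir, "hits.tsv"))
  # default SusD marker: negative
  sc_default <- run_vicinity(file.path(dir, "genes.tsv"),
                             file.path(dir, "hits.tsv"),
                             file.path(dir, "d"))
  expect_equal(sc_default$summary$n_pul_positive, 0L)
  # K00001 as the identifying KO: detected at tier ID
  sc_marker <- run_vicinity(file.path(dir, "genes.tsv"),
                            file.path(dir, "hits.tsv"),
                            file.path(dir, "m"), marker_ko = "K00001")
  expect_equal(sc_marker$summary$n_pul_positive, 1L)
  expect_equal(sc_marker$results$susd_tier, "SusD-ID")
})

test_that("flat key:value config files parse with numeric coercion", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# a comment", "domain: BACON", "cutoff: 0.0001",
               "window: 5"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$domain, "BACON")
  expect_equal(cfg$cutoff, 1e-4)
  expect_equal(cfg$window, 5)
  bad <- withr::local_tempfile()
  writeLines("no separator here", bad)
  expect_error(read_run_config(bad), class = "pulcensus_format_error")
})

test_that("tidy, glance and autoplot expose scan results", {
  sim <- simulate_dataset(synthetic_config(n_genomes = 4, n_planted = 8,
                                           n_decoys = 1),
                          seed = 9)
  sc <- scan_vicinity(sim$genes, sim$hits)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), sc$summary$n_targets)
  gl <- glance(sc)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$window, 5L)
  p <- ggplot2::autoplot(sc)
  expect_s3_class(p, "ggplot")
  tab <- architecture_table(
    architectures(sim$genes, sim$hits, target_domain = "DUF1735"),
    min_n = 0
  )
  expect_s3_class(ggplot2::autoplot(tab), "ggplot")
})
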