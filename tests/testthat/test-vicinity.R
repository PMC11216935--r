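test_that("numbering step is the mode of index differences", {
  expect_equal(infer_step(c(5, 10, 15, 20, 25)), list(step = 5L, regular = TRUE))
  expect_equal(infer_step(1:4), list(step = 1L, regular = TRUE))
  # one gap: diffs {10,10,20,10} -> mode 10, not regular
  expect_equal(infer_step(c(10, 20, 30, 50, 60)),
               list(step = 10L, regular = FALSE))
  # tie between candidates (diffs {5,5,10,10}) breaks toward the smaller step
  expect_equal(infer_step(c(0, 5, 10, 20, 30))$step, 5L)
  expect_error(infer_step(7), class = "pulcensus_insufficient_data_error")
})

test_that("neighborhoods cover the window and truncate at genome edges", {
  genes <- make_genes("g01", seq(10, 110, by = 10)) # 11 genes
  target <- genes$gene_id[6]
  nb <- neighbors(genes, target, w = 5)
  expect_equal(nrow(nb), 10)
  expect_equal(nb$offset, setdiff(-5:5, 0))

  first <- genes$gene_id[1]
  nb_edge <- neighbors(genes, first, w = 5)
  expect_equal(nb_edge$offset, 1:5)

  expect_error(neighbors(genes, "g01:99999"),
               class = "pulcensus_lookup_error")
})

test_that("rank windows agree with brute force and with index arithmetic", {
  set.seed(202)
  for (rep in 1:60) {
    step <- sample(c(1L, 5L, 10L), 1)
    gap_rate <- sample(c(0, 0.1, 0.2), 1)
    genes <- random_genome("gX", sample(15:40, 1), step, gap_rate)
    target <- sample(genes$gene_id, 1)
    w <- sample(1:6, 1)
    nb <- neighbors(genes, target, w)
    expect_equal(sort(nb$gene_id), sort(oracle_neighbors(genes, target, w)))
    if (gap_rate == 0) {
      # regular genome: rank window == index arithmetic target +/- k*step
      t_idx <- genes$gene_index[genes$gene_id == target]
      by_index <- genes$gene_id[
        genes$gene_index %in% (t_idx + step * setdiff(-w:w, 0))
      ]
      expect_setequal(nb$gene_id, by_index)
    }
  }
})

test_that("SusD evidence tiers: KO beats domain beats name, else none", {
  ko_gene <- make_genes("g", 1, ko = "K21572",
                        annotation = "hypothetical protein")
  expect_equal(susd_evidence(ko_gene)$tier, "SusD-ID")

  d_gene <- make_genes("g", 2)
  d_hit <- hit_row(d_gene$gene_id, "SusD-like domain", 10, 400)
  expect_equal(susd_evidence(d_gene, d_hit)$tier, "SusD-D")

  n_gene <- make_genes("g", 3, annotation = "RagB/SusD family protein")
  ev <- susd_evidence(n_gene)
  expect_equal(ev$tier, "SusD-N")
  expect_false(is.na(ev$matched_text))

  plain <- make_genes("g", 4)
  expect_equal(susd_evidence(plain)$tier, "none")
})

test_that("adding the SusD KO upgrades and never downgrades a gene's tier", {
  base_genes <- list(
    make_genes("g", 1, annotation = "RagB/SusD family protein"),
    make_genes("g", 2),
    make_genes("g", 3, name = "susD homolog")
  )
  hits <- hit_row("g:00002", "RagB", 5, 300)
  rank_of <- function(t) match(t, c("SusD-ID", "SusD-D", "SusD-N", "none"))
  for (g in base_genes) {
    h <- hits[hits$gene_id == g$gene_id, ]
    before <- susd_evidence(g, h)$tier
    g$ko <- "K21572"
    after <- susd_evidence(g, h)$tier
    expect_equal(after, "SusD-ID")
    expect_lte(rank_of(after), rank_of(before))
  }
})

test_that("scan finds planted SusD and respects the window boundary", {
  genes <- make_genes("g01", 1:20)
  genes$ko[9] <- "K21572" # susD one gene upstream of the target at rank 10
  hits <- hit_row(genes$gene_id[10], "DUF1735", 25, 140)
  sc <- scan_vicinity(genes, hits, w = 5)
  expect_true(sc$results$pul_positive)
  expect_equal(sc$results$offset, -1L)
  expect_equal(sc$results$susd_tier, "SusD-ID")

  genes2 <- make_genes("g02", 1:20)
  genes2$ko[16] <- "K21572" # 6 genes downstream: outside +/-5
  hits2 <- hit_row(genes2$gene_id[10], "DUF1735", 25, 140)
  sc2 <- scan_vicinity(genes2, hits2, w = 5)
  expect_false(sc2$results$pul_positive)
  expect_true(scan_vicinity(genes2, hits2, w = 6)$results$pul_positive)
})

test_that("widening the window only ever adds PUL-positive targets", {
  set.seed(77)
  sim <- simulate_dataset(synthetic_config(n_genomes = 6, n_planted = 12,
                                           n_decoys = 2),
                          seed = 5)
  positives <- lapply(c(1, 3, 5, 7), function(w) {
    r <- scan_vicinity(sim$genes, sim$hits, w = w)$results
    r$target_gene_id[r$pul_positive]
  })
  for (i in seq_len(length(positives) - 1)) {
    expect_true(all(positives[[i]] %in% positives[[i + 1]]))
  }
})

test_that("ties among SusD neighbors: best tier, then closest, then upstream", {
  genes <- make_genes("g01", 1:11)
  # target at rank 6; name-evidence adjacent, KO-evidence farther away
  genes$annotation[5] <- "RagB/SusD family protein"
  genes$ko[9] <- "K21572"
  hits <- hit_row(genes$gene_id[6], "DUF1735", 25, 140)
  sc <- scan_vicinity(genes, hits, w = 5)
  expect_equal(sc$results$susd_tier, "SusD-ID") # tier wins over distance
  expect_equal(sc$results$offset, 3L)

  genes2 <- make_genes("g02", 1:11)
  genes2$ko[c(4, 8)] <- "K21572" # equal tier, equal |offset| 2
  hits2 <- hit_row(genes2$gene_id[6], "DUF1735", 25, 140)
  sc2 <- scan_vicinity(genes2, hits2, w = 5)
  expect_equal(sc2$results$offset, -2L) # upstream preferred
})

test_that("targets are genes with surviving target-domain hits only", {
  genes <- make_genes("g01", 1:10)
  hits <- make_hits(
    hit_row(genes$gene_id[3], "DUF1735", 25, 140, evalue = 1e-6),
    hit_row(genes$gene_id[5], "DUF1735", 25, 140, evalue = 2e-3), # fails
    hit_row(genes$gene_id[7], "BACON", 25, 140, evalue = 1e-6)
  )
  sc <- scan_vicinity(genes, hits, w = 5)
  expect_equal(sc$results$target_gene_id, genes$gene_id[3])
  expect_message(sc0 <- scan_vicinity(genes, hits,
                                      target_domain = "NoSuchDomain"),
                 "NoSuchDomain")
  expect_equal(nrow(sc0$results), 0)
})

test_that("positions downstream of susD classify as susE/F/G-like", {
  genes <- make_genes("g01", 1:15)
  genes$annotation[5] <- "SusC-like TonB-dependent transporter"
  genes$ko[6] <- "K21572" # susD; downstream = increasing rank
  susd <- genes$gene_id[6]
  expect_equal(classify_position(genes, genes$gene_id[7], susd), "susE-like")
  expect_equal(classify_position(genes, genes$gene_id[8], susd), "susF-like")
  expect_equal(classify_position(genes, genes$gene_id[9], susd), "susG-like")
  expect_equal(classify_position(genes, genes$gene_id[10], susd), "other")
  # upstream of the pair
  expect_equal(classify_position(genes, genes$gene_id[4], susd), "other")
  expect_error(classify_position(genes, genes$gene_id[7], NA_character_),
               class = "pulcensus_state_error")
})

test_that("susC on the high-index side flips the downstream direction", {
  genes <- make_genes("g01", 1:15)
  genes$annotation[7] <- "SusC-like TonB-dependent transporter"
  genes$ko[6] <- "K21572"
  susd <- genes$gene_id[6]
  expect_equal(classify_position(genes, genes$gene_id[5], susd), "susE-like")
  expect_equal(classify_position(genes, genes$gene_id[3], susd), "susG-like")
  expect_equal(classify_position(genes, genes$gene_id[8], susd), "other")
})

test_that("per-genome step models summarize a gene table", {
  genes <- dplyr::bind_rows(
    make_genes("g01", seq(5, 100, by = 5)),
    make_genes("g02", c(1:5, 7:10))
  )
  steps <- genome_steps(genes)
  expect_equal(steps$step[steps$genome_id == "g01"], 5L)
  expect_true(steps$regular[steps$genome_id == "g01"])
  expect_false(steps$regular[steps$genome_id == "g02"])
})
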