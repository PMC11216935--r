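# Synthetic KEGG-like genome generator with a ground-truth manifest.
# Everything the scanner and census must recover is *planted by counting*,
# not sampled: requested fractions are realized exactly, so downstream
# checks are equalities rather than statistical tests.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# split n into integer counts proportional to probs (largest-remainder)
alloc_counts <- function(n, probs) {
  probs <- probs / sum(probs)
  v <- n * probs
  base <- floor(v)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(v - base), seq_along(v))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generator settings for synthetic KEGG-like datasets
#'
#' Defaults emulate the statistical structure of the mined KEGG data: all
#' three locus-tag numbering dialects (steps 1, 5, 10) with occasional
#' gaps; susC/susD-anchored loci with the target-domain gene 1-3 genes
#' downstream of susD in the reported susE/F/G position mix (47/35/18%);
#' a planted co-localization rate of 45/46 targets (97.8%, the reported
#' rate); SusD evidence split 14% KO-identified (reported) with the
#' remainder split evenly between domain- and name-evidence; 84%
#' multimodular target proteins (reported); and E-values straddling the
#' 1e-4 cutoff, including hits exactly at it.
#'
#' @param n_genomes number of genomes.
#' @param genes_per_genome genes per genome.
#' @param steps locus-tag numbering steps, assigned cyclically so every
#'   dialect occurs.
#' @param gap_rate fraction of inter-gene positions where one index slot is
#'   skipped (a deleted/unannotated gene).
#' @param n_planted susC/D-anchored loci with a target gene inside the
#'   window.
#' @param n_decoys target genes with no SusD evidence within the window.
#' @param offset_mix named fractions over downstream offsets `"1"`, `"2"`,
#'   `"3"` (susE-, susF-, susG-like).
#' @param tier_mix named fractions over evidence tiers `SusD-ID`,
#'   `SusD-D`, `SusD-N`.
#' @param multimodular_frac fraction of target proteins given a C-terminal
#'   partner domain.
#' @param overlap_pair_rate fraction of target proteins whose target
#'   domain gets an overlapping DUF4973-style call.
#' @param second_copy_rate fraction of target proteins carrying a second
#'   target-domain copy.
#' @param phylum_mix named fractions of target-domain copies per phylum
#'   (names are marked synthetic).
#' @param n_noise_hits off-target domain hits with E-values straddling the
#'   cutoff.
#' @param n_failing_targets genes given a target-domain hit *above* the
#'   cutoff (must not become targets).
#' @param target_domain,w,cutoff analysis parameters the truth is planted
#'   against.
#' @return list of settings (class `pul_synth_config`).
#' @export
synthetic_config <- function(n_genomes = 12,
                             genes_per_genome = 60,
                             steps = c(1L, 5L, 10L),
                             gap_rate = 0.1,
                             n_planted = 45,
                             n_decoys = 1,
                             offset_mix = c("1" = 0.47, "2" = 0.35,
                                            "3" = 0.18),
                             tier_mix = c("SusD-ID" = 0.14,
                                          "SusD-D" = 0.43,
                                          "SusD-N" = 0.43),
                             multimodular_frac = 0.84,
                             overlap_pair_rate = 0.3,
                             second_copy_rate = 0.15,
                             phylum_mix = c("Bacteroidota (synthetic)" = 0.98,
                                            "Pseudophyla (synthetic)" = 0.02),
                             n_noise_hits = 30,
                             n_failing_targets = 3,
                             target_domain = "DUF1735",
                             w = PUL_WINDOW,
                             cutoff = PUL_EVALUE_CUTOFF) {
  structure(as.list(environment()), class = "pul_synth_config")
}

#' Generate a synthetic dataset with ground-truth manifest
#'
#' Deterministic for a given `(config, seed)`. Loci are laid out in
#' non-overlapping blocks spaced farther apart than the scan window, so
#' planted offsets and decoys are window-exact by construction (and
#' re-verified by brute force before returning).
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list of class `pul_synthetic`: `$genes`, `$hits` (the io-module
#'   table layouts) and `$manifest` (class `pul_manifest`) holding the
#'   planted truth: `$genomes` (step per genome), `$planted` (locus table
#'   with tier, offset and position class), `$decoys`, `$hit_truth`
#'   (per-hit should-survive flags), `$gene_map` (per-gene planted
#'   evidence tier, for the brute-force oracle), `$phylum_copies`.
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "pul_synth_config"))
  with_seed(seed, simulate_dataset_impl(config, seed))
}

simulate_dataset_impl <- function(cfg, seed) {
  w <- cfg$w
  spacing <- 2L * w + 4L
  locus_starts <- seq(3L, cfg$genes_per_genome - 6L, by = spacing)
  total_slots <- cfg$n_genomes * length(locus_starts)
  n_loci <- cfg$n_planted + cfg$n_decoys
  if (n_loci > total_slots) {
    stop_pulcensus(
      sprintf("infeasible config: %d loci requested but only %d slots (%d genomes x %d)",
              n_loci, total_slots, cfg$n_genomes, length(locus_starts)),
      "pulcensus_config_error"
    )
  }

  # genome skeletons: id, step, indices with gaps
  genomes <- tibble(
    genome_id = sprintf("g%02d", seq_len(cfg$n_genomes)),
    step = rep(as.integer(cfg$steps),
               length.out = cfg$n_genomes)
  )
  gene_rows <- vector("list", cfg$n_genomes)
  n_gaps_per_genome <- integer(cfg$n_genomes)
  for (i in seq_len(cfg$n_genomes)) {
    s <- genomes$step[i]
    n <- cfg$genes_per_genome
    n_gaps <- round(cfg$gap_rate * (n - 1))
    gap_pos <- if (n_gaps > 0) sample(seq_len(n - 1), n_gaps) else integer(0)
    incr <- rep(s, n - 1)
    incr[gap_pos] <- 2L * s
    idx <- s + c(0L, cumsum(incr))
    n_gaps_per_genome[i] <- n_gaps
    gene_rows[[i]] <- tibble(
      genome_id = genomes$genome_id[i],
      gene_index = idx,
      rank = seq_len(n)
    )
  }
  genes <- bind_rows(gene_rows) |>
    mutate(
      gene_id = make_gene_id(.data$genome_id, .data$gene_index),
      name = "hypothetical protein",
      ko = NA_character_,
      annotation = "hypothetical protein",
      kingdom = "Bacteria (synthetic)",
      phylum = NA_character_,
      species = paste0("Synthetica fictiva ", .data$genome_id)
    )
  genomes$n_genes <- cfg$genes_per_genome
  genomes$n_gaps <- n_gaps_per_genome

  # slot table: (genome, locus start rank) in deterministic order
  slots <- tidyr::expand_grid(
    genome_id = genomes$genome_id,
    start_rank = locus_starts
  )
  slots <- slots[seq_len(n_loci), ]
  is_decoy <- c(rep(FALSE, cfg$n_planted), rep(TRUE, cfg$n_decoys))

  # planted mixes, realized by counting
  d_values <- rep(as.integer(names(cfg$offset_mix)),
                  alloc_counts(cfg$n_planted, cfg$offset_mix))
  tiers <- rep(names(cfg$tier_mix),
               alloc_counts(cfg$n_planted, cfg$tier_mix))
  # interleave tiers across the offset sequence so combinations vary
  tiers <- tiers[order(seq_along(tiers) %% 3, seq_along(tiers))]

  gene_at <- function(genome, rank) {
    genes$gene_id[genes$genome_id == genome & genes$rank == rank]
  }

  planted <- list()
  decoys <- list()
  hits <- list()
  set_gene <- function(gid, field, value) {
    genes[[field]][genes$gene_id == gid] <<- value
  }

  susd_domain_strings <- c("SusD-like domain", "RagB")
  target_gene_ids <- character(0)
  k_planted <- 0
  for (j in seq_len(n_loci)) {
    genome <- slots$genome_id[j]
    start <- slots$start_rank[j]
    if (is_decoy[j]) {
      tgt <- gene_at(genome, start + 2L)
      decoys[[length(decoys) + 1]] <- tibble(target_gene_id = tgt)
      target_gene_ids <- c(target_gene_ids, tgt)
      next
    }
    k_planted <- k_planted + 1
    d <- d_values[k_planted]
    tier <- tiers[k_planted]
    susc <- gene_at(genome, start)
    susd <- gene_at(genome, start + 1L)
    tgt <- gene_at(genome, start + 1L + d)
    target_gene_ids <- c(target_gene_ids, tgt)

    set_gene(susc, "annotation", "SusC-like TonB-dependent transporter")
    set_gene(susc, "name", "susC homolog")
    if (tier == "SusD-ID") {
      set_gene(susd, "ko", "K21572")
      set_gene(susd, "annotation", "hypothetical protein")
    } else if (tier == "SusD-D") {
      dom <- susd_domain_strings[1 + (k_planted %% 2)]
      hits[[length(hits) + 1]] <- tibble(
        gene_id = susd, domain = dom,
        start = 30L, end = 480L, evalue = 1e-25, source = "synthetic"
      )
      set_gene(susd, "annotation", "outer membrane lipoprotein")
    } else {
      ann <- c("RagB/SusD family nutrient uptake protein",
               "SusD homolog, starch-binding")[1 + (k_planted %% 2)]
      set_gene(susd, "annotation", ann)
    }

    planted[[k_planted]] <- tibble(
      target_gene_id = tgt, susd_gene_id = susd, susc_gene_id = susc,
      d_downstream = d, offset = -d, tier = tier,
      position_class = c("susE-like", "susF-like", "susG-like")[d]
    )
  }
  planted <- bind_rows(planted)
  decoys <- if (length(decoys) > 0) bind_rows(decoys) else {
    tibble(target_gene_id = character(0))
  }

  # target-domain hits: all targets (planted + decoys) get a surviving hit;
  # subsets get an overlapping DUF4973, a second copy, a C-terminal partner
  n_tgt <- length(target_gene_ids)
  surviving_evs <- c(1e-30, 1e-12, 1e-6, cfg$cutoff) # boundary included
  partners <- c("LamG3", "DUF4361", "F5/8-typeC", "DUF5627", "GH18")
  n_mm <- round(cfg$multimodular_frac * n_tgt)
  n_ov <- round(cfg$overlap_pair_rate * n_tgt)
  n_2c <- round(cfg$second_copy_rate * n_tgt)
  mm_set <- seq_len(n_mm)
  ov_set <- ((seq_len(n_ov) + 2L - 1L) %% n_tgt) + 1L # rotated subset
  c2_set <- ((seq_len(n_2c) + 7L - 1L) %% n_tgt) + 1L
  for (t in seq_len(n_tgt)) {
    gid <- target_gene_ids[t]
    set_gene(gid, "annotation", "uncharacterized lipoprotein")
    hits[[length(hits) + 1]] <- tibble(
      gene_id = gid, domain = cfg$target_domain,
      start = 25L, end = 140L,
      evalue = surviving_evs[1 + (t %% length(surviving_evs))],
      source = "synthetic"
    )
    if (t %in% ov_set) {
      hits[[length(hits) + 1]] <- tibble(
        gene_id = gid, domain = "DUF4973",
        start = 30L, end = 145L, evalue = 1e-8, source = "synthetic"
      )
    }
    if (t %in% c2_set) {
      hits[[length(hits) + 1]] <- tibble(
        gene_id = gid, domain = cfg$target_domain,
        start = 160L, end = 275L, evalue = 1e-9, source = "synthetic"
      )
    }
    if (t %in% mm_set) {
      hits[[length(hits) + 1]] <- tibble(
        gene_id = gid, domain = partners[1 + (t %% length(partners))],
        start = 290L, end = 430L, evalue = 1e-15, source = "synthetic"
      )
    }
  }

  # decoy-ish noise: off-target hits straddling the cutoff, and
  # target-domain hits above the cutoff on filler genes
  filler <- setdiff(genes$gene_id, c(
    target_gene_ids, planted$susd_gene_id, planted$susc_gene_id
  ))
  noise_domains <- c("BACON", "GH16", "DUF4999", "LRR_5")
  noise_evs <- c(1e-6, 5e-5, cfg$cutoff, 2e-4, 1e-3)
  if (cfg$n_noise_hits > 0) {
    ng <- sample(filler, cfg$n_noise_hits, replace = FALSE)
    for (t in seq_len(cfg$n_noise_hits)) {
      hits[[length(hits) + 1]] <- tibble(
        gene_id = ng[t],
        domain = noise_domains[1 + (t %% length(noise_domains))],
        start = 10L, end = 120L,
        evalue = noise_evs[1 + (t %% length(noise_evs))],
        source = "synthetic"
      )
    }
    filler <- setdiff(filler, ng)
  }
  if (cfg$n_failing_targets > 0) {
    fg <- sample(filler, cfg$n_failing_targets)
    for (t in seq_len(cfg$n_failing_targets)) {
      hits[[length(hits) + 1]] <- tibble(
        gene_id = fg[t], domain = cfg$target_domain,
        start = 25L, end = 140L,
        evalue = cfg$cutoff * 10^t, # strictly above the cutoff
        source = "synthetic"
      )
    }
  }
  hits <- bind_rows(hits)

  # phylum planted at the gene level so the requested copy split is exact
  copies_per_target <- hits |>
    filter(.data$domain == cfg$target_domain,
           .data$evalue <= cfg$cutoff,
           .data$gene_id %in% target_gene_ids) |>
    count(.data$gene_id, name = "copies")
  total_copies <- sum(copies_per_target$copies)
  quota <- alloc_counts(total_copies, cfg$phylum_mix)
  phyla <- names(cfg$phylum_mix)
  ord <- order(-copies_per_target$copies, copies_per_target$gene_id)
  assigned <- rep(phyla[length(phyla)], nrow(copies_per_target))
  remaining <- quota
  for (pi in seq_along(phyla)[-length(phyla)]) {
    for (r in ord) {
      if (assigned[r] == phyla[length(phyla)] &&
          remaining[pi] >= copies_per_target$copies[r]) {
        assigned[r] <- phyla[pi]
        remaining[pi] <- remaining[pi] - copies_per_target$copies[r]
      }
      if (remaining[pi] == 0) break
    }
  }
  genes$phylum <- phyla[1] # genome baseline
  for (r in seq_len(nrow(copies_per_target))) {
    genes$phylum[genes$gene_id == copies_per_target$gene_id[r]] <- assigned[r]
  }
  phylum_copies <- copies_per_target |>
    mutate(phylum = assigned) |>
    group_by(.data$phylum) |>
    summarise(n_copies = sum(.data$copies), .groups = "drop")

  # sequences for genes with hits; lengths cover the farthest hit end
  max_end <- hits |>
    group_by(.data$gene_id) |>
    summarise(max_end = max(.data$end), .groups = "drop")
  genes <- genes |>
    left_join(max_end, by = "gene_id") |>
    mutate(protein_length = ifelse(is.na(.data$max_end), 250L,
                                   .data$max_end + 10L)) |>
    select(-"max_end")
  with_hits <- genes$gene_id %in% hits$gene_id
  genes$sequence <- NA_character_
  genes$sequence[with_hits] <- vapply(
    genes$protein_length[with_hits],
    function(len) paste(sample(AA_LETTERS, len, replace = TRUE),
                        collapse = ""),
    character(1)
  )

  genes <- genes |>
    select(all_of(GENE_TABLE_COLS)) |>
    arrange(.data$genome_id, .data$gene_index)
  hits <- hits |> arrange(.data$gene_id, .data$start, .data$domain)

  hit_truth <- hits |>
    mutate(should_survive = .data$evalue <= cfg$cutoff) |>
    select("gene_id", "domain", "evalue", "should_survive")

  gene_map <- genes |>
    select("gene_id", "genome_id", "gene_index") |>
    mutate(
      tier = ifelse(.data$gene_id %in% planted$susd_gene_id,
                    planted$tier[match(.data$gene_id,
                                       planted$susd_gene_id)],
                    "none"),
      is_target = .data$gene_id %in% target_gene_ids
    )

  manifest <- structure(
    list(
      seed = seed, config = cfg, genomes = genomes,
      planted = planted, decoys = decoys,
      hit_truth = hit_truth, gene_map = gene_map,
      phylum_copies = phylum_copies
    ),
    class = "pul_manifest"
  )

  verify_decoys(manifest)

  structure(list(genes = genes, hits = hits, manifest = manifest),
            class = "pul_synthetic")
}

# brute-force check that no decoy has SusD evidence within the window
verify_decoys <- function(manifest) {
  w <- manifest$config$w
  gm <- manifest$gene_map
  for (tgt in manifest$decoys$target_gene_id) {
    genome <- gm$genome_id[gm$gene_id == tgt]
    chrom <- gm[gm$genome_id == genome, ]
    chrom <- chrom[order(chrom$gene_index), ]
    pos <- which(chrom$gene_id == tgt)
    win <- setdiff(seq(max(1, pos - w), min(nrow(chrom), pos + w)), pos)
    if (any(chrom$tier[win] != "none")) {
      stop_pulcensus(
        paste0("internal: decoy ", tgt, " has SusD evidence in window"),
        "pulcensus_config_error"
      )
    }
  }
  invisible(manifest)
}

#' @export
print.pul_synthetic <- function(x, ...) {
  cat(sprintf(
    "<pul_synthetic> seed %d: %d genes / %d genomes, %d hits, %d planted loci + %d decoys\n",
    x$manifest$seed, nrow(x$genes), nrow(x$manifest$genomes),
    nrow(x$hits), nrow(x$manifest$planted), nrow(x$manifest$decoys)
  ))
  invisible(x)
}

#' Brute-force expected scan summary from a manifest
#'
#' Recomputes, by direct sort-rank-scan over the manifest's gene map, the
#' vicinity results the scanner must produce: an independent oracle that
#' shares no code with [scan_vicinity()].
#'
#' @param manifest a `pul_manifest`.
#' @param w window half-width.
#' @return list with `$results` (`target_gene_id`, `pul_positive`, `tier`,
#'   `offset`) and `$summary` (`n_targets`, `n_pul_positive`, `fraction`,
#'   tier counts).
#' @export
expected_scan <- function(manifest, w = manifest$config$w) {
  gm <- as.data.frame(manifest$gene_map)
  tier_rank <- function(tier) match(tier, TIER_LEVELS)
  targets <- gm$gene_id[gm$is_target]
  rows <- list()
  for (tgt in targets) {
    genome <- gm$genome_id[gm$gene_id == tgt]
    chrom <- gm[gm$genome_id == genome, ]
    chrom <- chrom[order(chrom$gene_index), ]
    pos <- which(chrom$gene_id == tgt)
    win <- setdiff(seq(max(1, pos - w), min(nrow(chrom), pos + w)), pos)
    cand <- data.frame(gene_id = chrom$gene_id[win],
                       tier = chrom$tier[win],
                       offset = win - pos)
    cand <- cand[cand$tier != "none", ]
    if (nrow(cand) == 0) {
      rows[[tgt]] <- data.frame(target_gene_id = tgt, pul_positive = FALSE,
                                tier = "none", offset = NA_integer_)
    } else {
      cand <- cand[order(tier_rank(cand$tier), abs(cand$offset),
                         cand$offset), ]
      rows[[tgt]] <- data.frame(target_gene_id = tgt, pul_positive = TRUE,
                                tier = cand$tier[1], offset = cand$offset[1])
    }
  }
  results <- as_tibble(do.call(rbind, rows))
  tier_counts <- table(factor(results$tier, levels = TIER_LEVELS))
  summary <- tibble(
    n_targets = nrow(results),
    n_pul_positive = sum(results$pul_positive),
    fraction = sum(results$pul_positive) / nrow(results)
  )
  for (tier in TIER_LEVELS) {
    summary[[paste0("n_", gsub("-", "_", tolower(tier)))]] <-
      as.integer(tier_counts[[tier]])
  }
  list(results = results, summary = summary)
}
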