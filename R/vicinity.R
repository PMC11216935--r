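# Gene-neighborhood analysis. KEGG locus tags number genes in steps of 1,
# 5 or 10, so "5 genes away" cannot be read off index arithmetic directly:
# the numbering step is inferred per genome and neighborhoods are taken
# over index *ranks*, which coincides with index arithmetic exactly on
# regularly numbered genomes.

TIER_LEVELS <- c("SusD-ID", "SusD-D", "SusD-N", "none")

#' Infer a genome's locus-tag numbering step
#'
#' The step is the mode of consecutive differences of the sorted gene
#' indices, ties broken toward the smaller candidate; the genome is
#' `regular` when every difference equals the step (no gaps, no mixed
#' numbering).
#'
#' @param indices integer vector of one genome's gene indices (any order).
#' @return list with `step` (positive integer) and `regular` (logical).
#' @export
#' @examples
#' infer_step(c(5, 10, 15, 20, 25))   # step 5, regular
#' infer_step(c(10, 20, 30, 50, 60))  # step 10, irregular (one gap)
infer_step <- function(indices) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) < 2) {
    stop_pulcensus("need at least 2 gene indices to infer a step",
                   "pulcensus_insufficient_data_error")
  }
  d <- diff(indices)
  tab <- table(d)
  best <- max(tab)
  candidates <- as.integer(names(tab)[tab == best])
  step <- min(candidates)
  list(step = step, regular = all(d == step))
}

#' Per-genome step models for a gene table
#'
#' @param genes gene tibble.
#' @return tibble: `genome_id`, `step`, `regular`, `n_genes`.
#' @export
genome_steps <- function(genes) {
  genes |>
    group_by(.data$genome_id) |>
    summarise(
      step = infer_step(.data$gene_index)$step,
      regular = infer_step(.data$gene_index)$regular,
      n_genes = n(),
      .groups = "drop"
    )
}

#' Genes within a rank window of a target gene
#'
#' Returns the up-to-`2w` genes of the target's genome whose rank distance
#' (after sorting that genome's indices) is between 1 and `w`; the window
#' truncates at genome edges. Ordered by signed offset from `-w` to `+w`,
#' target excluded.
#'
#' @param genes gene tibble.
#' @param target gene_id of the focal gene.
#' @param w window half-width in genes; default [PUL_WINDOW].
#' @return tibble: `gene_id`, `offset` (signed rank distance).
#' @export
neighbors <- function(genes, target, w = PUL_WINDOW) {
  stopifnot(w >= 0)
  row <- genes[genes$gene_id == target, ]
  if (nrow(row) == 0) {
    stop_pulcensus(paste0("unknown target gene: ", target),
                   "pulcensus_lookup_error")
  }
  chrom <- genes |>
    filter(.data$genome_id == row$genome_id[1]) |>
    arrange(.data$gene_index)
  pos <- which(chrom$gene_id == target)
  lo <- max(1, pos - w)
  hi <- min(nrow(chrom), pos + w)
  idx <- setdiff(seq(lo, hi), pos)
  tibble(gene_id = chrom$gene_id[idx], offset = idx - pos)
}

susd_tier_rank <- function(tier) match(tier, TIER_LEVELS)

#' SusD evidence tier of a single gene
#'
#' Applies the three-tier marker definition of [susd_marker()]: exact KO
#' match (`SusD-ID`) beats a domain-name match (`SusD-D`) beats a
#' name/annotation match (`SusD-N`). `matched_text` records the deciding
#' string.
#'
#' @param gene one-row gene tibble.
#' @param hits this gene's domain hits (any coordinates, any E-values;
#'   domain *names* are what is matched).
#' @param marker a [susd_marker()] definition.
#' @return list with `gene_id`, `tier`, `matched_text`.
#' @export
susd_evidence <- function(gene, hits = NULL, marker = susd_marker()) {
  stopifnot(nrow(gene) == 1)
  hit_domains <- if (is.null(hits)) character(0) else hits$domain
  ev <- susd_evidence_impl(
    ko = gene$ko, name = gene$name, annotation = gene$annotation,
    hit_domains = hit_domains, marker = marker
  )
  c(list(gene_id = gene$gene_id), ev)
}

susd_evidence_impl <- function(ko, name, annotation, hit_domains, marker) {
  if (!is.na(ko) && ko %in% marker$ko) {
    return(list(tier = "SusD-ID", matched_text = ko))
  }
  dom_match <- ci_contains(hit_domains, marker$domain_patterns)
  if (any(dom_match)) {
    return(list(tier = "SusD-D", matched_text = hit_domains[dom_match][1]))
  }
  for (field in c(name, annotation)) {
    if (!is.na(field) && ci_contains(field, marker$name_patterns)) {
      return(list(tier = "SusD-N",
                  matched_text = ci_first_match(field, marker$name_patterns)))
    }
  }
  list(tier = "none", matched_text = NA_character_)
}

# vectorized evidence over a whole gene table
susd_evidence_table <- function(genes, hits, marker = susd_marker()) {
  hit_domains <- split(hits$domain, hits$gene_id)
  purrr::pmap_dfr(
    list(genes$gene_id, genes$ko, genes$name, genes$annotation),
    function(gid, ko, name, ann) {
      ev <- susd_evidence_impl(ko, name, ann,
                               hit_domains[[gid]] %||% character(0), marker)
      tibble(gene_id = gid, tier = ev$tier, matched_text = ev$matched_text)
    }
  )
}

#' Scan gene neighborhoods for SusD evidence
#'
#' The vicinity analysis proper: every gene carrying at least one surviving
#' hit of `target_domain` is a target; its `±w`-gene neighborhood is
#' searched for SusD evidence, PUL membership is called when any neighbor
#' carries evidence, and positive targets are classified by their position
#' downstream of the susC/D pair. When several neighbors carry evidence the
#' best tier wins, then the smallest |offset|, then the upstream (negative
#' offset) gene.
#'
#' @param genes gene tibble.
#' @param hits domain-hit tibble.
#' @param target_domain domain defining targets (default `"DUF1735"`).
#' @param w window half-width in genes; default [PUL_WINDOW].
#' @param cutoff E-value cutoff applied to hits before target selection and
#'   domain-evidence matching; default [PUL_EVALUE_CUTOFF].
#' @param marker [susd_marker()] definition (swap it to scan for any other
#'   neighborhood marker).
#' @return object of class `pul_vicinity_scan`: list with `$results` (one
#'   row per target: `target_gene_id`, `genome_id`, `n_copies`,
#'   `susd_gene_id`, `susd_tier`, `offset`, `pul_positive`,
#'   `position_class`), `$summary` (one row: `n_targets`, `n_pul_positive`,
#'   `fraction`, one `n_<tier>` column per tier), `$params`.
#' @export
scan_vicinity <- function(genes, hits, target_domain = "DUF1735",
                          w = PUL_WINDOW, cutoff = PUL_EVALUE_CUTOFF,
                          marker = susd_marker()) {
  if (nrow(genes) == 0) {
    stop_pulcensus("empty gene table", "pulcensus_domain_error")
  }
  surviving <- filter_hits(hits, cutoff)
  target_hits <- surviving |> filter(.data$domain == target_domain)
  if (nrow(target_hits) == 0) {
    inform(paste0("no surviving hits of domain '", target_domain,
                  "' in dataset"))
  }
  copies <- target_hits |> count(.data$gene_id, name = "n_copies")
  evidence <- susd_evidence_table(genes, surviving, marker)

  results <- vector("list", nrow(copies))
  genes_by_genome <- split(genes, genes$genome_id)
  target_genome <- setNames(genes$genome_id, genes$gene_id)

  for (i in seq_len(nrow(copies))) {
    gid <- copies$gene_id[i]
    chrom <- genes_by_genome[[target_genome[[gid]]]] |>
      arrange(.data$gene_index)
    pos <- which(chrom$gene_id == gid)
    lo <- max(1, pos - w); hi <- min(nrow(chrom), pos + w)
    nb_idx <- setdiff(seq(lo, hi), pos)
    nb <- tibble(gene_id = chrom$gene_id[nb_idx], offset = nb_idx - pos) |>
      left_join(evidence, by = "gene_id") |>
      filter(.data$tier != "none")
    if (nrow(nb) > 0) {
      nb <- nb |>
        arrange(susd_tier_rank(.data$tier), abs(.data$offset), .data$offset)
      best <- nb[1, ]
      results[[i]] <- tibble(
        target_gene_id = gid,
        genome_id = target_genome[[gid]],
        susd_gene_id = best$gene_id,
        susd_tier = best$tier,
        offset = best$offset,
        pul_positive = TRUE
      )
    } else {
      results[[i]] <- tibble(
        target_gene_id = gid,
        genome_id = target_genome[[gid]],
        susd_gene_id = NA_character_,
        susd_tier = "none",
        offset = NA_integer_,
        pul_positive = FALSE
      )
    }
  }
  results <- bind_rows(results)
  if (nrow(results) == 0) {
    results <- tibble(
      target_gene_id = character(0), genome_id = character(0),
      susd_gene_id = character(0), susd_tier = character(0),
      offset = integer(0), pul_positive = logical(0)
    )
  }
  results <- results |>
    left_join(copies, by = c(target_gene_id = "gene_id")) |>
    mutate(window = w)

  results$position_class <- purrr::map_chr(seq_len(nrow(results)), function(i) {
    if (!results$pul_positive[i]) return("none")
    classify_position(genes, results$target_gene_id[i],
                      results$susd_gene_id[i])
  })

  tier_counts <- table(factor(results$susd_tier, levels = TIER_LEVELS))
  summary <- tibble(
    target_domain = target_domain,
    n_targets = nrow(results),
    n_pul_positive = sum(results$pul_positive),
    fraction = if (nrow(results) > 0) {
      sum(results$pul_positive) / nrow(results)
    } else {
      NA_real_
    }
  )
  for (tier in TIER_LEVELS) {
    summary[[paste0("n_", gsub("-", "_", tolower(tier)))]] <-
      as.integer(tier_counts[[tier]])
  }

  structure(
    list(
      results = results, summary = summary,
      params = list(target_domain = target_domain, w = w, cutoff = cutoff,
                    marker = marker)
    ),
    class = "pul_vicinity_scan"
  )
}

#' @export
print.pul_vicinity_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<pul_vicinity_scan> %s: %d targets, %d PUL-positive (%.1f%%), window +/-%d\n",
    s$target_domain, s$n_targets, s$n_pul_positive,
    ifelse(is.na(s$fraction), NA, 100 * s$fraction), x$params$w
  ))
  invisible(x)
}

#' Classify a PUL-positive target's position relative to susC/D
#'
#' By analogy with the starch utilization operon, the first, second and
#' third gene downstream of susD (moving away from the adjacent susC) are
#' the susE-, susF- and susG-like positions. "Downstream" is resolved by
#' locating a susC-like gene (name/annotation containing "SusC", or KO
#' `susc_ko`) among the two rank-neighbors of the susD gene and walking the
#' other way; without an adjacent susC the direction of increasing gene
#' index is taken as downstream. Targets upstream of the pair, or more
#' than three genes downstream, are `"other"`.
#'
#' @param genes gene tibble.
#' @param target_gene_id,susd_gene_id the target gene and its SusD
#'   neighbor (same genome).
#' @param susc_ko KO accession identifying susC (default `"K21573"`).
#' @return one of `"susE-like"`, `"susF-like"`, `"susG-like"`, `"other"`.
#' @export
classify_position <- function(genes, target_gene_id, susd_gene_id,
                              susc_ko = "K21573") {
  if (is.na(susd_gene_id)) {
    stop_pulcensus("classify_position() needs a PUL-positive result",
                   "pulcensus_state_error")
  }
  genome <- genes$genome_id[genes$gene_id == target_gene_id][1]
  chrom <- genes |>
    filter(.data$genome_id == genome) |>
    arrange(.data$gene_index)
  rt <- which(chrom$gene_id == target_gene_id)
  rs <- which(chrom$gene_id == susd_gene_id)
  if (length(rt) == 0 || length(rs) == 0) {
    stop_pulcensus("target or susD gene not found in genome",
                   "pulcensus_lookup_error")
  }

  is_susc <- function(r) {
    if (r < 1 || r > nrow(chrom)) return(FALSE)
    g <- chrom[r, ]
    (!is.na(g$ko) && g$ko %in% susc_ko) ||
      ci_contains(g$name, "SusC") || ci_contains(g$annotation, "SusC")
  }
  downstream_dir <- if (is_susc(rs - 1)) {
    1L
  } else if (is_susc(rs + 1)) {
    -1L
  } else {
    1L # fallback: increasing index
  }

  d <- (rt - rs) * downstream_dir
  if (d == 1) "susE-like"
  else if (d == 2) "susF-like"
  else if (d == 3) "susG-like"
  else "other"
}
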