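# Census arithmetic: frequency tables with half-away-from-zero percentages,
# fold-changes, per-genome copy numbers, and taxonomy rollups. Count modes
# (domain copies vs proteins vs genomes) are always labeled explicitly.

#' One-decimal percentage, rounded half away from zero
#'
#' @param n count (0 <= n <= total).
#' @param total positive total.
#' @return `100 * n / total`, rounded to one decimal.
#' @export
#' @examples
#' percentage(449, 1414) # 31.8
#' percentage(160, 775)  # 20.6
percentage <- function(n, total) {
  if (any(total <= 0)) {
    stop_pulcensus("percentage(): total must be positive",
                   "pulcensus_domain_error")
  }
  stopifnot(all(n >= 0), all(n <= total))
  round_half_away(100 * n / total, 1)
}

#' Fold change against a baseline count
#'
#' @param n count.
#' @param baseline positive baseline count.
#' @param decimals decimals to keep (half-away-from-zero).
#' @return rounded `n / baseline`.
#' @export
#' @examples
#' fold_change(775, 135, 1)  # 5.7
#' fold_change(4047, 135, 0) # 30
fold_change <- function(n, baseline, decimals = 1) {
  if (any(baseline <= 0)) {
    stop_pulcensus("fold_change(): baseline must be positive",
                   "pulcensus_domain_error")
  }
  round_half_away(n / baseline, decimals)
}

#' Build a frequency table from keyed counts
#'
#' Rows are sorted by count descending, ties by key; rows with `n < min_n`
#' are collapsed into a final `"Other (n <= min_n - 1)"` row, which is
#' pinned last regardless of its size (as census tables print it).
#'
#' @param keys character vector of observations (one element per counted
#'   unit), or a pre-counted tibble with columns `key`, `n`.
#' @param min_n collapse threshold; `NULL` or 0 disables collapsing.
#' @param count_mode label recording what one count means (`"proteins"`,
#'   `"domains"`, `"genomes"`).
#' @return tibble of class `pul_frequency_table` with columns `key`, `n`,
#'   `pct`; attributes `total` and `count_mode`.
#' @export
frequency_table <- function(keys, min_n = NULL, count_mode = "items") {
  counts <- if (is.data.frame(keys)) {
    as_tibble(keys)
  } else {
    if (length(keys) == 0) {
      stop_pulcensus("empty census", "pulcensus_domain_error")
    }
    tibble(key = as.character(keys)) |> count(.data$key, name = "n")
  }
  if (nrow(counts) == 0) {
    stop_pulcensus("empty census", "pulcensus_domain_error")
  }
  total <- sum(counts$n)
  counts <- counts |> arrange(dplyr::desc(.data$n), .data$key)
  if (!is.null(min_n) && min_n > 0 && any(counts$n < min_n)) {
    small <- counts |> filter(.data$n < min_n)
    counts <- counts |>
      filter(.data$n >= min_n) |>
      bind_rows(tibble(
        key = sprintf("Other (n <= %d)", as.integer(min_n) - 1L),
        n = sum(small$n)
      ))
  }
  out <- counts |> mutate(pct = percentage(.data$n, total))
  structure(out, total = total, count_mode = count_mode,
            class = c("pul_frequency_table", class(out)))
}

#' @export
print.pul_frequency_table <- function(x, ...) {
  cat(sprintf("# frequency table: %d %s total\n",
              attr(x, "total"), attr(x, "count_mode")))
  NextMethod()
}

#' Architecture frequency table
#'
#' Counts proteins per canonical architecture label. `total` counts
#' domain-bearing proteins (not domain copies).
#'
#' @param archs architecture tibble from [architectures()].
#' @param min_n collapse threshold (printed KEGG-style tables use 6, i.e.
#'   "Other (n <= 5)"; UniProt-style 21).
#' @return a [frequency_table()] keyed by label.
#' @export
architecture_table <- function(archs, min_n = 6) {
  labels <- archs$label[archs$label != ""]
  if (length(labels) == 0) {
    stop_pulcensus("empty census", "pulcensus_domain_error")
  }
  frequency_table(labels, min_n = min_n, count_mode = "proteins")
}

#' Per-genome copy-number table for a target domain
#'
#' For every genome with at least one surviving hit of `target_domain`:
#' the number of proteins carrying the domain, the number of domain
#' copies, and their ratio rounded to one decimal. Genomes without the
#' domain are excluded. The mean number of domain copies per
#' domain-carrying genome is attached as attribute `mean_per_genome`.
#'
#' @param genes gene tibble.
#' @param hits domain-hit tibble.
#' @param target_domain counted domain.
#' @param cutoff E-value cutoff; default [PUL_EVALUE_CUTOFF].
#' @return tibble: `genome_id`, `species`, `n_proteins`, `n_domains`,
#'   `mean_domains_per_protein`, sorted by `n_proteins` descending.
#' @export
copy_number_table <- function(genes, hits, target_domain,
                              cutoff = PUL_EVALUE_CUTOFF) {
  surviving <- filter_hits(hits, cutoff) |>
    filter(.data$domain == target_domain)
  species_of <- genes |> distinct(.data$genome_id, .data$species)
  tab <- surviving |>
    left_join(select(genes, "gene_id", "genome_id"), by = "gene_id") |>
    group_by(.data$genome_id) |>
    summarise(
      n_proteins = dplyr::n_distinct(.data$gene_id),
      n_domains = n(),
      .groups = "drop"
    ) |>
    mutate(mean_domains_per_protein =
             round_half_away(.data$n_domains / .data$n_proteins, 1)) |>
    left_join(species_of, by = "genome_id") |>
    select("genome_id", "species", "n_proteins", "n_domains",
           "mean_domains_per_protein") |>
    arrange(dplyr::desc(.data$n_proteins), .data$genome_id)
  structure(
    tab,
    mean_per_genome = if (nrow(tab) > 0) {
      round_half_away(sum(tab$n_domains) / nrow(tab), 1)
    } else {
      NA_real_
    }
  )
}

#' Taxonomic rollup of a target domain
#'
#' Counts domain copies (default), carrier genes, or carrier genomes per
#' taxonomic rank.
#'
#' @param genes gene tibble.
#' @param hits domain-hit tibble.
#' @param target_domain counted domain.
#' @param rank `"phylum"`, `"kingdom"` or `"species"` column of the gene
#'   table.
#' @param count what one count means: `"domains"` (copies), `"genes"`, or
#'   `"genomes"`.
#' @param cutoff E-value cutoff; default [PUL_EVALUE_CUTOFF].
#' @return a [frequency_table()] keyed by the rank's values.
#' @export
taxonomy_table <- function(genes, hits, target_domain,
                           rank = c("phylum", "kingdom", "species"),
                           count = c("domains", "genes", "genomes"),
                           cutoff = PUL_EVALUE_CUTOFF) {
  rank <- match.arg(rank)
  count <- match.arg(count)
  surviving <- filter_hits(hits, cutoff) |>
    filter(.data$domain == target_domain) |>
    left_join(select(genes, "gene_id", "genome_id",
                     taxon = all_of(rank)),
              by = "gene_id")
  keys <- switch(count,
    domains = surviving$taxon,
    genes = (surviving |> distinct(.data$gene_id, .keep_all = TRUE))$taxon,
    genomes = (surviving |> distinct(.data$genome_id, .keep_all = TRUE))$taxon
  )
  frequency_table(ifelse(is.na(keys), "(unclassified)", keys),
                  count_mode = count)
}

#' Write a frequency or copy-number table to TSV
#'
#' Emits the table with `# key=value` provenance comment lines (cutoff,
#' window, thresholds, totals) so every output records how it was made.
#'
#' @param x a `pul_frequency_table` or plain tibble.
#' @param path output file.
#' @param params named list of parameters for the comment header.
#' @return `path`, invisibly.
#' @export
write_census_table <- function(x, path, params = list()) {
  if (inherits(x, "pul_frequency_table")) {
    params <- c(params, list(total = attr(x, "total"),
                             count_mode = attr(x, "count_mode")))
  }
  write_tsv_commented(as_tibble(x), path, params)
}
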