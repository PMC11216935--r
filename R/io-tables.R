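# Tabular I/O: the TSV gene table and domain-hit table are the package's
# normalized on-disk form of KEGG/UniProt-derived annotation data.

GENE_TABLE_COLS <- c(
  "gene_id", "genome_id", "gene_index", "name", "ko", "annotation",
  "kingdom", "phylum", "species", "protein_length", "sequence"
)
GENE_TABLE_MANDATORY <- c(
  "gene_id", "genome_id", "gene_index", "name", "annotation", "phylum"
)
HIT_TABLE_COLS <- c("gene_id", "domain", "start", "end", "evalue", "source")

#' Read a TSV gene table
#'
#' Reads a tab-separated gene annotation table (UTF-8, header row) into a
#' tibble of gene records. The `gene_index` column may hold plain integers
#' or full locus tags ("BT_3987"); the longest trailing digit run is parsed
#' as the index. Blank `ko` / `sequence` cells become `NA`, never empty
#' strings. Lines starting with `#` are treated as provenance comments.
#'
#' @param path file to read.
#' @return tibble with columns `gene_id`, `genome_id`, `gene_index`,
#'   `name`, `ko`, `annotation`, `kingdom`, `phylum`, `species`,
#'   `protein_length`, `sequence`.
#' @seealso [read_domain_hits()], [write_gene_table()]
#' @export
read_gene_table <- function(path) {
  genes <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", na = character(), progress = FALSE
  )
  missing <- setdiff(GENE_TABLE_MANDATORY, names(genes))
  if (length(missing) > 0) {
    stop_pulcensus(
      paste0("gene table is missing mandatory column(s): ",
             paste(missing, collapse = ", ")),
      "pulcensus_format_error"
    )
  }
  for (col in setdiff(GENE_TABLE_COLS, names(genes))) genes[[col]] <- ""
  genes <- genes[GENE_TABLE_COLS]
  genes <- genes |>
    mutate(across(all_of(GENE_TABLE_COLS), ~ dplyr::na_if(.x, ""))) |>
    mutate(
      gene_index = locus_index(.data$gene_index),
      protein_length = suppressWarnings(as.integer(.data$protein_length))
    )
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    stop_pulcensus(
      paste0("duplicate gene_id(s): ", paste(unique(dup), collapse = ", ")),
      "pulcensus_duplicate_error"
    )
  }
  validate_genes(genes)
  genes
}

#' Read a TSV domain-hit table
#'
#' @param path file to read; columns `gene_id`, `domain`, `start`, `end`,
#'   `evalue`, `source` (1-based inclusive amino-acid coordinates).
#' @return tibble of domain hits.
#' @export
read_domain_hits <- function(path) {
  hits <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", na = character(), progress = FALSE
  )
  missing <- setdiff(c("gene_id", "domain", "evalue"), names(hits))
  if (length(missing) > 0) {
    stop_pulcensus(
      paste0("hit table is missing mandatory column(s): ",
             paste(missing, collapse = ", ")),
      "pulcensus_format_error"
    )
  }
  for (col in setdiff(HIT_TABLE_COLS, names(hits))) hits[[col]] <- ""
  hits <- hits[HIT_TABLE_COLS] |>
    mutate(across(all_of(HIT_TABLE_COLS), ~ dplyr::na_if(.x, ""))) |>
    mutate(
      domain = stringr::str_trim(.data$domain),
      start = suppressWarnings(as.integer(.data$start)),
      end = suppressWarnings(as.integer(.data$end)),
      evalue = suppressWarnings(as.numeric(.data$evalue))
    )
  validate_hits(hits)
  hits
}

#' Write gene / domain-hit tables
#'
#' Inverse of the readers: tab-separated, header row, `NA` written as empty
#' cells, gene indices written as plain integers. Optional `params` are
#' recorded as `# key=value` comment lines for provenance.
#'
#' @param genes,hits tibbles as returned by the readers.
#' @param path output file.
#' @param params named list recorded as comment header lines.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path, params = NULL) {
  write_tsv_commented(genes[intersect(GENE_TABLE_COLS, names(genes))],
                      path, params)
}

#' @rdname write_gene_table
#' @export
write_domain_hits <- function(hits, path, params = NULL) {
  write_tsv_commented(hits[intersect(HIT_TABLE_COLS, names(hits))],
                      path, params)
}

write_tsv_commented <- function(df, path, params = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(params) > 0) {
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, format, character(1))), con)
  }
  out <- df |> mutate(across(dplyr::everything(), ~ {
    x <- as.character(.x)
    ifelse(is.na(x), "", x)
  }))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

validate_genes <- function(genes) {
  bad_len <- !is.na(genes$sequence) & !is.na(genes$protein_length) &
    nchar(genes$sequence) != genes$protein_length
  if (any(bad_len)) {
    stop_pulcensus(
      paste0("sequence length disagrees with protein_length for: ",
             paste(genes$gene_id[bad_len], collapse = ", ")),
      "pulcensus_integrity_error"
    )
  }
  dup_idx <- genes |>
    filter(!is.na(.data$gene_index)) |>
    count(.data$genome_id, .data$gene_index) |>
    filter(.data$n > 1)
  if (nrow(dup_idx) > 0) {
    stop_pulcensus(
      paste0("gene_index not unique within genome(s): ",
             paste(unique(dup_idx$genome_id), collapse = ", ")),
      "pulcensus_integrity_error"
    )
  }
  invisible(genes)
}

validate_hits <- function(hits) {
  with_coord <- !is.na(hits$start) & !is.na(hits$end)
  bad <- with_coord & (hits$start < 1 | hits$end < hits$start)
  if (any(bad)) {
    stop_pulcensus(
      paste0("invalid hit coordinates for gene(s): ",
             paste(unique(hits$gene_id[bad]), collapse = ", ")),
      "pulcensus_format_error"
    )
  }
  if (any(!is.na(hits$evalue) & hits$evalue < 0)) {
    stop_pulcensus("negative E-values in hit table",
                   "pulcensus_format_error")
  }
  invisible(hits)
}

#' Bundle genes and hits into a cross-checked dataset
#'
#' Verifies that every domain hit points at a known gene and that hit
#' coordinates fit inside the owning protein, then returns a light
#' container used by the scan and census drivers.
#'
#' @param genes gene tibble ([read_gene_table()] layout).
#' @param hits domain-hit tibble ([read_domain_hits()] layout).
#' @param provenance free-text origin tag (fixture path, backend name).
#' @return object of class `pul_dataset`: list with `$genes`, `$hits`,
#'   `$provenance`.
#' @export
pul_dataset <- function(genes, hits, provenance = "in-memory") {
  genes <- as_tibble(genes)
  hits <- as_tibble(hits)
  orphan <- setdiff(hits$gene_id, genes$gene_id)
  if (length(orphan) > 0) {
    stop_pulcensus(
      paste0("domain hits reference unknown gene_id(s): ",
             paste(head(orphan, 5), collapse = ", ")),
      "pulcensus_integrity_error"
    )
  }
  lens <- setNames(genes$protein_length, genes$gene_id)
  plen <- lens[hits$gene_id]
  over <- !is.na(hits$end) & !is.na(plen) & hits$end > plen
  if (any(over)) {
    stop_pulcensus(
      paste0("hit end exceeds protein length for: ",
             paste(unique(hits$gene_id[over]), collapse = ", ")),
      "pulcensus_integrity_error"
    )
  }
  structure(list(genes = genes, hits = hits, provenance = provenance),
            class = "pul_dataset")
}

#' @export
print.pul_dataset <- function(x, ...) {
  cat(sprintf(
    "<pul_dataset> %d genes in %d genomes, %d domain hits (%s)\n",
    nrow(x$genes), dplyr::n_distinct(x$genes$genome_id), nrow(x$hits),
    x$provenance
  ))
  invisible(x)
}
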