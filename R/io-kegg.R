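# Parser for KEGG-style flat gene entries (ENTRY / NAME / ORTHOLOGY /
# ORGANISM / MOTIF / AASEQ blocks). This replaces a live fetch: the same
# layout is served by the REST interface, so entries captured to text files
# feed the pipeline offline.

#' Parse a KEGG-style flat gene entry
#'
#' Takes the raw text of one flat-file entry and returns the gene record
#' plus the domain hits listed in its MOTIF block. MOTIF hits carry no
#' coordinates or E-values (`NA`); a coordinate-bearing hit table, when
#' available, overrides them. The declared AASEQ length is checked against
#' the actual sequence.
#'
#' @param text a single string or character vector of lines.
#' @return list with `$gene` (one-row tibble, [read_gene_table()] layout)
#'   and `$hits` (tibble, [read_domain_hits()] layout).
#' @export
#' @examples
#' entry <- c(
#'   "ENTRY       BT_3987           CDS       bth",
#'   "NAME        chitinase-like protein",
#'   "ORTHOLOGY   K01183  chitinase",
#'   "ORGANISM    bth  Bacteroides thetaiotaomicron",
#'   "MOTIF       Pfam: DUF1735 Glyco_18",
#'   "AASEQ       12",
#'   "            MKTAYIAKQRQI",
#'   "///"
#' )
#' read_kegg_flatfile(entry)$gene$ko
read_kegg_flatfile <- function(text) {
  lines <- unlist(stringr::str_split(paste(text, collapse = "\n"), "\n"))
  lines <- lines[lines != "///"]
  keys <- stringr::str_match(lines, "^([A-Z_]+)\\s")[, 2]
  # continuation lines inherit the preceding keyword
  for (i in seq_along(keys)) {
    if (is.na(keys[i]) && i > 1) keys[i] <- keys[i - 1]
  }
  if (!"ENTRY" %in% keys) {
    stop_pulcensus("no ENTRY line in flat-file text",
                   "pulcensus_format_error")
  }
  body <- function(key) {
    stringr::str_trim(stringr::str_sub(lines[keys %in% key], 13))
  }

  entry_fields <- stringr::str_split_1(body("ENTRY")[1], "\\s+")
  locus_tag <- entry_fields[1]

  organism <- body("ORGANISM")
  genome_id <- if (length(organism) > 0) {
    stringr::str_split_1(organism[1], "\\s+")[1]
  } else {
    NA_character_
  }
  species <- if (length(organism) > 0) {
    stringr::str_trim(stringr::str_remove(organism[1], "^\\S+\\s*"))
  } else {
    NA_character_
  }

  orth <- body("ORTHOLOGY")
  ko <- if (length(orth) > 0) {
    stringr::str_extract(orth[1], "^K\\d{5}")
  } else {
    NA_character_
  }

  name <- paste(body("NAME"), collapse = " ")
  name <- stringr::str_remove(name, "^\\(GenBank\\)\\s*")
  if (name == "") name <- NA_character_

  definition <- paste(body("DEFINITION"), collapse = " ")
  if (definition == "") definition <- NA_character_

  aaseq_block <- body("AASEQ")
  sequence <- NA_character_
  declared_len <- NA_integer_
  if (length(aaseq_block) > 0) {
    declared_len <- suppressWarnings(as.integer(aaseq_block[1]))
    sequence <- paste(aaseq_block[-1], collapse = "")
    if (sequence == "") sequence <- NA_character_
    if (!is.na(sequence) && !is.na(declared_len) &&
        nchar(sequence) != declared_len) {
      stop_pulcensus(
        sprintf("AASEQ declares %d aa but sequence has %d for entry %s",
                declared_len, nchar(sequence), locus_tag),
        "pulcensus_integrity_error"
      )
    }
  }

  gene_id <- if (is.na(genome_id)) locus_tag else {
    paste0(genome_id, ":", locus_tag)
  }

  motif <- paste(body("MOTIF"), collapse = " ")
  motif <- stringr::str_remove(motif, "^Pfam:\\s*")
  domains <- stringr::str_split_1(stringr::str_trim(motif), "\\s+")
  domains <- domains[domains != ""]
  hits <- tibble(
    gene_id = rep(gene_id, length(domains)),
    domain = domains,
    start = NA_integer_, end = NA_integer_,
    evalue = NA_real_, source = "kegg-motif"
  )

  gene <- tibble(
    gene_id = gene_id,
    genome_id = genome_id %||% NA_character_,
    gene_index = locus_index(locus_tag),
    name = name,
    ko = ko,
    annotation = definition %||% name,
    kingdom = NA_character_, phylum = NA_character_,
    species = species,
    protein_length = if (!is.na(sequence)) nchar(sequence) else declared_len,
    sequence = sequence
  )
  list(gene = gene, hits = hits)
}

#' Read a signalp6-style tabular prediction file
#'
#' Plain key/value parse of the tab-separated prediction output: first
#' column is the sequence id, `class_col` names the predicted signal-peptide
#' class. No prediction logic lives here.
#'
#' @param path file to read; `#`-prefixed lines are skipped.
#' @param class_col column holding the predicted class (default
#'   `"Prediction"`).
#' @return tibble with `gene_id`, `signal_class`.
#' @export
read_signalp <- function(path, class_col = "Prediction") {
  tab <- readr::read_tsv(
    path, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!class_col %in% names(tab)) {
    stop_pulcensus(
      paste0("signalp table lacks column '", class_col, "'"),
      "pulcensus_format_error"
    )
  }
  tibble(gene_id = tab[[1]], signal_class = tab[[class_col]])
}
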