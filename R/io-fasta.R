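# FASTA export of protein sequences (signal-peptide prediction input and
# general interchange).

#' Write gene sequences to FASTA
#'
#' Headers are `>gene_id annotation`; sequences are wrapped at 60 columns.
#' Records without a sequence are skipped with a warning and excluded from
#' the returned count.
#'
#' @param genes gene tibble ([read_gene_table()] layout).
#' @param path output file.
#' @param width wrap column (60, the conventional FASTA line length).
#' @return number of records written, invisibly returned as a visible
#'   integer for scripting.
#' @export
write_fasta <- function(genes, path, width = 60) {
  stopifnot(width >= 1)
  has_seq <- !is.na(genes$sequence) & nchar(genes$sequence) > 0
  if (any(!has_seq)) {
    warn(sprintf("skipping %d record(s) without sequence: %s",
                 sum(!has_seq),
                 paste(head(genes$gene_id[!has_seq], 5), collapse = ", ")))
  }
  keep <- genes[has_seq, ]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(keep))) {
    ann <- keep$annotation[i]
    header <- if (is.na(ann) || ann == "") {
      paste0(">", keep$gene_id[i])
    } else {
      paste0(">", keep$gene_id[i], " ", ann)
    }
    writeLines(header, con)
    seq <- keep$sequence[i]
    starts <- seq(1, nchar(seq), by = width)
    writeLines(stringr::str_sub(seq, starts,
                                pmin(starts + width - 1, nchar(seq))), con)
  }
  nrow(keep)
}

#' Read a FASTA file into an id/sequence tibble
#'
#' Minimal reader used for round-trip checks and for loading sequence-only
#' inputs; the first whitespace-delimited token of each header is the id,
#' the remainder the description.
#'
#' @param path FASTA file.
#' @return tibble with `gene_id`, `annotation`, `sequence`.
#' @export
read_fasta <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[lines != ""]
  is_header <- stringr::str_starts(lines, ">")
  if (length(lines) > 0 && !is_header[1]) {
    stop_pulcensus("FASTA file does not start with a '>' header",
                   "pulcensus_format_error")
  }
  rec <- cumsum(is_header)
  headers <- stringr::str_sub(lines[is_header], 2)
  seqs <- vapply(
    split(lines[!is_header], rec[!is_header]),
    paste0, character(1), collapse = ""
  )
  # records with empty sequence blocks still occupy a rec slot
  seq_by_rec <- setNames(rep("", sum(is_header)),
                         as.character(seq_len(sum(is_header))))
  seq_by_rec[names(seqs)] <- seqs
  tibble(
    gene_id = stringr::str_extract(headers, "^\\S+"),
    annotation = dplyr::na_if(
      stringr::str_trim(stringr::str_remove(headers, "^\\S+\\s*")), ""),
    sequence = unname(seq_by_rec)
  )
}
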