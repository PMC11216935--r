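# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Printed census tables round `.5` upward in magnitude (31.75 -> 31.8),
#' not to even as base [round()] does. This helper implements that rule.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(31.75, 1) # 31.8, where round() gives 31.7 or 31.8
#' round_half_away(-2.5, 0)  # -3
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  # small relative nudge so values that are exactly representable halves
  # (e.g. 2.5) round up despite binary floating point
  sign(x) * floor(abs(x) * p + 0.5 + .Machine$double.eps * abs(x) * p) / p
}

#' Extract the numeric index from a locus tag
#'
#' KEGG-style gene identifiers embed the gene's position in the genome as a
#' numeric tail of the locus tag ("BT_3987" -> 3987, "BACOVA_02653" -> 2653,
#' "00150" -> 150). The longest trailing run of digits is taken.
#'
#' @param x character vector of locus tags or full gene ids.
#' @return integer vector; `NA` where no trailing digits exist.
#' @export
#' @examples
#' locus_index(c("BT_3987", "BACOVA_02653", "00150"))
locus_index <- function(x) {
  m <- stringr::str_match(as.character(x), "([0-9]+)$")[, 2]
  out <- suppressWarnings(as.integer(m))
  out
}

#' Split a gene id into genome id and locus tag
#'
#' Accepts both the ":" and "_" separator dialects ("bth:BT_3987",
#' "g01:00150", "g01_00150"). The first separator occurrence splits the id;
#' everything after it is the locus tag.
#'
#' @param gene_id character vector.
#' @return tibble with columns `genome_id`, `locus_tag`, `gene_index`.
#' @export
split_gene_id <- function(gene_id) {
  gene_id <- as.character(gene_id)
  has_colon <- stringr::str_detect(gene_id, ":")
  genome <- ifelse(has_colon,
    stringr::str_extract(gene_id, "^[^:]+"),
    stringr::str_extract(gene_id, "^[^_]+")
  )
  tag <- ifelse(has_colon,
    stringr::str_remove(gene_id, "^[^:]+:"),
    stringr::str_remove(gene_id, "^[^_]+_")
  )
  tibble(genome_id = genome, locus_tag = tag, gene_index = locus_index(tag))
}

#' Build a canonical gene id
#'
#' The write-side dialect is always `genome:tag`; indices are zero-padded to
#' `pad` digits so that lexical and numeric order agree in fixtures.
#' @param genome_id,index vectors of equal length.
#' @param pad minimum digit count for the index.
#' @return character vector of ids.
#' @export
make_gene_id <- function(genome_id, index, pad = 5) {
  sprintf("%s:%0*d", genome_id, as.integer(pad), as.integer(index))
}

# case-insensitive substring match after collapsing runs of whitespace
ci_contains <- function(haystack, needles) {
  if (length(haystack) == 0) return(logical(0))
  hay <- stringr::str_squish(tolower(ifelse(is.na(haystack), "", haystack)))
  out <- rep(FALSE, length(hay))
  for (nd in needles) {
    out <- out | stringr::str_detect(hay, stringr::fixed(tolower(nd)))
  }
  out
}

# first needle found in a string, for evidence reporting
ci_first_match <- function(haystack, needles) {
  hay <- stringr::str_squish(tolower(ifelse(is.na(haystack), "", haystack)))
  for (nd in needles) {
    if (stringr::str_detect(hay, stringr::fixed(tolower(nd)))) return(nd)
  }
  NA_character_
}

stop_pulcensus <- function(msg, class) {
  abort(msg, class = c(class, "pulcensus_error"))
}
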