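# Domain-architecture canonicalization. A protein's filtered hits are
# grouped into connected components of the pairwise-overlap relation;
# groups are rendered "A|B" and joined "A + B" into a canonical label.
# A designated overlapping pair (DUF1735/DUF4973 by default) collapses to
# "DUF1735*", matching how census tables fold those calls together.

#' Filter domain hits at an E-value cutoff
#'
#' Keeps exactly the hits with `evalue <= cutoff` (inclusive: a hit at the
#' cutoff survives), preserving input order. Hits without an E-value
#' (curated motif annotations) are kept by default since there is no score
#' to test.
#'
#' @param hits domain-hit tibble.
#' @param cutoff positive E-value threshold; default
#'   [PUL_EVALUE_CUTOFF] (`1e-4`).
#' @param keep_na keep hits whose `evalue` is `NA`?
#' @return filtered tibble, same columns.
#' @export
#' @examples
#' hits <- tibble::tibble(
#'   gene_id = "g", domain = c("A", "B", "C"),
#'   start = 1L, end = 10L, evalue = c(1e-6, 1e-4, 2e-4), source = "x"
#' )
#' filter_hits(hits, 1e-4)$domain # "A" "B": the boundary hit survives
filter_hits <- function(hits, cutoff = PUL_EVALUE_CUTOFF, keep_na = TRUE) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop_pulcensus("cutoff must be a single positive number",
                   "pulcensus_domain_error")
  }
  keep <- (!is.na(hits$evalue) & hits$evalue <= cutoff) |
    (keep_na & is.na(hits$evalue))
  hits[keep, ]
}

#' Deduplicate identical hits from different sources
#'
#' Hits sharing (`gene_id`, `domain`, `start`, `end`) are collapsed to the
#' one with the lowest E-value.
#'
#' @param hits domain-hit tibble.
#' @return deduplicated tibble.
#' @export
dedup_hits <- function(hits) {
  hits |>
    arrange(.data$evalue) |>
    distinct(.data$gene_id, .data$domain, .data$start, .data$end,
             .keep_all = TRUE)
}

#' Group one gene's domain hits by overlap
#'
#' Two hits are linked when their intersection covers at least
#' `min_overlap_frac` of the shorter hit; groups are the connected
#' components of that relation. Within a group hits are ordered by start
#' then domain name; groups are ordered by their minimum start.
#'
#' @param hits hits of a single gene, coordinates present.
#' @param min_overlap_frac fraction in (0, 1] of the shorter hit that must
#'   be covered; default 0.5 separates nested or duplicated calls from
#'   merely adjacent domains.
#' @return the hits, arranged, with an integer `group` column.
#' @export
group_overlaps <- function(hits, min_overlap_frac = 0.5) {
  stopifnot(min_overlap_frac > 0, min_overlap_frac <= 1)
  if (dplyr::n_distinct(hits$gene_id) > 1) {
    stop_pulcensus("group_overlaps() expects hits of a single gene",
                   "pulcensus_domain_error")
  }
  no_coord <- is.na(hits$start) | is.na(hits$end)
  if (any(no_coord)) {
    stop_pulcensus(
      paste0("hit(s) without coordinates: ",
             paste(hits$domain[no_coord], collapse = ", ")),
      "pulcensus_coordinate_error"
    )
  }
  n <- nrow(hits)
  if (n == 0) {
    return(mutate(hits, group = integer(0)))
  }
  # union-find over the pairwise overlap relation; n is small (domains per
  # protein), so the quadratic pass is fine
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      inter <- min(hits$end[i], hits$end[j]) -
        max(hits$start[i], hits$start[j]) + 1
      shorter <- min(hits$end[i] - hits$start[i],
                     hits$end[j] - hits$start[j]) + 1
      if (inter >= min_overlap_frac * shorter) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  hits$group <- comp
  # order groups by minimum start, members by start then name
  grp_min <- hits |>
    group_by(.data$group) |>
    summarise(min_start = min(.data$start), .groups = "drop") |>
    arrange(.data$min_start, .data$group)
  relabel <- setNames(seq_len(nrow(grp_min)), grp_min$group)
  hits$group <- unname(relabel[as.character(hits$group)])
  hits |> arrange(.data$group, .data$start, .data$domain)
}

#' Default domain-name alias map
#'
#' Maps verbose database motif names onto the short names used in census
#' tables (e.g. `Laminin_G_3` -> `LamG3`). Extend or replace it via the
#' `aliases` argument of [canonical_architecture()].
#'
#' @return named character vector, `from = to`.
#' @export
domain_aliases <- function() {
  c(
    Laminin_G_3 = "LamG3",
    F5_F8_type_C = "F5/8-typeC",
    Glyco_hydro_18 = "GH18",
    Glyco_18 = "GH18",
    Glyco_hydro_16 = "GH16",
    Glyco_hydro_43 = "GH43"
  )
}

render_group <- function(domains, star_merge, overlap_sep) {
  if (!is.null(star_merge)) {
    for (pair in star_merge) {
      if (length(domains) == 2 && setequal(domains, pair)) {
        return(paste0(pair[1], "*"))
      }
    }
  }
  paste(domains, collapse = overlap_sep)
}

#' Canonical domain architecture of one protein
#'
#' Filters, deduplicates and overlap-groups a gene's hits, then builds the
#' canonical architecture label: groups joined `" + "` in N- to C-terminal
#' order, overlapping domains inside a group joined `"|"` (or `"I"` with
#' `paper_style = TRUE`, the typesetting used in printed tables). A group
#' whose two domains form a `star_merge` pair is rendered as the pair's
#' primary name plus `"*"` (default: DUF1735/DUF4973 -> `"DUF1735*"`).
#' Repeated domains are kept per occurrence (`"DUF1735 + DUF1735"`).
#'
#' @param hits hits of one gene (a `gene_id` column is expected).
#' @param gene_id gene identifier; defaults to the one in `hits`.
#' @param cutoff E-value cutoff passed to [filter_hits()].
#' @param min_overlap_frac overlap fraction passed to [group_overlaps()].
#' @param star_merge list of 2-element character vectors; first element is
#'   the primary (rendered) domain. `NULL` disables merging.
#' @param aliases named character vector renaming domains before grouping.
#' @param paper_style render overlap groups with `"I"` instead of `"|"`.
#' @return object of class `pul_architecture`: list with `gene_id`,
#'   `groups` (list of character vectors), `label`, `n_terminal_domain`,
#'   `multimodular`, `n_domains` (filtered hit count, before merging).
#' @export
canonical_architecture <- function(hits, gene_id = NULL,
                                   cutoff = PUL_EVALUE_CUTOFF,
                                   min_overlap_frac = 0.5,
                                   star_merge = list(c("DUF1735", "DUF4973")),
                                   aliases = domain_aliases(),
                                   paper_style = FALSE) {
  gene_id <- gene_id %||%
    (if (nrow(hits) > 0) hits$gene_id[1] else NA_character_)
  hits <- filter_hits(hits, cutoff)
  hits <- dedup_hits(hits)
  if (length(aliases) > 0 && nrow(hits) > 0) {
    hit_alias <- aliases[hits$domain]
    hits$domain <- unname(ifelse(is.na(hit_alias), hits$domain, hit_alias))
  }
  overlap_sep <- if (paper_style) "I" else "|"
  if (nrow(hits) == 0) {
    return(structure(
      list(gene_id = gene_id, groups = list(), label = "",
           n_terminal_domain = NA_character_, multimodular = FALSE,
           n_domains = 0L),
      class = "pul_architecture"
    ))
  }
  grouped <- group_overlaps(hits, min_overlap_frac)
  groups <- unname(split(grouped$domain, grouped$group))
  label <- paste(
    vapply(groups, render_group, character(1),
           star_merge = star_merge, overlap_sep = overlap_sep),
    collapse = " + "
  )
  structure(
    list(
      gene_id = gene_id,
      groups = groups,
      label = label,
      n_terminal_domain = groups[[1]][1],
      multimodular = length(groups) >= 2,
      n_domains = nrow(grouped)
    ),
    class = "pul_architecture"
  )
}

#' @export
print.pul_architecture <- function(x, ...) {
  cat(sprintf("<pul_architecture> %s: %s\n", x$gene_id,
              if (x$label == "") "(no surviving hits)" else x$label))
  invisible(x)
}

#' Does the architecture start with a given domain?
#'
#' `TRUE` iff `domain` is a member of the N-terminal (first) overlap group.
#'
#' @param arch a `pul_architecture`.
#' @param domain domain name.
#' @return logical scalar.
#' @export
has_n_terminal <- function(arch, domain) {
  if (length(arch$groups) == 0) return(FALSE)
  domain %in% arch$groups[[1]]
}

#' Parse a canonical architecture label back into groups
#'
#' Inverse of the label grammar: `" + "` separates groups, `"|"` (or `"I"`)
#' separates overlapping domains within a group, and a trailing `"*"`
#' expands through `star_merge` to the full pair. Starred groups lose the
#' within-group order, so they come back in the pair's stated order.
#'
#' @param label canonical label string.
#' @param star_merge as in [canonical_architecture()].
#' @param paper_style label uses `"I"` as the overlap separator.
#' @return list of character vectors (one per group); empty list for `""`.
#' @export
parse_architecture_label <- function(label,
                                     star_merge = list(c("DUF1735", "DUF4973")),
                                     paper_style = FALSE) {
  if (is.na(label) || label == "") return(list())
  overlap_sep <- if (paper_style) "I" else "|"
  groups <- stringr::str_split_1(label, stringr::fixed(" + "))
  lapply(groups, function(g) {
    if (stringr::str_ends(g, stringr::fixed("*"))) {
      primary <- stringr::str_sub(g, 1, -2)
      for (pair in (star_merge %||% list())) {
        if (pair[1] == primary) return(pair)
      }
      return(primary)
    }
    stringr::str_split_1(g, stringr::fixed(overlap_sep))
  })
}

#' Architecture table for many genes
#'
#' Applies [canonical_architecture()] to every gene in `genes` and returns
#' one row per gene. Genes without any (surviving) hit of `target_domain`
#' can be excluded by setting it.
#'
#' @param genes gene tibble.
#' @param hits domain-hit tibble for those genes.
#' @param target_domain if non-`NULL`, keep only genes with at least one
#'   surviving hit of this domain (after aliasing).
#' @inheritParams canonical_architecture
#' @return tibble: `gene_id`, `label`, `n_groups`, `multimodular`,
#'   `n_terminal_domain`, `n_domains`.
#' @export
architectures <- function(genes, hits, target_domain = NULL,
                          cutoff = PUL_EVALUE_CUTOFF,
                          min_overlap_frac = 0.5,
                          star_merge = list(c("DUF1735", "DUF4973")),
                          aliases = domain_aliases(),
                          paper_style = FALSE) {
  split_hits <- split(hits, hits$gene_id)
  archs <- purrr::map(genes$gene_id, function(gid) {
    canonical_architecture(
      split_hits[[gid]] %||% hits[0, ], gene_id = gid,
      cutoff = cutoff, min_overlap_frac = min_overlap_frac,
      star_merge = star_merge, aliases = aliases, paper_style = paper_style
    )
  })
  out <- tibble(
    gene_id = genes$gene_id,
    label = vapply(archs, `[[`, character(1), "label"),
    n_groups = vapply(archs, function(a) length(a$groups), integer(1)),
    multimodular = vapply(archs, `[[`, logical(1), "multimodular"),
    n_terminal_domain = vapply(archs, `[[`, character(1),
                               "n_terminal_domain"),
    n_domains = vapply(archs, `[[`, integer(1), "n_domains")
  )
  if (!is.null(target_domain)) {
    target_alias <- unname(aliases[target_domain])
    target <- if (!is.na(target_alias)) target_alias else target_domain
    carries <- vapply(archs, function(a) {
      any(vapply(a$groups, function(g) target %in% g, logical(1)))
    }, logical(1))
    out <- out[carries, ]
  }
  out
}
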