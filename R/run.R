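# End-to-end drivers behind the command-line interface: census, vicinity
# and simulate runs over TSV inputs, with a plain-text run log. The
# subcommand wrapper lives in inst/exec/pulcensus; these functions are the
# tested surface.

#' Read a flat key:value run-configuration file
#'
#' One `key: value` per line; `#` comments and blank lines ignored. Values
#' that parse as numbers become numeric. Flags passed to the runners
#' override file values.
#'
#' @param path config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  kv <- stringr::str_match(lines, "^([^:]+):\\s*(.*)$")
  bad <- is.na(kv[, 1])
  if (any(bad)) {
    stop_pulcensus(paste0("malformed config line(s): ",
                          paste(lines[bad], collapse = "; ")),
                   "pulcensus_format_error")
  }
  vals <- as.list(kv[, 3])
  names(vals) <- stringr::str_trim(kv[, 2])
  lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
}

run_log <- function(out_dir, lines) {
  path <- file.path(out_dir, "run.log")
  stamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  readr::write_lines(paste0("[", stamp, "] ", lines), path, append = TRUE)
  invisible(path)
}

input_checksums <- function(paths) {
  sums <- tools::md5sum(paths)
  sprintf("input %s md5=%s", names(sums), unname(sums))
}

#' Run the domain census over TSV inputs
#'
#' Reads a gene table and a domain-hit table, computes canonical
#' architectures for every gene carrying the target domain, and writes the
#' architecture frequency, per-genome copy-number and taxonomy tables plus
#' a run log (parameters and input checksums). An unknown target domain
#' yields empty tables and a logged notice, not an error.
#'
#' @param genes_path,hits_path TSV inputs ([read_gene_table()] /
#'   [read_domain_hits()] layouts).
#' @param out_dir output directory (created if needed).
#' @param target_domain census domain (default `"DUF1735"`).
#' @param cutoff E-value cutoff.
#' @param min_overlap_frac overlap-group threshold.
#' @param min_n architecture-table collapse threshold.
#' @return invisibly, a list with the three tables.
#' @export
run_census <- function(genes_path, hits_path, out_dir,
                       target_domain = "DUF1735",
                       cutoff = PUL_EVALUE_CUTOFF,
                       min_overlap_frac = 0.5,
                       min_n = 6) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(target_domain = target_domain, cutoff = cutoff,
                 min_overlap_frac = min_overlap_frac, min_n = min_n)
  run_log(out_dir, c(
    "census run",
    sprintf("param %s=%s", names(params), unlist(params)),
    input_checksums(c(genes_path, hits_path))
  ))
  genes <- read_gene_table(genes_path)
  hits <- read_domain_hits(hits_path)
  pul_dataset(genes, hits, provenance = genes_path) # cross-checks

  archs <- architectures(genes, hits, target_domain = target_domain,
                         cutoff = cutoff,
                         min_overlap_frac = min_overlap_frac)
  empty <- nrow(archs) == 0
  if (empty) {
    inform(paste0("no genes carry domain '", target_domain,
                  "'; writing empty tables"))
    run_log(out_dir, paste0("notice: no genes carry domain ",
                            target_domain))
    arch_tab <- tibble(key = character(0), n = integer(0),
                       pct = numeric(0))
    copy_tab <- copy_number_table(genes, hits, target_domain, cutoff)
    tax_tab <- tibble(key = character(0), n = integer(0),
                      pct = numeric(0))
  } else {
    arch_tab <- architecture_table(archs, min_n = min_n)
    copy_tab <- copy_number_table(genes, hits, target_domain, cutoff)
    tax_tab <- taxonomy_table(genes, hits, target_domain,
                              rank = "phylum", count = "domains",
                              cutoff = cutoff)
  }
  write_census_table(arch_tab, file.path(out_dir, "architecture_table.tsv"),
                     params)
  write_tsv_commented(as_tibble(copy_tab),
                      file.path(out_dir, "copy_number_table.tsv"), params)
  write_census_table(tax_tab, file.path(out_dir, "taxonomy_phylum.tsv"),
                     params)
  run_log(out_dir, sprintf("genome processed: %s",
                           unique(genes$genome_id)))
  run_log(out_dir, "census done")
  invisible(list(architecture = arch_tab, copy_number = copy_tab,
                 taxonomy = tax_tab))
}

#' Run the vicinity scan over TSV inputs
#'
#' Serializes [scan_vicinity()]: one per-target row (`target_gene_id`,
#' architecture label, SusD neighbor, tier, offset, position class) plus a
#' one-row summary table. Alternative markers (`marker_ko`,
#' `marker_domains`, `marker_names`) replace the SusD string sets.
#'
#' @inheritParams run_census
#' @param w window half-width.
#' @param marker_ko,marker_domains,marker_names marker overrides; defaults
#'   are the SusD sets of [susd_marker()].
#' @return invisibly, the `pul_vicinity_scan`.
#' @export
run_vicinity <- function(genes_path, hits_path, out_dir,
                         target_domain = "DUF1735",
                         w = PUL_WINDOW,
                         cutoff = PUL_EVALUE_CUTOFF,
                         marker_ko = NULL, marker_domains = NULL,
                         marker_names = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  default <- susd_marker()
  marker <- susd_marker(
    ko = marker_ko %||% default$ko,
    domain_patterns = marker_domains %||% default$domain_patterns,
    name_patterns = marker_names %||% default$name_patterns
  )
  params <- list(target_domain = target_domain, w = w, cutoff = cutoff,
                 marker_ko = paste(marker$ko, collapse = ","))
  run_log(out_dir, c(
    "vicinity run",
    sprintf("param %s=%s", names(params), unlist(params)),
    input_checksums(c(genes_path, hits_path))
  ))
  genes <- read_gene_table(genes_path)
  hits <- read_domain_hits(hits_path)
  pul_dataset(genes, hits, provenance = genes_path)

  scan <- scan_vicinity(genes, hits, target_domain = target_domain,
                        w = w, cutoff = cutoff, marker = marker)
  archs <- architectures(genes, hits, target_domain = target_domain,
                         cutoff = cutoff)
  per_target <- scan$results |>
    left_join(select(archs, "gene_id", architecture_label = "label"),
              by = c(target_gene_id = "gene_id")) |>
    select("target_gene_id", "architecture_label", "susd_gene_id",
           "susd_tier", "offset", "position_class", "pul_positive",
           "n_copies")
  write_tsv_commented(per_target,
                      file.path(out_dir, "vicinity_targets.tsv"), params)
  write_tsv_commented(scan$summary,
                      file.path(out_dir, "vicinity_summary.tsv"), params)
  run_log(out_dir, sprintf("genome processed: %s",
                           unique(genes$genome_id)))
  run_log(out_dir, "vicinity done")
  invisible(scan)
}

#' Generate and serialize a synthetic dataset
#'
#' Writes the io-module TSV gene/domain tables plus the ground-truth
#' manifest as plain-text TSV sections (`manifest_*.tsv`).
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param config a [synthetic_config()].
#' @return invisibly, the `pul_synthetic` object.
#' @export
run_simulate <- function(out_dir, seed = 1L, config = synthetic_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(config, seed)
  params <- list(seed = seed, n_genomes = config$n_genomes,
                 n_planted = config$n_planted, n_decoys = config$n_decoys,
                 w = config$w, cutoff = config$cutoff)
  write_gene_table(sim$genes, file.path(out_dir, "genes.tsv"), params)
  write_domain_hits(sim$hits, file.path(out_dir, "hits.tsv"), params)
  m <- sim$manifest
  write_tsv_commented(m$genomes, file.path(out_dir, "manifest_genomes.tsv"),
                      params)
  write_tsv_commented(m$planted, file.path(out_dir, "manifest_planted.tsv"),
                      params)
  write_tsv_commented(m$decoys, file.path(out_dir, "manifest_decoys.tsv"),
                      params)
  write_tsv_commented(m$hit_truth,
                      file.path(out_dir, "manifest_hit_truth.tsv"), params)
  run_log(out_dir, c("simulate run",
                     sprintf("param %s=%s", names(params), unlist(params)),
                     "simulate done"))
  invisible(sim)
}
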