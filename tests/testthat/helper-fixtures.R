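# Shared fixture builders and independent oracles. Everything is built in
# code; no binary fixtures.

hit_row <- function(gene_id, domain, start, end, evalue = 1e-10,
                    source = "test") {
  tibble::tibble(gene_id = gene_id, domain = domain,
                 start = as.integer(start), end = as.integer(end),
                 evalue = evalue, source = source)
}

make_hits <- function(...) dplyr::bind_rows(...)

# minimal gene table: one genome, explicit indices
make_genes <- function(genome_id, indices, ko = NA_character_,
                       name = "hypothetical protein",
                       annotation = "hypothetical protein",
                       phylum = "TestPhylum") {
  n <- length(indices)
  tibble::tibble(
    gene_id = make_gene_id(genome_id, indices),
    genome_id = genome_id,
    gene_index = as.integer(indices),
    name = rep_len(name, n),
    ko = rep_len(ko, n),
    annotation = rep_len(annotation, n),
    kingdom = "Bacteria",
    phylum = rep_len(phylum, n),
    species = paste("Testus species", genome_id),
    protein_length = 500L,
    sequence = NA_character_
  )
}

# random single-gene hit sets for overlap property tests
random_hit_set <- function(n, gene_id = "g:1", max_pos = 400) {
  starts <- sample.int(max_pos, n, replace = TRUE)
  lens <- sample(10:150, n, replace = TRUE)
  tibble::tibble(
    gene_id = gene_id,
    domain = paste0("D", sample(1:8, n, replace = TRUE)),
    start = as.integer(starts),
    end = as.integer(starts + lens),
    evalue = 10^(-sample(5:30, n, replace = TRUE)),
    source = "test"
  )
}

# O(n^2) connected-components oracle over the pairwise overlap relation,
# via igraph: fully independent of the union-find in the package
oracle_overlap_groups <- function(hits, frac) {
  n <- nrow(hits)
  if (n == 0) return(integer(0))
  edges <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        inter <- min(hits$end[i], hits$end[j]) -
          max(hits$start[i], hits$start[j]) + 1
        shorter <- min(hits$end[i] - hits$start[i],
                       hits$end[j] - hits$start[j]) + 1
        if (inter >= frac * shorter) edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# brute-force rank-window neighborhood oracle
oracle_neighbors <- function(genes, target, w) {
  genome <- genes$genome_id[genes$gene_id == target]
  sub <- genes[genes$genome_id == genome, ]
  sub <- sub[order(sub$gene_index), ]
  pos <- which(sub$gene_id == target)
  ranks <- seq_len(nrow(sub))
  keep <- abs(ranks - pos) >= 1 & abs(ranks - pos) <= w
  sub$gene_id[keep][order(ranks[keep])]
}

# random gapped genome with a given numbering step
random_genome <- function(genome_id, n_genes, step, gap_rate) {
  incr <- rep(step, n_genes - 1)
  n_gaps <- rbinom(1, n_genes - 1, gap_rate)
  if (n_gaps > 0) {
    incr[sample.int(n_genes - 1, n_gaps)] <- 2L * step
  }
  make_genes(genome_id, step + c(0L, cumsum(incr)))
}
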