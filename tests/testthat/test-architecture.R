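test_that("E-value filter is inclusive at the cutoff and order-preserving", {
  hits <- hit_row("g:1", c("A", "B", "C"), 1, 10,
                  evalue = c(1e-6, 1e-4, 2e-4))
  kept <- filter_hits(hits, 1e-4)
  expect_equal(kept$domain, c("A", "B")) # boundary hit survives
  expect_equal(nrow(filter_hits(hits[0, ], 1e-4)), 0)
  expect_error(filter_hits(hits, -1), class = "pulcensus_domain_error")
})

test_that("E-value filter is idempotent and monotone in the cutoff", {
  set.seed(7)
  for (rep in 1:20) {
    hits <- random_hit_set(12)
    strict <- filter_hits(hits, 1e-4)
    loose <- filter_hits(hits, 1e-2)
    expect_true(all(strict$evalue %in% loose$evalue))
    expect_equal(filter_hits(strict, 1e-4), strict)
  }
})

test_that("overlap grouping links the overlapping pair, splits the distant one", {
  pair <- make_hits(
    hit_row("g:1", "DUF1735", 25, 140),
    hit_row("g:1", "DUF4973", 30, 145)
  )
  g <- group_overlaps(pair, 0.5)
  expect_equal(unique(g$group), 1L)
  expect_equal(g$domain, c("DUF1735", "DUF4973"))

  apart <- make_hits(
    hit_row("g:1", "DUF1735", 25, 140),
    hit_row("g:1", "LamG3", 160, 330)
  )
  g2 <- group_overlaps(apart, 0.5)
  expect_equal(g2$group, c(1L, 2L))

  nocoord <- hit_row("g:1", "DUF1735", NA, NA)
  expect_error(group_overlaps(nocoord),
               class = "pulcensus_coordinate_error")
})

test_that("overlap groups match the graph connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(1:15, 1)
    hits <- random_hit_set(n)
    frac <- sample(c(0.3, 0.5, 0.8), 1)
    ours <- group_overlaps(hits, frac)
    membership <- oracle_overlap_groups(hits, frac)
    # same partition: group ids may differ, the grouping must not
    key <- paste(hits$start, hits$end, hits$domain)
    ours_part <- split(paste(ours$start, ours$end, ours$domain), ours$group)
    oracle_part <- split(key, membership)
    norm <- function(p) sort(unname(vapply(p, function(g) {
      paste(sort(g), collapse = ";")
    }, character(1))))
    expect_equal(norm(ours_part), norm(oracle_part))
  }
})

test_that("canonical labels reproduce census-table forms", {
  rep2 <- make_hits(
    hit_row("g:1", "DUF1735", 25, 140),
    hit_row("g:1", "DUF1735", 150, 270),
    hit_row("g:1", "F5/8-typeC", 290, 430)
  )
  expect_equal(canonical_architecture(rep2)$label,
               "DUF1735 + DUF1735 + F5/8-typeC")

  starred <- make_hits(
    hit_row("g:2", "DUF4973", 20, 130),
    hit_row("g:2", "DUF1735", 25, 140),
    hit_row("g:2", "DUF4361", 200, 350)
  )
  arch <- canonical_architecture(starred)
  expect_equal(arch$label, "DUF1735* + DUF4361")
  expect_true(arch$multimodular)
  expect_equal(arch$n_domains, 3L)

  # without star merging the overlap separator is visible; paper style uses I
  plain <- canonical_architecture(starred, star_merge = NULL)
  expect_equal(plain$label, "DUF4973|DUF1735 + DUF4361")
  paperish <- canonical_architecture(starred, star_merge = NULL,
                                     paper_style = TRUE)
  expect_equal(paperish$label, "DUF4973IDUF1735 + DUF4361")

  empty <- canonical_architecture(hit_row("g:3", "A", 1, 50, evalue = 1),
                                  cutoff = 1e-4)
  expect_equal(empty$label, "")
  expect_false(empty$multimodular)
})

test_that("canonical architecture is invariant under hit order", {
  set.seed(33)
  for (rep in 1:25) {
    hits <- random_hit_set(sample(2:10, 1))
    ref <- canonical_architecture(hits)
    for (k in 1:3) {
      perm <- hits[sample.int(nrow(hits)), ]
      expect_equal(canonical_architecture(perm)$label, ref$label)
    }
  }
})

test_that("duplicate calls from different sources keep the best E-value", {
  dup <- make_hits(
    hit_row("g:1", "DUF1735", 25, 140, evalue = 1e-6, source = "a"),
    hit_row("g:1", "DUF1735", 25, 140, evalue = 1e-12, source = "b")
  )
  arch <- canonical_architecture(dup)
  expect_equal(arch$label, "DUF1735")
  expect_equal(arch$n_domains, 1L)
  expect_equal(dedup_hits(dup)$evalue, 1e-12)
})

test_that("N-terminal predicate reads the first overlap group", {
  starred <- canonical_architecture(make_hits(
    hit_row("g:1", "DUF4973", 20, 130),
    hit_row("g:1", "DUF1735", 25, 140),
    hit_row("g:1", "LamG3", 200, 350)
  ))
  expect_true(has_n_terminal(starred, "DUF1735"))

  internal <- canonical_architecture(make_hits(
    hit_row("g:2", "DUF4999", 10, 100),
    hit_row("g:2", "DUF1735", 120, 230),
    hit_row("g:2", "DUF1735", 250, 360),
    hit_row("g:2", "F5/8-typeC", 380, 500)
  ))
  expect_equal(internal$label, "DUF4999 + DUF1735 + DUF1735 + F5/8-typeC")
  expect_false(has_n_terminal(internal, "DUF1735"))

  empty <- canonical_architecture(hit_row("g:3", "A", 1, 5)[0, ])
  expect_false(has_n_terminal(empty, "DUF1735"))
})

test_that("label grammar round-trips through the parser", {
  set.seed(55)
  for (rep in 1:25) {
    hits <- random_hit_set(sample(1:10, 1))
    arch <- canonical_architecture(hits, star_merge = NULL)
    parsed <- parse_architecture_label(arch$label, star_merge = NULL)
    expect_equal(parsed, arch$groups)
  }
  # starred labels expand back to the pair as a set
  expect_setequal(
    parse_architecture_label("DUF1735* + LamG3")[[1]],
    c("DUF1735", "DUF4973")
  )
  expect_equal(parse_architecture_label(""), list())
})

test_that("alias map renames verbose motif names before grouping", {
  hits <- make_hits(
    hit_row("g:1", "DUF1735", 25, 140),
    hit_row("g:1", "Laminin_G_3", 160, 330)
  )
  expect_equal(canonical_architecture(hits)$label, "DUF1735 + LamG3")
})
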