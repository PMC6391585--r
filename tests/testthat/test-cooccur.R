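mention_row <- function(idx, kind, id) {
  tibble::tibble(doc_id = "d", sentence_index = idx, kind = kind,
                 entity_id = id, term = tolower(id), start = 0L, end = 1L)
}

test_that("counting propagates phenotype mentions upward with sentence-set semantics", {
  g <- read_obo(chain_fork_obo())
  # one sentence mentioning gene G and leaf C:3 counts the leaf and both ancestors
  m <- dplyr::bind_rows(mention_row(0L, "gene", "G:1"),
                        mention_row(0L, "phenotype", "C:3"))
  st <- count_cooccurrences(m, 1L, g)
  for (cls in c("C:3", "C:2", "C:1")) {
    expect_equal(st$pairs$n[st$pairs$class_id == cls], 1L)
    expect_equal(st$phenotypes$n[st$phenotypes$class_id == cls], 1L)
  }
  # repeated mentions inside one sentence still count once
  m2 <- dplyr::bind_rows(mention_row(0L, "gene", "G:1"),
                         dplyr::mutate(mention_row(0L, "gene", "G:1"), start = 5L),
                         mention_row(0L, "phenotype", "C:3"))
  st2 <- count_cooccurrences(m2, 1L, g)
  expect_equal(st2$genes$n, 1L)
  # unknown mention classes go to a warning channel, not silently dropped
  m3 <- dplyr::bind_rows(m, mention_row(0L, "phenotype", "Z:9"))
  expect_warning(st3 <- count_cooccurrences(m3, 1L, g), "Z:9")
  expect_equal(st3$unknown$class_id, "Z:9")
})

test_that("all four counters equal a brute-force recount on random corpora", {
  fx <- make_random_dag_obo(25L, 31L)
  g <- read_obo(fx$path)
  corp <- make_random_tagged_corpus(fx$ids, 120L, 8L, 32L)
  st <- count_cooccurrences(corp$mentions, corp$n_tot, g)
  bf <- bf_count_store(corp$sentences, fx$edges)
  expect_equal(st$n_tot, bf$n_tot)
  expect_equal(stats::setNames(st$genes$n, st$genes$gene_id),
               bf$n_g[sort(names(bf$n_g))])
  expect_equal(stats::setNames(st$phenotypes$n, st$phenotypes$class_id),
               bf$n_d[sort(names(bf$n_d))])
  got <- stats::setNames(st$pairs$n, paste(st$pairs$gene_id, st$pairs$class_id,
                                           sep = "\t"))
  expect_equal(got, bf$n_gd[sort(names(bf$n_gd))])
})

test_that("npmi matches analytic values and enforces its bounds", {
  expect_identical(npmi_value(10, 10, 10, 100), 1)     # perfect co-occurrence
  expect_identical(npmi_value(1, 10, 10, 100), 0)      # exact independence
  expect_equal(npmi_value(5, 50, 20, 1000), log(5) / log(200),
               tolerance = 1e-12)
  expect_identical(npmi_value(7, 7, 7, 7), 1)          # n_GD = n_tot limit
  expect_error(npmi_value(0, 5, 5, 10), "zero co-occurrences")
  # bounds over a grid of feasible counter combinations
  grid <- expand.grid(n_gd = 1:6, n_g = 1:8, n_d = 1:8)
  grid <- grid[grid$n_gd <= pmin(grid$n_g, grid$n_d), ]
  v <- npmi_value(grid$n_gd, grid$n_g, grid$n_d, 50)
  expect_true(all(v >= -1 - 1e-12 & v <= 1 + 1e-12))
  at_one <- abs(v - 1) < 1e-12
  expect_equal(at_one, grid$n_gd == grid$n_g & grid$n_gd == grid$n_d)
})

test_that("store-level npmi lookup errors for pairs that never co-occur", {
  g <- read_obo(chain_fork_obo())
  m <- dplyr::bind_rows(mention_row(0L, "gene", "G:1"),
                        mention_row(0L, "phenotype", "C:3"),
                        mention_row(1L, "gene", "G:2"))
  st <- count_cooccurrences(m, 2L, g)
  expect_equal(npmi(st, "G:1", "C:3"), 1)
  expect_error(npmi(st, "G:2", "C:3"), "undefined")
})

test_that("duplicating every sentence leaves all npmi values unchanged", {
  fx <- make_random_dag_obo(20L, 41L)
  g <- read_obo(fx$path)
  corp <- make_random_tagged_corpus(fx$ids, 80L, 6L, 42L)
  a1 <- score_associations(count_cooccurrences(corp$mentions, corp$n_tot, g))
  doubled <- dplyr::bind_rows(
    corp$mentions,
    dplyr::mutate(corp$mentions, sentence_index = sentence_index + corp$n_tot))
  a2 <- score_associations(count_cooccurrences(doubled, 2L * corp$n_tot, g))
  j <- dplyr::inner_join(a1, a2, by = c("gene_id", "phenotype_id"))
  expect_equal(nrow(j), nrow(a1))
  expect_equal(j$npmi.x, j$npmi.y, tolerance = 1e-12)
})

test_that("ranking keeps top k per gene with the documented tie-breaks", {
  assoc <- tibble::tibble(
    gene_id = "g",
    phenotype_id = sprintf("P:%03d", 1:100),
    n_g = 100L, n_d = 50L, n_gd = rep(c(10L, 5L), 50),
    npmi = rep(seq(0.99, 0.01, length.out = 50), each = 2))
  few <- rank_associations(assoc[1:3, ], k = 25L)
  expect_equal(few$rank, 1:3)
  top <- rank_associations(assoc, k = 25L)
  expect_equal(nrow(top), 25L)
  expect_true(all(diff(top$npmi) <= 1e-12))
  # equal npmi and equal n_gd: lexicographic phenotype id decides
  tie <- tibble::tibble(gene_id = "g", phenotype_id = c("P:b", "P:a"),
                        n_g = 10L, n_d = 10L, n_gd = 2L, npmi = 0.5)
  expect_equal(rank_associations(tie, 25L)$phenotype_id, c("P:a", "P:b"))
  # equal npmi: higher n_gd first
  tie2 <- tibble::tibble(gene_id = "g", phenotype_id = c("P:a", "P:b"),
                         n_g = 10L, n_d = 10L, n_gd = c(1L, 3L), npmi = 0.5)
  expect_equal(rank_associations(tie2, 25L)$phenotype_id, c("P:b", "P:a"))
  expect_error(rank_associations(assoc, 0), "positive")
})

test_that("association tables round-trip through the TSV writer", {
  assoc <- tibble::tibble(gene_id = c("g1", "g1"), phenotype_id = c("P:1", "P:2"),
                          n_g = 5L, n_d = c(4L, 2L), n_gd = c(3L, 1L),
                          npmi = c(0.8, 0.2), rank = 1:2)
  path <- tempfile(fileext = ".tsv")
  write_associations(assoc, path)
  back <- read_associations(path)
  expect_equal(back$npmi, assoc$npmi)
  expect_equal(back$rank, assoc$rank)
  expect_equal(back$n_gd, assoc$n_gd)
})
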