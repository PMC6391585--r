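test_that("OBO parsing records is_a chains, drops obsoletes, tolerates empty files", {
  path <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: A:1", "name: a", "is_a: B:1 ! b", "",
    "[Term]", "id: B:1", "name: b", "is_a: C:1", "",
    "[Term]", "id: C:1", "name: c", "",
    "[Term]", "id: D:1", "name: gone", "is_obsolete: true"), path)
  g <- read_obo(path)
  expect_setequal(g$classes$class_id, c("A:1", "B:1", "C:1"))
  expect_equal(g$edges$parent_id[g$edges$class_id == "A:1"], "B:1")
  expect_equal(g$edges$parent_id[g$edges$class_id == "B:1"], "C:1")
  expect_setequal(descendants(g, "C:1"), c("A:1", "B:1", "C:1"))
  expect_setequal(ancestors(g, "A:1"), c("A:1", "B:1", "C:1"))

  empty <- tempfile(fileext = ".obo")
  writeLines("format-version: 1.2", empty)
  g0 <- read_obo(empty)
  expect_equal(nrow(g0$classes), 0L)
})

test_that("equivalence lines merge ids into one node reachable from either id", {
  path <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: MP:0006082", "name: CNS inflammation", "",
    "[Term]", "id: MP:0001847", "name: Brain inflammation",
    "is_a: MP:0006082", "xref: HP:0002383", "",
    "[Term]", "id: HP:0002383", "name: Encephalitis"), path)
  g <- read_obo(path)
  expect_equal(resolve_class(g, "MP:0001847"), resolve_class(g, "HP:0002383"))
  merged <- resolve_class(g, "MP:0001847")
  expect_true(merged %in% descendants(g, "MP:0006082"))
  # merged node pools labels from both members
  ts <- term_sets(g)
  cns <- ts$term[ts$class_id == "MP:0006082"]
  expect_true(all(c("cns inflammation", "brain inflammation", "encephalitis")
                  %in% cns))
  # equivalence target without its own stanza still resolves
  path2 <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: MP:0001847", "name: Brain inflammation",
               "xref: HP:0002383"), path2)
  g2 <- read_obo(path2)
  expect_false(is.na(resolve_class(g2, "HP:0002383")))
})

test_that("malformed stanzas and is_a cycles are structural errors", {
  bad <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A:1", "name: a", "not a tag line"), bad)
  expect_error(read_obo(bad), "line 4")

  cyc <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A:1", "name: a", "is_a: B:1", "",
               "[Term]", "id: B:1", "name: b", "is_a: A:1"), cyc)
  expect_error(read_obo(cyc), "cyclic.*A:1.*B:1")

  g <- read_obo(chain_fork_obo())
  expect_error(descendants(g, "nope"), "unknown class")
})

test_that("descendants agree with the brute-force closure oracle on random DAGs", {
  for (seed in c(11L, 12L, 13L)) {
    n <- c(50L, 120L, 200L)[seed - 10L]
    fx <- make_random_dag_obo(n, seed)
    g <- read_obo(fx$path)
    for (id in sample(fx$ids, 12L)) {
      expect_equal(descendants(g, id), bf_descendants(fx$edges, id))
      expect_equal(ancestors(g, id), bf_ancestors(fx$edges, id))
    }
  }
})

test_that("term sets are monotone along every is_a edge and complete at the root", {
  fx <- make_random_dag_obo(60L, 21L, n_syn = 2L)
  g <- read_obo(fx$path)
  ts <- term_sets(g)
  by_class <- split(ts$term, ts$class_id)
  for (i in seq_len(nrow(g$edges))) {
    sub <- by_class[[g$edges$class_id[i]]]
    sup <- by_class[[g$edges$parent_id[i]]]
    expect_true(all(sub %in% sup))
  }
  # |Terms(root)| equals the union of every label/synonym string
  all_strings <- normalize_term(c(g$classes$label, g$synonyms$synonym))
  expect_equal(sort(by_class[["T:0001"]]), sort(unique(all_strings)))
  # a leaf with one label and no synonyms carries exactly that label
  path <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: L:1", "name: Sole Label"), path)
  expect_equal(term_sets(read_obo(path))$term, "sole label")
})

test_that("merging equivalences never changes descendant sets of unrelated classes", {
  base <- c(
    "[Term]", "id: A:1", "name: a", "",
    "[Term]", "id: A:2", "name: a2", "is_a: A:1", "",
    "[Term]", "id: B:1", "name: b", "",
    "[Term]", "id: B:2", "name: b2", "is_a: B:1")
  p1 <- tempfile(fileext = ".obo"); writeLines(base, p1)
  p2 <- tempfile(fileext = ".obo")
  writeLines(c(base, "", "[Term]", "id: A:3", "name: a3",
               "is_a: A:1", "equivalent_to: A:9"), p2)
  g1 <- read_obo(p1); g2 <- read_obo(p2)
  expect_equal(descendants(g1, "B:1"), descendants(g2, "B:1"))
  expect_equal(descendants(g1, "A:2"), descendants(g2, "A:2"))
})
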