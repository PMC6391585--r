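chain_profiles <- function() {
  # 4 entities over the chain+fork ontology
  tibble::tibble(entity_id = c("g1", "g2", "g3", "g4"),
                 class_id = c("C:3", "C:4", "C:5", "C:3"))
}

test_that("information content comes from ancestor-closed annotation frequencies", {
  g <- read_obo(chain_fork_obo())
  prof <- chain_profiles()
  ic <- information_content(prof, g)
  ic_of <- stats::setNames(ic$ic, ic$class_id)
  expect_equal(ic_of[["C:1"]], 0)                       # annotated to all
  expect_equal(ic_of[["C:4"]], -log(1 / 4))             # 1 of 4 entities
  expect_equal(ic_of[["C:2"]], -log(3 / 4))             # closure: g1,g2,g4
  expect_equal(ic_of[["C:3"]], -log(2 / 4))
  # brute-force per-class recount over a toy chain
  path <- tempfile(fileext = ".obo")
  writeLines(unlist(lapply(1:5, function(i) c(
    "[Term]", sprintf("id: K:%d", i), sprintf("name: k%d", i),
    if (i > 1) sprintf("is_a: K:%d", i - 1)))), path)
  gk <- read_obo(path)
  profk <- tibble::tibble(entity_id = c("e1", "e2", "e3"),
                          class_id = c("K:5", "K:3", "K:2"))
  ick <- information_content(profk, gk)
  edges_k <- data.frame(child = sprintf("K:%d", 2:5), parent = sprintf("K:%d", 1:4))
  for (i in 1:5) {
    cls_i <- sprintf("K:%d", i)
    ann <- vapply(split(profk$class_id, profk$entity_id), function(cls)
      any(vapply(cls, function(cc) cls_i %in% bf_ancestors(edges_k, cc),
                 logical(1))), logical(1))
    expect_equal(ick$ic[ick$class_id == cls_i], -log(sum(ann) / 3))
  }
  expect_error(information_content(tibble::tibble(entity_id = character(0),
                                                  class_id = character(0)), g),
               "empty")
})

test_that("Resnik similarity is the MICA information content", {
  g <- read_obo(chain_fork_obo())
  ic <- information_content(chain_profiles(), g)
  ic_of <- stats::setNames(ic$ic, ic$class_id)
  expect_equal(resnik("C:3", "C:3", ic, g), ic_of[["C:3"]])  # self
  expect_equal(resnik("C:3", "C:5", ic, g), 0)               # only root shared
  expect_equal(resnik("C:3", "C:4", ic, g), ic_of[["C:2"]])
  expect_error(resnik("C:3", "Z:1", ic, g), "unknown class")
})

test_that("Resnik and BMA match brute-force oracles on random DAGs", {
  fx <- make_random_dag_obo(30L, 71L)
  g <- read_obo(fx$path)
  profs <- withr::with_seed(72L, tibble::tibble(
    entity_id = rep(sprintf("e%02d", 1:20), each = 3),
    class_id = sample(fx$ids, 60L, replace = TRUE)))
  ic <- information_content(profs, g)
  ic_named <- stats::setNames(ic$ic, ic$class_id)
  cls <- unique(profs$class_id)
  pick <- withr::with_seed(73L, cbind(sample(cls, 40L, TRUE), sample(cls, 40L, TRUE)))
  got <- resnik(pick[, 1], pick[, 2], ic, g)
  want <- mapply(bf_resnik, pick[, 1], pick[, 2],
                 MoreArgs = list(edges = fx$edges, ic_named = ic_named))
  expect_equal(got, unname(want), tolerance = 1e-12)
  # resnik(c1,c2) <= min(IC(c1), IC(c2))
  expect_true(all(got <= pmin(ic_named[pick[, 1]], ic_named[pick[, 2]]) + 1e-12))

  by_ent <- split(profs$class_id, profs$entity_id)
  ents <- names(by_ent)
  for (i in seq_len(6)) {
    a <- by_ent[[ents[i]]]; b <- by_ent[[ents[i + 6]]]
    expect_equal(sim_bma(a, b, ic, g), bf_bma(unique(a), unique(b),
                                              fx$edges, ic_named),
                 tolerance = 1e-12)
    expect_equal(sim_bma(a, b, ic, g), sim_bma(b, a, ic, g), tolerance = 1e-12)
  }
})

test_that("BMA has the expected closed forms and monotonicity", {
  g <- read_obo(chain_fork_obo())
  ic <- information_content(chain_profiles(), g)
  ic_of <- stats::setNames(ic$ic, ic$class_id)
  # identical profiles: mean of per-class IC
  p <- c("C:3", "C:4")
  expect_equal(sim_bma(p, p, ic, g), mean(ic_of[p]))
  # singleton vs singleton reduces to plain Resnik
  expect_equal(sim_bma("C:3", "C:4", ic, g), resnik("C:3", "C:4", ic, g))
  # 3-vs-2 hand evaluation of the double sum
  p1 <- c("C:3", "C:4", "C:5"); p2 <- c("C:3", "C:5")
  simm <- outer(p1, p2, function(a, b) resnik(a, b, ic, g))
  hand <- (sum(apply(simm, 1, max)) + sum(apply(simm, 2, max))) / (3 + 2)
  expect_equal(sim_bma(p1, p2, ic, g), hand, tolerance = 1e-12)
  # adding an identical class to both profiles never decreases BMA
  base <- sim_bma("C:3", "C:5", ic, g)
  expect_gte(sim_bma(c("C:3", "C:4"), c("C:5", "C:4"), ic, g), base)
  # empty profile scores 0 with a warning
  expect_warning(z <- sim_bma(character(0), "C:3", ic, g), "empty")
  expect_equal(z, 0)
})

test_that("candidate ranking is deterministic and recovers identical profiles first", {
  g <- read_obo(chain_fork_obo())
  prof <- chain_profiles()
  ic <- information_content(prof, g)
  rk <- rank_candidates(c("C:4"), prof, ic, g)
  expect_equal(rk$entity_id[1], "g2")  # g2's profile is exactly {C:4}
  # all-root targets: every score 0, lexicographic order
  roots <- tibble::tibble(entity_id = c("b", "a", "c"), class_id = "C:1")
  rk0 <- rank_candidates(c("C:1"), roots, ic, g)
  expect_equal(rk0$score, rep(0, 3))
  expect_equal(rk0$entity_id, c("a", "b", "c"))
  # ordering matches an independent all-pairs BMA computation
  fx <- make_random_dag_obo(20L, 81L)
  gg <- read_obo(fx$path)
  profs <- withr::with_seed(82L, tibble::tibble(
    entity_id = rep(sprintf("t%02d", 1:10), each = 2),
    class_id = sample(fx$ids, 20L, replace = TRUE)))
  icg <- information_content(profs, gg)
  icn <- stats::setNames(icg$ic, icg$class_id)
  q <- c(fx$ids[3], fx$ids[7])
  rk2 <- rank_candidates(q, profs, icg, gg)
  want <- vapply(split(profs$class_id, profs$entity_id), function(cls)
    bf_bma(unique(q), unique(cls), fx$edges, icn), numeric(1))
  want <- sort(want, decreasing = TRUE)
  expect_equal(rk2$score, unname(want), tolerance = 1e-12)
})

test_that("rank-sum AUC equals exhaustive concordance counting", {
  perfect <- tibble::tibble(query_id = "q", entity_id = letters[1:6],
                            score = 6:1)
  truth <- tibble::tibble(query_id = "q", entity_id = c("a", "b"))
  expect_equal(roc_auc(perfect, truth)$auc, 1)
  tied <- dplyr::mutate(perfect, score = 1)
  expect_equal(roc_auc(tied, truth)$auc, 0.5)
  # 100 random score/label sets against the O(P*N) oracle
  withr::with_seed(91L, {
    for (r in 1:100) {
      n <- sample(6:20, 1)
      score <- sample(round(stats::runif(n), 2), n)  # duplicates force ties
      label <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(label)) label[1] <- TRUE
      if (all(label)) label[n] <- FALSE
      rk <- tibble::tibble(query_id = "q", entity_id = as.character(seq_len(n)),
                           score = score)
      tr <- tibble::tibble(query_id = "q",
                           entity_id = as.character(which(label)))
      ev <- roc_auc(rk, tr)
      expect_equal(ev$auc, bf_auc(score, label), tolerance = 1e-12)
      # complement property: inverting labels flips the AUC
      ev_inv <- roc_auc(rk, tibble::tibble(
        query_id = "q", entity_id = as.character(which(!label))))
      expect_equal(ev$auc, 1 - ev_inv$auc, tolerance = 1e-12)
    }
  })
})

test_that("queries without positives are excluded with a warning; macro mode averages", {
  rk <- dplyr::bind_rows(
    tibble::tibble(query_id = "q1", entity_id = c("a", "b"), score = c(2, 1)),
    tibble::tibble(query_id = "q2", entity_id = c("a", "b"), score = c(1, 2)))
  tr <- tibble::tibble(query_id = c("q1", "q2"), entity_id = c("a", "a"))
  micro <- roc_auc(rk, tr)
  macro <- roc_auc(rk, tr, mode = "macro")
  expect_equal(macro$auc, mean(c(1, 0)))
  expect_equal(micro$n_queries, 2L)
  tr1 <- tibble::tibble(query_id = "q1", entity_id = "a")
  expect_warning(ev <- roc_auc(rk, tr1), "excluded")
  expect_equal(ev$n_queries, 1L)
  # tidiers expose the evaluation as tibbles
  expect_equal(glance(micro)$auc, micro$auc)
  expect_equal(nrow(tidy(micro)), 2L)
})
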