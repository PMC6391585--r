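# Independent brute-force oracles and random fixtures. Everything here is
# deliberately written in plain base R loops, independent of the package's
# dplyr/join implementation paths.

# --- random rooted DAG as OBO text ------------------------------------------
# Returns list(path, ids, edges) where edges is a plain data.frame
# (child, parent) read back from the raw OBO lines, independent of read_obo.
make_random_dag_obo <- function(n, seed, branching = 2L, n_syn = 1L) {
  withr::with_seed(seed, {
    ids <- sprintf("T:%04d", seq_len(n))
    lines <- c("format-version: 1.2")
    for (i in seq_len(n)) {
      lines <- c(lines, "", "[Term]", paste0("id: ", ids[i]),
                 paste0("name: label ", i, " node"))
      if (n_syn > 0) {
        lines <- c(lines, sprintf('synonym: "syn %d variant %d" EXACT []',
                                  i, seq_len(n_syn)))
      }
      if (i > 1L) {
        k <- sample.int(min(branching, i - 1L), 1L)
        for (p in sort(sample.int(i - 1L, k))) {
          lines <- c(lines, paste0("is_a: ", ids[p]))
        }
      }
    }
    path <- tempfile(fileext = ".obo")
    writeLines(lines, path)
    ch <- character(0); pa <- character(0); cur <- NA_character_
    for (ln in lines) {
      if (startsWith(ln, "id: ")) cur <- sub("^id: ", "", ln)
      if (startsWith(ln, "is_a: ")) {
        ch <- c(ch, cur); pa <- c(pa, sub("^is_a: ", "", ln))
      }
    }
    list(path = path, ids = ids, edges = data.frame(child = ch, parent = pa))
  })
}

# fixed point of one-step parent expansion (reflexive ancestor closure)
bf_ancestors <- function(edges, id) {
  out <- id
  repeat {
    nxt <- unique(c(out, edges$parent[edges$child %in% out]))
    if (length(nxt) == length(out)) return(sort(out))
    out <- nxt
  }
}

bf_descendants <- function(edges, id) {
  out <- id
  repeat {
    nxt <- unique(c(out, edges$child[edges$parent %in% out]))
    if (length(nxt) == length(out)) return(sort(out))
    out <- nxt
  }
}

# --- brute-force co-occurrence recount --------------------------------------
# sentences: list of list(genes = chr, phenos = chr); edges for propagation.
# Materializes the propagated class set per sentence and tallies with table().
bf_count_store <- function(sentences, edges) {
  n_g <- list(); n_d <- list(); n_gd <- list()
  for (s in sentences) {
    gs <- unique(s$genes)
    ps <- unique(unlist(lapply(unique(s$phenos), bf_ancestors, edges = edges)))
    for (g in gs) n_g[[g]] <- (n_g[[g]] %||% 0L) + 1L
    for (p in ps) n_d[[p]] <- (n_d[[p]] %||% 0L) + 1L
    for (g in gs) for (p in ps) {
      key <- paste(g, p, sep = "\t")
      n_gd[[key]] <- (n_gd[[key]] %||% 0L) + 1L
    }
  }
  list(n_tot = length(sentences), n_g = unlist(n_g), n_d = unlist(n_d),
       n_gd = unlist(n_gd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bf_npmi <- function(n_gd, n_g, n_d, n_tot) {
  if (n_gd == n_tot) return(1)
  log(n_gd * n_tot / (n_g * n_d)) / (-log(n_gd / n_tot))
}

# random tagged corpus over a DAG: returns list(mentions tibble, n_tot,
# sentences list for the oracle)
make_random_tagged_corpus <- function(ids, n_sentences, n_genes, seed) {
  withr::with_seed(seed, {
    genes <- sprintf("G:%03d", seq_len(n_genes))
    sent <- vector("list", n_sentences)
    rows <- list()
    for (i in seq_len(n_sentences)) {
      gs <- sample(genes, stats::rpois(1, 1.2), replace = TRUE)
      ps <- sample(ids, stats::rpois(1, 1.2), replace = TRUE)
      sent[[i]] <- list(genes = gs, phenos = ps)
      if (length(gs) || length(ps)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          doc_id = "d", sentence_index = i - 1L,
          kind = c(rep("gene", length(gs)), rep("phenotype", length(ps))),
          entity_id = c(gs, ps),
          term = tolower(c(gs, ps)), start = 0L, end = 1L)
      }
    }
    list(mentions = dplyr::bind_rows(rows), n_tot = n_sentences,
         sentences = sent)
  })
}

# --- brute-force Resnik / BMA / AUC -----------------------------------------
bf_resnik <- function(c1, c2, edges, ic_named) {
  common <- intersect(bf_ancestors(edges, c1), bf_ancestors(edges, c2))
  common <- intersect(common, names(ic_named))
  if (!length(common)) return(0)
  max(ic_named[common])
}

bf_bma <- function(p1, p2, edges, ic_named) {
  m <- length(p1); n <- length(p2)
  simm <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    simm[i, j] <- bf_resnik(p1[i], p2[j], edges, ic_named)
  }
  (sum(apply(simm, 1, max)) + sum(apply(simm, 2, max))) / (m + n)
}

# exhaustive pairwise-concordance AUC with 0.5 per tie
bf_auc <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# tiny in-code ontology used across unit tests: a chain with a fork
#        C:1 (root)
#        /        \
#      C:2        C:5
#     /   \
#   C:3   C:4
chain_fork_obo <- function() {
  path <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: C:1", "name: root finding", "",
    "[Term]", "id: C:2", "name: mid finding",
    'synonym: "middle anomaly" EXACT []', "is_a: C:1 ! root finding", "",
    "[Term]", "id: C:3", "name: leafa finding", "is_a: C:2", "",
    "[Term]", "id: C:4", "name: leafb finding", "is_a: C:2", "",
    "[Term]", "id: C:5", "name: other finding", "is_a: C:1"), path)
  path
}
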