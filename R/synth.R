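#' Configuration for the synthetic benchmark generator
#'
#' Describes a fully self-contained study: a random rooted is-a DAG of
#' phenotype classes with synthetic labels and synonyms, a gene lexicon, a
#' sentence corpus in which chosen gene-phenotype pairs are co-mentioned at
#' a controlled per-sentence probability, and matching reference annotation
#' tables. The seed fully determines every output byte.
#'
#' Each sentence of the corpus independently emits a co-mention clause for
#' every planted pair with probability `strength`, plus (with probability
#' `background_rate`) one co-mention of a uniformly random gene-class pair;
#' sentences without a co-mention may mention a lone gene or phenotype or
#' only filler text. Reference tables record the planted pairs, optionally
#' swapping a class for a random ancestor or descendant with probability
#' `hierarchy_noise` — emulating curated annotations that are related to,
#' but more or less specific than, what the literature states.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_classes Number of ontology classes (class 1 is the root).
#' @param n_genes Number of genes in the lexicon.
#' @param dag_branching Maximum number of parents per non-root class.
#' @param n_synonyms_per_class Synonyms generated per class.
#' @param n_sentences Corpus size in sentences.
#' @param planted_pairs Optional tibble `gene_id`, `class_id`, `strength`;
#'   if `NULL`, `n_planted` pairs are sampled (genes without replacement
#'   while they last, non-root classes) at the common `strength`.
#' @param n_planted,strength Used when `planted_pairs` is `NULL`.
#' @param background_rate Per-sentence probability of one random co-mention;
#'   must be below every planted strength.
#' @param hierarchy_noise Probability that a reference annotation swaps the
#'   planted class for a random (non-root) ancestor or descendant.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_classes = 50L, n_genes = 50L,
                         dag_branching = 2L, n_synonyms_per_class = 1L,
                         n_sentences = 20000L, planted_pairs = NULL,
                         n_planted = 20L, strength = 0.3,
                         background_rate = 0.01, hierarchy_noise = 0.3) {
  cfg <- list(seed = as.integer(seed), n_classes = as.integer(n_classes),
              n_genes = as.integer(n_genes),
              dag_branching = as.integer(dag_branching),
              n_synonyms_per_class = as.integer(n_synonyms_per_class),
              n_sentences = as.integer(n_sentences),
              planted_pairs = planted_pairs, n_planted = as.integer(n_planted),
              strength = strength, background_rate = background_rate,
              hierarchy_noise = hierarchy_noise)
  stopifnot(cfg$n_classes >= 2L, cfg$n_genes >= 1L, cfg$n_sentences >= 1L,
            cfg$background_rate >= 0, cfg$background_rate < 1,
            cfg$hierarchy_noise >= 0, cfg$hierarchy_noise <= 1)
  strengths <- if (is.null(planted_pairs)) strength else planted_pairs$strength
  if (any(strengths <= cfg$background_rate)) {
    stop("planted strengths must exceed background_rate", call. = FALSE)
  }
  if (any(strengths <= 0 | strengths > 1)) {
    stop("planted strengths must lie in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @param path JSON file of key-value pairs matching the `synth_config()`
#'   arguments (`planted_pairs` as an array of objects).
#' @export
read_synth_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  if (!is.null(vals$planted_pairs)) {
    vals$planted_pairs <- tibble::as_tibble(vals$planted_pairs)
  }
  do.call(synth_config, vals)
}

# deterministic 4-letter code for an index (supports up to 26^4 entities)
idx_code <- function(i) {
  vapply(i, function(k) {
    k <- k - 1L
    s <- ""
    for (j in 1:4) { s <- paste0(letters[k %% 26L + 1L], s); k <- k %/% 26L }
    s
  }, character(1))
}

#' Generate a synthetic benchmark dataset
#'
#' Writes, under `dir`: `ontology.obo`, `genes.tsv`, `corpus.jsonl`,
#' `gene_phenotype.tsv`, `disease_phenotype.tsv` and `gene_disease.tsv` —
#' exactly the formats the mining pipeline consumes. One disease is created
#' per planted gene, annotated with (noisy copies of) that gene's planted
#' classes, so candidate-gene ranking has a ground truth.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the output `paths`, the realized
#'   `planted` pairs, the `classes` and `genes` tables, and the reference
#'   tibbles.
#' @export
synth_generate <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(config$seed, synth_generate_impl(config, dir))
}

synth_generate_impl <- function(cfg, dir) {
  n_c <- cfg$n_classes; n_g <- cfg$n_genes

  # ---- ontology: random rooted DAG ----------------------------------------
  class_id <- sprintf("SP:%07d", seq_len(n_c))
  wcode <- paste0("q", idx_code(seq_len(n_c)))
  label <- paste("abnormal", wcode, "morphology")
  syns <- lapply(seq_len(n_c), function(i)
    if (cfg$n_synonyms_per_class > 0)
      paste(wcode[i], "dysplasia type", letters[seq_len(cfg$n_synonyms_per_class)])
    else character(0))
  parents <- vector("list", n_c)
  for (i in seq_len(n_c)[-1]) {
    k <- sample.int(min(cfg$dag_branching, i - 1L), 1L)
    parents[[i]] <- sort(sample.int(i - 1L, k))
  }
  obo_path <- file.path(dir, "ontology.obo")
  con <- file(obo_path, "wt")
  writeLines("format-version: 1.2", con)
  for (i in seq_len(n_c)) {
    writeLines(c("", "[Term]", paste0("id: ", class_id[i]),
                 paste0("name: ", label[i]),
                 sprintf('synonym: "%s" EXACT []', syns[[i]]),
                 sprintf("is_a: %s ! %s", class_id[parents[[i]]],
                         label[parents[[i]]])), con)
  }
  close(con)

  # ---- gene lexicon -------------------------------------------------------
  gene_id <- sprintf("GENE:%05d", seq_len(n_g))
  gcode <- idx_code(seq_len(n_g))
  symbol <- paste0("Gv", gcode, "1")
  gsyn <- paste0("gv", gcode, " protein")
  genes_path <- file.path(dir, "genes.tsv")
  readr::write_tsv(tibble::tibble(gene_id, symbol, synonyms = gsyn),
                   genes_path, col_names = FALSE)

  # ---- planted pairs ------------------------------------------------------
  planted <- cfg$planted_pairs
  if (is.null(planted)) {
    pg <- if (cfg$n_planted <= n_g) sample.int(n_g, cfg$n_planted) else
      sample.int(n_g, cfg$n_planted, replace = TRUE)
    pc <- sample(2:n_c, cfg$n_planted, replace = TRUE)
    planted <- tibble::tibble(gene_id = gene_id[pg], class_id = class_id[pc],
                              strength = cfg$strength) %>%
      dplyr::distinct(.data$gene_id, .data$class_id, .keep_all = TRUE)
  }
  if (!all(planted$class_id %in% class_id)) {
    stop("planted class not in ontology: ",
         paste(setdiff(planted$class_id, class_id), collapse = ", "),
         call. = FALSE)
  }
  if (!all(planted$gene_id %in% gene_id)) {
    stop("planted gene not in lexicon: ",
         paste(setdiff(planted$gene_id, gene_id), collapse = ", "),
         call. = FALSE)
  }

  gidx <- stats::setNames(seq_len(n_g), gene_id)
  cidx <- stats::setNames(seq_len(n_c), class_id)
  gene_term <- function(gi) {        # random surface form of a gene
    ifelse(stats::runif(length(gi)) < 0.5, symbol[gi], gsyn[gi])
  }
  pheno_term <- function(ci) {       # random surface form of a class
    pick <- ceiling(stats::runif(length(ci)) * (1L + cfg$n_synonyms_per_class))
    vapply(seq_along(ci), function(j)
      if (pick[j] == 1L) label[ci[j]] else syns[[ci[j]]][pick[j] - 1L],
      character(1))
  }

  # ---- corpus -------------------------------------------------------------
  n_s <- cfg$n_sentences
  emis <- list()
  for (p in seq_len(nrow(planted))) {
    hit <- which(stats::runif(n_s) < planted$strength[p])
    if (length(hit)) {
      emis[[length(emis) + 1L]] <- tibble::tibble(
        sent = hit, gi = gidx[[planted$gene_id[p]]],
        ci = cidx[[planted$class_id[p]]])
    }
  }
  bg <- which(stats::runif(n_s) < cfg$background_rate)
  if (length(bg)) {
    emis[[length(emis) + 1L]] <- tibble::tibble(
      sent = bg, gi = sample.int(n_g, length(bg), replace = TRUE),
      ci = sample.int(n_c, length(bg), replace = TRUE))
  }
  emis <- dplyr::bind_rows(emis)
  if (nrow(emis)) {
    emis <- emis %>%
      dplyr::mutate(clause = paste("Mutation of", gene_term(.data$gi),
                                   "is associated with", pheno_term(.data$ci))) %>%
      dplyr::arrange(.data$sent, .data$gi, .data$ci) %>%
      dplyr::group_by(.data$sent) %>%
      dplyr::summarise(body = paste(.data$clause, collapse = ", and "),
                       .groups = "drop")
  } else {
    emis <- tibble::tibble(sent = integer(0), body = character(0))
  }
  sent_text <- rep(NA_character_, n_s)
  sent_text[emis$sent] <- paste0(emis$body, ".")
  idle <- which(is.na(sent_text))
  if (length(idle)) {
    u <- stats::runif(length(idle))
    lone_g <- idle[u < 0.25]
    lone_p <- idle[u >= 0.25 & u < 0.5]
    filler <- idle[u >= 0.5]
    sent_text[lone_g] <- paste0("Mutation of ",
                                gene_term(sample.int(n_g, length(lone_g),
                                                     replace = TRUE)),
                                " was examined further.")
    sent_text[lone_p] <- paste0("Subjects presented ",
                                pheno_term(sample.int(n_c, length(lone_p),
                                                      replace = TRUE)),
                                " on review.")
    sent_text[filler] <- "No additional findings were recorded in this cohort."
  }
  doc <- (seq_len(n_s) - 1L) %/% 20L + 1L
  corpus_path <- file.path(dir, "corpus.jsonl")
  docs <- tibble::tibble(doc_id = sprintf("DOC:%05d", unique(doc)),
                         text = vapply(split(sent_text, doc), paste,
                                       character(1), collapse = " "))
  con <- file(corpus_path, "wt")
  for (i in seq_len(nrow(docs))) {
    writeLines(jsonlite::toJSON(list(doc_id = docs$doc_id[i],
                                     text = docs$text[i]),
                                auto_unbox = TRUE), con)
  }
  close(con)

  # ---- reference tables with hierarchy noise ------------------------------
  anc_of <- vector("list", n_c); dec_of <- vector("list", n_c)
  for (i in seq_len(n_c)) anc_of[[i]] <- integer(0)
  for (i in seq_len(n_c)) {
    anc_of[[i]] <- sort(unique(c(parents[[i]],
                                 unlist(anc_of[parents[[i]]]))))
    for (a in anc_of[[i]]) dec_of[[a]] <- c(dec_of[[a]], i)
  }
  noisy_class <- function(ci) {
    vapply(ci, function(i) {
      if (stats::runif(1) >= cfg$hierarchy_noise) return(i)
      pool <- setdiff(c(anc_of[[i]], dec_of[[i]]), 1L)  # never the root
      if (!length(pool)) i else pool[[sample.int(length(pool), 1L)]]
    }, integer(1))
  }
  ref_gp <- planted %>%
    dplyr::transmute(entity_id = .data$gene_id,
                     class_id = .env$class_id[noisy_class(cidx[.data$class_id])])
  gp_path <- file.path(dir, "gene_phenotype.tsv")
  readr::write_tsv(dplyr::distinct(ref_gp), gp_path, col_names = FALSE)

  causal <- sort(unique(planted$gene_id))
  disease_id <- sprintf("DIS:%05d", seq_along(causal))
  gd <- tibble::tibble(query_id = disease_id, entity_id = causal)
  dp <- planted %>%
    dplyr::inner_join(tibble::tibble(gene_id = causal, disease = disease_id),
                      by = "gene_id") %>%
    dplyr::transmute(entity_id = .data$disease,
                     class_id = .env$class_id[noisy_class(cidx[.data$class_id])]) %>%
    dplyr::distinct()
  dp_path <- file.path(dir, "disease_phenotype.tsv")
  gd_path <- file.path(dir, "gene_disease.tsv")
  readr::write_tsv(dp, dp_path, col_names = FALSE)
  readr::write_tsv(gd, gd_path, col_names = FALSE)

  invisible(list(
    paths = list(ontology = obo_path, genes = genes_path, corpus = corpus_path,
                 gene_phenotype = gp_path, disease_phenotype = dp_path,
                 gene_disease = gd_path),
    planted = planted,
    classes = tibble::tibble(class_id, label),
    genes = tibble::tibble(gene_id, symbol, synonyms = gsyn),
    gene_phenotype = dplyr::distinct(ref_gp),
    disease_phenotype = dp,
    gene_disease = gd
  ))
}
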