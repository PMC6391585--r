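#' Mine gene-phenotype associations from a corpus
#'
#' Convenience wrapper over the full pipeline: build the refined gene and
#' phenotype dictionaries, split the corpus into sentences, tag mentions,
#' count ontology-propagated sentence co-occurrences, score every
#' co-mentioned pair with NPMI and keep each gene's top-`k` phenotypes.
#'
#' @param corpus Corpus tibble (`doc_id`, `text`) or a path accepted by
#'   [read_corpus()].
#' @param ontology A [phenomine_ontology] or a path to an OBO file.
#' @param genes Gene table tibble (`gene_id`, `symbol`, `synonyms`) or a
#'   path accepted by [read_gene_table()].
#' @param orthologs Optional gene-id pair table passed to
#'   [build_gene_lexicon()].
#' @param k Rank threshold; `NULL` returns the full scored table unranked.
#' @param stoplist Common-English stoplist for dictionary refinement.
#' @return Ranked association tibble (see [rank_associations()]), with the
#'   co-occurrence store attached as attribute `"store"`.
#' @export
mine_associations <- function(corpus, ontology, genes, orthologs = NULL,
                              k = 25L, stoplist = default_stoplist()) {
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  if (is.character(ontology)) ontology <- read_obo(ontology)
  if (is.character(genes)) genes <- read_gene_table(genes)
  gene_lex <- build_gene_lexicon(genes, orthologs, stoplist = stoplist)
  pheno_lex <- build_phenotype_lexicon(ontology, stoplist = stoplist)
  sentences <- corpus_sentences(corpus)
  mentions <- tag_sentences(sentences, gene_lex, pheno_lex)
  store <- count_cooccurrences(mentions, sentences, ontology)
  assoc <- score_associations(store)
  if (!is.null(k)) assoc <- rank_associations(assoc, k)
  attr(assoc, "store") <- store
  assoc
}

#' Sweep the rank threshold and measure gene-recovery AUC
#'
#' Reproduces the protocol used to choose the rank threshold: for each
#' candidate `k`, genes keep their top-`k` text-mined phenotypes, each such
#' gene's profile is compared by Resnik/BMA similarity against the curated
#' phenotype profiles of all reference genes, and the AUC of re-finding the
#' same gene among the reference set is recorded. IC is computed from the
#' reference (target-side) profiles.
#'
#' @param associations Scored association tibble from
#'   [score_associations()] (unranked; ranking happens per `k`).
#' @param reference_profiles Curated gene profiles, tibble `entity_id`,
#'   `class_id`.
#' @param ontology A [phenomine_ontology].
#' @param ks Integer vector of rank thresholds to evaluate.
#' @param mode AUC pooling mode, see [roc_auc()].
#' @return Tibble `k`, `auc`, `n_queries` with class `phenomine_sweep`.
#' @export
sweep_rank_threshold <- function(associations, reference_profiles, ontology,
                                 ks = c(5L, 10L, 25L, 50L, 75L),
                                 mode = "micro") {
  ic <- information_content(reference_profiles, ontology)
  res <- purrr::map_dfr(ks, function(k) {
    prof_k <- associations_to_profiles(rank_associations(associations, k))
    shared <- intersect(unique(prof_k$entity_id),
                        unique(reference_profiles$entity_id))
    if (!length(shared)) {
      return(tibble::tibble(k = k, auc = NA_real_, n_queries = 0L))
    }
    rankings <- bma_scores(dplyr::filter(prof_k, .data$entity_id %in% shared),
                           reference_profiles, ic, ontology)
    ev <- roc_auc(rankings, tibble::tibble(query_id = shared,
                                           entity_id = shared), mode = mode)
    tibble::tibble(k = k, auc = ev$auc, n_queries = ev$n_queries)
  })
  class(res) <- c("phenomine_sweep", class(res))
  res
}

#' Rank candidate genes for diseases and evaluate recovery
#'
#' Scores every (disease, gene) combination by BMA similarity between the
#' disease's phenotype profile and each gene's phenotype profile, then
#' computes the ROC AUC of recovering the known causal genes. IC comes from
#' the gene (target-side) profiles.
#'
#' @param disease_profiles Tibble `entity_id`, `class_id` of disease
#'   phenotype annotations (queries).
#' @param gene_profiles Tibble `entity_id`, `class_id` of gene phenotype
#'   profiles (candidates).
#' @param truth Tibble `query_id` (disease), `entity_id` (causal gene).
#' @param ontology A [phenomine_ontology].
#' @param mode AUC pooling mode, see [roc_auc()].
#' @return A `phenomine_eval` object (see [roc_auc()]); the full ranking
#'   table is attached as attribute `"rankings"`.
#' @export
evaluate_candidate_genes <- function(disease_profiles, gene_profiles, truth,
                                     ontology, mode = "micro") {
  ic <- information_content(gene_profiles, ontology)
  dq <- dplyr::rename(disease_profiles, query_id = "entity_id")
  rankings <- bma_scores(
    dplyr::rename(dq, entity_id = "query_id"), gene_profiles, ic, ontology)
  ev <- roc_auc(rankings, truth, mode = mode)
  attr(ev, "rankings") <- rankings
  ev
}
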