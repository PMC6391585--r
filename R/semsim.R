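#' Read annotation profiles and truth tables
#'
#' Annotation profiles follow the genes-to-phenotype TSV dialect:
#' `entity_id<TAB>phenotype_id`, no header, one row per annotation. Truth
#' tables for evaluation use `query_id<TAB>entity_id`.
#'
#' @param path Path to a two-column TSV.
#' @return Tibble with columns `entity_id`, `class_id` (profiles) or
#'   `query_id`, `entity_id` (truth).
#' @export
read_profiles <- function(path) {
  readr::read_tsv(path, col_names = c("entity_id", "class_id"),
                  col_types = "cc", progress = FALSE)
}

#' @rdname read_profiles
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_names = c("query_id", "entity_id"),
                  col_types = "cc", progress = FALSE)
}

#' Turn a ranked association table into phenotype profiles
#'
#' @param associations Ranked association tibble (see [rank_associations()]).
#' @return Tibble `entity_id`, `class_id` — each gene's retained phenotypes.
#' @export
associations_to_profiles <- function(associations) {
  dplyr::distinct(associations, entity_id = .data$gene_id,
                  class_id = .data$phenotype_id)
}

# resolve profile classes to merged ontology nodes, dropping (with one
# warning) classes the ontology does not contain
resolve_profiles <- function(profiles, ontology) {
  out <- profiles %>%
    dplyr::mutate(class_id = resolve_class(ontology, .data$class_id))
  bad <- sum(is.na(out$class_id))
  if (bad) {
    warning(sprintf("%d profile annotation(s) reference classes not in the ontology; dropped",
                    bad), call. = FALSE)
    out <- out[!is.na(out$class_id), ]
  }
  dplyr::distinct(out)
}

#' Information content of ontology classes from annotation profiles
#'
#' Each entity's class set is closed under ancestors, then
#' \eqn{p(c)} is the fraction of entities annotated (post-closure) to
#' \eqn{c}, and \eqn{IC(c) = -\log p(c)} in natural-log units. The closure
#' makes \eqn{p} monotone over the hierarchy, so IC never decreases toward
#' the leaves, and a root that subsumes every annotation gets IC 0. Classes
#' with \eqn{p = 0} (never annotated) are absent from the table.
#'
#' @param profiles Tibble `entity_id`, `class_id` — the entity set whose
#'   annotation frequencies define \eqn{p(c)} (conventionally the target
#'   side of a ranking task, e.g. gene profiles when ranking genes).
#' @param ontology A [phenomine_ontology].
#' @return Tibble `class_id`, `ic` (non-negative).
#' @export
information_content <- function(profiles, ontology) {
  stopifnot(inherits(ontology, "phenomine_ontology"))
  if (!nrow(profiles)) stop("empty profile set", call. = FALSE)
  profiles <- resolve_profiles(profiles, ontology)
  n_ent <- dplyr::n_distinct(profiles$entity_id)
  profiles %>%
    dplyr::inner_join(ontology$ancestors, by = "class_id",
                      relationship = "many-to-many") %>%
    dplyr::distinct(.data$entity_id, class_id = .data$ancestor_id) %>%
    dplyr::count(.data$class_id, name = "n_annotated") %>%
    dplyr::transmute(.data$class_id, ic = -log(.data$n_annotated / n_ent))
}

# max-IC common ancestor for every (class1, class2) combination of two class
# vectors; combinations without an IC-covered common ancestor are absent
class_pair_sims <- function(classes1, classes2, ic, ontology) {
  a1 <- ontology$ancestors %>%
    dplyr::filter(.data$class_id %in% classes1) %>%
    dplyr::rename(class1 = "class_id")
  a2 <- ontology$ancestors %>%
    dplyr::filter(.data$class_id %in% classes2) %>%
    dplyr::rename(class2 = "class_id")
  a1 %>%
    dplyr::inner_join(a2, by = "ancestor_id", relationship = "many-to-many") %>%
    dplyr::inner_join(ic, by = c(ancestor_id = "class_id")) %>%
    dplyr::group_by(.data$class1, .data$class2) %>%
    dplyr::summarise(sim = max(.data$ic), .groups = "drop")
}

#' Resnik similarity of two ontology classes
#'
#' The information content of the most informative common ancestor (MICA):
#' \eqn{sim(c_1, c_2) = \max_{c \in S(c_1, c_2)} -\log p(c)}, where
#' \eqn{S(c_1,c_2)} is the set of common ancestors. Two classes whose only
#' shared ancestor is a fully-annotated root score 0.
#'
#' @param class1,class2 Class ids (vectors of equal length are scored
#'   elementwise).
#' @param ic IC table from [information_content()].
#' @param ontology A [phenomine_ontology].
#' @return Numeric vector of similarities (non-negative).
#' @export
resnik <- function(class1, class2, ic, ontology) {
  stopifnot(length(class1) == length(class2))
  c1 <- resolve_class(ontology, class1)
  c2 <- resolve_class(ontology, class2)
  if (anyNA(c1) || anyNA(c2)) {
    stop("unknown class id: ",
         paste(unique(c(class1[is.na(c1)], class2[is.na(c2)])), collapse = ", "),
         call. = FALSE)
  }
  covered <- unique(ontology$ancestors$class_id[
    ontology$ancestors$ancestor_id %in% ic$class_id])
  uncov <- setdiff(unique(c(c1, c2)), covered)
  if (length(uncov)) {
    stop("class(es) with no IC-covered ancestor: ",
         paste(uncov, collapse = ", "), call. = FALSE)
  }
  sims <- class_pair_sims(unique(c1), unique(c2), ic, ontology)
  tibble::tibble(class1 = c1, class2 = c2) %>%
    dplyr::left_join(sims, by = c("class1", "class2")) %>%
    dplyr::pull("sim") %>%
    dplyr::coalesce(0)
}

#' Best-match-average similarity of two phenotype profiles
#'
#' Symmetric aggregation of pairwise Resnik similarities between two class
#' sets of sizes \eqn{m} and \eqn{n}: every class is matched with its best
#' counterpart in the other profile and the \eqn{m + n} best-match values
#' are averaged. An empty profile scores 0 with a warning rather than
#' erroring, so partially annotated entity sets can still be ranked.
#'
#' @param profile1,profile2 Character vectors of class ids.
#' @param ic IC table from [information_content()].
#' @param ontology A [phenomine_ontology].
#' @return A single non-negative similarity value.
#' @export
sim_bma <- function(profile1, profile2, ic, ontology) {
  if (!length(profile1) || !length(profile2)) {
    warning("empty phenotype profile; similarity defined as 0", call. = FALSE)
    return(0)
  }
  c1 <- unique(resolve_class(ontology, profile1))
  c2 <- unique(resolve_class(ontology, profile2))
  if (anyNA(c1) || anyNA(c2)) stop("unknown class id in profile", call. = FALSE)
  sims <- class_pair_sims(c1, c2, ic, ontology)
  full <- tidyr::expand_grid(class1 = c1, class2 = c2) %>%
    dplyr::left_join(sims, by = c("class1", "class2")) %>%
    dplyr::mutate(sim = dplyr::coalesce(.data$sim, 0))
  best1 <- full %>% dplyr::group_by(.data$class1) %>%
    dplyr::summarise(b = max(.data$sim), .groups = "drop")
  best2 <- full %>% dplyr::group_by(.data$class2) %>%
    dplyr::summarise(b = max(.data$sim), .groups = "drop")
  (sum(best1$b) + sum(best2$b)) / (length(c1) + length(c2))
}

# BMA scores for every (query entity, target entity) combination, sharing
# the class-pair similarity table across all profile pairs
bma_scores <- function(queries, targets, ic, ontology) {
  q <- resolve_profiles(queries, ontology)
  t <- resolve_profiles(targets, ontology)
  sims <- class_pair_sims(unique(q$class_id), unique(t$class_id), ic, ontology)
  qq <- dplyr::rename(q, query_id = "entity_id", class1 = "class_id")
  tt <- dplyr::rename(t, entity_id2 = "entity_id", class2 = "class_id")
  all_pairs <- tidyr::expand_grid(
    query_id = unique(qq$query_id), entity_id = unique(tt$entity_id2))
  cross <- qq %>%
    dplyr::cross_join(tt) %>%
    dplyr::left_join(sims, by = c("class1", "class2")) %>%
    dplyr::mutate(sim = dplyr::coalesce(.data$sim, 0))
  m_sizes <- dplyr::count(qq, .data$query_id, name = "m")
  n_sizes <- dplyr::count(tt, .data$entity_id2, name = "n")
  best1 <- cross %>%
    dplyr::group_by(.data$query_id, .data$entity_id2, .data$class1) %>%
    dplyr::summarise(b = max(.data$sim), .groups = "drop_last") %>%
    dplyr::summarise(s1 = sum(.data$b), .groups = "drop")
  best2 <- cross %>%
    dplyr::group_by(.data$query_id, .data$entity_id2, .data$class2) %>%
    dplyr::summarise(b = max(.data$sim), .groups = "drop_last") %>%
    dplyr::summarise(s2 = sum(.data$b), .groups = "drop")
  scored <- best1 %>%
    dplyr::inner_join(best2, by = c("query_id", "entity_id2")) %>%
    dplyr::inner_join(m_sizes, by = "query_id") %>%
    dplyr::inner_join(n_sizes, by = "entity_id2") %>%
    dplyr::transmute(.data$query_id, entity_id = .data$entity_id2,
                     score = (.data$s1 + .data$s2) / (.data$m + .data$n))
  # entities that lost their whole profile to resolution score 0
  all_pairs %>%
    dplyr::left_join(scored, by = c("query_id", "entity_id")) %>%
    dplyr::mutate(score = dplyr::coalesce(.data$score, 0))
}

#' Rank candidate entities against a query phenotype profile
#'
#' Scores every target entity by BMA similarity to the query profile and
#' sorts descending, breaking ties by entity id so rankings are
#' deterministic.
#'
#' @param query Character vector of class ids (the query profile), or a
#'   one-entity profile tibble.
#' @param targets Profile tibble `entity_id`, `class_id` of candidate
#'   entities.
#' @param ic IC table from [information_content()].
#' @param ontology A [phenomine_ontology].
#' @return Tibble `entity_id`, `score`, best candidate first.
#' @export
rank_candidates <- function(query, targets, ic, ontology) {
  if (is.data.frame(query)) query <- query$class_id
  qtb <- tibble::tibble(entity_id = ".query", class_id = unique(query))
  bma_scores(qtb, targets, ic, ontology) %>%
    dplyr::arrange(dplyr::desc(.data$score), .data$entity_id) %>%
    dplyr::select("entity_id", "score")
}

#' Full query-by-target BMA similarity matrix
#'
#' @param queries,targets Profile tibbles `entity_id`, `class_id`.
#' @param ic,ontology As in [rank_candidates()].
#' @return Wide tibble: one row per query (`query_id` column), one column
#'   per target entity.
#' @export
similarity_matrix <- function(queries, targets, ic, ontology) {
  bma_scores(queries, targets, ic, ontology) %>%
    tidyr::pivot_wider(names_from = "entity_id", values_from = "score",
                       names_sort = TRUE) %>%
    dplyr::arrange(.data$query_id)
}

#' @rdname similarity_matrix
#' @param mat Wide similarity tibble from `similarity_matrix()`.
#' @param path Output TSV path (header row of entity ids; first column the
#'   query ids).
#' @export
write_similarity_matrix <- function(mat, path) {
  readr::write_tsv(mat, path)
  invisible(path)
}

#' Rank-sum ROC AUC of candidate rankings
#'
#' Labels every ranked candidate positive or negative from a truth table and
#' computes the Mann-Whitney (rank-sum) AUC; tied scores contribute 0.5 per
#' tied positive-negative pair. The default pools all queries' (score,
#' label) pairs into one micro-averaged AUC; `mode = "macro"` instead
#' averages per-query AUCs. Queries with no positive or no negative among
#' their candidates carry no ranking signal and are excluded with a warning.
#'
#' @param rankings Tibble `query_id`, `entity_id`, `score` — each query's
#'   scored candidates (see [bma_scores] via [rank_candidates()]).
#' @param truth Tibble `query_id`, `entity_id` of known positives.
#' @param mode `"micro"` (pooled, default) or `"macro"` (mean per-query AUC).
#' @return A `phenomine_eval` object: list with `auc`, `n_queries`,
#'   `n_pairs` (positive-negative pairs compared) and a per-query tibble.
#' @export
roc_auc <- function(rankings, truth, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  stopifnot(all(c("query_id", "entity_id", "score") %in% names(rankings)))
  labelled <- rankings %>%
    dplyr::mutate(label = paste(.data$query_id, .data$entity_id, sep = "\r") %in%
                    paste(truth$query_id, truth$entity_id, sep = "\r"))
  usable <- labelled %>%
    dplyr::group_by(.data$query_id) %>%
    dplyr::summarise(n_pos = sum(.data$label), n_neg = sum(!.data$label),
                     .groups = "drop")
  bad <- usable$query_id[usable$n_pos == 0L | usable$n_neg == 0L]
  if (length(bad)) {
    warning(sprintf("%d query(ies) without both positives and negatives excluded",
                    length(bad)), call. = FALSE)
    labelled <- labelled[!labelled$query_id %in% bad, ]
    usable <- usable[!usable$query_id %in% bad, ]
  }
  if (!nrow(labelled)) stop("no evaluable queries", call. = FALSE)

  ranksum_auc <- function(score, label) {
    r <- rank(score)  # average ranks handle ties -> 0.5 per tied pair
    p <- sum(label); n <- sum(!label)
    (sum(r[label]) - p * (p + 1) / 2) / (p * n)
  }
  per_query <- labelled %>%
    dplyr::group_by(.data$query_id) %>%
    dplyr::summarise(auc = ranksum_auc(.data$score, .data$label),
                     n_pos = sum(.data$label), n_neg = sum(!.data$label),
                     .groups = "drop")
  auc <- if (mode == "micro") {
    ranksum_auc(labelled$score, labelled$label)
  } else {
    mean(per_query$auc)
  }
  n_pairs <- if (mode == "micro") {
    p <- sum(labelled$label); n <- sum(!labelled$label); p * n
  } else {
    sum(per_query$n_pos * per_query$n_neg)
  }
  structure(list(auc = auc, n_queries = nrow(per_query), n_pairs = n_pairs,
                 mode = mode, per_query = per_query,
                 labelled = dplyr::select(labelled, "query_id", "entity_id",
                                          "score", "label")),
            class = "phenomine_eval")
}

#' @export
print.phenomine_eval <- function(x, ...) {
  cat(sprintf("<phenomine_eval> %s AUC = %.4f over %d queries (%d pos/neg pairs)\n",
              x$mode, x$auc, x$n_queries, x$n_pairs))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname roc_auc
#' @param x A `phenomine_eval` object.
#' @param ... Unused.
#' @method glance phenomine_eval
#' @export
glance.phenomine_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_queries = x$n_queries, n_pairs = x$n_pairs,
                 mode = x$mode)
}

#' @rdname roc_auc
#' @method tidy phenomine_eval
#' @export
tidy.phenomine_eval <- function(x, ...) x$per_query

#' Write an evaluation report as JSON
#'
#' Emits `{"auc": ..., "n_queries": ..., "n_pairs": ...}`.
#'
#' @param eval A `phenomine_eval` object.
#' @param path Output path.
#' @export
write_eval_json <- function(eval, path) {
  jsonlite::write_json(list(auc = eval$auc, n_queries = eval$n_queries,
                            n_pairs = eval$n_pairs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
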