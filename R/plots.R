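#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an association table
#'
#' NPMI against per-gene rank, one line per gene — the shape shows how
#' quickly association strength decays below the top-ranked phenotypes and
#' where a rank threshold starts admitting weak pairs.
#'
#' @param object Ranked association tibble (see [rank_associations()]).
#' @param max_genes At most this many genes are drawn (those with the
#'   strongest top association), to keep the plot readable.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phenomine_associations
#' @export
autoplot.phenomine_associations <- function(object, max_genes = 20L, ...) {
  tb <- tibble::as_tibble(object)
  if (!"rank" %in% names(tb)) {
    tb <- rank_associations(tb, k = max(table(tb$gene_id)))
  }
  keep <- tb %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(top = max(.data$npmi), .groups = "drop") %>%
    dplyr::slice_max(.data$top, n = max_genes, with_ties = FALSE) %>%
    dplyr::pull("gene_id")
  ggplot2::ggplot(dplyr::filter(tb, .data$gene_id %in% keep),
                  ggplot2::aes(x = .data$rank, y = .data$npmi,
                               group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = "phenotype rank within gene", y = "NPMI",
                  title = "Gene-phenotype association strength by rank") +
    ggplot2::theme_minimal()
}

#' Plot a rank-threshold sweep
#'
#' AUC of recovering reference genes as a function of the per-gene rank
#' threshold k.
#'
#' @param object A `phenomine_sweep` tibble from [sweep_rank_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phenomine_sweep
#' @export
autoplot.phenomine_sweep <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$k, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$k) +
    ggplot2::labs(x = "rank threshold k", y = "AUC",
                  title = "Gene recovery by phenotype similarity vs rank threshold") +
    ggplot2::theme_minimal()
}

#' Plot the pooled ROC curve of an evaluation
#'
#' @param object A `phenomine_eval` object from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phenomine_eval
#' @export
autoplot.phenomine_eval <- function(object, ...) {
  lb <- object$labelled %>% dplyr::arrange(dplyr::desc(.data$score))
  roc <- tibble::tibble(
    tpr = c(0, cumsum(lb$label) / sum(lb$label)),
    fpr = c(0, cumsum(!lb$label) / sum(!lb$label))
  )
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (%s AUC = %.3f)", object$mode, object$auc)) +
    ggplot2::theme_minimal()
}
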