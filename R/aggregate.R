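#' Normalized per-dataset fold-change ranks
#'
#' Per dataset, genes are ranked by log2 fold change (descending for
#' `direction = "up"`, ascending for `"down"`; ties get average ranks) and
#' the rank is normalized by the number of genes measured in that dataset,
#' giving values in (0, 1]. Genes absent from a dataset get no entry there.
#'
#' @param de_tables Named list of [differential_expression()] tables (names
#'   are dataset ids).
#' @param direction `"up"` or `"down"`.
#' @return Named list (per dataset) of named numeric vectors of normalized
#'   ranks.
#' @export
normalized_ranks <- function(de_tables, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(length(de_tables) >= 1L)
  if (is.null(names(de_tables)))
    names(de_tables) <- paste0("dataset", seq_along(de_tables))
  lapply(de_tables, function(tab) {
    key <- if (direction == "up") -tab$log2fc else tab$log2fc
    r <- rank(key, ties.method = "average") / nrow(tab)
    names(r) <- tab$gene_id
    r
  })
}

#' Robust-rank-aggregation score of one gene's rank vector
#'
#' Under the null, a gene's normalized ranks across n independent datasets
#' are uniform on (0, 1], so its k-th smallest rank follows Beta(k, n-k+1).
#' The score is the Bonferroni-corrected minimum over k of that beta CDF at
#' the observed order statistic:
#' `rho = min(1, n * min_k P(Beta(k, n-k+1) <= r_(k)))`.
#' Small rho means the gene sits improbably high across datasets.
#'
#' @param ranks Numeric vector of normalized ranks in (0, 1] (any order).
#' @return rho in (0, 1].
#' @export
rra_score <- function(ranks) {
  if (!length(ranks)) stop("empty rank vector")
  if (any(!is.finite(ranks)) || any(ranks <= 0) || any(ranks > 1))
    stop("normalized ranks must lie in (0, 1]")
  r <- sort(ranks)
  n <- length(r)
  k <- seq_len(n)
  min(1, n * min(stats::pbeta(r, k, n - k + 1)))
}

#' Aggregate per-dataset DE rankings into AR scores
#'
#' Computes [rra_score()] per gene over the datasets in which the gene is
#' measured (n is per-gene, so platform coverage differences are not
#' penalized). The display `meta_score` is `-log10(rho)` signed by direction
#' (+ for up, - for down); the raw rho is always kept.
#'
#' @inheritParams normalized_ranks
#' @return data.frame `gene_id`, `direction`, `rho`, `meta_score`,
#'   `n_datasets_measured`, sorted ascending by rho (ties by gene id), with a
#'   list-column `per_dataset_ranks`.
#' @export
aggregate_datasets <- function(de_tables, direction = c("up", "down")) {
  direction <- match.arg(direction)
  ranks <- normalized_ranks(de_tables, direction)
  genes <- sort(unique(unlist(lapply(ranks, names), use.names = FALSE)))
  if (!length(genes)) {
    warning("no genes found in the DE tables")
    return(data.frame(gene_id = character(0), direction = character(0),
                      rho = numeric(0), meta_score = numeric(0),
                      n_datasets_measured = integer(0)))
  }
  per_gene <- lapply(genes, function(g) {
    v <- vapply(ranks, function(r) if (g %in% names(r)) r[[g]] else NA_real_,
                numeric(1))
    v[!is.na(v)]
  })
  rho <- vapply(per_gene, rra_score, numeric(1))
  out <- data.frame(
    gene_id = genes, direction = direction, rho = rho,
    meta_score = (if (direction == "up") 1 else -1) * -log10(rho),
    n_datasets_measured = lengths(per_gene),
    stringsAsFactors = FALSE)
  out$per_dataset_ranks <- per_gene
  out <- out[order(out$rho, out$gene_id), ]
  rownames(out) <- NULL
  out
}
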