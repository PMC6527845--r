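# per-abstract sets of entities present, by category
.doc_entities <- function(annotations, category) {
  lapply(annotations, function(ann)
    unique(ann$hits$canonical_id[ann$hits$category == category]))
}

#' Abstract-level co-occurrence counts for one gene-drug pair
#'
#' Document frequencies: `df_gd` abstracts mentioning both entities, `df_g` /
#' `df_d` abstracts mentioning the gene / drug, `P` the corpus size.
#' Presence is abstract-level (any hit anywhere), not sentence-level.
#'
#' @param annotations A `"corpus_annotation"`.
#' @param gene_id,drug_id Canonical ids.
#' @return Named list `df_gd`, `df_g`, `df_d`, `P`.
#' @export
cooccurrence_counts <- function(annotations, gene_id, drug_id) {
  g_sets <- .doc_entities(annotations, "gene")
  d_sets <- .doc_entities(annotations, "drug")
  has_g <- vapply(g_sets, function(s) gene_id %in% s, logical(1))
  has_d <- vapply(d_sets, function(s) drug_id %in% s, logical(1))
  list(df_gd = sum(has_g & has_d), df_g = sum(has_g), df_d = sum(has_d),
       P = length(annotations))
}

#' Average absolute expression correlation of a drug's targets with a gene
#'
#' The flat mean of `|Pearson r(target, gene)|` over every (target, dataset)
#' pair in which both genes are measured with nonzero variance. A target that
#' is the gene itself contributes 1 per dataset where the gene is measured
#' (direct-target signal). With no valid pair (no annotated targets, or
#' nothing measured) the correlation component is 0.
#'
#' @param gene_id Gene of interest.
#' @param targets Character vector of the drug's target gene ids.
#' @param datasets List of [expression_dataset()]s (or bare gene x sample
#'   matrices), normalized and gene-level.
#' @param averaging `"flat"` (default; one pool over all pairs) or
#'   `"per-dataset"` (mean of per-dataset means).
#' @return `corr_gd` in [0, 1].
#' @export
target_correlation <- function(gene_id, targets, datasets,
                               averaging = c("flat", "per-dataset")) {
  averaging <- match.arg(averaging)
  if (!length(targets)) return(0)
  by_ds <- lapply(datasets, function(ds) {
    mat <- if (inherits(ds, "expression_dataset")) ds$matrix else ds
    if (!gene_id %in% rownames(mat)) return(numeric(0))
    x <- mat[gene_id, ]
    vals <- numeric(0)
    for (t in targets) {
      if (t == gene_id) { vals <- c(vals, 1); next }
      if (!t %in% rownames(mat)) next
      y <- mat[t, ]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      vals <- c(vals, abs(stats::cor(x[ok], y[ok])))
    }
    vals
  })
  if (averaging == "flat") {
    all_vals <- unlist(by_ds, use.names = FALSE)
    if (!length(all_vals)) 0 else mean(all_vals)
  } else {
    means <- vapply(by_ds[lengths(by_ds) > 0], mean, numeric(1))
    if (!length(means)) 0 else mean(means)
  }
}

#' Regularized log-odds drug-gene connectivity score
#'
#' `theta = ln((df_gd * P + lambda) / (df_g * df_d + lambda)) * (1 + corr_gd)`
#' with `lambda = 1` by default, the small constant that keeps the ratio
#' defined at zero counts. Positive theta means the pair co-occurs more often
#' than independence predicts; the `(1 + corr_gd)` factor amplifies pairs
#' whose drug targets co-express with the gene. Note the factor also
#' amplifies negative log-odds; no clamping is applied.
#'
#' @param df_gd,df_g,df_d,P Document frequencies ([cooccurrence_counts()]).
#' @param corr_gd Correlation component in [0, 1]
#'   ([target_correlation()]).
#' @param lambda Regularization constant, > 0.
#' @return theta (may be negative).
#' @export
connectivity_score <- function(df_gd, df_g, df_d, P, corr_gd, lambda = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a positive number")
  if (df_gd > min(df_g, df_d) || max(df_g, df_d) > P || min(df_gd, df_g,
                                                            df_d, P) < 0)
    stop("inconsistent document frequencies: need 0 <= df_gd <= min(df_g, ",
         "df_d) <= P")
  if (!is.finite(corr_gd) || corr_gd < 0 || corr_gd > 1)
    stop("corr_gd must lie in [0, 1]")
  log((df_gd * P + lambda) / (df_g * df_d + lambda)) * (1 + corr_gd)
}

#' Read a drug-to-target table
#'
#' @param path TSV with columns `drug_id`, `gene_id` (one target per row).
#' @return Named list: drug id -> character vector of target gene ids.
#' @export
read_drug_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("drug_id", "gene_id") %in% names(df)))
    stop("drug target TSV must have columns drug_id, gene_id")
  lapply(split(df$gene_id, df$drug_id), unique)
}

#' Build the full gene x drug connectivity map
#'
#' Computes document frequencies once over the corpus and fills the complete
#' genes-by-drugs theta matrix, retaining every component per cell for audit.
#'
#' @param annotations A `"corpus_annotation"`.
#' @param gene_list,drug_list Canonical ids (rows / columns).
#' @param drug_targets Named list from [read_drug_targets()]; drugs without an
#'   entry have no targets (corr_gd = 0).
#' @param datasets List of normalized gene-level [expression_dataset()]s
#'   (may be empty; corr_gd is then 0 throughout).
#' @param lambda Regularization constant.
#' @param averaging Passed to [target_correlation()].
#' @return Object of class `"connectivity_map"`: list with `scores` (long
#'   data.frame gene_id, drug_id, df_gd, df_g, df_d, P, corr_gd, lambda,
#'   theta) and `theta` (genes x drugs matrix).
#' @export
build_connectivity_matrix <- function(annotations, gene_list, drug_list,
                                      drug_targets = list(),
                                      datasets = list(), lambda = 1,
                                      averaging = "flat") {
  stopifnot(length(gene_list) > 0L, length(drug_list) > 0L)
  P <- length(annotations)
  g_sets <- .doc_entities(annotations, "gene")
  d_sets <- .doc_entities(annotations, "drug")
  has_g <- sapply(gene_list, function(g)
    vapply(g_sets, function(s) g %in% s, logical(1)), simplify = "array")
  has_d <- sapply(drug_list, function(d)
    vapply(d_sets, function(s) d %in% s, logical(1)), simplify = "array")
  if (P == 0L) {
    has_g <- matrix(FALSE, 0, length(gene_list))
    has_d <- matrix(FALSE, 0, length(drug_list))
  }
  df_g <- colSums(has_g); df_d <- colSums(has_d)
  corr <- vapply(gene_list, function(g)
    vapply(drug_list, function(d)
      target_correlation(g, drug_targets[[d]], datasets, averaging),
      numeric(1)), numeric(length(drug_list)))
  corr <- matrix(corr, nrow = length(drug_list),
                 dimnames = list(drug_list, gene_list))
  rows <- vector("list", length(gene_list) * length(drug_list))
  theta_m <- matrix(NA_real_, length(gene_list), length(drug_list),
                    dimnames = list(gene_list, drug_list))
  k <- 0L
  for (gi in seq_along(gene_list)) for (di in seq_along(drug_list)) {
    g <- gene_list[gi]; d <- drug_list[di]
    df_gd <- sum(has_g[, gi] & has_d[, di])
    th <- connectivity_score(df_gd, df_g[gi], df_d[di], P, corr[d, g], lambda)
    theta_m[gi, di] <- th
    k <- k + 1L
    rows[[k]] <- data.frame(gene_id = g, drug_id = d, df_gd = df_gd,
                            df_g = df_g[[gi]], df_d = df_d[[di]], P = P,
                            corr_gd = corr[d, g], lambda = lambda,
                            theta = th, stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  structure(list(scores = scores, theta = theta_m),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> %d genes x %d drugs (P = %d abstracts)\n",
              nrow(x$theta), ncol(x$theta),
              if (nrow(x$scores)) x$scores$P[1] else 0L))
  top <- x$scores[order(-x$scores$theta), ][seq_len(min(5, nrow(x$scores))), ]
  cat("top pairs by theta:\n")
  print(top[, c("gene_id", "drug_id", "df_gd", "corr_gd", "theta")],
        row.names = FALSE)
  invisible(x)
}

#' Write a connectivity map as long and wide TSVs
#'
#' @param cmap A `"connectivity_map"`.
#' @param long_path Long-format TSV path (one row per pair).
#' @param wide_path Optional wide theta-matrix TSV path.
#' @return Invisibly, the paths.
#' @export
write_connectivity_map <- function(cmap, long_path, wide_path = NULL) {
  utils::write.table(cmap$scores, long_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(wide_path))
    write_expression_matrix(cmap$theta, wide_path, id_col = "gene_id")
  invisible(c(long = long_path, wide = wide_path))
}
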