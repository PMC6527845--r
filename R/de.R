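#' Inverse of the trigamma function
#'
#' Newton iteration on `trigamma(y) = x`, used when moment-matching the
#' scaled inverse-chi-square prior of the moderated t. Monotone decreasing
#' trigamma makes the iteration globally stable from the `1/x`-scale start.
#'
#' @param x Positive numeric vector.
#' @return `y` with `trigamma(y) = x` elementwise.
#' @keywords internal
trigamma_inverse <- function(x) {
  stopifnot(all(is.finite(x)), all(x > 0))
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Moment-match an inverse-chi-square prior to observed gene variances
#'
#' Given per-gene pooled variances `s2` on `df` residual degrees of freedom,
#' estimates the prior degrees of freedom `d0` and prior variance `s0^2` of
#' the standard empirical-Bayes hierarchy by matching the mean and variance
#' of `log(s2)` to their theoretical values under the scaled F distribution.
#' When the observed spread of log-variances does not exceed the sampling
#' spread, `d0 = Inf` (all variances shrunk fully to `s0^2`).
#'
#' @param s2 Per-gene variances (zeros/NAs are ignored in the fit).
#' @param df Residual degrees of freedom (scalar).
#' @return `list(prior_df =, prior_var =)`.
#' @export
fit_variance_prior <- function(s2, df) {
  z <- log(s2[is.finite(s2) & s2 > 0])
  if (length(z) < 2L) return(list(prior_df = 0, prior_var = NA_real_))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - trigamma(df / 2)
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(prior_df = d0, prior_var = s02)
}

.contrast_spec <- function(contrast) {
  switch(contrast,
    tumor_vs_normal = list(col = "group", g1 = "tumor", g2 = "normal"),
    hpv_pos_vs_neg = list(col = "hpv", g1 = "positive", g2 = "negative"),
    smoker_vs_non = list(col = "smoking", g1 = "smoker", g2 = "non-smoker"))
}

#' Two-group moderated-t differential expression
#'
#' For each gene: `log2fc = mean(group1) - mean(group2)` and a two-sample t
#' statistic whose pooled variance is shrunk toward an empirical-Bayes prior
#' fitted across genes ([fit_variance_prior()]); the moderated t is referred
#' to a t distribution on `prior_df + n1 + n2 - 2` degrees of freedom.
#' Forcing `prior_df = 0` recovers the classical equal-variance two-sample t.
#' Genes with zero variance in both groups get `t = 0, p = 1`. No multiple
#' testing correction gates the result (the significance rule is raw
#' `p < alpha`); a Benjamini-Hochberg `fdr` column is emitted for reference.
#'
#' @param ds An [expression_dataset()] with a log2-scale matrix, or a plain
#'   matrix plus `metadata`.
#' @param contrast One of `"tumor_vs_normal"`, `"hpv_pos_vs_neg"`,
#'   `"smoker_vs_non"`.
#' @param metadata Required when `ds` is a bare matrix.
#' @param prior_df `NULL` (estimate from the data), `0` (classical t), or a
#'   fixed positive value.
#' @return data.frame `gene_id`, `log2fc`, `t_stat`, `p_value`, `fdr`, `n1`,
#'   `n2`.
#' @export
differential_expression <- function(ds,
                                    contrast = c("tumor_vs_normal",
                                                 "hpv_pos_vs_neg",
                                                 "smoker_vs_non"),
                                    metadata = NULL, prior_df = NULL) {
  contrast <- match.arg(contrast)
  if (inherits(ds, "expression_dataset")) {
    mat <- ds$matrix; metadata <- ds$metadata
  } else {
    mat <- ds
    if (is.null(metadata)) stop("metadata required with a bare matrix")
  }
  spec <- .contrast_spec(contrast)
  labels <- metadata[[spec$col]]
  i1 <- which(labels == spec$g1); i2 <- which(labels == spec$g2)
  n_other <- ncol(mat) - length(i1) - length(i2)
  if (n_other > 0)
    message(n_other, " sample(s) with other/unknown labels excluded from ",
            contrast)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L)
    stop("contrast ", contrast, " needs >= 2 samples per group (got ",
         n1, " vs ", n2, ")")
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  v1 <- apply(mat[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(mat[, i2, drop = FALSE], 1L, stats::var)
  df_resid <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_resid

  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, df_resid)
  } else if (prior_df == 0) {
    prior <- list(prior_df = 0, prior_var = NA_real_)
  } else {
    prior <- list(prior_df = prior_df,
                  prior_var = fit_variance_prior(s2, df_resid)$prior_var)
  }
  d0 <- prior$prior_df
  s2_post <- if (d0 == 0) s2
             else if (is.infinite(d0)) rep(prior$prior_var, length(s2))
             else (d0 * prior$prior_var + df_resid * s2) / (d0 + df_resid)
  df_total <- if (is.infinite(d0)) Inf else d0 + df_resid

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, (m1 - m2) / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), df = df_total), 1)
  data.frame(gene_id = rownames(mat), log2fc = m1 - m2, t_stat = t_stat,
             p_value = p, fdr = stats::p.adjust(p, method = "BH"),
             n1 = n1, n2 = n2, row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter a DE table at a raw p-value threshold
#'
#' Strict `p < alpha`: a gene with `p` exactly equal to `alpha` is excluded.
#'
#' @param results A [differential_expression()] table.
#' @param alpha Significance threshold (default 0.05).
#' @return The significant subset.
#' @export
significant_genes <- function(results, alpha = 0.05) {
  out <- results[results$p_value < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}
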