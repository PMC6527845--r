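#' Association score weights
#'
#' Weights for the sentence-count association scores. Co-occurrence sentences
#' carry the strongest evidence, hence the default `w_c = 10` against unit
#' weights for the context terms; only the relative order of scores matters
#' for ranking, and scaling all weights by a positive constant scales every
#' score by the same constant.
#'
#' @param w_c Weight of sentences where disease and gene/drug terms co-occur.
#' @param w_hnc Weight of disease-only sentences.
#' @param w_gene Weight of gene-only (no disease term) sentences.
#' @param w_drug Weight of drug-only (no disease term) sentences.
#' @return Object of class `"score_weights"`.
#' @export
score_weights <- function(w_c = 10, w_hnc = 1, w_gene = 1, w_drug = 1) {
  w <- list(w_c = w_c, w_hnc = w_hnc, w_gene = w_gene, w_drug = w_drug)
  for (nm in names(w)) {
    v <- w[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("weight ", nm, " must be a finite nonnegative number")
  }
  structure(w, class = "score_weights")
}

#' Gene-disease association score of one annotated abstract
#'
#' `SGD = N_c * w_c + FLAG_gene * N_hnc * w_hnc + FLAG_hnc * N_gene * w_gene`.
#' Disease-only context counts only when the abstract mentions a gene at all,
#' and gene-only sentences count only when the abstract mentions the disease.
#'
#' @param ann An `"abstract_annotation"` (or any list with the count/flag
#'   fields).
#' @param w A [score_weights()] object.
#' @return Nonnegative numeric score.
#' @export
score_gene_association <- function(ann, w = score_weights()) {
  if (!inherits(w, "score_weights")) w <- do.call(score_weights, as.list(w))
  ann$N_c * w$w_c + ann$FLAG_gene * ann$N_hnc * w$w_hnc +
    ann$FLAG_hnc * ann$N_gene * w$w_gene
}

#' Drug-disease association score of one annotated abstract
#'
#' `SDD = N_c * w_c + FLAG_drug * N_hnc * w_hnc + FLAG_hnc * N_drug * w_drug`.
#'
#' @inheritParams score_gene_association
#' @return Nonnegative numeric score.
#' @export
score_drug_association <- function(ann, w = score_weights()) {
  if (!inherits(w, "score_weights")) w <- do.call(score_weights, as.list(w))
  ann$N_c * w$w_c + ann$FLAG_drug * ann$N_hnc * w$w_hnc +
    ann$FLAG_hnc * ann$N_drug * w$w_drug
}

# Recompute the annotation counts of `ann` restricted to one candidate
# entity: disease hits are kept, the entity's own hits define the gene/drug
# context, and other entities of the same kind are ignored. This is what makes
# the per-abstract score entity-specific.
.entity_annotation <- function(ann, entity_id, kind) {
  n <- length(ann$sentences)
  h <- ann$hits
  d_idx <- unique(h$sentence_index[h$category == "disease"])
  e_idx <- unique(h$sentence_index[h$category == kind &
                                   h$canonical_id == entity_id])
  d <- (seq_len(n) - 1L) %in% d_idx
  e <- (seq_len(n) - 1L) %in% e_idx
  out <- list(N_c = sum(d & e), N_hnc = sum(d & !e),
              FLAG_hnc = ann$FLAG_hnc)
  if (kind == "gene") {
    out$N_gene <- sum(e & !d); out$FLAG_gene <- as.integer(any(e))
    out$N_drug <- 0L; out$FLAG_drug <- 0L
  } else {
    out$N_drug <- sum(e & !d); out$FLAG_drug <- as.integer(any(e))
    out$N_gene <- 0L; out$FLAG_gene <- 0L
  }
  out
}

#' Per-entity association scores within one abstract
#'
#' @param ann An `"abstract_annotation"`.
#' @param kind `"gene"` or `"drug"`.
#' @param w A [score_weights()].
#' @return Named numeric vector: score per canonical entity of that kind
#'   occurring in the abstract.
#' @export
entity_scores <- function(ann, kind = c("gene", "drug"), w = score_weights()) {
  kind <- match.arg(kind)
  ids <- sort(unique(ann$hits$canonical_id[ann$hits$category == kind]))
  scorer <- if (kind == "gene") score_gene_association else score_drug_association
  vapply(ids, function(id) scorer(.entity_annotation(ann, id, kind), w),
         numeric(1))
}

#' Rank candidate entities across an annotated corpus
#'
#' Sums the per-abstract association score of every candidate gene (or drug)
#' over the corpus and ranks entities by total score. By default the threshold
#' is applied to the per-entity total; `threshold = "per-abstract"` instead
#' drops individual abstract contributions below `min_score` before summing.
#'
#' @param annotations A `"corpus_annotation"` (list of abstract annotations).
#' @param kind `"gene"` or `"drug"`.
#' @param w A [score_weights()].
#' @param min_score Minimum score to survive to the candidate list.
#' @param threshold `"per-entity"` (default) or `"per-abstract"`.
#' @return data.frame `entity_id`, `total_score`, `n_abstracts`, sorted by
#'   descending score, ties broken by `n_abstracts` then id.
#' @export
rank_candidates <- function(annotations, kind = c("gene", "drug"),
                            w = score_weights(), min_score = 1,
                            threshold = c("per-entity", "per-abstract")) {
  kind <- match.arg(kind)
  threshold <- match.arg(threshold)
  empty <- data.frame(entity_id = character(0), total_score = numeric(0),
                      n_abstracts = integer(0), stringsAsFactors = FALSE)
  if (!length(annotations)) return(empty)
  total <- numeric(0); nabs <- integer(0)
  for (ann in annotations) {
    sc <- entity_scores(ann, kind, w)
    if (threshold == "per-abstract") sc <- sc[sc >= min_score]
    for (id in names(sc)) {
      total[id] <- (if (id %in% names(total)) total[[id]] else 0) + sc[[id]]
      nabs[id] <- (if (id %in% names(nabs)) nabs[[id]] else 0L) + 1L
    }
  }
  if (!length(total)) return(empty)
  df <- data.frame(entity_id = names(total), total_score = unname(total),
                   n_abstracts = unname(nabs[names(total)]),
                   stringsAsFactors = FALSE)
  if (threshold == "per-entity") df <- df[df$total_score >= min_score, ]
  df <- df[order(-df$total_score, -df$n_abstracts, df$entity_id), ]
  rownames(df) <- NULL
  df
}

#' Build curation records for manual review
#'
#' One record per (abstract, entity) pair whose per-abstract score reaches
#' `min_score`, carrying the evidence spans (all hits of the entity plus all
#' disease and event hits) for highlighting.
#'
#' @inheritParams rank_candidates
#' @return data.frame `abstract_id`, `entity_id`, `kind`, `score`, `n_spans`,
#'   with a list-column `spans` of per-record span tables
#'   (`sentence_index`, `start`, `end`, `category`).
#' @export
curation_records <- function(annotations, kind = c("gene", "drug"),
                             w = score_weights(), min_score = 1) {
  kind <- match.arg(kind)
  rows <- list()
  for (ann in annotations) {
    sc <- entity_scores(ann, kind, w)
    sc <- sc[sc >= min_score]
    for (id in names(sc)) {
      h <- ann$hits
      keep <- h$category %in% c("disease", "event") |
        (h$category == kind & h$canonical_id == id)
      spans <- h[keep, c("sentence_index", "start", "end", "category")]
      rownames(spans) <- NULL
      rows[[length(rows) + 1L]] <- list(abstract_id = ann$abstract_id,
                                        entity_id = id, kind = kind,
                                        score = sc[[id]], spans = spans)
    }
  }
  df <- data.frame(
    abstract_id = vapply(rows, `[[`, character(1), "abstract_id"),
    entity_id = vapply(rows, `[[`, character(1), "entity_id"),
    kind = vapply(rows, `[[`, character(1), "kind"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    n_spans = vapply(rows, function(r) nrow(r$spans), integer(1)),
    stringsAsFactors = FALSE)
  df$spans <- lapply(rows, `[[`, "spans")
  df
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# one sentence with <mark> tags inserted at the given 0-based half-open spans
.highlight_sentence <- function(sentence, spans) {
  if (!nrow(spans)) return(.html_escape(sentence))
  spans <- spans[order(spans$start, -spans$end), , drop = FALSE]
  # drop spans nested inside an earlier span to keep the markup well-formed
  keep <- rep(TRUE, nrow(spans)); last_end <- -1L
  for (i in seq_len(nrow(spans))) {
    if (spans$start[i] < last_end) keep[i] <- FALSE
    else last_end <- spans$end[i]
  }
  spans <- spans[keep, , drop = FALSE]
  out <- ""; pos <- 0L
  for (i in seq_len(nrow(spans))) {
    out <- paste0(out,
                  .html_escape(substr(sentence, pos + 1L, spans$start[i])),
                  sprintf('<mark class="%s">', spans$category[i]),
                  .html_escape(substr(sentence, spans$start[i] + 1L,
                                      spans$end[i])),
                  "</mark>")
    pos <- spans$end[i]
  }
  paste0(out, .html_escape(substr(sentence, pos + 1L, nchar(sentence))))
}

#' Export a curation sheet as TSV and highlighted HTML
#'
#' The TSV carries one row per (abstract, entity) record; the HTML renders
#' each record's sentences with category-coloured `<mark>` highlights, the way
#' a curation interface presents evidence for manual review.
#'
#' @param records Output of [curation_records()].
#' @param annotations The `"corpus_annotation"` the records came from
#'   (supplies sentence text). Required when `html_path` is given.
#' @param tsv_path Output TSV path.
#' @param html_path Optional output HTML path.
#' @return Invisibly, the paths written.
#' @export
export_curation_sheet <- function(records, annotations = NULL,
                                  tsv_path, html_path = NULL) {
  tab <- records[, c("abstract_id", "entity_id", "kind", "score", "n_spans")]
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(html_path)) {
    if (is.null(annotations))
      stop("annotations are required to render HTML highlights")
    css <- paste(
      "<style>",
      "mark.disease{background:#fbb}mark.gene{background:#bfb}",
      "mark.drug{background:#bbf}mark.event{background:#ffb}",
      "</style>", sep = "\n")
    body <- character(0)
    for (i in seq_len(nrow(records))) {
      ann <- annotations[[records$abstract_id[i]]]
      spans <- records$spans[[i]]
      sent_html <- vapply(seq_along(ann$sentences), function(s) {
        sp <- spans[spans$sentence_index == s - 1L, , drop = FALSE]
        .highlight_sentence(ann$sentences[s], sp)
      }, character(1))
      body <- c(body, sprintf(
        "<section><h3>%s &middot; %s (%s, score %g)</h3><p>%s</p></section>",
        .html_escape(records$abstract_id[i]),
        .html_escape(records$entity_id[i]), records$kind[i],
        records$score[i], paste(sent_html, collapse = " ")))
    }
    writeLines(c("<!DOCTYPE html><html><head><meta charset='utf-8'>", css,
                 "</head><body>", body, "</body></html>"), html_path)
  }
  invisible(c(tsv = tsv_path, html = html_path))
}
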