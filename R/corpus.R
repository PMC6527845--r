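#' Default sentence-segmentation abbreviation list
#'
#' Reads the packaged abbreviation list used by [segment_sentences()]. A period
#' terminating one of these tokens is never treated as a sentence boundary.
#' Users may pass their own vector (or a superset) to [segment_sentences()].
#'
#' @return Character vector of abbreviations, each ending in a period.
#' @export
default_abbreviations <- function() {
  path <- system.file("extdata", "abbreviations.txt", package = "cmapminer")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Split abstract text into sentences
#'
#' Deterministic rule-based segmentation: a sentence ends at terminal
#' punctuation (`.`, `!`, `?`) followed by whitespace and an uppercase letter
#' or digit, unless the token ending at the punctuation is a protected
#' abbreviation (e.g. "vs.", "et al."). Whitespace between sentences is
#' dropped; all other characters are preserved, so the concatenated sentences
#' reconstruct the input modulo whitespace.
#'
#' @param text A single character string (UTF-8 plain text).
#' @param abbreviations Character vector of protected abbreviations, each
#'   ending in a period. Defaults to the packaged list.
#' @return Character vector of sentences; `character(0)` for empty/whitespace
#'   input. If an abstract title is part of `text` (ending in a period) it
#'   simply becomes the first sentence (index 0 downstream).
#' @examples
#' segment_sentences("EGFR is overexpressed in HNC. Cetuximab targets EGFR.")
#' @export
segment_sentences <- function(text, abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  abbr <- tolower(abbreviations)

  # candidate boundaries: terminal punctuation, whitespace, then [A-Z0-9"'(]
  m <- gregexpr("[.!?](?=\\s+[\"'(]?[A-Z0-9])", text, perl = TRUE)[[1]]
  ends <- integer(0)
  if (m[1] != -1L) {
    low <- tolower(text)
    for (pos in as.integer(m)) {
      if (substr(text, pos, pos) == ".") {
        # token ending at pos, including the period
        head <- substr(low, 1L, pos)
        protected <- any(vapply(abbr, function(a) endsWith(head, a), logical(1)))
        if (!protected) {
          # single-initial guard: "J. Smith" should not split
          tok <- sub(".*[[:space:]]", "", substr(text, 1L, pos))
          if (grepl("^[A-Z]\\.$", tok)) protected <- TRUE
        }
        if (protected) next
      }
      ends <- c(ends, pos)
    }
  }
  starts <- c(1L, ends + 1L)
  stops <- c(ends, nchar(text))
  out <- character(0)
  for (i in seq_along(starts)) {
    if (starts[i] > stops[i]) next
    s <- trimws(substr(text, starts[i], stops[i]))
    if (nzchar(s)) out <- c(out, s)
  }
  out
}

#' Construct a term lexicon
#'
#' A lexicon maps canonical entity identifiers to sets of synonym strings for
#' one category of entity (disease, gene, drug, or the display-only "event"
#' category). The same synonym may appear under several canonical ids; the
#' ambiguity is preserved and surfaces as one hit per canonical id.
#'
#' @param category One of `"disease"`, `"gene"`, `"drug"`, `"event"`.
#' @param entries Named list: canonical id -> character vector of synonyms.
#' @return An object of class `"lexicon"`.
#' @export
lexicon <- function(category, entries) {
  category <- match.arg(category, c("disease", "gene", "drug", "event"))
  stopifnot(is.list(entries), length(names(entries)) == length(entries))
  for (id in names(entries)) {
    syn <- entries[[id]]
    if (!is.character(syn) || length(syn) == 0L || any(!nzchar(syn)))
      stop("lexicon entry '", id, "' must be a non-empty set of non-empty synonyms")
    entries[[id]] <- unique(syn)
  }
  structure(list(category = category, entries = entries), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %s> %d entities, %d synonyms\n", x$category,
              length(x$entries), sum(lengths(x$entries))))
  invisible(x)
}

#' Read lexicons from a TSV file
#'
#' Expected columns: `canonical_id`, `category`, `synonym` (one synonym per
#' row). Returns one lexicon per category present in the file.
#'
#' @param path Path to the TSV file.
#' @return Named list of [lexicon()] objects, keyed by category.
#' @export
read_lexicons <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("canonical_id", "category", "synonym")
  if (!all(need %in% names(df)))
    stop("lexicon TSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (cat in unique(df$category)) {
    sub <- df[df$category == cat, , drop = FALSE]
    entries <- split(sub$synonym, sub$canonical_id)
    out[[cat]] <- lexicon(cat, entries)
  }
  out
}

#' Read an abstract corpus from TSV
#'
#' @param path TSV with columns `abstract_id` and `text`.
#' @return data.frame with character columns `abstract_id`, `text`.
#' @export
read_corpus <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!all(c("abstract_id", "text") %in% names(df)))
    stop("corpus TSV must have columns abstract_id, text")
  df$abstract_id <- as.character(df$abstract_id)
  df$text <- as.character(df$text)
  df[, c("abstract_id", "text")]
}

# All candidate synonym matches in one sentence, before longest-match
# resolution. Word boundaries are ASCII alphanumeric transitions, so hyphens
# and underscores delimit tokens ("EGFR-positive" matches "EGFR").
.candidate_matches <- function(sentence, lexicon) {
  syn2id <- list()
  for (id in names(lexicon$entries))
    for (s in lexicon$entries[[id]]) {
      key <- tolower(s)
      syn2id[[key]] <- c(syn2id[[key]], id)
    }
  rows <- list()
  for (syn in names(syn2id)) {
    esc <- gsub("([^A-Za-z0-9 ])", "\\\\\\1", syn)  # literal-escape the synonym
    pat <- paste0("(?<![A-Za-z0-9])", esc, "(?![A-Za-z0-9])")
    m <- gregexpr(pat, sentence, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      start0 <- as.integer(m[k]) - 1L          # 0-based
      end0 <- start0 + len[k]                  # half-open
      for (id in syn2id[[syn]])
        rows[[length(rows) + 1L]] <- list(
          canonical_id = id, start = start0, end = end0,
          matched_text = substr(sentence, start0 + 1L, end0))
    }
  }
  if (!length(rows)) {
    return(data.frame(canonical_id = character(0), start = integer(0),
                      end = integer(0), matched_text = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
}

#' Match lexicon terms in a sentence
#'
#' Case-insensitive, word-boundary-delimited dictionary matching with a
#' longest-match rule: a match overlapping a strictly longer match at the same
#' location is suppressed (so "TP53BP1" wins over "TP53"). Equal-length
#' overlapping matches, and ambiguous synonyms mapping to several canonical
#' ids, each produce their own hit.
#'
#' @param sentence A single character string.
#' @param lexicon A [lexicon()].
#' @return data.frame with columns `canonical_id`, `category`, `start`, `end`
#'   (0-based half-open character offsets), `matched_text`, ordered by `start`.
#' @export
match_terms <- function(sentence, lexicon) {
  stopifnot(inherits(lexicon, "lexicon"), is.character(sentence),
            length(sentence) == 1L)
  cand <- .candidate_matches(sentence, lexicon)
  if (nrow(cand)) {
    cand$len <- cand$end - cand$start
    # distinct spans, longest first; keep a span unless a kept strictly longer
    # span overlaps it
    spans <- unique(cand[, c("start", "end", "len")])
    spans <- spans[order(-spans$len, spans$start), , drop = FALSE]
    kept <- spans[0, , drop = FALSE]
    for (i in seq_len(nrow(spans))) {
      sp <- spans[i, ]
      clash <- kept$len > sp$len & kept$start < sp$end & sp$start < kept$end
      if (!any(clash)) kept <- rbind(kept, sp)
    }
    keep_key <- paste(kept$start, kept$end)
    cand <- cand[paste(cand$start, cand$end) %in% keep_key, , drop = FALSE]
    cand$len <- NULL
    cand <- cand[order(cand$start, cand$end, cand$canonical_id), , drop = FALSE]
  }
  cand$category <- rep(lexicon$category, nrow(cand))
  rownames(cand) <- NULL
  cand[, c("canonical_id", "category", "start", "end", "matched_text")]
}

.empty_hits <- function() {
  data.frame(sentence_index = integer(0), canonical_id = character(0),
             category = character(0), start = integer(0), end = integer(0),
             matched_text = character(0), stringsAsFactors = FALSE)
}

#' Annotate one abstract against disease/gene/drug lexicons
#'
#' Segments the text, matches all lexicons per sentence, and derives the
#' sentence-classification counts that the association scores consume:
#' \describe{
#'   \item{N_c}{sentences containing a disease term and a gene or drug term}
#'   \item{N_hnc}{sentences containing disease terms but no gene/drug term}
#'   \item{N_gene}{sentences containing gene terms but no disease term}
#'   \item{N_drug}{sentences containing drug terms but no disease term}
#' }
#' `FLAG_gene`/`FLAG_drug` are 1 iff any gene/drug term occurs anywhere in the
#' abstract. `FLAG_hnc` is 1 iff any disease term occurs (the
#' `"any-disease-term"` rule); `flag_hnc_rule = "always-on"` forces it to 1,
#' for corpora already restricted to the disease by the retrieval query.
#'
#' @param abstract_id Identifier string.
#' @param text Abstract text (title, if available, should be prepended; it is
#'   then sentence 0).
#' @param disease,genes,drugs Lexicons of the respective categories.
#' @param events Optional display-only lexicon (category `"event"`); its hits
#'   are recorded for highlighting but never enter counts or flags.
#' @param flag_hnc_rule `"any-disease-term"` (default) or `"always-on"`.
#' @param abbreviations Passed to [segment_sentences()].
#' @return Object of class `"abstract_annotation"`.
#' @export
annotate_abstract <- function(abstract_id, text, disease, genes, drugs,
                              events = NULL,
                              flag_hnc_rule = c("any-disease-term", "always-on"),
                              abbreviations = default_abbreviations()) {
  flag_hnc_rule <- match.arg(flag_hnc_rule)
  lexs <- list(disease, genes, drugs)
  cats <- vapply(lexs, function(l) l$category, character(1))
  if (anyDuplicated(cats) || !setequal(cats, c("disease", "gene", "drug")))
    stop("need one lexicon each of category disease, gene, drug")
  sentences <- segment_sentences(text, abbreviations)
  if (!is.null(events)) lexs <- c(lexs, list(events))

  hits <- .empty_hits()
  for (i in seq_along(sentences)) {
    for (lex in lexs) {
      h <- match_terms(sentences[i], lex)
      if (nrow(h)) {
        h <- cbind(sentence_index = i - 1L, h)
        hits <- rbind(hits, h)
      }
    }
  }
  score_hits <- hits[hits$category != "event", , drop = FALSE]
  has <- function(cat) {
    idx <- unique(score_hits$sentence_index[score_hits$category == cat])
    (seq_along(sentences) - 1L) %in% idx
  }
  d <- has("disease"); g <- has("gene"); dr <- has("drug")
  structure(list(
    abstract_id = as.character(abstract_id),
    sentences = sentences,
    hits = hits,
    N_c = sum(d & (g | dr)),
    N_hnc = sum(d & !g & !dr),
    N_gene = sum(g & !d),
    N_drug = sum(dr & !d),
    FLAG_gene = as.integer(any(g)),
    FLAG_drug = as.integer(any(dr)),
    FLAG_hnc = if (flag_hnc_rule == "always-on") 1L else as.integer(any(d))
  ), class = "abstract_annotation")
}

#' @export
print.abstract_annotation <- function(x, ...) {
  cat(sprintf(
    "<abstract_annotation %s> %d sentences, %d hits | N_c=%d N_hnc=%d N_gene=%d N_drug=%d flags(g,d,hnc)=(%d,%d,%d)\n",
    x$abstract_id, length(x$sentences), nrow(x$hits), x$N_c, x$N_hnc,
    x$N_gene, x$N_drug, x$FLAG_gene, x$FLAG_drug, x$FLAG_hnc))
  invisible(x)
}

#' Annotate every abstract in a corpus
#'
#' @param corpus data.frame with columns `abstract_id`, `text`
#'   (see [read_corpus()]).
#' @inheritParams annotate_abstract
#' @return Named list of [annotate_abstract()] results (class
#'   `"corpus_annotation"`), keyed by abstract id.
#' @export
annotate_corpus <- function(corpus, disease, genes, drugs, events = NULL,
                            flag_hnc_rule = c("any-disease-term", "always-on"),
                            abbreviations = default_abbreviations()) {
  flag_hnc_rule <- match.arg(flag_hnc_rule)
  out <- lapply(seq_len(nrow(corpus)), function(i)
    annotate_abstract(corpus$abstract_id[i], corpus$text[i], disease, genes,
                      drugs, events, flag_hnc_rule, abbreviations))
  names(out) <- corpus$abstract_id
  class(out) <- "corpus_annotation"
  out
}

#' @export
print.corpus_annotation <- function(x, ...) {
  cat(sprintf("<corpus_annotation> %d abstracts, %d term hits\n", length(x),
              sum(vapply(x, function(a) nrow(a$hits), integer(1)))))
  invisible(x)
}
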