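# Shared fixtures and independent brute-force oracles.

fix_disease <- function() {
  lexicon("disease", list(HNC = c("head and neck cancer", "oral cancer",
                                  "HNSCC")))
}

fix_genes <- function() {
  lexicon("gene", list(EGFR = c("EGFR", "ERBB1"), TP53 = "TP53",
                       TP53BP1 = "TP53BP1", CCND1 = "CCND1"))
}

fix_drugs <- function() {
  lexicon("drug", list(CETUXIMAB = "cetuximab", CISPLATIN = "cisplatin"))
}

# annotation stub with explicit counts/flags, for formula tests
ann_stub <- function(N_c = 0, N_hnc = 0, N_gene = 0, N_drug = 0,
                     FLAG_gene = 1, FLAG_drug = 1, FLAG_hnc = 1) {
  list(N_c = N_c, N_hnc = N_hnc, N_gene = N_gene, N_drug = N_drug,
       FLAG_gene = FLAG_gene, FLAG_drug = FLAG_drug, FLAG_hnc = FLAG_hnc)
}

# Brute-force dictionary matcher: character-by-character scan with boundary
# checks, then exhaustive longest-match suppression. Shares no code with
# match_terms.
oracle_match <- function(sentence, lex) {
  low <- tolower(sentence)
  is_word <- function(ch) grepl("[a-z0-9]", ch)
  cand <- list()
  for (id in names(lex$entries)) for (syn in lex$entries[[id]]) {
    s <- tolower(syn); L <- nchar(s)
    for (pos in seq_len(max(0, nchar(low) - L + 1))) {
      if (substr(low, pos, pos + L - 1) != s) next
      before <- if (pos == 1) "" else substr(low, pos - 1, pos - 1)
      after <- if (pos + L > nchar(low)) "" else substr(low, pos + L, pos + L)
      if ((before == "" || !is_word(before)) &&
          (after == "" || !is_word(after)))
        cand[[length(cand) + 1]] <- data.frame(
          canonical_id = id, start = pos - 1L, end = pos - 1L + L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(canonical_id = character(0), start = integer(0),
                      end = integer(0)))
  df <- unique(do.call(rbind, cand))
  len <- df$end - df$start
  drop <- vapply(seq_len(nrow(df)), function(i) {
    any(len > len[i] & df$start < df$end[i] & df$start[i] < df$end)
  }, logical(1))
  df <- df[!drop, , drop = FALSE]
  df <- df[order(df$start, df$end, df$canonical_id), ]
  rownames(df) <- NULL
  df
}

# Beta order-statistic CDF via the binomial tail identity
# P(Beta(k, n-k+1) <= r) = P(Binom(n, r) >= k); independent of pbeta.
oracle_rra <- function(ranks) {
  r <- sort(ranks); n <- length(r)
  probs <- vapply(seq_len(n), function(k) {
    j <- k:n
    sum(choose(n, j) * r[k]^j * (1 - r[k])^(n - j))
  }, numeric(1))
  min(1, n * min(probs))
}

# all-pairs interval scan with the same priority rules, loop-based
oracle_assign <- function(features, gene_models, ignore_strand = FALSE) {
  out <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    hits <- integer(0)
    for (j in seq_len(nrow(gene_models))) {
      if (features$chrom[i] != gene_models$chrom[j]) next
      if (!ignore_strand && features$strand[i] != gene_models$strand[j]) next
      if (features$start[i] < gene_models$end[j] &&
          gene_models$start[j] < features$end[i]) hits <- c(hits, j)
    }
    bt <- gene_models$biotype[hits]
    coding <- hits[bt == "coding"]
    out[i] <- if (length(coding) == 1) gene_models$gene_id[coding]
      else if (length(coding) == 0 && length(hits) == 1)
        gene_models$gene_id[hits]
      else NA_character_
  }
  out
}

# does some window of >= k sorted perfect-probe starts have all adjacent
# gaps <= gap? exhaustive over windows
oracle_probeset_retained <- function(starts, k, gap) {
  s <- sort(starts)
  n <- length(s)
  if (n < k) return(FALSE)
  for (i in 1:(n - k + 1)) for (j in (i + k - 1):n) {
    if (all(diff(s[i:j]) <= gap)) return(TRUE)
  }
  FALSE
}

make_alns <- function(probe_id, start, end, mismatches = 0, gap_count = 0,
                      matches = NULL, query_size = 60, chrom = "chrT",
                      strand = "+", probe_set_id = NA_character_) {
  n <- length(probe_id)
  if (is.null(matches)) matches <- query_size - mismatches
  df <- data.frame(
    probe_id = probe_id, probe_set_id = rep_len(probe_set_id, n),
    chrom = rep_len(chrom, n), start = start, end = end,
    strand = rep_len(strand, n), matches = rep_len(matches, n),
    mismatches = rep_len(mismatches, n), gap_count = rep_len(gap_count, n),
    query_size = rep_len(query_size, n),
    block_count = 1L,
    block_sizes = paste0(end - start, ","),
    t_starts = paste0(start, ","), stringsAsFactors = FALSE)
  df$similarity <- 100 * df$matches / df$query_size
  class(df) <- c("probe_alignments", "data.frame")
  df
}
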