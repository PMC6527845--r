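test_that("sentence segmentation handles empty text, terminal periods and abbreviations", {
  expect_identical(segment_sentences(""), character(0))
  expect_identical(segment_sentences("   "), character(0))
  expect_length(
    segment_sentences("EGFR is overexpressed in HNC. Cetuximab targets EGFR."),
    2L)
  # hand-segmented fixture: "vs." and "e.g." must not split; true count is 3
  fix <- paste("EGFR expression was higher in tumors vs. normal tissue.",
               "Inhibitors, e.g. cetuximab, improved outcomes in trials.",
               "Median survival differed by 10 vs. 12 months overall.")
  expect_length(segment_sentences(fix), 3L)
})

test_that("segmented sentences reconstruct the text modulo whitespace", {
  texts <- c(
    "TP53 was mutated. CCND1 was amplified! Was EGFR involved? Yes.",
    "One sentence only",
    "Trailing space after period. Next one.  Double space before this."
  )
  for (tx in texts) {
    s <- segment_sentences(tx)
    expect_identical(gsub("\\s+", "", paste(s, collapse = "")),
                     gsub("\\s+", "", tx))
  }
})

test_that("term matching is case-insensitive with word boundaries and longest match", {
  g <- fix_genes()
  expect_identical(nrow(match_terms("no terms here at all", g)), 0L)
  h <- match_terms("egfr and EGFR", g)
  expect_identical(h$canonical_id, c("EGFR", "EGFR"))
  expect_identical(h$matched_text, c("egfr", "EGFR"))
  # hyphen is a boundary
  expect_identical(match_terms("EGFR-positive cases", g)$canonical_id, "EGFR")
  # no match inside a longer token
  expect_identical(nrow(match_terms("xEGFRx", g)), 0L)
  # longest match wins over the contained symbol
  h <- match_terms("TP53BP1 studied", g)
  expect_identical(h$canonical_id, "TP53BP1")
  # matched_text always equals the sentence slice at the 0-based span
  s <- "TP53 and EGFR in head and neck cancer"
  for (lex in list(g, fix_disease())) {
    h <- match_terms(s, lex)
    for (i in seq_len(nrow(h)))
      expect_identical(h$matched_text[i],
                       substr(s, h$start[i] + 1, h$end[i]))
  }
})

test_that("ambiguous synonyms yield one hit per canonical id", {
  amb <- lexicon("gene", list(A1 = "shared", A2 = c("shared", "own")))
  h <- match_terms("the shared term and its own", amb)
  expect_setequal(h$canonical_id[h$matched_text == "shared"], c("A1", "A2"))
  expect_identical(sum(h$matched_text == "own"), 1L)
})

test_that("term matching agrees with the brute-force scan oracle on generated sentences", {
  cfg <- synth_config(seed = 104, n_abstracts = 12)
  corp <- generate_corpus(cfg)
  sentences <- unlist(lapply(corp$corpus$text, segment_sentences))
  expect_gt(length(sentences), 20)
  for (lex in corp$lexicons) {
    for (s in sentences[seq_len(min(50, length(sentences)))]) {
      got <- match_terms(s, lex)[, c("canonical_id", "start", "end")]
      rownames(got) <- NULL
      expect_identical(got, oracle_match(s, lex))
    }
  }
})

test_that("abstract annotation derives the sentence-classification counts", {
  dz <- fix_disease(); g <- fix_genes(); dr <- fix_drugs()
  # zero hits
  a <- annotate_abstract("a0", "Nothing relevant happened today.", dz, g, dr)
  expect_identical(c(a$N_c, a$N_hnc, a$N_gene, a$N_drug), rep(0L, 4))
  expect_identical(c(a$FLAG_gene, a$FLAG_drug, a$FLAG_hnc), rep(0L, 3))
  # single co-occurrence sentence
  a <- annotate_abstract("a1", "Oral cancer involves EGFR.", dz, g, dr)
  expect_identical(c(a$N_c, a$N_hnc, a$N_gene), c(1L, 0L, 0L))
  expect_identical(c(a$FLAG_gene, a$FLAG_hnc), c(1L, 1L))
  # 4-sentence fixture: 1 co-occurrence, 2 disease-only, 1 gene-only
  tx <- paste("EGFR drives oral cancer.",
              "Oral cancer is common.",
              "HNSCC outcomes are poor.",
              "TP53 regulates apoptosis.")
  a <- annotate_abstract("a2", tx, dz, g, dr)
  expect_identical(c(a$N_c, a$N_hnc, a$N_gene, a$N_drug), c(1L, 2L, 1L, 0L))
})

test_that("every disease sentence counts in exactly one of N_c and N_hnc", {
  cfg <- synth_config(seed = 105, n_abstracts = 20)
  corp <- generate_corpus(cfg)
  ann <- annotate_corpus(corp$corpus, corp$lexicons$disease,
                         corp$lexicons$gene, corp$lexicons$drug)
  for (a in ann) {
    expect_lte(a$N_c + a$N_hnc, length(a$sentences))
    n_disease_sent <- length(unique(
      a$hits$sentence_index[a$hits$category == "disease"]))
    expect_identical(a$N_c + a$N_hnc, n_disease_sent)
  }
})

test_that("annotation is deterministic and independent of lexicon entry order", {
  dz <- fix_disease(); dr <- fix_drugs()
  g1 <- fix_genes()
  g2 <- lexicon("gene", rev(g1$entries))
  tx <- "EGFR and TP53BP1 interact in oral cancer. Cetuximab blocks EGFR."
  a1 <- annotate_abstract("x", tx, dz, g1, dr)
  a2 <- annotate_abstract("x", tx, dz, g2, dr)
  expect_identical(a1$hits[order(a1$hits$sentence_index, a1$hits$start,
                                 a1$hits$canonical_id), ],
                   a2$hits[order(a2$hits$sentence_index, a2$hits$start,
                                 a2$hits$canonical_id), ],
                   ignore_attr = TRUE)
  expect_identical(a1[c("N_c", "N_hnc", "N_gene", "N_drug")],
                   a2[c("N_c", "N_hnc", "N_gene", "N_drug")])
})

test_that("FLAG_hnc rule is configurable", {
  dz <- fix_disease(); g <- fix_genes(); dr <- fix_drugs()
  tx <- "TP53 regulates apoptosis."
  a <- annotate_abstract("y", tx, dz, g, dr)
  expect_identical(a$FLAG_hnc, 0L)
  a2 <- annotate_abstract("y", tx, dz, g, dr, flag_hnc_rule = "always-on")
  expect_identical(a2$FLAG_hnc, 1L)
})

test_that("corpus and lexicon readers round-trip generated files", {
  cfg <- synth_config(seed = 106, n_abstracts = 8)
  dir <- withr::local_tempdir()
  corp <- generate_corpus(cfg, dir = dir)
  rc <- read_corpus(corp$paths[["corpus"]])
  expect_identical(rc, corp$corpus)
  lex <- read_lexicons(corp$paths[["lexicon"]])
  expect_setequal(names(lex), c("disease", "gene", "drug"))
  expect_identical(sort(names(lex$gene$entries)),
                   sort(names(corp$lexicons$gene$entries)))
})
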