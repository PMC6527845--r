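cooc_corpus <- function() {
  dz <- fix_disease(); g <- fix_genes(); dr <- fix_drugs()
  corp <- data.frame(
    abstract_id = c("a1", "a2", "a3"),
    text = c("Cetuximab targets EGFR in oral cancer.",   # both
             "EGFR is amplified in HNSCC.",              # gene only
             "Oral cancer screening matters."),          # neither
    stringsAsFactors = FALSE)
  annotate_corpus(corp, dz, g, dr)
}

test_that("document co-occurrence counts are abstract-level", {
  expect_identical(cooccurrence_counts(structure(list(),
                                                 class = "corpus_annotation"),
                                       "EGFR", "CETUXIMAB"),
                   list(df_gd = 0L, df_g = 0L, df_d = 0L, P = 0L))
  ann <- cooc_corpus()
  cc <- cooccurrence_counts(ann, "EGFR", "CETUXIMAB")
  expect_identical(cc, list(df_gd = 1L, df_g = 2L, df_d = 1L, P = 3L))
})

test_that("df_gd never exceeds the marginal frequencies on random corpora", {
  for (seed in 701:703) {
    corp <- generate_corpus(synth_config(seed = seed, n_abstracts = 30))
    ann <- annotate_corpus(corp$corpus, corp$lexicons$disease,
                           corp$lexicons$gene, corp$lexicons$drug)
    pair <- corp$truth$planted_pair
    cc <- cooccurrence_counts(ann, pair$gene_id, pair$drug_id)
    expect_lte(cc$df_gd, min(cc$df_g, cc$df_d))
    expect_lte(max(cc$df_g, cc$df_d), cc$P)
  }
})

test_that("connectivity score evaluates the regularized log-odds formula", {
  # hand evaluation: ln(201/21) * 1.5
  expect_equal(connectivity_score(2, 4, 5, 100, 0.5, 1), log(201 / 21) * 1.5,
               tolerance = 1e-12)
  expect_equal(connectivity_score(2, 4, 5, 100, 0.5, 1), 3.388174,
               tolerance = 1e-6)
  # zero counts: ln(lambda/lambda) = 0 whatever the correlation
  expect_identical(connectivity_score(0, 0, 0, 0, 0.7), 0)
  # zero correlation leaves the bare log-odds
  expect_equal(connectivity_score(3, 6, 7, 50, 0),
               log((3 * 50 + 1) / (6 * 7 + 1)))
  expect_error(connectivity_score(2, 4, 5, 100, 0.5, lambda = 0), "positive")
  expect_error(connectivity_score(5, 4, 5, 100, 0.5), "inconsistent")
  expect_error(connectivity_score(2, 4, 5, 100, 1.5), "0, 1")
})

test_that("theta is monotone in df_gd, corpus size and marginal frequencies", {
  base <- connectivity_score(2, 10, 10, 100, 0.3)
  expect_gt(connectivity_score(3, 10, 10, 100, 0.3), base)
  expect_gt(connectivity_score(2, 10, 10, 200, 0.3), base)   # doubling P
  expect_lt(connectivity_score(2, 20, 10, 100, 0.3), base)
  expect_lt(connectivity_score(2, 10, 20, 100, 0.3), base)
  # (1 + corr) amplifies a positive log term
  expect_gt(connectivity_score(2, 10, 10, 100, 0.8), base)
  # ... and deepens a negative one (documented: no clamping)
  neg <- connectivity_score(1, 50, 50, 100, 0)
  expect_lt(connectivity_score(1, 50, 50, 100, 0.9), neg)
})

test_that("target correlation handles self-targets, absences and attenuation", {
  set.seed(702)
  m <- matrix(rnorm(3 * 50, 8), 3, dimnames = list(c("A", "B", "C"),
                                                   sprintf("s%02d", 1:50)))
  expect_identical(target_correlation("A", "A", list(m)), 1)
  expect_identical(target_correlation("A", character(0), list(m)), 0)
  expect_identical(target_correlation("Z", "A", list(m)), 0)  # gene unmeasured
  expect_equal(target_correlation("A", "B", list(m)),
               abs(cor(m["A", ], m["B", ])))
  # flat mean over (target, dataset) pairs
  m2 <- m + rnorm(length(m))
  expect_equal(target_correlation("A", c("B", "C"), list(m, m2)),
               mean(c(abs(cor(m["A", ], m["B", ])),
                      abs(cor(m["A", ], m["C", ])),
                      abs(cor(m2["A", ], m2["B", ])),
                      abs(cor(m2["A", ], m2["C", ])))))
  # attenuation: y = x + noise(sigma) gives corr_gd (the mean |r| over
  # datasets) near 1/sqrt(1+sigma^2)
  set.seed(703)
  for (sig in c(0.5, 1)) {
    dss <- lapply(1:5, function(i) {
      x <- rnorm(200)
      mm <- rbind(X = x, Y = x + rnorm(200, 0, sig))
      colnames(mm) <- sprintf("s%03d", 1:200)
      mm
    })
    expect_lt(abs(target_correlation("X", "Y", dss) -
                  1 / sqrt(1 + sig^2)), 0.05)
  }
})

test_that("the matrix build agrees cell-by-cell with per-pair calls", {
  corp <- generate_corpus(synth_config(seed = 704, n_abstracts = 40))
  ann <- annotate_corpus(corp$corpus, corp$lexicons$disease,
                         corp$lexicons$gene, corp$lexicons$drug)
  ex <- generate_expression(synth_config(seed = 704, n_datasets = 2,
                                         samples_per_group = 5))
  genes <- c(corp$truth$planted_gene_ids[1:3],
             corp$truth$background_gene_ids[1:2])
  drugs <- corp$truth$drug_ids[1:3]
  cm <- build_connectivity_matrix(ann, genes, drugs, corp$drug_targets,
                                  ex$datasets)
  expect_identical(dim(cm$theta), c(5L, 3L))
  for (i in seq_len(nrow(cm$scores))) {
    row <- cm$scores[i, ]
    cc <- cooccurrence_counts(ann, row$gene_id, row$drug_id)
    corr <- target_correlation(row$gene_id,
                               corp$drug_targets[[row$drug_id]],
                               ex$datasets)
    theta <- connectivity_score(cc$df_gd, cc$df_g, cc$df_d, cc$P, corr)
    expect_lt(abs(row$theta - theta), 1e-12)
    expect_lt(abs(cm$theta[row$gene_id, row$drug_id] - theta), 1e-12)
  }
})

test_that("the planted drug-gene pair dominates its row and column", {
  cfg <- synth_config(seed = 705)
  corp <- generate_corpus(cfg)
  ann <- annotate_corpus(corp$corpus, corp$lexicons$disease,
                         corp$lexicons$gene, corp$lexicons$drug)
  ex <- generate_expression(cfg)
  pair <- corp$truth$planted_pair
  genes <- c(corp$truth$planted_gene_ids, corp$truth$background_gene_ids[1:10])
  cm <- build_connectivity_matrix(ann, genes, corp$truth$drug_ids,
                                  corp$drug_targets, ex$datasets)
  th <- cm$theta
  expect_identical(names(which.max(th[pair$gene_id, ])), pair$drug_id)
  expect_identical(names(which.max(th[, pair$drug_id])), pair$gene_id)
})

test_that("drug-target tables read and connectivity maps export", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "targets.tsv")
  writeLines(c("drug_id\tgene_id", "D1\tG1", "D1\tG2", "D2\tG1"), p)
  tg <- read_drug_targets(p)
  expect_identical(tg, list(D1 = c("G1", "G2"), D2 = "G1"))
  ann <- cooc_corpus()
  cm <- build_connectivity_matrix(ann, c("EGFR", "TP53"),
                                  c("CETUXIMAB", "CISPLATIN"))
  lp <- file.path(dir, "long.tsv"); wp <- file.path(dir, "wide.tsv")
  write_connectivity_map(cm, lp, wp)
  expect_identical(nrow(read.delim(lp)), 4L)
  wide <- read_expression_matrix(wp)
  expect_equal(wide, cm$theta)
})
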