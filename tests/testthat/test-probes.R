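test_that("PSL parsing recovers authored fields and flags malformed lines", {
  dir <- withr::local_tempdir()
  fx <- generate_probe_fixture(synth_config(seed = 301), dir = dir)
  alns <- read_psl(fx$paths[["psl_long"]])
  expect_s3_class(alns, "probe_alignments")
  expect_identical(nrow(alns), length(fx$psl_long))
  ok <- alns[alns$probe_id == "p_ok", ]
  expect_identical(c(ok$start, ok$end), c(1200L, 1260L))
  expect_identical(c(ok$matches, ok$mismatches, ok$gap_count), c(60L, 0L, 0L))
  expect_equal(ok$similarity, 100)
  expect_identical(alns$gap_count[alns$probe_id == "p_gap"], 1L)
  # header tolerated
  hdr <- file.path(dir, "with_header.psl")
  writeLines(c("psLayout version 3", "", "match\tmis-", "     \tmatch",
               "---------------", fx$psl_long), hdr)
  expect_identical(nrow(read_psl(hdr)), length(fx$psl_long))
  # empty PSL
  empty <- file.path(dir, "empty.psl")
  writeLines(character(0), empty)
  expect_identical(nrow(read_psl(empty)), 0L)
  # 20 columns -> parse error naming the line
  bad <- file.path(dir, "bad.psl")
  writeLines(c(fx$psl_long[1],
               paste(strsplit(fx$psl_long[2], "\t")[[1]][-21], collapse = "\t")),
             bad)
  expect_error(read_psl(bad), "line 2")
})

test_that("alignment filtering applies the mismatch, gap and strict similarity rules", {
  a <- make_alns(c("keep", "keep_mm1", "mm2", "gap", "sim90"),
                 start = c(0, 100, 200, 300, 400),
                 end = c(60, 160, 260, 360, 454),
                 mismatches = c(0, 1, 2, 0, 0),
                 gap_count = c(0, 0, 0, 1, 0),
                 matches = c(60, 59, 58, 60, 54))
  f <- filter_alignments(a)
  expect_setequal(f$probe_id, c("keep", "keep_mm1"))
  # similarity of exactly 90 is excluded (strict >)
  expect_false("sim90" %in% f$probe_id)
  # idempotent and order-independent
  expect_identical(filter_alignments(f), f)
  perm <- a[c(4, 2, 5, 1, 3), ]
  expect_setequal(filter_alignments(perm)$probe_id, f$probe_id)
})

test_that("probe-set collapse keeps runs of >=3 perfect adjacent probes", {
  two <- make_alns(paste0("S1:", 1:2), start = c(100, 140),
                   end = c(125, 165), query_size = 25,
                   probe_set_id = "S1")
  expect_identical(nrow(collapse_affymetrix_probesets(two)), 0L)
  four <- make_alns(paste0("S2:", 1:4), start = c(100, 150, 200, 250),
                    end = c(125, 175, 225, 275), query_size = 25,
                    probe_set_id = "S2")
  col <- collapse_affymetrix_probesets(four)
  expect_identical(col$probe_id, "S2")
  expect_equal(c(col$start, col$end), c(100, 275))
  # a mismatched probe breaks the run when the gap budget is tight
  mixed <- four
  mixed$mismatches <- c(0L, 1L, 0L, 0L)
  mixed$matches <- c(25L, 24L, 25L, 25L)
  expect_identical(nrow(collapse_affymetrix_probesets(four, 3, 60)), 1L)
  expect_identical(nrow(collapse_affymetrix_probesets(mixed, 3, 60)), 0L)
  expect_error(collapse_affymetrix_probesets(make_alns("x", 1, 26)),
               "probe_set_id")
})

test_that("probe-set retention agrees with the exhaustive window oracle", {
  set.seed(302)
  for (rep in 1:40) {
    n <- sample(1:8, 1)
    starts <- sort(sample(0:3000, n))
    a <- make_alns(paste0("S:", seq_len(n)), start = starts,
                   end = starts + 25L, query_size = 25, probe_set_id = "S")
    got <- nrow(collapse_affymetrix_probesets(a, 3, 200)) == 1L
    expect_identical(got, oracle_probeset_retained(starts, 3, 200),
                     info = paste(starts, collapse = ","))
  }
})

test_that("gene assignment follows coding priority and drops ambiguity", {
  gm <- data.frame(
    gene_id = c("A", "B", "L", "L2"),
    biotype = c("coding", "coding", "lncRNA", "lncRNA"),
    chrom = "chr1", start = c(0, 900, 50, 2000), end = c(1000, 1900, 500, 2500),
    strand = "+", stringsAsFactors = FALSE)
  f <- make_alns(c("in_lnc_only", "coding_beats_lnc", "two_coding",
                   "wrong_strand"),
                 start = c(2100, 100, 950, 100), end = c(2160, 160, 1010, 160),
                 strand = c("+", "+", "+", "-"), chrom = "chr1")
  res <- assign_genes(f, gm)
  expect_identical(res$gene_id[res$feature_id == "in_lnc_only"], "L2")
  prio <- res[res$feature_id == "coding_beats_lnc", ]
  expect_identical(prio$gene_id, "A")
  expect_true(prio$coding_priority_applied)
  amb <- res[res$feature_id == "two_coding", ]
  expect_identical(amb$status, "ambiguous")
  expect_identical(amb$n_candidates, 2L)
  expect_identical(res$status[res$feature_id == "wrong_strand"], "unmapped")
  # --ignore-strand analogue relaxes the last case
  res2 <- assign_genes(f, gm, ignore_strand = TRUE)
  expect_identical(res2$gene_id[res2$feature_id == "wrong_strand"], "A")
})

test_that("overlap assignment agrees with the all-pairs brute-force scan", {
  set.seed(303)
  for (rep in 1:10) {
    n_g <- 30
    gs <- sort(sample(0:20000, n_g))
    gm <- data.frame(gene_id = paste0("g", seq_len(n_g)),
                     biotype = sample(c("coding", "lncRNA"), n_g, TRUE),
                     chrom = sample(c("c1", "c2"), n_g, TRUE),
                     start = gs, end = gs + sample(200:2000, n_g, TRUE),
                     strand = sample(c("+", "-"), n_g, TRUE),
                     stringsAsFactors = FALSE)
    fs <- sample(0:21000, 40)
    f <- make_alns(paste0("p", 1:40), start = fs, end = fs + 60L,
                   chrom = sample(c("c1", "c2"), 40, TRUE),
                   strand = sample(c("+", "-"), 40, TRUE))
    res <- assign_genes(f, gm)
    expect_identical(res$gene_id, oracle_assign(f, gm))
  }
})

test_that("the fixture reannotation reproduces the truth map exactly", {
  dir <- withr::local_tempdir()
  fx <- generate_probe_fixture(synth_config(seed = 304), dir = dir)
  gm <- read_gene_models(fx$paths[["gtf"]])
  expect_identical(gm, fx$gene_models)   # GTF round-trip incl. 1-based shift
  long <- reannotate_probes(read_psl(fx$paths[["psl_long"]]), gm,
                            platform = "long-oligo")
  affx <- reannotate_probes(read_psl(fx$paths[["psl_affx"]]), gm,
                            platform = "affymetrix")
  got <- rbind(long, affx)
  truth <- fx$truth
  for (i in seq_len(nrow(truth))) {
    fid <- truth$feature_id[i]
    expected <- truth$expected_gene[i]
    row <- got[got$feature_id == fid, ]
    if (startsWith(truth$reason[i], "assigned")) {
      expect_identical(row$gene_id, expected, info = fid)
      expect_identical(row$status, "assigned", info = fid)
    } else if (truth$reason[i] %in% c("ambiguous_coding_coding",
                                      "strand_mismatch")) {
      expect_true(is.na(row$gene_id), info = fid)   # reaches assignment, fails
    } else {
      expect_identical(nrow(row), 0L, info = fid)   # dropped before assignment
    }
  }
  # coding-over-lncRNA provenance recorded
  expect_true(got$coding_priority_applied[got$feature_id == "p_prio"])
})

test_that("PSL to BED12 export preserves 0-based half-open coordinates", {
  dir <- withr::local_tempdir()
  fx <- generate_probe_fixture(synth_config(seed = 305), dir = dir)
  alns <- read_psl(fx$paths[["psl_long"]])
  bed <- file.path(dir, "out.bed")
  export_bed12(alns, bed)
  tab <- read.delim(bed, header = FALSE)
  expect_identical(tab$V2, alns$start)
  expect_identical(tab$V3, alns$end)
  expect_identical(as.character(tab$V4), alns$probe_id)
  expect_identical(as.character(tab$V6), alns$strand)
})
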