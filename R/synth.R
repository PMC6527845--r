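#' Configuration for the synthetic-data generators
#'
#' Defines the simulated study conditions: a toy literature corpus with
#' planted disease-associated genes and one planted drug-gene pair, a set of
#' expression datasets with planted group effects and one planted gene-gene
#' correlation, and an authored probe-alignment fixture. Defaults: 200
#' abstracts with 5 planted genes among 50 background genes (planted genes
#' co-occur with disease terms in half the abstracts, background genes appear
#' without disease context at rate 0.1, the planted drug-gene pair co-occurs
#' in 20% of abstracts); 3 expression datasets of 200 genes with 10 tumor and
#' 10 normal samples, unit noise, a 2 log2-unit tumor effect in the planted
#' DE genes, and the correlated pair generated as y = x + N(0, 0.5^2).
#'
#' @param seed Integer master seed; each generator draws from its own
#'   labelled substream so generators do not perturb one another.
#' @param n_abstracts,n_background_genes,n_planted_genes,n_drugs Corpus sizes.
#' @param planted_cooccurrence_rate Probability an abstract carries a
#'   disease/planted-gene co-occurrence sentence.
#' @param background_mention_rate Per-abstract mention probability of each
#'   background gene (gene-only sentences).
#' @param planted_pair_rate Probability an abstract carries the planted
#'   drug-gene-disease sentence.
#' @param sentences_per_abstract Integer range (length-2) of sentence counts.
#' @param n_datasets,genes_per_dataset,samples_per_group Expression sizes.
#' @param n_de_genes Number of genes with a planted tumor effect.
#' @param effect_size_log2,noise_sd Planted effect and baseline SD (log2
#'   units).
#' @param planted_corr_sigma SD of the noise added to generate the planted
#'   correlated gene pair (analytic correlation `1/sqrt(1 + sigma^2)` when
#'   the base gene has unit variance).
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L,
                         n_abstracts = 200L,
                         n_background_genes = 50L,
                         n_planted_genes = 5L,
                         n_drugs = 6L,
                         planted_cooccurrence_rate = 0.5,
                         background_mention_rate = 0.1,
                         planted_pair_rate = 0.2,
                         sentences_per_abstract = c(4L, 8L),
                         n_datasets = 3L,
                         genes_per_dataset = 200L,
                         samples_per_group = 10L,
                         n_de_genes = 20L,
                         effect_size_log2 = 2,
                         noise_sd = 1,
                         planted_corr_sigma = 0.5) {
  cfg <- list(seed = as.integer(seed), n_abstracts = n_abstracts,
              n_background_genes = n_background_genes,
              n_planted_genes = n_planted_genes, n_drugs = n_drugs,
              planted_cooccurrence_rate = planted_cooccurrence_rate,
              background_mention_rate = background_mention_rate,
              planted_pair_rate = planted_pair_rate,
              sentences_per_abstract = sentences_per_abstract,
              n_datasets = n_datasets,
              genes_per_dataset = genes_per_dataset,
              samples_per_group = samples_per_group,
              n_de_genes = n_de_genes,
              effect_size_log2 = effect_size_log2, noise_sd = noise_sd,
              planted_corr_sigma = planted_corr_sigma)
  rates <- c(cfg$planted_cooccurrence_rate, cfg$background_mention_rate,
             cfg$planted_pair_rate)
  stopifnot(all(rates >= 0 & rates <= 1),
            cfg$n_abstracts >= 0, cfg$n_background_genes > 0,
            cfg$n_planted_genes > 0, cfg$n_drugs > 0,
            length(cfg$sentences_per_abstract) == 2L,
            cfg$samples_per_group >= 2, cfg$noise_sd > 0,
            cfg$n_de_genes < cfg$genes_per_dataset)
  if (cfg$planted_cooccurrence_rate < cfg$background_mention_rate)
    warning("planted co-occurrence rate below background mention rate; ",
            "planted signal may not be recoverable")
  structure(cfg, class = "synth_config")
}

# labelled substream seed, kept inside 32-bit integer range
.substream_seed <- function(cfg, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(cfg$seed) * 7919 + h) %% .Machine$integer.max)
}

.gene_ids <- function(n) sprintf("GENE%03d", seq_len(n))
.drug_ids <- function(n) sprintf("DRUG%02d", seq_len(n))

.disease_synonyms <- c("head and neck cancer", "oral cancer", "HNSCC",
                       "laryngeal cancer")

#' Generate a synthetic abstract corpus with planted associations
#'
#' Abstracts are composed from minimal subject-verb-object template
#' sentences. Planted genes co-occur with disease terms; background genes
#' appear in gene-only sentences; drugs appear in drug-disease sentences; one
#' planted drug-gene pair co-occurs (with a disease term) at its own rate.
#' Fully reproducible from the seed.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory; `corpus.tsv` and `lexicon.tsv` are
#'   written there.
#' @return List with `corpus` (data.frame abstract_id/text), `lexicons`
#'   (disease/gene/drug [lexicon()]s), `drug_targets` (the planted pair's
#'   drug targets the expression generator correlates), `truth`
#'   (planted/background ids, planted pair), and `paths` when `dir` is given.
#' @export
generate_corpus <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(.substream_seed(cfg, "corpus"))
  n_genes <- cfg$n_background_genes + cfg$n_planted_genes
  genes <- .gene_ids(n_genes)
  planted <- genes[seq_len(cfg$n_planted_genes)]
  background <- setdiff(genes, planted)
  drugs <- .drug_ids(cfg$n_drugs)
  pair <- list(gene_id = planted[1], drug_id = drugs[1])
  # the pair drug's annotated target: the gene the expression generator
  # correlates with the pair gene
  drug_targets <- stats::setNames(list(.gene_ids(cfg$n_planted_genes + 1)
                                       [cfg$n_planted_genes + 1]),
                                  drugs[1])

  disease_only <- c("Oral cancer incidence continues to rise worldwide.",
                    "Head and neck cancer remains difficult to treat.",
                    "HNSCC prognosis is poor in advanced stages.")
  fillers <- c("The cohort was recruited prospectively.",
               "Samples were processed under a uniform protocol.",
               "Clinical follow-up exceeded five years.",
               "Statistical analyses were two-sided.")
  texts <- character(cfg$n_abstracts)
  ids <- sprintf("PMID%05d", seq_len(cfg$n_abstracts))
  for (i in seq_len(cfg$n_abstracts)) {
    n_sent <- sample(cfg$sentences_per_abstract[1]:
                     cfg$sentences_per_abstract[2], 1L)
    sents <- character(0)
    if (stats::runif(1) < cfg$planted_cooccurrence_rate) {
      g <- sample(planted, 1L)
      dz <- sample(.disease_synonyms, 1L)
      sents <- c(sents, sprintf("%s is frequently overexpressed in %s.", g, dz))
    }
    if (stats::runif(1) < cfg$planted_pair_rate) {
      sents <- c(sents, sprintf("%s inhibits %s in %s models.",
                                pair$drug_id, pair$gene_id,
                                sample(.disease_synonyms, 1L)))
    }
    if (stats::runif(1) < 0.7)
      sents <- c(sents, sample(disease_only, 1L))
    if (stats::runif(1) < 0.3) {
      d <- sample(drugs, 1L)
      sents <- c(sents, sprintf("%s showed activity in patients with %s.",
                                d, sample(.disease_synonyms, 1L)))
    }
    bg_hit <- background[stats::runif(length(background)) <
                         cfg$background_mention_rate]
    if (length(bg_hit) > 3L) bg_hit <- sample(bg_hit, 3L)
    for (g in bg_hit)
      sents <- c(sents, sprintf("%s participates in cell cycle regulation.", g))
    while (length(sents) < n_sent)
      sents <- c(sents, sample(fillers, 1L))
    texts[i] <- paste(sents, collapse = " ")
  }
  corpus <- data.frame(abstract_id = ids, text = texts,
                       stringsAsFactors = FALSE)
  lexicons <- list(
    disease = lexicon("disease", list(HNC = .disease_synonyms)),
    gene = lexicon("gene", stats::setNames(as.list(genes), genes)),
    drug = lexicon("drug", stats::setNames(as.list(drugs), drugs)))
  out <- list(corpus = corpus, lexicons = lexicons,
              drug_targets = drug_targets,
              truth = list(planted_gene_ids = planted,
                           background_gene_ids = background,
                           drug_ids = drugs, planted_pair = pair))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cp <- file.path(dir, "corpus.tsv"); lp <- file.path(dir, "lexicon.tsv")
    utils::write.table(corpus, cp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    lex_df <- do.call(rbind, lapply(lexicons, function(l)
      data.frame(canonical_id = rep(names(l$entries), lengths(l$entries)),
                 category = l$category,
                 synonym = unlist(l$entries, use.names = FALSE),
                 stringsAsFactors = FALSE)))
    utils::write.table(lex_df, lp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tp <- file.path(dir, "drug_targets.tsv")
    utils::write.table(
      data.frame(drug_id = rep(names(drug_targets), lengths(drug_targets)),
                 gene_id = unlist(drug_targets, use.names = FALSE)),
      tp, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- c(corpus = cp, lexicon = lp, drug_targets = tp)
  }
  out
}

#' Generate synthetic expression datasets with planted effects
#'
#' Per dataset: a log2-scale genes-by-samples matrix with baseline
#' N(8, noise_sd^2); the planted DE genes are shifted by `effect_size_log2`
#' (alternating sign) in the tumor group; the planted correlated pair is
#' generated as `y = x + N(0, planted_corr_sigma^2)`. Sample labels cover the
#' tumor/normal, HPV and smoking contrasts. The DE genes are disjoint from
#' the correlated pair so truth labels stay unconfounded.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory for per-dataset matrix/metadata TSVs.
#' @return List with `datasets` (list of [expression_dataset()], already
#'   log2), `truth` (`de_gene_ids` with signed effects, `corr_pair`), and
#'   `paths` when `dir` is given.
#' @export
generate_expression <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$samples_per_group < 2L) stop("samples_per_group must be >= 2")
  genes <- .gene_ids(cfg$genes_per_dataset)
  # DE genes start after the corpus entities' planted block + pair target
  de_start <- cfg$n_planted_genes + 2L
  de_genes <- genes[de_start:(de_start + cfg$n_de_genes - 1L)]
  effects <- stats::setNames(cfg$effect_size_log2 *
                             rep_len(c(1, -1), cfg$n_de_genes), de_genes)
  corr_pair <- c(x = genes[1], y = genes[cfg$n_planted_genes + 1L])
  datasets <- vector("list", cfg$n_datasets)
  paths <- character(0)
  for (d in seq_len(cfg$n_datasets)) {
    set.seed(.substream_seed(cfg, paste0("expression", d)))
    n <- 2L * cfg$samples_per_group
    samples <- sprintf("DS%d_S%02d", d, seq_len(n))
    group <- rep(c("tumor", "normal"), each = cfg$samples_per_group)
    mat <- matrix(stats::rnorm(length(genes) * n, mean = 8,
                               sd = cfg$noise_sd),
                  nrow = length(genes), dimnames = list(genes, samples))
    for (g in de_genes)
      mat[g, group == "tumor"] <- mat[g, group == "tumor"] + effects[[g]]
    mat[corr_pair[["y"]], ] <- mat[corr_pair[["x"]], ] +
      stats::rnorm(n, 0, cfg$planted_corr_sigma)
    hpv <- ifelse(group == "tumor",
                  rep_len(c("positive", "negative"), n), "unknown")
    smoking <- rep_len(c("smoker", "non-smoker"), n)
    meta <- data.frame(sample_id = samples, group = group, hpv = hpv,
                       smoking = smoking, stringsAsFactors = FALSE)
    ds_id <- sprintf("synthDS%d", d)
    datasets[[d]] <- expression_dataset(ds_id, mat, meta, is_log2 = TRUE)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      mp <- file.path(dir, paste0(ds_id, "_matrix.tsv"))
      sp <- file.path(dir, paste0(ds_id, "_metadata.tsv"))
      write_expression_matrix(mat, mp)
      utils::write.table(meta, sp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, mp, sp)
    }
  }
  names(datasets) <- vapply(datasets, `[[`, character(1), "dataset_id")
  out <- list(datasets = datasets,
              truth = list(de_gene_ids = de_genes, de_effects = effects,
                           corr_pair = corr_pair))
  if (!is.null(dir)) out$paths <- paths
  out
}

.psl_line <- function(matches, mismatches, qnumins, tnumins, strand, qname,
                      qsize, tname, tstart, tend) {
  paste(matches, mismatches, 0L, 0L, qnumins, qnumins, tnumins, tnumins,
        strand, qname, qsize, 0L, qsize, tname, 50000L, tstart, tend, 1L,
        paste0(tend - tstart, ","), "0,", paste0(tstart, ","), sep = "\t")
}

#' Generate the probe-reannotation fixture with truth labels
#'
#' Authors a toy chromosome with four coding genes and two lncRNAs, a
#' long-oligo PSL containing one probe per assignment outcome (clean
#' assignment, one tolerated mismatch, and decoys violating each rule:
#' two mismatches, a gap, similarity exactly at the threshold, a
#' multi-mapper, a strand mismatch, coding/coding ambiguity) plus the
#' coding-over-lncRNA priority case, and an Affymetrix PSL with probe sets
#' that pass, fail the three-perfect-probes rule, and fail the adjacency
#' rule. The truth table records the intended assignment or drop reason per
#' feature.
#'
#' @param cfg A [synth_config()] (the fixture is deterministic; the seed only
#'   names the output).
#' @param dir Optional output directory for `probes_long.psl`,
#'   `probes_affx.psl` and `genes.gtf`.
#' @return List with `psl_long`, `psl_affx` (character vectors of PSL lines),
#'   `gtf` (GTF lines), `gene_models` (parsed data.frame), `truth`
#'   (data.frame feature_id / expected_gene / reason), and `paths` when
#'   `dir` is given.
#' @export
generate_probe_fixture <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  gm <- data.frame(
    gene_id = c("G1", "G2", "G3", "G4", "L1", "L2"),
    biotype = c("coding", "coding", "coding", "coding", "lncRNA", "lncRNA"),
    chrom = "chrT",
    start = c(1000L, 10000L, 20000L, 20500L, 5000L, 10500L),
    end = c(3000L, 11000L, 21000L, 21500L, 6000L, 11500L),
    strand = c("+", "+", "+", "+", "+", "+"),
    stringsAsFactors = FALSE)
  long <- c(
    .psl_line(60, 0, 0, 0, "+", "p_ok", 60, "chrT", 1200, 1260),
    .psl_line(59, 1, 0, 0, "+", "p_mm1", 60, "chrT", 1320, 1380),
    .psl_line(58, 2, 0, 0, "+", "p_mm2", 60, "chrT", 1440, 1500),
    .psl_line(60, 0, 1, 0, "+", "p_gap", 60, "chrT", 1560, 1621),
    .psl_line(54, 0, 0, 0, "+", "p_sim90", 60, "chrT", 1680, 1734),
    .psl_line(60, 0, 0, 0, "+", "p_lnc", 60, "chrT", 5100, 5160),
    .psl_line(60, 0, 0, 0, "+", "p_prio", 60, "chrT", 10600, 10660),
    .psl_line(60, 0, 0, 0, "+", "p_amb", 60, "chrT", 20600, 20660),
    .psl_line(60, 0, 0, 0, "+", "p_multi", 60, "chrT", 1800, 1860),
    .psl_line(60, 0, 0, 0, "+", "p_multi", 60, "chrT", 5300, 5360),
    .psl_line(60, 0, 0, 0, "-", "p_strand", 60, "chrT", 1900, 1960))
  affx_starts <- list(
    AFFX1 = c(1400L, 1450L, 1500L, 1550L),          # pass: 4 perfect, adjacent
    AFFX2 = c(2100L, 2150L),                        # fail: only 2 perfect
    AFFX3 = c(2300L, 2600L, 2900L, 3200L))          # fail: starts 300 bp apart
  affx <- unlist(lapply(names(affx_starts), function(set) {
    vapply(seq_along(affx_starts[[set]]), function(i) {
      s <- affx_starts[[set]][i]
      .psl_line(25, 0, 0, 0, "+", paste0(set, ":", i), 25, "chrT", s, s + 25L)
    }, character(1))
  }))
  truth <- data.frame(
    feature_id = c("p_ok", "p_mm1", "p_mm2", "p_gap", "p_sim90", "p_lnc",
                   "p_prio", "p_amb", "p_multi", "p_strand",
                   "AFFX1", "AFFX2", "AFFX3"),
    expected_gene = c("G1", "G1", NA, NA, NA, "L1", "G2", NA, NA, NA,
                      "G1", NA, NA),
    reason = c("assigned", "assigned", "filtered_mismatch", "filtered_gap",
               "filtered_similarity", "assigned", "assigned_coding_priority",
               "ambiguous_coding_coding", "multimapper", "strand_mismatch",
               "assigned", "too_few_perfect_probes", "not_adjacent"),
    stringsAsFactors = FALSE)
  gtf <- vapply(seq_len(nrow(gm)), function(i) {
    bt <- if (gm$biotype[i] == "coding") "protein_coding" else "lncRNA"
    paste(gm$chrom[i], "synth", "gene", gm$start[i] + 1L, gm$end[i], ".",
          gm$strand[i], ".",
          sprintf('gene_id "%s"; gene_biotype "%s";', gm$gene_id[i], bt),
          sep = "\t")
  }, character(1))
  out <- list(psl_long = long, psl_affx = affx, gtf = gtf, gene_models = gm,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pl <- file.path(dir, "probes_long.psl")
    pa <- file.path(dir, "probes_affx.psl")
    gp <- file.path(dir, "genes.gtf")
    writeLines(long, pl); writeLines(affx, pa); writeLines(gtf, gp)
    tp <- file.path(dir, "probe_truth.tsv")
    utils::write.table(truth, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- c(psl_long = pl, psl_affx = pa, gtf = gp, truth = tp)
  }
  out
}
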