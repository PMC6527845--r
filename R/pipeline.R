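#' Run the whole pipeline end-to-end on synthetic inputs
#'
#' Simulates a corpus, expression datasets and the probe fixture from one
#' seed, then runs every stage: probe reannotation, corpus annotation,
#' gene/drug candidate ranking, per-dataset differential expression and
#' significance filtering, robust rank aggregation in both directions, and
#' the gene x drug connectivity map over the top-ranked candidates. Writes
#' all stage outputs plus a markdown report of per-stage record counts and
#' the top connectivity pairs. Deterministic given the seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for the generators.
#' @param cfg A [synth_config()]; defaults to `synth_config(seed = seed)`.
#' @param weights A [score_weights()].
#' @param min_score Candidate threshold, see [rank_candidates()].
#' @param alpha DE significance threshold.
#' @param lambda Connectivity regularization constant.
#' @param n_top_genes Number of top-ranked genes carried into the
#'   connectivity map (all ranked drugs are used as columns).
#' @return Invisibly, a list with the stage objects (`gene_ranking`,
#'   `drug_ranking`, `de_tables`, `ar_up`, `ar_down`, `cmap`, `probe_map`,
#'   `report_path`, ...).
#' @export
run_end_to_end <- function(out_dir, seed = 1L, cfg = synth_config(seed = seed),
                           weights = score_weights(), min_score = 1,
                           alpha = 0.05, lambda = 1, n_top_genes = 20L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_dir <- file.path(out_dir, "simulated")
  corp <- generate_corpus(cfg, dir = sim_dir)
  expr <- generate_expression(cfg, dir = sim_dir)
  probes <- generate_probe_fixture(cfg, dir = sim_dir)

  # probe reannotation on the authored fixture
  gm <- read_gene_models(probes$paths[["gtf"]])
  long <- read_psl(probes$paths[["psl_long"]])
  affx <- read_psl(probes$paths[["psl_affx"]])
  map_long <- reannotate_probes(long, gm, platform = "long-oligo")
  map_affx <- reannotate_probes(affx, gm, platform = "affymetrix")
  probe_map <- rbind(map_long, map_affx)
  utils::write.table(probe_map, file.path(out_dir, "probe_gene_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # corpus annotation and candidate ranking
  ann <- annotate_corpus(corp$corpus, corp$lexicons$disease,
                         corp$lexicons$gene, corp$lexicons$drug)
  gene_ranking <- rank_candidates(ann, "gene", weights, min_score)
  drug_ranking <- rank_candidates(ann, "drug", weights, min_score)
  utils::write.table(gene_ranking, file.path(out_dir, "gene_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(drug_ranking, file.path(out_dir, "drug_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # per-dataset DE + aggregation
  de_tables <- lapply(expr$datasets, differential_expression,
                      contrast = "tumor_vs_normal")
  for (id in names(de_tables))
    utils::write.table(de_tables[[id]],
                       file.path(out_dir, paste0("de_", id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  n_sig <- vapply(de_tables, function(t) nrow(significant_genes(t, alpha)),
                  integer(1))
  ar_up <- aggregate_datasets(de_tables, "up")
  ar_down <- aggregate_datasets(de_tables, "down")
  for (dirn in c("up", "down")) {
    tab <- if (dirn == "up") ar_up else ar_down
    utils::write.table(
      tab[, c("gene_id", "direction", "rho", "meta_score",
              "n_datasets_measured")],
      file.path(out_dir, paste0("ar_", dirn, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # connectivity map over the top candidates
  top_genes <- utils::head(gene_ranking$entity_id, n_top_genes)
  cmap_drugs <- if (nrow(drug_ranking)) drug_ranking$entity_id
                else corp$truth$drug_ids
  cmap <- build_connectivity_matrix(ann, top_genes, cmap_drugs,
                                    corp$drug_targets, expr$datasets,
                                    lambda = lambda)
  write_connectivity_map(cmap, file.path(out_dir, "cmap_long.tsv"),
                         file.path(out_dir, "cmap_theta.tsv"))

  top_pairs <- cmap$scores[order(-cmap$scores$theta), ][1:min(5, nrow(cmap$scores)), ]
  report <- c(
    "# Pipeline report", "",
    sprintf("- seed: %d", cfg$seed),
    sprintf("- abstracts scanned: %d", nrow(corp$corpus)),
    sprintf("- term hits: %d",
            sum(vapply(ann, function(a) nrow(a$hits), integer(1)))),
    sprintf("- gene candidates above threshold: %d", nrow(gene_ranking)),
    sprintf("- drug candidates above threshold: %d", nrow(drug_ranking)),
    sprintf("- probe features assigned: %d / %d",
            sum(probe_map$status == "assigned"), nrow(probe_map)),
    sprintf("- expression datasets: %d (%d genes each)",
            length(expr$datasets), cfg$genes_per_dataset),
    sprintf("- significant genes (p < %g) per dataset: %s", alpha,
            paste(n_sig, collapse = ", ")),
    sprintf("- connectivity map: %d genes x %d drugs",
            nrow(cmap$theta), ncol(cmap$theta)),
    "", "## Top connectivity pairs", "",
    sprintf("| %s | %s | theta %.3f (df_gd=%d, corr=%.2f) |",
            top_pairs$gene_id, top_pairs$drug_id, top_pairs$theta,
            top_pairs$df_gd, top_pairs$corr_gd))
  report_path <- file.path(out_dir, "report.md")
  writeLines(report, report_path)
  invisible(list(gene_ranking = gene_ranking, drug_ranking = drug_ranking,
                 annotations = ann, de_tables = de_tables, ar_up = ar_up,
                 ar_down = ar_down, cmap = cmap, probe_map = probe_map,
                 truth = list(corpus = corp$truth, expression = expr$truth,
                              probes = probes$truth),
                 report_path = report_path, out_dir = out_dir))
}
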