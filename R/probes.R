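#' Default alignment similarity score
#'
#' `100 * matches / query_size`, i.e. the percentage of the probe sequence
#' aligned without mismatch. Any function of the three arguments returning a
#' 0-100 score can be substituted in [filter_alignments()].
#'
#' @param matches,mismatches,query_size Integer vectors from the PSL record.
#' @return Numeric similarity on a 0-100 scale.
#' @export
psl_similarity <- function(matches, mismatches, query_size) {
  100 * matches / query_size
}

.psl_cols <- c("matches", "misMatches", "repMatches", "nCount", "qNumInsert",
               "qBaseInsert", "tNumInsert", "tBaseInsert", "strand", "qName",
               "qSize", "qStart", "qEnd", "tName", "tSize", "tStart", "tEnd",
               "blockCount", "blockSizes", "qStarts", "tStarts")

#' Read BLAT alignments from a PSL file
#'
#' Parses the standard 21-column PSL format (optional 5-line header
#' tolerated). Target coordinates are kept in PSL's native 0-based half-open
#' convention. The probe-set id of Affymetrix-style probes is taken from the
#' query name by the convention `<probe_set_id>:<probe_index>`; query names
#' without a colon get `probe_set_id = NA`. Gap count is
#' `qNumInsert + tNumInsert`.
#'
#' @param path Path to a PSL file.
#' @param similarity Similarity function, see [psl_similarity()].
#' @return data.frame of class `"probe_alignments"` with columns `probe_id`,
#'   `probe_set_id`, `chrom`, `start`, `end`, `strand`, `matches`,
#'   `mismatches`, `gap_count`, `query_size`, `similarity`, plus the raw
#'   block columns (`block_count`, `block_sizes`, `t_starts`) for BED12
#'   export.
#' @export
read_psl <- function(path, similarity = psl_similarity) {
  lines <- readLines(path, warn = FALSE)
  # optional header: "psLayout ..." then column names over two lines and a
  # dashed rule
  if (length(lines) && startsWith(lines[1], "psLayout")) {
    rule <- grep("^-{5,}", lines)
    lines <- if (length(rule)) lines[-seq_len(rule[1])] else lines[-(1:5)]
  }
  keep <- which(nzchar(trimws(lines)))
  recs <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 21L)
      stop("PSL parse error at line ", i, ": expected 21 tab-separated ",
           "columns, found ", length(f))
    recs[[j]] <- f
  }
  m <- do.call(rbind, recs)
  if (is.null(m)) m <- matrix(character(0), ncol = 21)
  colnames(m) <- .psl_cols
  num <- function(col) as.integer(m[, col])
  qname <- as.character(m[, "qName"])
  df <- data.frame(
    probe_id = qname,
    probe_set_id = ifelse(grepl(":", qname), sub(":[^:]*$", "", qname),
                          NA_character_),
    chrom = as.character(m[, "tName"]),
    start = num("tStart"), end = num("tEnd"),
    strand = as.character(m[, "strand"]),
    matches = num("matches"), mismatches = num("misMatches"),
    gap_count = num("qNumInsert") + num("tNumInsert"),
    query_size = num("qSize"),
    block_count = num("blockCount"),
    block_sizes = as.character(m[, "blockSizes"]),
    t_starts = as.character(m[, "tStarts"]),
    stringsAsFactors = FALSE)
  bad <- which(df$start >= df$end | df$matches + df$mismatches > df$query_size)
  if (length(bad))
    stop("PSL record invariant violated at line ", keep[bad[1]],
         " (need start < end and matches + mismatches <= query size)")
  df$similarity <- similarity(df$matches, df$mismatches, df$query_size)
  class(df) <- c("probe_alignments", "data.frame")
  df
}

#' Filter probe alignments on mismatch, gap and similarity rules
#'
#' Keeps alignments with at most `max_mismatch` mismatches, at most `max_gap`
#' gap openings, and similarity strictly greater than `min_similarity`
#' (defaults: one mismatch, no gaps, similarity > 90).
#'
#' @param alns A `"probe_alignments"` data.frame.
#' @param max_mismatch,max_gap,min_similarity Filter thresholds.
#' @param similarity Similarity function used to (re)compute the score.
#' @return The surviving subset, same class. Idempotent and
#'   order-independent.
#' @export
filter_alignments <- function(alns, max_mismatch = 1, max_gap = 0,
                              min_similarity = 90,
                              similarity = psl_similarity) {
  sim <- similarity(alns$matches, alns$mismatches, alns$query_size)
  keep <- alns$mismatches <= max_mismatch & alns$gap_count <= max_gap &
    sim > min_similarity
  out <- alns[keep, , drop = FALSE]
  out$similarity <- sim[keep]
  rownames(out) <- NULL
  out
}

# maximal runs of perfect probes (sorted by start) whose consecutive starts
# differ by <= gap
.probe_runs <- function(starts, gap) {
  if (!length(starts)) return(list())
  o <- order(starts); s <- starts[o]
  brk <- c(0L, which(diff(s) > gap), length(s))
  lapply(seq_len(length(brk) - 1L),
         function(i) o[(brk[i] + 1L):brk[i + 1L]])
}

#' Collapse Affymetrix probe sets to one record per retained set
#'
#' A probe set is retained iff, on a single chromosome/strand, it has a run of
#' at least `min_perfect_adjacent` perfectly matching probes (no mismatches,
#' no gaps) whose consecutive genomic starts differ by at most
#' `adjacency_gap_bp`. The emitted record spans the qualifying run (longest
#' run; the set's id becomes the feature id). Sets qualifying at more than one
#' locus are dropped as non-specific.
#'
#' @param alns A `"probe_alignments"` data.frame; every record must carry a
#'   `probe_set_id`.
#' @param min_perfect_adjacent Minimum run length (default 3).
#' @param adjacency_gap_bp Maximum start-to-start distance within a run
#'   (default 200 bp; Affymetrix 25-mers tile short target regions).
#' @return A `"probe_alignments"` data.frame with one synthetic record per
#'   retained probe set.
#' @export
collapse_affymetrix_probesets <- function(alns, min_perfect_adjacent = 3,
                                          adjacency_gap_bp = 200) {
  if (anyNA(alns$probe_set_id))
    stop("all alignments must carry a probe_set_id ",
         "(qName convention '<set>:<probe>')")
  out <- list()
  for (set in unique(alns$probe_set_id)) {
    sub <- alns[alns$probe_set_id == set & alns$mismatches == 0 &
                alns$gap_count == 0, , drop = FALSE]
    loci <- list()
    for (key in unique(paste(sub$chrom, sub$strand))) {
      grp <- sub[paste(sub$chrom, sub$strand) == key, , drop = FALSE]
      runs <- .probe_runs(grp$start, adjacency_gap_bp)
      runs <- runs[lengths(runs) >= min_perfect_adjacent]
      if (!length(runs)) next
      run <- runs[[which.max(lengths(runs))]]
      loci[[length(loci) + 1L]] <- data.frame(
        probe_id = set, probe_set_id = set,
        chrom = grp$chrom[1], start = min(grp$start[run]),
        end = max(grp$end[run]), strand = grp$strand[1],
        matches = sum(grp$matches[run]), mismatches = 0L, gap_count = 0L,
        query_size = sum(grp$query_size[run]),
        block_count = length(run),
        block_sizes = paste0(paste(grp$end[run][order(grp$start[run])] -
                                   sort(grp$start[run]), collapse = ","), ","),
        t_starts = paste0(paste(sort(grp$start[run]), collapse = ","), ","),
        stringsAsFactors = FALSE)
    }
    if (length(loci) == 1L) out[[length(out) + 1L]] <- loci[[1L]]
  }
  res <- if (length(out)) do.call(rbind, out) else
    alns[0, setdiff(names(alns), "similarity"), drop = FALSE]
  res$similarity <- 100 * res$matches / res$query_size
  rownames(res) <- NULL
  class(res) <- c("probe_alignments", "data.frame")
  res
}

#' Drop features aligning to more than one genomic locus
#'
#' @param alns A `"probe_alignments"` data.frame (post-filter).
#' @return Subset with only uniquely aligning feature ids.
#' @export
drop_multimappers <- function(alns) {
  n <- table(alns$probe_id)
  out <- alns[alns$probe_id %in% names(n)[n == 1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene models from GTF or TSV
#'
#' GTF/GFF input is parsed with rtracklayer; `gene`-type features are used
#' (all features if no `type` column), with `gene_biotype`/`gene_type`
#' attributes mapped onto the two classes this pipeline distinguishes:
#' `protein_coding` -> `coding`, `lncRNA`/`lincRNA` -> `lncRNA` (other
#' biotypes are dropped with a message). Alternatively a TSV with columns
#' `gene_id`, `biotype`, `chrom`, `start`, `end`, `strand` already in 0-based
#' half-open coordinates is accepted as-is. GTF's 1-based closed coordinates
#' are converted at this boundary; everything downstream is 0-based half-open.
#'
#' @param path Path to a `.gtf`/`.gff` or `.tsv`/`.txt` file.
#' @return data.frame `gene_id`, `biotype` (`coding`/`lncRNA`), `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff2", "gff3")) {
    gr <- rtracklayer::import(path, format = if (ext == "gtf") "gtf" else "gff")
    mc <- S4Vectors::mcols(gr)
    if ("type" %in% names(mc) && any(mc$type == "gene"))
      gr <- gr[mc$type == "gene"]
    mc <- S4Vectors::mcols(gr)
    bt_col <- intersect(c("gene_biotype", "gene_type", "biotype"), names(mc))
    if (!length(bt_col)) stop("GTF lacks a gene biotype attribute")
    raw_bt <- as.character(mc[[bt_col[1]]])
    biotype <- ifelse(raw_bt == "protein_coding", "coding",
                      ifelse(raw_bt %in% c("lncRNA", "lincRNA"), "lncRNA",
                             NA_character_))
    if (anyNA(biotype))
      message(sum(is.na(biotype)), " gene model(s) with other biotypes dropped")
    df <- data.frame(
      gene_id = as.character(mc$gene_id),
      biotype = biotype,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    df <- df[!is.na(df$biotype), , drop = FALSE]
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "biotype", "chrom", "start", "end", "strand")
    if (!all(need %in% names(df)))
      stop("gene model TSV must have columns: ", paste(need, collapse = ", "))
    df <- df[, need]
  }
  stopifnot(all(df$start < df$end), all(df$biotype %in% c("coding", "lncRNA")))
  rownames(df) <- NULL
  df
}

#' Assign features to genes by genomic overlap with coding priority
#'
#' A feature overlapping exactly one gene is assigned to it; a feature
#' overlapping one coding gene plus any number of lncRNAs is assigned to the
#' coding gene (coding priority); a feature overlapping two or more coding
#' genes, or two or more lncRNAs and no coding gene, is dropped as ambiguous.
#' Overlap is strand-aware unless `ignore_strand = TRUE`.
#'
#' @param features data.frame with `probe_id` (or `feature_id`), `chrom`,
#'   `start`, `end`, `strand` in 0-based half-open coordinates (e.g. filtered
#'   [read_psl()] output or [collapse_affymetrix_probesets()] output).
#' @param gene_models data.frame from [read_gene_models()].
#' @param ignore_strand Relax the strand-match requirement.
#' @return data.frame `feature_id`, `gene_id` (NA when not assigned),
#'   `biotype`, `n_candidates`, `coding_priority_applied`, `status`
#'   (`assigned`/`ambiguous`/`unmapped`). The probe-to-gene map proper is the
#'   `status == "assigned"` subset.
#' @export
assign_genes <- function(features, gene_models, ignore_strand = FALSE) {
  fid <- if ("feature_id" %in% names(features)) features$feature_id
         else features$probe_id
  fgr <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start + 1L, features$end),  # GRanges is 1-based
    strand = features$strand)
  ggr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$start + 1L, gene_models$end),
    strand = gene_models$strand)
  ov <- GenomicRanges::findOverlaps(fgr, ggr, ignore.strand = ignore_strand)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  out <- data.frame(feature_id = fid, gene_id = NA_character_,
                    biotype = NA_character_, n_candidates = 0L,
                    coding_priority_applied = FALSE,
                    status = "unmapped", stringsAsFactors = FALSE)
  for (i in seq_along(fid)) {
    cand <- sh[qh == i]
    out$n_candidates[i] <- length(cand)
    if (!length(cand)) next
    bt <- gene_models$biotype[cand]
    coding <- cand[bt == "coding"]
    if (length(coding) == 1L) {
      out$gene_id[i] <- gene_models$gene_id[coding]
      out$biotype[i] <- "coding"
      out$coding_priority_applied[i] <- any(bt == "lncRNA")
      out$status[i] <- "assigned"
    } else if (length(coding) == 0L && length(cand) == 1L) {
      out$gene_id[i] <- gene_models$gene_id[cand]
      out$biotype[i] <- "lncRNA"
      out$status[i] <- "assigned"
    } else {
      out$status[i] <- "ambiguous"
    }
  }
  out
}

#' Full probe reannotation pipeline
#'
#' Filter alignments, (for Affymetrix) collapse probe sets, drop
#' multi-mapping features, and assign the survivors to genes.
#'
#' @param alns [read_psl()] output.
#' @param gene_models [read_gene_models()] output.
#' @param platform `"long-oligo"` (one probe = one feature; Agilent/Illumina
#'   style) or `"affymetrix"` (collapse probe sets first).
#' @inheritParams filter_alignments
#' @inheritParams collapse_affymetrix_probesets
#' @inheritParams assign_genes
#' @return As [assign_genes()], with dropped-before-assignment features
#'   absent.
#' @export
reannotate_probes <- function(alns, gene_models,
                              platform = c("long-oligo", "affymetrix"),
                              max_mismatch = 1, max_gap = 0,
                              min_similarity = 90,
                              min_perfect_adjacent = 3,
                              adjacency_gap_bp = 200,
                              ignore_strand = FALSE,
                              similarity = psl_similarity) {
  platform <- match.arg(platform)
  flt <- filter_alignments(alns, max_mismatch, max_gap, min_similarity,
                           similarity)
  feats <- if (platform == "affymetrix")
    collapse_affymetrix_probesets(flt, min_perfect_adjacent, adjacency_gap_bp)
  else drop_multimappers(flt)
  assign_genes(feats, gene_models, ignore_strand)
}

#' Export alignment features as BED12
#'
#' Coordinates pass through unchanged (PSL and BED share the 0-based
#' half-open convention), so PSL -> internal -> BED12 is lossless.
#'
#' @param alns A `"probe_alignments"` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_bed12 <- function(alns, path) {
  block_starts <- vapply(seq_len(nrow(alns)), function(i) {
    ts <- as.integer(strsplit(sub(",$", "", alns$t_starts[i]), ",")[[1]])
    paste0(paste(ts - alns$start[i], collapse = ","), ",")
  }, character(1))
  bed <- data.frame(alns$chrom, alns$start, alns$end, alns$probe_id, 0L,
                    alns$strand, alns$start, alns$end, "0,0,0",
                    alns$block_count, alns$block_sizes, block_starts)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
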