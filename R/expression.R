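#' Construct an expression dataset
#'
#' Bundles a features-by-samples matrix with per-sample metadata. Metadata
#' columns `group` (tumor/normal), `hpv` (positive/negative/unknown) and
#' `smoking` (smoker/non-smoker/unknown) drive the differential-expression
#' contrasts; absent columns are filled with "unknown".
#'
#' @param dataset_id Identifier string.
#' @param matrix Numeric matrix, feature ids as rownames, sample ids as
#'   colnames. NAs allowed; infinite values are not.
#' @param metadata data.frame keyed by `sample_id` (column or rownames).
#' @param is_log2 Logical or NA (unknown until [log2_if_needed()] runs).
#' @return Object of class `"expression_dataset"`.
#' @export
expression_dataset <- function(dataset_id, matrix, metadata = NULL,
                               is_log2 = NA) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("matrix needs feature rownames and sample colnames")
  if (anyDuplicated(rownames(matrix)) || anyDuplicated(colnames(matrix)))
    stop("duplicate feature or sample ids")
  if (any(is.infinite(matrix))) stop("matrix contains infinite values")
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = colnames(matrix),
                           stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(metadata)) {
    metadata <- cbind(sample_id = rownames(metadata), metadata,
                      stringsAsFactors = FALSE)
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  if (!setequal(metadata$sample_id, colnames(matrix)))
    stop("metadata sample ids do not match matrix columns")
  metadata <- metadata[match(colnames(matrix), metadata$sample_id), ,
                       drop = FALSE]
  for (col in c("group", "hpv", "smoking"))
    if (!col %in% names(metadata)) metadata[[col]] <- "unknown"
  rownames(metadata) <- NULL
  structure(list(dataset_id = as.character(dataset_id), matrix = matrix,
                 metadata = metadata, is_log2 = is_log2),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset %s> %d features x %d samples (log2: %s)\n",
              x$dataset_id, nrow(x$matrix), ncol(x$matrix),
              as.character(x$is_log2)))
  print(table(group = x$metadata$group))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' First column feature ids, header sample ids.
#'
#' @param path TSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Read sample metadata from TSV
#'
#' @param path TSV path with a `sample_id` column.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata TSV needs a sample_id column")
  df
}

#' Quantile-normalize a matrix
#'
#' Forces every sample column onto one common empirical distribution: the
#' value at rank r of each column is replaced by the mean across columns of
#' the r-th order statistics. Ties within a column receive the mean of the
#' tied target values (via average ranks with linear interpolation into the
#' target vector). Rows containing any NA are excluded from the target
#' computation and returned as NA.
#'
#' @param mat Numeric matrix (features x samples), >= 2 columns.
#' @return Normalized matrix of the same shape and dimnames. A single-column
#'   matrix is returned unchanged with a warning.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 2L) {
    warning("quantile normalization needs >= 2 samples; matrix unchanged")
    return(mat)
  }
  complete <- stats::complete.cases(mat)
  sub <- mat[complete, , drop = FALSE]
  out <- mat
  out[!complete, ] <- NA_real_
  if (nrow(sub) == 0L) return(out)
  target <- rowMeans(apply(sub, 2L, sort))
  for (j in seq_len(ncol(sub))) {
    r <- rank(sub[, j], ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    out[complete, j] <- target[lo] + (r - lo) * (target[hi] - target[lo])
  }
  out
}

#' Log2-transform a matrix if it is not already in log space
#'
#' Heuristic: microarray intensities already on the log2 scale rarely exceed
#' ~20, so the transform `x -> log2(x + eps)` is applied iff the matrix
#' maximum exceeds `threshold` (default 50). `eps` (default 1) guards zeros in
#' raw intensities.
#'
#' @param mat Numeric matrix.
#' @param threshold Linear-scale detection threshold on the matrix maximum.
#' @param eps Pseudocount added before the log.
#' @return `list(matrix =, was_transformed =)`.
#' @export
log2_if_needed <- function(mat, threshold = 50, eps = 1) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  mx <- suppressWarnings(max(mat, na.rm = TRUE))
  if (is.finite(mx) && mx > threshold) {
    if (any(mat < 0, na.rm = TRUE))
      stop("matrix looks linear-scale (max > ", threshold,
           ") but contains negative values; cannot log2-transform")
    list(matrix = log2(mat + eps), was_transformed = TRUE)
  } else {
    list(matrix = mat, was_transformed = FALSE)
  }
}

#' Collapse probe-level values to gene level by averaging
#'
#' Per gene and sample, the arithmetic mean of all mapped probe values.
#' Probes absent from the map are dropped; genes are ordered
#' lexicographically.
#'
#' @param mat Probe-level matrix (probes x samples).
#' @param map Probe-to-gene map: either the [assign_genes()] output (its
#'   `status == "assigned"` rows are used) or any data.frame with columns
#'   `feature_id`, `gene_id`.
#' @return Gene-level matrix.
#' @export
collapse_to_genes <- function(mat, map) {
  if ("status" %in% names(map)) map <- map[map$status == "assigned", ]
  map <- map[!is.na(map$gene_id), c("feature_id", "gene_id")]
  common <- intersect(rownames(mat), map$feature_id)
  if (!length(common))
    stop("no matrix features found in the probe-gene map")
  gene <- map$gene_id[match(common, map$feature_id)]
  sums <- rowsum(mat[common, , drop = FALSE], group = gene, reorder = TRUE)
  counts <- as.vector(table(gene)[rownames(sums)])
  sums / counts
}

#' Normalize an expression dataset
#'
#' Applies [log2_if_needed()] and then [quantile_normalize()] (quantile step
#' optional), recording the log-scale state.
#'
#' @param ds An [expression_dataset()].
#' @param quantile Apply quantile normalization (default TRUE).
#' @param log2_threshold,eps Passed to [log2_if_needed()].
#' @return The normalized `expression_dataset` with `is_log2 = TRUE`.
#' @export
normalize_dataset <- function(ds, quantile = TRUE, log2_threshold = 50,
                              eps = 1) {
  stopifnot(inherits(ds, "expression_dataset"))
  lg <- log2_if_needed(ds$matrix, log2_threshold, eps)
  m <- lg$matrix
  if (quantile && ncol(m) >= 2L) m <- quantile_normalize(m)
  expression_dataset(ds$dataset_id, m, ds$metadata, is_log2 = TRUE)
}

#' Write an expression matrix as TSV
#'
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the leading feature-id column.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
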