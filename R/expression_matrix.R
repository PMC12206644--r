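#' Construct an expression matrix
#'
#' Container for a gene-by-sample expression matrix. Values are linear TPM
#' (transcripts per million) unless `transformed = TRUE`, in which case they
#' are `log2(TPM + 1)`. All scoring functions require the transformed view;
#' use [log2_transform()] to obtain it.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names are sample identifiers; both required
#'   and duplicate-free.
#' @param transformed Logical flag: are the values already `log2(TPM + 1)`?
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix), `gene_ids`, `sample_ids` and `transformed`.
#' @seealso [read_tpm_matrix()], [log2_transform()]
#' @export
expr_matrix <- function(values, transformed = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`values` must have gene row names and sample column names", call. = FALSE)
  }
  if (nrow(values) == 0L) stop("expression matrix has no genes", call. = FALSE)
  if (ncol(values) == 0L) stop("expression matrix has no samples", call. = FALSE)
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) {
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "), call. = FALSE)
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
  }
  if (!transformed && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative TPM at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
  }
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         transformed = isTRUE(transformed)),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              length(x$gene_ids), length(x$sample_ids),
              if (x$transformed) "log2(TPM+1)" else "linear TPM"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' Read a TPM expression matrix from TSV
#'
#' Expects a tab-separated file whose header row carries sample identifiers
#' (first cell is the gene-id column name, conventionally `gene_id`), whose
#' first column carries gene identifiers, and whose remaining cells are
#' numeric linear TPM values.
#'
#' @param path Path to the TSV file.
#' @return A linear-TPM [expr_matrix()].
#' @export
read_tpm_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) {
    stop("malformed header in ", path, ": need a gene-id column plus >=1 sample column",
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("empty matrix in ", path, ": header only, no data rows", call. = FALSE)
  }
  gene_ids <- df[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop("duplicate gene id(s) in ", path, ": ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (any(is.na(num) & !is.na(vals))) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell in %s at gene '%s', column '%s': '%s'",
                 path, gene_ids[bad[1L]], colnames(vals)[bad[2L]],
                 vals[bad[1L], bad[2L]]), call. = FALSE)
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  expr_matrix(num, transformed = FALSE)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_tpm_matrix()]; the first header cell is `gene_id`.
#' Round-trips values through the default 15-significant-digit formatting.
#'
#' @param m An [expr_matrix()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tpm_matrix <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene_id = m$gene_ids, m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform a linear TPM matrix
#'
#' Replaces every value v by `log2(v + 1)`. The pseudocount of 1 keeps the
#' transform defined at zero and strictly monotone, so within-sample ranks
#' are preserved. Applying the transform twice is refused.
#'
#' @param m A linear-TPM [expr_matrix()].
#' @return The transformed `expr_matrix` (`transformed = TRUE`).
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$transformed) {
    stop("matrix is already log2-transformed", call. = FALSE)
  }
  expr_matrix(log2(m$values + 1), transformed = TRUE)
}
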