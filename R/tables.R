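#' Read a sample metadata table
#'
#' CSV with required columns `sample_id`, `cell_type`, `timepoint`,
#' `dataset_id`; any further columns are kept as free annotations.
#' `cell_type` must be one of `Treg`, `Teff`, `destabilized`; `timepoint`
#' one of `D0`, `D14`.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "cell_type", "timepoint", "dataset_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("metadata ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_metadata(df)
  df
}

validate_metadata <- function(df) {
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id(s) in metadata: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  ct_ok <- c("Treg", "Teff", "destabilized")
  bad_ct <- setdiff(unique(df$cell_type), ct_ok)
  if (length(bad_ct)) {
    stop("invalid cell_type value(s): ", paste(bad_ct, collapse = ", "),
         "; allowed: ", paste(ct_ok, collapse = ", "), call. = FALSE)
  }
  bad_tp <- setdiff(unique(df$timepoint), c("D0", "D14"))
  if (length(bad_tp)) {
    stop("invalid timepoint value(s): ", paste(bad_tp, collapse = ", "),
         "; allowed: D0, D14", call. = FALSE)
  }
  invisible(df)
}

#' Read a differential-expression result table
#'
#' TSV with columns `gene_id`, `log2fc`, `pvalue` and optionally `padj`.
#' Positive `log2fc` means up in the first-named group of the contrast
#' (Treg for identity contrasts, D14 for expansion contrasts); the caller
#' asserts this orientation via `orientation`. If `padj` is absent it is
#' computed on load by Benjamini-Hochberg over the available p-values and a
#' message is logged.
#'
#' @param path Path to the TSV file.
#' @param orientation Must be `"first_up"`, an explicit acknowledgement that
#'   positive log2 fold changes mean up in the first-named group.
#' @return A data.frame with columns `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @export
read_de_table <- function(path, orientation = c("first_up")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene_id", "log2fc", "pvalue")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("DE table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!("padj" %in% names(df))) {
    df$padj <- bh_adjust(df$pvalue)
    message("NOTE\tpadj absent in ", path, "; computed by Benjamini-Hochberg on load")
  }
  de_table(df)
}

#' Construct/validate a DE table
#'
#' @param df Data.frame with columns `gene_id`, `log2fc`, `pvalue` and
#'   optionally `padj`.
#' @return The validated data.frame (with `padj` filled in by BH when absent).
#' @export
de_table <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("gene_id", "log2fc", "pvalue")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("DE table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id(s) in DE table: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$pvalue < 0 | df$pvalue > 1, na.rm = TRUE)) {
    stop("pvalue outside [0, 1] in DE table", call. = FALSE)
  }
  if (!("padj" %in% names(df))) df$padj <- bh_adjust(df$pvalue)
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE)) {
    stop("padj outside [0, 1] in DE table", call. = FALSE)
  }
  both <- !is.na(df$padj) & !is.na(df$pvalue)
  if (any(df$padj[both] < df$pvalue[both])) {
    stop("padj < pvalue in DE table; adjusted values cannot undercut raw p-values",
         call. = FALSE)
  }
  df[, c("gene_id", "log2fc", "pvalue", "padj")]
}

#' Write a DE table to TSV
#'
#' @param df A DE table as from [de_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(df, path) {
  utils::write.table(de_table(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
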