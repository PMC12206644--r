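#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: on sorted p-values,
#' `adj_(i) = min_{j >= i} min(1, m * p_(j) / j)`, mapped back to input
#' order. Delegates to [stats::p.adjust()] after validating the input range.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("p-values must be numeric", call. = FALSE)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-value(s) outside [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Filter a DE table into an up- or down-regulated gene set
#'
#' A gene qualifies as `up` when `log2fc > lfc_threshold` and
#' `padj < alpha_fdr`; as `down` when `log2fc < -lfc_threshold` and
#' `padj < alpha_fdr`. Both inequalities are strict, so a gene exactly at a
#' threshold is excluded.
#'
#' @param tab A DE table (see [de_table()]).
#' @param direction `"up"` or `"down"`.
#' @param lfc_threshold Positive log2 fold-change cutoff (default 1).
#' @param alpha_fdr FDR cutoff in (0, 1) (default 0.05).
#' @param require_padj Error if any `padj` is missing (default `TRUE`).
#' @return Character vector of qualifying gene ids.
#' @export
de_filter <- function(tab, direction = c("up", "down"), lfc_threshold = 1,
                      alpha_fdr = 0.05, require_padj = TRUE) {
  direction <- match.arg(direction)
  tab <- de_table(tab)
  stopifnot(lfc_threshold > 0, alpha_fdr > 0, alpha_fdr < 1)
  if (require_padj && any(is.na(tab$padj))) {
    stop("DE table has missing padj values and require_padj is TRUE", call. = FALSE)
  }
  keep <- if (direction == "up") tab$log2fc > lfc_threshold else tab$log2fc < -lfc_threshold
  keep <- keep & !is.na(tab$padj) & tab$padj < alpha_fdr
  tab$gene_id[keep]
}

#' Bundle a DE table with its contrast labels
#'
#' @param dataset_id Dataset identifier.
#' @param label Contrast label: the timepoint (`"D0"`/`"D14"`) of a
#'   Treg-vs-Teff identity contrast, or `"D14_vs_D0"` for an expansion
#'   contrast. Positive log2fc always means up in the first-named group
#'   (Treg, resp. D14).
#' @param table The DE table.
#' @return A `contrast_set` object.
#' @export
contrast_set <- function(dataset_id, label, table) {
  structure(list(dataset_id = dataset_id, label = label, table = de_table(table)),
            class = "contrast_set")
}

# UpSet-style membership-pattern counts over named gene sets
intersection_table <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  genes <- unique(unlist(sets, use.names = FALSE))
  if (!length(genes)) {
    return(data.frame(pattern = character(), count = integer()))
  }
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  member <- matrix(member, nrow = length(genes))
  pattern <- apply(member, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  counts <- table(pattern)
  out <- data.frame(pattern = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$pattern), , drop = FALSE]
}

derive_bidir <- function(name, up_sets, dn_sets, reference = NULL) {
  pos <- Reduce(intersect, up_sets)
  neg <- Reduce(intersect, dn_sets)
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "bidir_signature"))
    pos <- intersect(pos, reference$positive)
    neg <- intersect(neg, reference$negative)
  }
  if (length(pos) == 0L || length(neg) == 0L) {
    card <- function(sets) paste(sprintf("%s=%d", names(sets), lengths(sets)),
                                 collapse = ", ")
    stop(sprintf(paste0("derivation of '%s' produced an empty %s set; ",
                        "per-contrast cardinalities: up [%s]; down [%s]%s"),
                 name, if (length(pos) == 0L) "positive" else "negative",
                 card(up_sets), card(dn_sets),
                 if (is.null(reference)) "" else
                   sprintf("; reference pos=%d, neg=%d",
                           length(reference$positive), length(reference$negative))),
         call. = FALSE)
  }
  sig <- bidir_signature(name, positive = sort(pos), negative = sort(neg))
  attr(sig, "intersections") <- list(up = intersection_table(up_sets),
                                     down = intersection_table(dn_sets))
  sig
}

#' Derive an expansion-independent identity signature
#'
#' Intersects per-contrast DE gene sets so that only genes differential in
#' the same direction at both the unexpanded (D0) and expanded (D14)
#' timepoints survive: the positive set is the intersection of all up-in-Treg
#' sets, the negative set the intersection of all up-in-Teff (down) sets.
#' An optional published reference signature can be intersected in as well.
#' The returned signature carries UpSet-style membership-pattern counts of
#' the per-contrast sets in its `"intersections"` attribute.
#'
#' @param contrasts List of [contrast_set()]s with labels `"D0"`/`"D14"`
#'   (Treg vs Teff orientation: positive log2fc = up in Treg). At least one
#'   contrast per timepoint is required.
#' @param reference Optional [bidir_signature()] to intersect with.
#' @param name Name for the derived signature.
#' @param lfc_threshold,alpha_fdr,require_padj Passed to [de_filter()].
#' @return A [bidir_signature()].
#' @export
derive_identity <- function(contrasts, reference = NULL, name = "identity",
                            lfc_threshold = 1, alpha_fdr = 0.05,
                            require_padj = TRUE) {
  stopifnot(all(vapply(contrasts, inherits, logical(1L), "contrast_set")))
  labels <- vapply(contrasts, `[[`, character(1L), "label")
  bad <- setdiff(labels, c("D0", "D14"))
  if (length(bad)) {
    stop("identity contrasts must be labelled D0 or D14; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!("D0" %in% labels) || !("D14" %in% labels)) {
    stop("identity derivation needs at least one D0 and one D14 contrast; got: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  key <- vapply(contrasts, function(cs) paste(cs$dataset_id, cs$label, sep = "."),
                character(1L))
  filt <- function(direction) {
    stats::setNames(lapply(contrasts, function(cs) {
      de_filter(cs$table, direction, lfc_threshold, alpha_fdr, require_padj)
    }), key)
  }
  derive_bidir(name, filt("up"), filt("down"), reference = reference)
}

#' Derive an identity-independent expansion signature
#'
#' Intersects D14-vs-D0 DE gene sets across datasets: the positive set is
#' the overlap of up-at-D14 genes, the negative set the overlap of
#' up-at-D0 (down) genes. At least two datasets are required — overlap is
#' undefined otherwise.
#'
#' @param contrasts List of [contrast_set()]s, one `"D14_vs_D0"` contrast
#'   per dataset (positive log2fc = up at D14), from >= 2 distinct datasets.
#' @param name Name for the derived signature.
#' @param lfc_threshold,alpha_fdr,require_padj Passed to [de_filter()].
#' @return A [bidir_signature()].
#' @export
derive_expansion <- function(contrasts, name = "expansion", lfc_threshold = 1,
                             alpha_fdr = 0.05, require_padj = TRUE) {
  stopifnot(all(vapply(contrasts, inherits, logical(1L), "contrast_set")))
  datasets <- vapply(contrasts, `[[`, character(1L), "dataset_id")
  if (length(unique(datasets)) < 2L) {
    stop("expansion derivation needs contrasts from >= 2 datasets; got: ",
         paste(unique(datasets), collapse = ", "), call. = FALSE)
  }
  filt <- function(direction) {
    stats::setNames(lapply(contrasts, function(cs) {
      de_filter(cs$table, direction, lfc_threshold, alpha_fdr, require_padj)
    }), datasets)
  }
  derive_bidir(name, filt("up"), filt("down"))
}

#' Simple per-gene Welch differential expression
#'
#' Lightweight two-group test for synthetic end-to-end runs: per gene the
#' log2 fold change is `mean(group A) - mean(group B)` of the
#' log2-transformed values and the p-value comes from Welch's two-sample
#' t-test (unequal variances, Welch-Satterthwaite degrees of freedom),
#' computed in closed form across all genes at once. A gene that is
#' constant within both groups gets p-value 1 when the group means are
#' equal and 0 otherwise. Not a replacement for a count-model DE engine.
#'
#' @param m A log2-transformed [expr_matrix()].
#' @param group_a,group_b Sample ids of the two groups (>= 2 each).
#'   Positive log2fc means up in `group_a`.
#' @return A DE table (see [de_table()]) with BH-adjusted p-values.
#' @export
simple_de <- function(m, group_a, group_b) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$transformed) stop("matrix must be log2-transformed for simple_de", call. = FALSE)
  ja <- match(group_a, m$sample_ids)
  jb <- match(group_b, m$sample_ids)
  if (anyNA(ja) || anyNA(jb)) {
    stop("unknown sample id(s): ",
         paste(c(group_a[is.na(ja)], group_b[is.na(jb)]), collapse = ", "),
         call. = FALSE)
  }
  na <- length(ja); nb <- length(jb)
  if (na < 2L || nb < 2L) stop("need >= 2 samples per group", call. = FALSE)
  a <- m$values[, ja, drop = FALSE]
  b <- m$values[, jb, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  lfc <- ma - mb
  p <- numeric(nrow(a))
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)
  if (any(!degenerate)) {
    i <- !degenerate
    tstat <- lfc[i] / sqrt(se2[i])
    df <- se2[i]^2 / ((va[i] / na)^2 / (na - 1L) + (vb[i] / nb)^2 / (nb - 1L))
    p[i] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  de_table(data.frame(gene_id = m$gene_ids, log2fc = unname(lfc),
                      pvalue = unname(p), padj = bh_adjust(unname(p)),
                      stringsAsFactors = FALSE))
}
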