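#' Rank genes within one sample
#'
#' First step of single-sample GSEA: within-sample ranking of the
#' log2-transformed expression values. The highest-expressed gene receives
#' rank N; ties receive the average of their rank positions.
#'
#' @param m A log2-transformed [expr_matrix()].
#' @param sample Sample identifier.
#' @return Named numeric vector of ranks in `[1, N]`, one per gene.
#' @export
rank_within_sample <- function(m, sample) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$transformed) stop("matrix must be log2-transformed before ranking", call. = FALSE)
  j <- match(sample, m$sample_ids)
  if (is.na(j)) stop("unknown sample id: ", sample, call. = FALSE)
  r <- rank(m$values[, j], ties.method = "average")
  names(r) <- m$gene_ids
  r
}

#' ssGSEA enrichment score for one gene set
#'
#' Rank-weighted running-sum enrichment. Genes are walked in order of
#' decreasing expression (positions i = 1..N; ties in rank are ordered by
#' gene id so the result does not depend on row order). With weights
#' `w_g = rank_g^alpha` for set genes, the score is
#' `ES = sum_i (P_in(i) - P_out(i))` where `P_in(i)` is the weight-fraction
#' of set genes encountered up to position i and `P_out(i)` the count
#' fraction of non-set genes. Depends on the values only through their
#' ranks.
#'
#' @param ranks Named rank vector from [rank_within_sample()].
#' @param gene_set Character vector of gene ids; scored on its intersection
#'   with the ranked genes, which must be non-empty and proper.
#' @param alpha Non-negative rank-weighting exponent (default 0.25).
#' @param set_name Name used in error messages.
#' @return The enrichment score, a finite scalar.
#' @export
enrichment_score <- function(ranks, gene_set, alpha = 0.25, set_name = "gene set") {
  stopifnot(is.numeric(ranks), !is.null(names(ranks)), alpha >= 0)
  n <- length(ranks)
  in_set <- names(ranks) %in% gene_set
  n_s <- sum(in_set)
  if (n_s == 0L) {
    stop("no genes of ", set_name, " present in the ranked genes", call. = FALSE)
  }
  if (n_s == n) {
    stop(set_name, " covers every ranked gene; enrichment is undefined", call. = FALSE)
  }
  ord <- order(-ranks, names(ranks))
  in_ord <- in_set[ord]
  w <- ranks[ord]^alpha
  w[!in_ord] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (n - n_s)
  sum(p_in - p_out)
}

#' Score samples with a bidirectional fingerprint signature
#'
#' The central scoring routine. Each sample gets two ssGSEA sub-scores —
#' `score_pos` on the favorable set and `score_neg` on the unfavorable set —
#' and the final fingerprint score `score = score_pos - score_neg`.
#' Samples are classified at a strict zero threshold: `score > 0` is the
#' positive class; a score of exactly 0 is the negative class, since a QC
#' decision must not pass a product sitting on the boundary.
#'
#' With `normalize = TRUE` (the default, matching the reference ssGSEA
#' implementation's per-run range normalization), all raw sub-scores of the
#' run — both sets, all samples — are divided by the range (max - min) of
#' that collection before subtraction. If the range is zero, normalization
#' is skipped with a warning and the raw scores are returned.
#'
#' Signature genes absent from the matrix are dropped with a logged count;
#' an error is raised only when an entire set vanishes.
#'
#' @param m An [expr_matrix()]; linear TPM input is log2-transformed
#'   automatically, an already-transformed matrix is used as is.
#' @param signature A [bidir_signature()].
#' @param alpha Rank-weighting exponent, see [enrichment_score()].
#' @param normalize Apply per-run range normalization (default `TRUE`).
#' @return An object of class `fingerprint_scores`: a data.frame with
#'   columns `sample_id`, `signature`, `score_pos`, `score_neg`, `score`,
#'   `label`, plus attributes `alpha` and `normalized`.
#' @examples
#' tpm <- matrix(c(90, 5, 5, 5, 90, 5), nrow = 3,
#'               dimnames = list(c("FOXP3", "CD40LG", "ACTB"), c("s1", "s2")))
#' sig <- bidir_signature("identity", positive = "FOXP3", negative = "CD40LG")
#' fingerprint_score(expr_matrix(tpm), sig, normalize = FALSE)
#' @export
fingerprint_score <- function(m, signature, alpha = 0.25, normalize = TRUE) {
  stopifnot(inherits(m, "expr_matrix"), inherits(signature, "bidir_signature"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  }
  if (!m$transformed) m <- log2_transform(m)

  pos <- intersect(signature$positive, m$gene_ids)
  neg <- intersect(signature$negative, m$gene_ids)
  n_drop <- (length(signature$positive) - length(pos)) +
    (length(signature$negative) - length(neg))
  if (length(pos) == 0L) {
    stop("signature '", signature$name,
         "': no positive-set gene present in the matrix", call. = FALSE)
  }
  if (length(neg) == 0L) {
    stop("signature '", signature$name,
         "': no negative-set gene present in the matrix", call. = FALSE)
  }
  if (n_drop > 0L) {
    message(sprintf("NOTE\tsignature '%s': %d gene(s) absent from matrix, dropped",
                    signature$name, n_drop))
  }

  es_pos <- vapply(m$sample_ids, function(s) {
    enrichment_score(rank_within_sample(m, s), pos, alpha = alpha,
                     set_name = paste0("positive set of '", signature$name, "'"))
  }, numeric(1L))
  es_neg <- vapply(m$sample_ids, function(s) {
    enrichment_score(rank_within_sample(m, s), neg, alpha = alpha,
                     set_name = paste0("negative set of '", signature$name, "'"))
  }, numeric(1L))

  normalized <- FALSE
  if (normalize) {
    rng <- max(es_pos, es_neg) - min(es_pos, es_neg)
    if (rng > 0) {
      es_pos <- es_pos / rng
      es_neg <- es_neg / rng
      normalized <- TRUE
    } else {
      warning("zero range across sub-scores; normalization skipped", call. = FALSE)
    }
  }

  score <- es_pos - es_neg
  out <- data.frame(
    sample_id = m$sample_ids,
    signature = signature$name,
    score_pos = unname(es_pos),
    score_neg = unname(es_neg),
    score = unname(score),
    label = ifelse(score > 0, "positive_class", "negative_class"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(out, class = c("fingerprint_scores", "data.frame"),
            alpha = alpha, normalized = normalized)
}

#' Classify fingerprint scores at a threshold
#'
#' Strict rule: `positive_class` iff `score > threshold`. A score exactly at
#' the threshold is the negative class.
#'
#' @param scores A `fingerprint_scores` object or numeric vector of scores.
#' @param threshold Decision threshold (default 0).
#' @return Character vector of labels (`positive_class`/`negative_class`).
#' @export
classify_scores <- function(scores, threshold = 0) {
  s <- if (inherits(scores, "fingerprint_scores")) scores$score else as.numeric(scores)
  ifelse(s > threshold, "positive_class", "negative_class")
}

#' @export
print.fingerprint_scores <- function(x, ...) {
  cat(sprintf("Fingerprint scores: signature '%s', %d samples (alpha = %g, %s)\n",
              x$signature[1L], nrow(x), attr(x, "alpha"),
              if (isTRUE(attr(x, "normalized"))) "range-normalized" else "raw"))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' @export
summary.fingerprint_scores <- function(object, ...) {
  n_pos <- sum(object$label == "positive_class")
  cat(sprintf("Signature '%s': %d samples, %d positive_class / %d negative_class\n",
              object$signature[1L], nrow(object), n_pos, nrow(object) - n_pos))
  print(summary(object$score))
  invisible(object)
}

#' Plot fingerprint scores
#'
#' Strip chart of the final scores, optionally grouped by a sample
#' annotation, with the zero decision threshold drawn as a dashed line.
#'
#' @param x A `fingerprint_scores` object.
#' @param group Optional factor/character vector, one value per sample.
#' @param ... Passed to [graphics::stripchart()].
#' @return Invisibly, `x`.
#' @export
plot.fingerprint_scores <- function(x, group = NULL, ...) {
  if (is.null(group)) group <- rep("all", nrow(x))
  graphics::stripchart(split(x$score, group), vertical = TRUE, pch = 19,
                       method = "jitter",
                       ylab = sprintf("'%s' fingerprint score", x$signature[1L]),
                       ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Write fingerprint scores to CSV
#'
#' @param scores A `fingerprint_scores` object (or plain data.frame with the
#'   same columns).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
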