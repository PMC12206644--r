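# Brute-force double-loop ssGSEA enrichment oracle: for each prefix of the
# decreasing-expression ordering, re-accumulate the set-weight and miss
# fractions from scratch. Deliberately naive (O(N^2)) and independent of the
# package's cumulative-sum implementation.
ssgsea_oracle <- function(values, gene_set, alpha = 0.25) {
  stopifnot(!is.null(names(values)))
  n <- length(values)
  r <- rank(values, ties.method = "average")
  ord <- order(-r, names(values))
  genes <- names(values)[ord]
  in_set <- genes %in% gene_set
  ns <- sum(in_set)
  wts <- r[ord]^alpha
  wsum <- sum(wts[in_set])
  es <- 0
  for (i in seq_len(n)) {
    pin <- 0
    pout <- 0
    for (j in seq_len(i)) {
      if (in_set[j]) pin <- pin + wts[j] else pout <- pout + 1
    }
    es <- es + pin / wsum - pout / (n - ns)
  }
  unname(es)
}

# small transformed expression matrix from a named list of sample vectors
toy_matrix <- function(samples, transformed = TRUE) {
  vals <- do.call(cbind, samples)
  expr_matrix(vals, transformed = transformed)
}

# random transformed matrix with unique values, named genes/samples
random_matrix <- function(n_genes, n_samples) {
  vals <- matrix(stats::runif(n_genes * n_samples, 0, 12),
                 nrow = n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  expr_matrix(vals, transformed = TRUE)
}

sample_ids_of <- function(cohort, cell_type = NULL, timepoint = NULL) {
  md <- cohort$metadata
  keep <- rep(TRUE, nrow(md))
  if (!is.null(cell_type)) keep <- keep & md$cell_type == cell_type
  if (!is.null(timepoint)) keep <- keep & md$timepoint == timepoint
  md$sample_id[keep]
}

# identity/expansion derivation from a simulated cohort via the internal
# Welch DE, as one replicate of the recovery experiments
derive_from_cohort <- function(cohort, type = c("identity", "expansion"),
                               cohort2 = NULL) {
  type <- match.arg(type)
  m <- log2_transform(cohort$matrix)
  if (type == "identity") {
    derive_identity(list(
      contrast_set(cohort$config$dataset_id, "D0",
                   simple_de(m, sample_ids_of(cohort, "Treg", "D0"),
                             sample_ids_of(cohort, "Teff", "D0"))),
      contrast_set(cohort$config$dataset_id, "D14",
                   simple_de(m, sample_ids_of(cohort, "Treg", "D14"),
                             sample_ids_of(cohort, "Teff", "D14")))))
  } else {
    stopifnot(!is.null(cohort2))
    m2 <- log2_transform(cohort2$matrix)
    derive_expansion(list(
      contrast_set(cohort$config$dataset_id, "D14_vs_D0",
                   simple_de(m, sample_ids_of(cohort, "Treg", "D14"),
                             sample_ids_of(cohort, "Treg", "D0"))),
      contrast_set(cohort2$config$dataset_id, "D14_vs_D0",
                   simple_de(m2, sample_ids_of(cohort2, "Treg", "D14"),
                             sample_ids_of(cohort2, "Treg", "D0")))))
  }
}
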