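test_that("simulated cohorts are TPM-normalized, deterministic, and sized as configured", {
  co <- simulate_cohort(n_genes = 400, seed = 7)
  expect_equal(colSums(co$matrix$values), rep(1e6, 40), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_identical(simulate_cohort(n_genes = 400, seed = 7)$matrix$values,
                   co$matrix$values)
  expect_false(identical(simulate_cohort(n_genes = 400, seed = 8)$matrix$values,
                         co$matrix$values))
  expect_equal(table(co$truth)[["identity_pos"]], 32L)
  expect_equal(table(co$truth)[["identity_neg"]], 11L)

  uneven <- simulate_cohort(n_genes = 400, seed = 1,
                            n_per_group = c(Treg_D0 = 4, Treg_D14 = 19,
                                            Teff_D0 = 2, Teff_D14 = 5))
  tab <- table(uneven$metadata$cell_type, uneven$metadata$timepoint)
  expect_equal(tab["Treg", "D14"], 19L)
  expect_equal(tab["Teff", "D0"], 2L)

  expect_error(simulate_cohort(n_genes = 100, n_expansion_pos = 80,
                               n_expansion_neg = 80), "less than n_genes")
})

test_that("planted effects survive compositional renormalization (noise-free check)", {
  co <- simulate_cohort(n_genes = 300, noise_sd = 0, transient_fraction = 0,
                        n_expansion_pos = 20, n_expansion_neg = 20,
                        n_per_group = 2, seed = 3)
  lm <- log2(co$matrix$values)  # exact log2 TPM; no zeros in this generator
  treg <- sample_ids_of(co, "Treg", "D0")[1]
  teff <- sample_ids_of(co, "Teff", "D0")[1]
  idp <- names(co$truth)[co$truth == "identity_pos"]
  bg <- names(co$truth)[co$truth == "background"]
  # per-gene Treg-Teff difference, relative to the background column shift,
  # recovers the planted identity effect exactly
  shift <- lm[bg[1], treg] - lm[bg[1], teff]
  expect_equal(unname(lm[idp, treg] - lm[idp, teff] - shift),
               rep(2, length(idp)), tolerance = 1e-9)
})

test_that("transient genes leak into activated Teff by the configured fraction", {
  co <- simulate_cohort(n_genes = 300, noise_sd = 0, n_per_group = 2,
                        n_expansion_pos = 20, n_expansion_neg = 20, seed = 4)
  lm <- log2(co$matrix$values)
  tg <- names(co$truth)[co$truth == "transient"]
  bg1 <- names(co$truth)[co$truth == "background"][1]
  d0_teff <- sample_ids_of(co, "Teff", "D0")[1]
  d14_teff <- sample_ids_of(co, "Teff", "D14")[1]
  shift <- lm[bg1, d14_teff] - lm[bg1, d0_teff]
  expect_equal(unname(lm[tg, d14_teff] - lm[tg, d0_teff] - shift),
               rep(0.4 * 2, length(tg)), tolerance = 1e-9)
})

test_that("destabilized samples interpolate between D14 Treg and Teff", {
  co <- simulate_cohort(n_genes = 500, seed = 5)
  expect_error(destabilize(co, lambda = 1.2), "lambda")
  for (l in c(0, 0.5, 1)) co <- destabilize(co, l, n_samples = 6, seed = 50)
  md <- co$metadata
  expect_equal(sum(md$cell_type == "destabilized"), 18L)
  expect_equal(colSums(co$matrix$values), rep(1e6, ncol(co$matrix$values)),
               tolerance = 1e-3, ignore_attr = TRUE)

  sc <- fingerprint_score(co$matrix, truth_signature(co, "identity"))
  by_group <- function(ct, tp = NULL, lam = NULL) {
    keep <- md$cell_type == ct
    if (!is.null(tp)) keep <- keep & md$timepoint == tp
    if (!is.null(lam)) keep <- keep & !is.na(md$lambda) & md$lambda == lam
    mean(sc$score[match(md$sample_id[keep], sc$sample_id)])
  }
  # endpoints bracket the parents; lambda = 0 sits with Treg, 1 with Teff
  expect_gt(by_group("destabilized", lam = 0), 0)
  expect_lt(by_group("destabilized", lam = 1), 0)
  expect_lt(abs(by_group("destabilized", lam = 0) - by_group("Treg", "D14")), 0.15)
  expect_lt(abs(by_group("destabilized", lam = 1) - by_group("Teff", "D14")), 0.15)
  expect_true(by_group("destabilized", lam = 0) >
                by_group("destabilized", lam = 0.5))
  expect_true(by_group("destabilized", lam = 0.5) >
                by_group("destabilized", lam = 1))
})

test_that("score ordering follows the stability gradient D0 Treg >= D14 Treg >= destabilized >= D14 Teff", {
  # tonic-signaling CAR condition: identity expression weakens with expansion
  co <- simulate_cohort(seed = 11, tonic_attenuation = 0.2)
  co <- destabilize(co, 0.5, n_samples = 10, seed = 11)
  sc <- fingerprint_score(co$matrix, truth_signature(co, "identity"))
  md <- co$metadata
  grp_mean <- function(ct, tp) {
    ids <- md$sample_id[md$cell_type == ct & md$timepoint == tp]
    mean(sc$score[match(ids, sc$sample_id)])
  }
  expect_gte(grp_mean("Treg", "D0"), grp_mean("Treg", "D14"))
  expect_gte(grp_mean("Treg", "D14"), grp_mean("destabilized", "D14"))
  expect_gte(grp_mean("destabilized", "D14"), grp_mean("Teff", "D14"))
})

test_that("single transient-gene expression confounds Teff, the bidirectional score does not", {
  overlap_total <- 0L
  for (seed in 1:20) {
    co <- simulate_cohort(seed = seed)
    md <- co$metadata
    tg <- names(co$truth)[co$truth == "transient"][1]
    expr <- log2(co$matrix$values[tg, ] + 1)
    treg <- md$sample_id[md$cell_type == "Treg"]
    teff14 <- md$sample_id[md$cell_type == "Teff" & md$timepoint == "D14"]
    # any threshold keeping all Treg admits every D14 Teff above the Treg min
    overlap_total <- overlap_total + sum(expr[teff14] > min(expr[treg]))
    sc <- fingerprint_score(co$matrix, truth_signature(co, "identity"))
    truth <- ifelse(md$cell_type == "Treg", "positive_class", "negative_class")
    cm <- confusion_metrics(sc$label[match(md$sample_id, sc$sample_id)],
                            truth, "positive_class")
    expect_equal(cm$fp + cm$fn, 0L)
  }
  expect_gt(overlap_total, 0L)
})

test_that("cohorts write to disk and read back consistently", {
  co <- simulate_cohort(n_genes = 200, n_per_group = 3,
                        n_expansion_pos = 20, n_expansion_neg = 20, seed = 2)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  m <- read_tpm_matrix(file.path(dir, "matrix.tsv"))
  expect_equal(m$gene_ids, co$matrix$gene_ids)
  expect_equal(signif(m$values, 6), signif(co$matrix$values, 6),
               ignore_attr = TRUE)
  md <- read_sample_metadata(file.path(dir, "metadata.csv"))
  expect_equal(md$sample_id, co$metadata$sample_id)
  sigs <- suppressWarnings(pair_signatures(read_gmt(file.path(dir, "truth.gmt"))))
  expect_setequal(sigs$identity$positive, truth_signature(co, "identity")$positive)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg$seed, 2)
})
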