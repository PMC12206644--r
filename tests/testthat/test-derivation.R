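test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "outside \\[0, 1\\]")
})

test_that("DE filtering applies strict thresholds in both directions", {
  tab <- data.frame(
    gene_id = c("at_lfc", "good_up", "late", "good_dn", "weak"),
    log2fc = c(1.0, 2.3, 1.8, -1.6, 0.4),
    pvalue = c(0.001, 0.004, 0.2, 0.002, 0.5),
    padj   = c(0.01, 0.049, 0.30, 0.01, 0.6))
  expect_setequal(de_filter(tab, "up"), "good_up")   # at_lfc excluded: strict >
  expect_setequal(de_filter(tab, "down"), "good_dn")
  expect_setequal(de_filter(tab, "up", lfc_threshold = 0.5, alpha_fdr = 0.5),
                  c("at_lfc", "good_up", "late"))
  # padj exactly at alpha is excluded (strict <)
  at_alpha <- data.frame(gene_id = "g", log2fc = 3, pvalue = 0.01, padj = 0.05)
  expect_length(de_filter(at_alpha, "up"), 0L)
  no_padj <- data.frame(gene_id = "g", log2fc = 3, pvalue = 0.01, padj = NA_real_)
  expect_error(de_filter(no_padj, "up"), "missing padj")
})

test_that("raising lfc or lowering alpha never grows a filtered set", {
  set.seed(21)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    log2fc = stats::rnorm(200, 0, 2),
                    pvalue = stats::runif(200)^2)
  tab$padj <- bh_adjust(tab$pvalue)
  for (dir in c("up", "down")) {
    prev <- de_filter(tab, dir, lfc_threshold = 0.5, alpha_fdr = 0.2)
    for (lfc in c(1, 1.5, 2.5)) {
      cur <- de_filter(tab, dir, lfc_threshold = lfc, alpha_fdr = 0.2)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
    prev <- de_filter(tab, dir, lfc_threshold = 1, alpha_fdr = 0.2)
    for (a in c(0.1, 0.05, 0.01)) {
      cur <- de_filter(tab, dir, lfc_threshold = 1, alpha_fdr = a)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

make_tab <- function(up = character(), down = character(),
                     null = sprintf("n%02d", 1:5)) {
  genes <- c(up, down, null)
  data.frame(gene_id = genes,
             log2fc = c(rep(3, length(up)), rep(-3, length(down)),
                        rep(0, length(null))),
             pvalue = c(rep(1e-6, length(up) + length(down)),
                        rep(0.8, length(null))),
             padj = c(rep(1e-4, length(up) + length(down)),
                      rep(0.9, length(null))))
}

test_that("identity derivation intersects D0 and D14 contrasts (and a reference)", {
  d0 <- contrast_set("ds1", "D0", make_tab(up = c("FOXP3", "IL2RA", "A"),
                                           down = c("CD40LG", "GNLY")))
  d14 <- contrast_set("ds1", "D14", make_tab(up = c("FOXP3", "IL2RA", "B"),
                                             down = c("CD40LG", "NKG7")))
  sig <- derive_identity(list(d0, d14))
  expect_setequal(sig$positive, c("FOXP3", "IL2RA"))
  expect_setequal(sig$negative, "CD40LG")
  # order invariance
  sig_rev <- derive_identity(list(d14, d0))
  expect_equal(sig_rev$positive, sig$positive)
  expect_equal(sig_rev$negative, sig$negative)
  # reference intersection narrows further
  ref <- bidir_signature("ref", positive = "FOXP3", negative = c("CD40LG", "Z"))
  sig_ref <- derive_identity(list(d0, d14), reference = ref)
  expect_equal(sig_ref$positive, "FOXP3")
  # intersection-cardinality side artifact is attached
  tabs <- attr(sig, "intersections")
  expect_true(is.data.frame(tabs$up))
  expect_equal(sum(tabs$up$count), 4L)  # FOXP3, IL2RA, A, B
  expect_equal(tabs$up$count[tabs$up$pattern == "ds1.D0&ds1.D14"], 2L)
})

test_that("identity derivation demands timepoint coverage and non-empty sets", {
  d0 <- contrast_set("ds1", "D0", make_tab(up = "A", down = "X"))
  expect_error(derive_identity(list(d0)), "at least one D0 and one D14")
  d14 <- contrast_set("ds1", "D14", make_tab(up = "B", down = "X"))
  expect_error(derive_identity(list(d0, d14)), "empty positive set.*cardinalities")
  bad <- contrast_set("ds1", "D14_vs_D0", make_tab(up = "A", down = "X"))
  expect_error(derive_identity(list(d0, bad)), "labelled D0 or D14")
})

test_that("expansion derivation overlaps >= 2 datasets", {
  e1 <- contrast_set("ds1", "D14_vs_D0", make_tab(up = c("LAG3", "CCR5", "X"),
                                                  down = c("FOS", "JUNB")))
  e2 <- contrast_set("ds2", "D14_vs_D0", make_tab(up = c("LAG3", "CCR5", "Y"),
                                                  down = "FOS"))
  sig <- derive_expansion(list(e1, e2))
  expect_setequal(sig$positive, c("LAG3", "CCR5"))
  expect_setequal(sig$negative, "FOS")
  expect_error(derive_expansion(list(e1)), ">= 2 datasets")
  # identical tables in both datasets: signature equals the single-table filter
  e2same <- contrast_set("ds2", "D14_vs_D0", e1$table)
  twin <- derive_expansion(list(e1, e2same))
  expect_setequal(twin$positive, de_filter(e1$table, "up"))
  expect_setequal(twin$negative, de_filter(e1$table, "down"))
})

test_that("vectorized Welch DE matches t.test and handles degenerate genes", {
  set.seed(33)
  n <- 50
  vals <- matrix(stats::rnorm(n * 9, 6, 1), nrow = n,
                 dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:9)))
  vals[1, ] <- 4                 # constant everywhere -> p = 1, lfc = 0
  vals[2, 1:4] <- vals[2, 5:8] + 2  # constant shift -> lfc = 2
  m <- expr_matrix(vals, transformed = TRUE)
  tab <- simple_de(m, paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(tab$log2fc[1], 0)
  expect_equal(tab$pvalue[1], 1)
  expect_equal(tab$log2fc[2], 2)
  for (g in 3:n) {
    tt <- stats::t.test(vals[g, 1:4], vals[g, 5:8])
    expect_equal(tab$pvalue[g], tt$p.value, tolerance = 1e-9)
    expect_equal(tab$log2fc[g], unname(diff(-tt$estimate)), tolerance = 1e-12)
  }
  expect_error(simple_de(m, "s1", paste0("s", 5:8)), ">= 2 samples")
})

test_that("derivation recovers planted sets from a simulated cohort", {
  co <- simulate_cohort(seed = 7, n_transient = 0)
  sig <- derive_from_cohort(co, "identity")
  tru <- truth_signature(co, "identity")
  expect_setequal(sig$positive, tru$positive)
  expect_setequal(sig$negative, tru$negative)

  co2 <- simulate_cohort(seed = 107, n_transient = 0, dataset_id = "ds2")
  esig <- derive_from_cohort(co, "expansion", cohort2 = co2)
  etru <- truth_signature(co, "expansion")
  expect_setequal(esig$positive, etru$positive)
  expect_setequal(esig$negative, etru$negative)
})
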