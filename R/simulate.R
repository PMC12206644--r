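#' Simulate a Treg/Teff expansion cohort with planted signature genes
#'
#' Generates a synthetic bulk RNA-seq cohort with the statistical structure
#' the fingerprints assume: four populations (Treg/Teff at day 0 and day 14)
#' and planted gene roles on the log2 scale —
#'
#' * `identity_pos`: up by `effect_identity` in Treg at both timepoints
#'   (optionally attenuated by `tonic_attenuation` at D14, see below);
#' * `identity_neg`: up by `effect_identity` in Teff at both timepoints;
#' * `expansion_pos`: up by `effect_expansion` at D14 in both cell types;
#' * `expansion_neg`: up by `effect_expansion` at D0 in both cell types;
#' * `transient`: FOXP3-like activation-confounded genes — up by
#'   `effect_identity` in Treg, and additionally up by
#'   `transient_fraction * effect_identity` in activated (D14) Teff only,
#'   emulating transient FOXP3 upregulation in activated effector cells;
#' * `background`: no planted effect.
#'
#' Per gene a log2 baseline is drawn from
#' `Normal(baseline_mean, baseline_sd)`; for planted (non-background) genes
#' the draw is truncated below at `baseline_mean - baseline_sd`, because
#' curated signature genes are by construction robustly expressed — a
#' discriminative role planted on a gene near the detection floor would be
#' compressed away by the log2(TPM+1) transform and could never be curated
#' from real data. Per sample the log2 expression is
#' baseline + planted effect + `Normal(0, noise_sd)` noise. Values are then
#' exponentiated and each column rescaled to sum to 1e6, yielding linear
#' TPM. The renormalization induces small compensatory shifts in background
#' genes — accepted as realistic compositional behavior. A log-normal model
#' is used rather than a count model: the scorer is rank-based, so only the
#' rank structure needs to be realistic.
#'
#' @param n_genes Total number of genes (default 2000).
#' @param n_per_group Samples per (cell type x timepoint) population:
#'   either one integer for all four, or a named vector with names
#'   `Treg_D0`, `Treg_D14`, `Teff_D0`, `Teff_D14` (default 10 each).
#' @param n_identity_pos,n_identity_neg Planted identity set sizes
#'   (defaults 32 and 11, the sizes of the curated Treg-up and Teff-up
#'   identity sets).
#' @param n_expansion_pos,n_expansion_neg Planted expansion set sizes
#'   (defaults 150 each).
#' @param n_transient Number of activation-confounded genes (default 5).
#' @param effect_identity,effect_expansion Planted log2-scale shifts
#'   (defaults 2.0).
#' @param transient_fraction Fraction of the identity effect leaking into
#'   D14 Teff at transient genes, in `[0, 1)` (default 0.4).
#' @param tonic_attenuation Fractional reduction of the Treg identity effect
#'   at D14, in `[0, 0.5)` (default 0). Set it positive (e.g. 0.2) to
#'   emulate an expansion protocol with chronic tonic CAR signaling, in
#'   which identity expression weakens in the expanded product and D0 Treg
#'   sit systematically above D14 Treg on the identity score; the default
#'   product has no tonic-signaling penalty.
#' @param baseline_mean,baseline_sd Log2 baseline distribution (defaults 5, 2).
#' @param noise_sd Within-group log2 noise standard deviation (default 0.5).
#' @param dataset_id Dataset identifier written into the metadata.
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   cohort exactly.
#' @return An object of class `treg_cohort`: list with `matrix` (linear-TPM
#'   [expr_matrix()]), `metadata` (data.frame: sample_id, cell_type,
#'   timepoint, dataset_id, lambda), `truth` (named character vector,
#'   gene id -> role) and `config` (the arguments).
#' @seealso [truth_signature()], [destabilize()]
#' @export
simulate_cohort <- function(n_genes = 2000,
                            n_per_group = 10,
                            n_identity_pos = 32, n_identity_neg = 11,
                            n_expansion_pos = 150, n_expansion_neg = 150,
                            n_transient = 5,
                            effect_identity = 2.0, effect_expansion = 2.0,
                            transient_fraction = 0.4,
                            tonic_attenuation = 0,
                            baseline_mean = 5, baseline_sd = 2,
                            noise_sd = 0.5,
                            dataset_id = "sim",
                            seed = 1L) {
  groups <- c("Treg_D0", "Treg_D14", "Teff_D0", "Teff_D14")
  if (length(n_per_group) == 1L && is.null(names(n_per_group))) {
    n_per_group <- stats::setNames(rep(as.integer(n_per_group), 4L), groups)
  } else {
    missing <- setdiff(groups, names(n_per_group))
    if (length(missing)) {
      stop("n_per_group must name all of ", paste(groups, collapse = ", "),
           call. = FALSE)
    }
    n_per_group <- stats::setNames(as.integer(n_per_group[groups]), groups)
  }
  n_planted <- n_identity_pos + n_identity_neg + n_expansion_pos +
    n_expansion_neg + n_transient
  if (n_planted >= n_genes) {
    stop("planted set sizes must sum to less than n_genes", call. = FALSE)
  }
  stopifnot(baseline_sd > 0, noise_sd >= 0,
            transient_fraction >= 0, transient_fraction < 1,
            tonic_attenuation >= 0, tonic_attenuation < 0.5,
            all(n_per_group >= 1L))

  config <- list(n_genes = n_genes, n_per_group = as.list(n_per_group),
                 n_identity_pos = n_identity_pos, n_identity_neg = n_identity_neg,
                 n_expansion_pos = n_expansion_pos, n_expansion_neg = n_expansion_neg,
                 n_transient = n_transient,
                 effect_identity = effect_identity,
                 effect_expansion = effect_expansion,
                 transient_fraction = transient_fraction,
                 tonic_attenuation = tonic_attenuation,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, dataset_id = dataset_id, seed = seed)

  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  roles <- rep("background", n_genes)
  idx <- 0L
  assign_role <- function(role, n) {
    if (n > 0L) roles[idx + seq_len(n)] <<- role
    idx <<- idx + n
  }
  assign_role("identity_pos", n_identity_pos)
  assign_role("identity_neg", n_identity_neg)
  assign_role("expansion_pos", n_expansion_pos)
  assign_role("expansion_neg", n_expansion_neg)
  assign_role("transient", n_transient)
  truth <- stats::setNames(roles, gene_ids)

  meta <- do.call(rbind, lapply(groups, function(g) {
    parts <- strsplit(g, "_", fixed = TRUE)[[1L]]
    n <- n_per_group[[g]]
    data.frame(sample_id = sprintf("%s_%02d", g, seq_len(n)),
               cell_type = parts[1L], timepoint = parts[2L],
               dataset_id = dataset_id, lambda = NA_real_,
               stringsAsFactors = FALSE)
  }))

  with_seed(seed, {
    # planted genes: baseline truncated at mean - sd (robustly expressed);
    # background: untruncated. One uniform stream keeps determinism simple.
    u <- stats::runif(n_genes)
    planted <- roles != "background"
    lo <- stats::pnorm(-1)
    z <- ifelse(planted, stats::qnorm(lo + u * (1 - lo)), stats::qnorm(u))
    baseline <- baseline_mean + baseline_sd * z
    log2mat <- matrix(NA_real_, nrow = n_genes, ncol = nrow(meta),
                      dimnames = list(gene_ids, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      delta <- planted_effect(roles, meta$cell_type[j], meta$timepoint[j],
                              effect_identity, effect_expansion,
                              transient_fraction, tonic_attenuation)
      log2mat[, j] <- baseline + delta + stats::rnorm(n_genes, 0, noise_sd)
    }
  })

  tpm <- to_tpm(log2mat)
  structure(list(matrix = expr_matrix(tpm, transformed = FALSE),
                 metadata = meta, truth = truth, config = config),
            class = "treg_cohort")
}

# log2-scale planted shift for every gene in one sample
planted_effect <- function(roles, cell_type, timepoint,
                           effect_identity, effect_expansion,
                           transient_fraction, tonic_attenuation = 0) {
  delta <- numeric(length(roles))
  # Treg identity expression weakens slightly in the expanded product
  eff_id_treg <- if (timepoint == "D14") {
    (1 - tonic_attenuation) * effect_identity
  } else {
    effect_identity
  }
  delta[roles == "identity_pos" & cell_type == "Treg"] <- eff_id_treg
  delta[roles == "identity_neg" & cell_type == "Teff"] <- effect_identity
  delta[roles == "expansion_pos" & timepoint == "D14"] <- effect_expansion
  delta[roles == "expansion_neg" & timepoint == "D0"] <- effect_expansion
  if (cell_type == "Treg") {
    delta[roles == "transient"] <- eff_id_treg
  } else if (cell_type == "Teff" && timepoint == "D14") {
    delta[roles == "transient"] <- transient_fraction * effect_identity
  }
  delta
}

# exponentiate log2 expression and rescale each column to TPM (sum 1e6)
to_tpm <- function(log2mat) {
  lin <- 2^log2mat
  sweep(lin, 2L, colSums(lin), "/") * 1e6
}

# run code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Planted ground-truth signature of a simulated cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @param type `"identity"` (Treg-up vs Teff-up genes) or `"expansion"`
#'   (D14-up vs D0-up genes).
#' @return The planted [bidir_signature()].
#' @export
truth_signature <- function(cohort, type = c("identity", "expansion")) {
  type <- match.arg(type)
  stopifnot(inherits(cohort, "treg_cohort"))
  g <- names(cohort$truth)
  bidir_signature(type,
                  positive = g[cohort$truth == paste0(type, "_pos")],
                  negative = g[cohort$truth == paste0(type, "_neg")])
}

#' Add destabilized-Treg samples to a simulated cohort
#'
#' Destabilized Treg (exTreg-like cells that lost FOXP3 stability) are
#' modeled as a linear interpolation in log2 space between the mean D14
#' Treg and mean D14 Teff profiles: the new log2 profile is
#' `(1 - lambda) * mean(D14 Treg) + lambda * mean(D14 Teff)` plus the
#' cohort's within-group noise, then exponentiated and renormalized to TPM.
#' `lambda = 0` reproduces the D14 Treg generator, `lambda = 1` the D14
#' Teff generator. The new samples get `cell_type = "destabilized"`,
#' `timepoint = "D14"` and the `lambda` recorded in the metadata.
#'
#' @param cohort A [simulate_cohort()] result with D14 Treg and D14 Teff
#'   samples.
#' @param lambda Interpolation weight in `[0, 1]` towards the Teff profile.
#' @param n_samples Number of destabilized samples to add.
#' @param seed Integer seed for the added noise.
#' @return The cohort extended with the new samples.
#' @export
destabilize <- function(cohort, lambda, n_samples = 10, seed = 1L) {
  stopifnot(inherits(cohort, "treg_cohort"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  meta <- cohort$metadata
  treg14 <- meta$sample_id[meta$cell_type == "Treg" & meta$timepoint == "D14"]
  teff14 <- meta$sample_id[meta$cell_type == "Teff" & meta$timepoint == "D14"]
  if (!length(treg14) || !length(teff14)) {
    stop("cohort must contain D14 Treg and D14 Teff samples", call. = FALSE)
  }
  logm <- log2(cohort$matrix$values + 1)
  profile <- (1 - lambda) * rowMeans(logm[, treg14, drop = FALSE]) +
    lambda * rowMeans(logm[, teff14, drop = FALSE])
  noise_sd <- cohort$config$noise_sd
  existing <- sum(meta$cell_type == "destabilized")
  ids <- sprintf("destab_l%03d_%02d", round(100 * lambda),
                 existing + seq_len(n_samples))
  with_seed(seed, {
    new_log2 <- profile +
      matrix(stats::rnorm(length(profile) * n_samples, 0, noise_sd),
             nrow = length(profile),
             dimnames = list(names(profile), ids))
  })
  new_tpm <- to_tpm(new_log2)
  cohort$matrix <- expr_matrix(cbind(cohort$matrix$values, new_tpm),
                               transformed = FALSE)
  cohort$metadata <- rbind(meta, data.frame(
    sample_id = ids, cell_type = "destabilized", timepoint = "D14",
    dataset_id = meta$dataset_id[1L], lambda = lambda,
    stringsAsFactors = FALSE))
  cohort
}

#' @export
print.treg_cohort <- function(x, ...) {
  cat(sprintf("treg_cohort: %d genes x %d samples (seed %d)\n",
              nrow(x$matrix$values), ncol(x$matrix$values), x$config$seed))
  print(table(x$metadata$cell_type, x$metadata$timepoint))
  cat("planted roles:\n")
  print(table(x$truth))
  invisible(x)
}

#' Write a simulated cohort to a directory
#'
#' Writes `matrix.tsv` (linear TPM), `metadata.csv`, `truth.gmt` (the
#' planted identity and expansion sets as `_UP`/`_DN` pairs plus the
#' transient set) and `config.yaml` (configuration echo).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory, created if needed.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "treg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tpm_matrix(cohort$matrix, file.path(dir, "matrix.tsv"))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  g <- names(cohort$truth)
  sets <- list(identity_UP = g[cohort$truth == "identity_pos"],
               identity_DN = g[cohort$truth == "identity_neg"],
               expansion_UP = g[cohort$truth == "expansion_pos"],
               expansion_DN = g[cohort$truth == "expansion_neg"])
  transient <- g[cohort$truth == "transient"]
  if (length(transient)) sets$transient <- transient
  write_gmt(sets, file.path(dir, "truth.gmt"), description = "planted")
  yaml::write_yaml(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
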