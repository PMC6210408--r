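#' Null-calibration experiment for the round-robin meta-analysis
#'
#' Simulates three cohorts with no genetic effects, runs the full pipeline
#' (alignment, symmetrization, correction, segmentation, per-segment PCA),
#' and measures the empirical type-I error of the round-robin meta p-values
#' at a nominal level.
#'
#' The rate is measured over near-independent tests: one meta p-value (the
#' first discovery row) per (SNP, leaf segment). SNPs are simulated
#' independently and leaf segments partition the landmarks into disjoint
#' sets, so the binomial reference distribution applies; meta p-values of
#' overlapping ancestor segments, or the three discovery rows of one pair,
#' are strongly dependent and would invalidate a binomial check (all meta
#' p-values are nevertheless returned for inspection).
#'
#' @param n_per_cohort individuals per cohort (default 300).
#' @param L landmarks (default 200).
#' @param depth segment-tree depth (default 5; leaves = 32).
#' @param n_snps number of null SNPs (default 63, so 63 x 32 = 2016 tests).
#' @param pa_reps parallel-analysis replicates (default 50).
#' @param alpha nominal level measured (default 0.05).
#' @param seed integer seed.
#' @return list: `type_I_error` (leaf tests), `n_tests`, `ci99` (binomial
#'   99% CI around `alpha`), `type_I_error_all` (over every meta p-value,
#'   dependence included), `meta_table`.
#' @export
calibration_experiment <- function(n_per_cohort = 300L, L = 200L, depth = 5L,
                                   n_snps = 63L, pa_reps = 50L, alpha = 0.05,
                                   seed = 1L) {
  tpl <- make_template(L, seed = seed)
  set.seed(seed + 1L)
  mafs <- stats::setNames(round(stats::runif(n_snps, 0.1, 0.5), 2),
                          paste0("snp_", seq_len(n_snps)))
  cfg <- sim_config(n_per_cohort = rep(n_per_cohort, 3L), L = L, mafs = mafs,
                    seed = seed + 2L)
  sim <- simulate_cohorts(tpl, cfg)
  core <- pipeline_core(sim, depth = depth, pa_reps = pa_reps, seed = seed + 3L)
  leaves <- core$tree$nodes$node_id[core$tree$nodes$level == depth]
  meta <- run_round_robin(core$seg_pca, core$genotype_residuals,
                          n_covariates = length(core$corrected[[1]]$covariates_used))
  leaf_rows <- meta$segment_id %in% leaves
  p_leaf <- meta[[grep("^p_meta_", names(meta), value = TRUE)[1]]][leaf_rows]
  p_all <- as.matrix(meta[, grep("^p_meta_", names(meta))])
  rate <- mean(p_leaf < alpha)
  hw <- stats::qnorm(0.995) * sqrt(alpha * (1 - alpha) / length(p_leaf))
  list(type_I_error = rate,
       n_tests = length(p_leaf),
       ci99 = c(alpha - hw, alpha + hw),
       type_I_error_all = mean(p_all < alpha),
       meta_table = meta)
}

#' Planted-effect recovery experiment
#'
#' Repeatedly simulates three cohorts with one SNP displacing a contiguous
#' landmark region (a pure shape-space field, 2x the landmark noise SD per
#' allele by default), runs the full pipeline, and checks that (a) the
#' minimum meta p-value over segments falls in a segment overlapping the
#' planted region and (b) the per-allele effect direction reconstructed on
#' the full configuration from the pooled cohorts points along the planted
#' field.
#'
#' The analysis operates on symmetrized configurations, so the recovered
#' direction is compared against the symmetrized image of the planted field
#' (its average with its own reflection), expressed in the root segment's
#' Procrustes frame.
#'
#' @param n_runs number of independent seeded runs (default 20).
#' @param n_per_cohort individuals per cohort (default 500).
#' @param L landmarks (default 64).
#' @param depth segment-tree depth (default 3).
#' @param effect_size per-allele displacement in landmark-noise SD units
#'   (default 2).
#' @param region_size landmarks in the planted contiguous region (default 7).
#' @param pa_reps parallel-analysis replicates (default 30).
#' @param seed integer seed.
#' @return list: `hit_rate` (fraction of runs localizing the effect),
#'   `cosines` (per-run recovered-direction cosine with the planted field),
#'   `hits` (logical per run).
#' @export
recovery_experiment <- function(n_runs = 20L, n_per_cohort = 500L, L = 64L,
                                depth = 3L, effect_size = 2, region_size = 7L,
                                pa_reps = 30L, seed = 1L) {
  tpl <- make_template(L, seed = seed)
  # contiguous region: nearest neighbours of an off-midline anchor landmark
  anchor <- tpl$pairs[ceiling(nrow(tpl$pairs) / 3), "right"]
  d <- sqrt(rowSums(sweep(tpl$coords, 2, tpl$coords[anchor, ])^2))
  region <- order(d)[seq_len(region_size)]
  hits <- logical(n_runs); cosines <- numeric(n_runs)
  for (run in seq_len(n_runs)) {
    run_seed <- seed + 1000L * run
    cfg <- sim_config(n_per_cohort = rep(n_per_cohort, 3L), L = L,
                      mafs = c(snp_1 = 0.3),
                      effect_segments = list(snp_1 = region),
                      effect_size = c(snp_1 = effect_size),
                      seed = run_seed)
    sim <- simulate_cohorts(tpl, cfg)
    core <- pipeline_core(sim, depth = depth, pa_reps = pa_reps,
                          seed = run_seed + 1L)
    n_cov <- length(core$corrected[[1]]$covariates_used)
    meta <- run_round_robin(core$seg_pca, core$genotype_residuals,
                            n_covariates = n_cov)
    pm <- apply(as.matrix(meta[, grep("^p_meta_", names(meta))]), 1, min)
    best <- meta$segment_id[which.min(pm)]
    hits[run] <- length(intersect(core$tree$landmarks[[as.character(best)]],
                                  region)) > 0
    # pooled effect direction on the root segment
    root <- core$seg_pca$segments[["1"]]
    S <- do.call(rbind, lapply(names(core$corrected), function(nm) {
      rows <- which(core$seg_pca$cohort == nm)
      scale(root$scores[rows, , drop = FALSE], center = TRUE, scale = FALSE)
    }))
    g <- unlist(lapply(core$genotype_residuals, function(m) m[, "snp_1"]))
    rec <- cca_test(S, g, n_covariates = n_cov, snp_id = "snp_1",
                    segment_id = 1L)
    viz <- effect_visualization(core$seg_pca, rec, exaggeration = 1)
    U <- sim$snp_fields$snp_1
    perm <- reflection_permutation(tpl$pairs, tpl$midline, L)
    Ur <- U[perm, , drop = FALSE]; Ur[, 1] <- -Ur[, 1]
    Usym <- (U + Ur) / 2
    R <- opa_rotation(scale(tpl$coords, scale = FALSE), root$mean_config)
    Uf <- Usym %*% R
    cosines[run] <- sum(viz$direction * Uf) /
      sqrt(sum(viz$direction^2) * sum(Uf^2))
  }
  list(hit_rate = mean(hits), cosines = cosines, hits = hits)
}
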