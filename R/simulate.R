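#' Simulation configuration for the synthetic multi-cohort generator
#'
#' Bundles the knobs of the synthetic study design: three cohort sizes, the
#' landmark count, per-SNP minor allele frequencies, which landmarks each SNP
#' displaces and by how much, the landmark noise level, and covariate effect
#' scales. Defaults emulate the three-cohort candidate-SNP study design the
#' pipeline targets: cohort sizes 2297, 1555 and 3566, a dense template of
#' 200 landmarks, and unit Gaussian landmark noise.
#'
#' @param n_per_cohort integer vector of three cohort sizes.
#' @param L landmark count (must match the template used).
#' @param mafs named numeric vector of per-SNP minor allele frequencies in
#'   `(0, 0.5]`.
#' @param effect_segments named list mapping SNP id to the 1-based landmark
#'   index set it displaces; SNPs absent from the list have no shape effect.
#' @param effect_size named numeric vector: per-allele displacement magnitude
#'   for each SNP's affected landmarks, in units of `noise_sd`.
#' @param noise_sd standard deviation of the iid Gaussian landmark noise, in
#'   the template's length units.
#' @param covariate_effect_scales named numeric vector of displacement scales
#'   (same length units, per covariate SD) for `age`, `sex`, `weight`,
#'   `height` and the four ancestry axes (`anc`).
#' @param age_range numeric length-2, uniform age range in years.
#' @param cohort_noise_mult length-3 multiplier on `noise_sd` per cohort
#'   (default homogeneous cohorts).
#' @param seed integer master seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_per_cohort = c(2297L, 1555L, 3566L),
                       L = 200L,
                       mafs = c(snp_1 = 0.25),
                       effect_segments = list(),
                       effect_size = numeric(),
                       noise_sd = 1,
                       covariate_effect_scales = c(age = 0.5, sex = 2,
                                                   weight = 0.3, height = 0.3,
                                                   anc = 0.5),
                       age_range = c(15, 40),
                       cohort_noise_mult = c(1, 1, 1),
                       seed = 1L) {
  if (length(n_per_cohort) != 3L || any(n_per_cohort < 1))
    stop("`n_per_cohort` must be three positive integers")
  if (any(mafs <= 0) || any(mafs > 0.5))
    stop("all minor allele frequencies must lie in (0, 0.5]")
  if (is.null(names(mafs))) names(mafs) <- paste0("snp_", seq_along(mafs))
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  for (s in names(effect_segments)) {
    idx <- effect_segments[[s]]
    if (any(idx < 1) || any(idx > L))
      stop("effect landmark sets must be subsets of 1..L")
    es <- if (s %in% names(effect_size)) effect_size[[s]] else 0
    if (es != 0 && length(idx) == 0)
      stop(sprintf("SNP %s has nonzero effect_size but an empty landmark set", s))
  }
  structure(list(n_per_cohort = as.integer(n_per_cohort), L = as.integer(L),
                 mafs = mafs, effect_segments = effect_segments,
                 effect_size = effect_size, noise_sd = noise_sd,
                 covariate_effect_scales = covariate_effect_scales,
                 age_range = age_range,
                 cohort_noise_mult = cohort_noise_mult,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws additive minor-allele counts per SNP as Binomial(2, f), i.e. genotype
#' probabilities \eqn{(1-f)^2, 2f(1-f), f^2} under Hardy-Weinberg equilibrium.
#'
#' @param n number of individuals.
#' @param mafs (named) numeric vector of minor allele frequencies in
#'   `(0, 0.5]`.
#' @param seed integer seed.
#' @return a [genotype_panel()].
#' @export
simulate_genotypes <- function(n, mafs, seed = 1L) {
  if (any(mafs <= 0) || any(mafs > 0.5))
    stop("all minor allele frequencies must lie in (0, 0.5]")
  if (is.null(names(mafs))) names(mafs) <- paste0("snp_", seq_along(mafs))
  set.seed(seed)
  counts <- vapply(mafs, function(f) stats::rbinom(n, 2L, f), numeric(n))
  if (n == 1L) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, names(mafs)))
  colnames(counts) <- names(mafs)
  genotype_panel(counts,
                 meta = data.frame(snp_id = names(mafs), maf = unname(mafs),
                                   stringsAsFactors = FALSE))
}

# Smooth covariate displacement fields: low-order polynomial in the template
# coordinates, scaled to unit RMS per-landmark displacement. Deterministic
# given (template, seed).
covariate_fields <- function(template, seed) {
  set.seed(seed + 104729L)
  xs <- scale(template$coords)   # z-scored coordinates keep the basis tame
  B <- cbind(1, xs, xs[, 1]^2, xs[, 2] * xs[, 3], xs[, 1] * xs[, 2])
  mk <- function() {
    f <- B %*% matrix(stats::rnorm(ncol(B) * 3), ncol = 3)
    f / sqrt(mean(rowSums(f^2)))
  }
  covs <- c("age", "sex", "weight", "height", "anc_1", "anc_2", "anc_3", "anc_4")
  stats::setNames(lapply(covs, function(.) mk()), covs)
}

# Per-SNP displacement fields, exactly supported on the effect landmark set
# and orthogonal to the configuration's similarity modes (translation,
# infinitesimal rotation, scale), so the planted effect is a pure shape-space
# displacement that superimposition and size correction cannot absorb.
# Normalized to unit RMS per-landmark displacement over the support.
snp_fields <- function(template, config) {
  set.seed(config$seed + 224737L)
  xc <- scale(template$coords, scale = FALSE)
  L <- config$L
  # similarity modes as L x 3 fields, flattened column-wise to 3L vectors
  sim_modes <- function() {
    tr <- lapply(1:3, function(j) {
      m <- matrix(0, L, 3); m[, j] <- 1; m
    })
    rot <- lapply(1:3, function(j) {
      e <- c(0, 0, 0); e[j] <- 1
      t(apply(xc, 1, function(x) c(e[2] * x[3] - e[3] * x[2],
                                   e[3] * x[1] - e[1] * x[3],
                                   e[1] * x[2] - e[2] * x[1])))
    })
    c(tr, rot, list(xc))
  }
  modes <- sim_modes()
  out <- list()
  for (s in names(config$effect_segments)) {
    idx <- config$effect_segments[[s]]
    k <- length(idx)
    if (k == 0L) {
      out[[s]] <- matrix(0, L, 3)
      next
    }
    U <- matrix(0, L, 3)
    U[idx, ] <- matrix(stats::rnorm(3 * k), k, 3)
    # project out the similarity modes restricted to the support
    M <- vapply(modes, function(m) {
      mr <- matrix(0, L, 3); mr[idx, ] <- m[idx, ]; as.vector(mr)
    }, numeric(3L * L))
    qm <- qr(M)
    u <- as.vector(U)
    u <- u - qr.fitted(qm, u)
    U <- matrix(u, L, 3)
    U[-idx, ] <- 0                      # numerical exactness of the support
    rms <- sqrt(mean(rowSums(U[idx, , drop = FALSE]^2)))
    if (rms < 1e-12)
      stop(sprintf("SNP %s: effect landmark set too degenerate for a shape-space field", s))
    out[[s]] <- U / rms
  }
  out
}

#' Simulate three correspondence-matched cohorts
#'
#' Generates three cohorts of dense landmark configurations sharing one
#' template (hence in point-to-point correspondence), with covariate tables,
#' Hardy-Weinberg genotypes, smooth additive covariate effects on shape,
#' localized additive per-allele SNP displacements, and iid Gaussian landmark
#' noise. Cohorts differ only in size and random stream (and optionally a
#' per-cohort noise multiplier).
#'
#' The shape model for individual i is
#' `template + sum_c scale_c * z_c,i * F_c + sum_s effect_size_s * noise_sd *
#' g_s,i * U_s + noise`, where `z_c` are standardized covariates, `F_c` fixed
#' smooth unit fields, `g_s` minor-allele counts and `U_s` a unit direction
#' supported only on the SNP's effect landmark set.
#'
#' @param template a [make_template()] object.
#' @param config a [sim_config()]; `config$L` must equal the template size.
#' @return an object of class `sim_cohorts`: list with `cohorts` (three
#'   elements, each holding a `shapes` [shape_panel()], a `genotypes`
#'   [genotype_panel()] and a `covariates` data frame), plus the `template`,
#'   `config`, and the true `snp_fields` used (for validation studies).
#' @export
simulate_cohorts <- function(template, config) {
  stopifnot(inherits(template, "template"), inherits(config, "sim_config"))
  if (template$L != config$L)
    stop("`config$L` must match the template landmark count")
  fields <- covariate_fields(template, config$seed)
  U <- snp_fields(template, config)
  scales <- config$covariate_effect_scales
  sc <- function(name) {
    if (name %in% names(scales)) scales[[name]]
    else if (startsWith(name, "anc")) scales[["anc"]]
    else 0
  }

  cohorts <- vector("list", 3L)
  names(cohorts) <- paste0("cohort_", 1:3)
  for (ci in 1:3) {
    n <- config$n_per_cohort[ci]
    geno <- simulate_genotypes(n, config$mafs, seed = config$seed + 31L * ci)
    set.seed(config$seed + 7919L * ci)
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- stats::rbinom(n, 1L, 0.5)
    height <- stats::rnorm(n, 170, 9) + 8 * sex
    weight <- stats::rnorm(n, 68, 11) + 6 * sex
    anc <- matrix(stats::rnorm(n * 4), ncol = 4,
                  dimnames = list(NULL, paste0("anc_", 1:4)))
    cov_tab <- data.frame(age = age, age_squared = age^2, sex = sex,
                          weight = weight, height = height, anc,
                          stringsAsFactors = FALSE)

    A <- array(rep(template$coords, each = n),
               dim = c(n, config$L, 3))
    zc <- function(v) as.numeric(scale(v))
    for (nm in names(fields)) {
      v <- switch(nm, age = age, sex = sex, weight = weight, height = height,
                  cov_tab[[nm]])
      contrib <- outer(sc(nm) * zc(v), fields[[nm]])   # n x L x 3
      A <- A + contrib
    }
    for (s in names(U)) {
      es <- if (s %in% names(config$effect_size)) config$effect_size[[s]] else 0
      if (es == 0) next
      g <- geno$counts[, s]
      A <- A + outer(es * config$noise_sd * g, U[[s]])
    }
    A <- A + array(stats::rnorm(length(A),
                                sd = config$noise_sd * config$cohort_noise_mult[ci]),
                   dim = dim(A))

    ids <- sprintf("c%d_id_%04d", ci, seq_len(n))
    cov_tab$individual_id <- ids
    cov_tab$centroid_size <- apply(A, 1, centroid_size)
    cov_tab <- cov_tab[, c("individual_id", "age", "age_squared", "sex",
                           "weight", "height", "centroid_size",
                           paste0("anc_", 1:4))]
    rownames(geno$counts) <- ids
    geno$ids <- ids
    cohorts[[ci]] <- list(
      shapes = shape_panel(A, ids = ids, cohort = names(cohorts)[ci]),
      genotypes = geno,
      covariates = cov_tab)
  }
  structure(list(cohorts = cohorts, template = template, config = config,
                 snp_fields = U),
            class = "sim_cohorts")
}

#' @export
print.sim_cohorts <- function(x, ...) {
  cat(sprintf("<sim_cohorts> 3 cohorts (n = %s), L = %d, %d SNPs\n",
              paste(x$config$n_per_cohort, collapse = "/"),
              x$config$L, length(x$config$mafs)))
  invisible(x)
}
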