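#' Residualize a response block on covariates via partial least squares
#'
#' Fits a partial least-squares regression (SIMPLS) of the response block on
#' the covariate block with `n_components` latent components and returns the
#' response minus its fitted values. At `n_components = ncol(covariates)`
#' (the default used throughout the pipeline) the PLS fit spans the full
#' covariate column space, so the residuals coincide with ordinary
#' least-squares residuals and are exactly uncorrelated with every covariate.
#'
#' Covariates are standardized internally for numerical stability; residuals
#' are returned on the original response scale.
#'
#' @param response `N x d` numeric matrix (or vector).
#' @param covariates `N x c` numeric matrix, full column rank.
#' @param n_components number of latent components (default `ncol(covariates)`).
#' @return `N x d` residual matrix.
#' @export
plsr_residualize <- function(response, covariates, n_components = NULL) {
  Y <- as.matrix(response)
  X <- as.matrix(covariates)
  if (nrow(Y) != nrow(X)) stop("response and covariates must have matching rows")
  if (nrow(X) <= ncol(X)) stop("need more observations than covariates")
  qx <- qr(scale(X, center = TRUE, scale = FALSE))
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    if (is.null(bad)) bad <- qx$pivot[(qx$rank + 1L):ncol(X)]
    stop("covariates are rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(n_components)) n_components <- ncol(X)
  if (n_components < 1L || n_components > ncol(X))
    stop("`n_components` must be between 1 and the covariate count")
  Y - simpls_fitted(X, Y, n_components)
}

# SIMPLS (de Jong 1993): latent components maximizing covariance with the
# response under orthogonal score constraints. Returns fitted values on the
# original response scale.
simpls_fitted <- function(X, Y, ncomp) {
  X0 <- scale(X)                       # z-scored covariates
  Y0 <- scale(Y, center = TRUE, scale = FALSE)
  ybar <- attr(Y0, "scaled:center")
  S <- crossprod(X0, Y0)
  p <- ncol(X0)
  R <- matrix(0, p, ncomp)
  TT <- matrix(0, nrow(X0), ncomp)
  V <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    r <- svd(S, nu = 1, nv = 0)$u[, 1]
    t <- drop(X0 %*% r)
    t <- t - mean(t)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-300) break
    t <- t / nt; r <- r / nt
    pp <- crossprod(X0, t)
    v <- pp
    if (a > 1) {
      Va <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Va %*% crossprod(Va, pp)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; TT[, a] <- t; V[, a] <- v
  }
  fitted0 <- TT %*% crossprod(TT, Y0)   # scores are orthonormal
  sweep(fitted0, 2, ybar, "+")
}

#' Residualize shape and genotypes on confounders within one cohort
#'
#' Builds the confounder design — age, age squared, sex, weight, height,
#' centroid size and the first four ancestry axes — z-scores it within the
#' cohort, and residualizes both the flattened shape coordinates and every
#' genotype column on it with [plsr_residualize()]. This produces the
#' "reduced model" inputs for segmentation and association. Correction is
#' cohort-local by design: each cohort is corrected on its own covariates.
#'
#' @param panel a symmetrized [shape_panel()] for one cohort.
#' @param genotypes a [genotype_panel()], rows aligned with `panel`.
#' @param covariates covariate data frame with columns `individual_id`,
#'   `age`, `age_squared`, `sex`, `weight`, `height`, `centroid_size`,
#'   `anc_1` ... `anc_4`, rows aligned with `panel`.
#' @param n_components PLS components (default: covariate count, making the
#'   correction an exact linear projection).
#' @return an object of class `residual_panel`: list with `shape_residuals`
#'   (`N x 3L`), `shape_corrected` (residuals plus the cohort mean shape, as
#'   configurations in an `N x L x 3` array), `genotype_residuals`
#'   (`N x n_snp`), `covariates_used`, `cohort`, `ids`.
#' @export
correct_dataset <- function(panel, genotypes, covariates, n_components = NULL) {
  stopifnot(inherits(panel, "shape_panel"), inherits(genotypes, "genotype_panel"))
  cov_names <- c("age", "age_squared", "sex", "weight", "height",
                 "centroid_size", paste0("anc_", 1:4))
  missing_cols <- setdiff(cov_names, names(covariates))
  if (length(missing_cols))
    stop("covariate table lacks columns: ", paste(missing_cols, collapse = ", "))
  n <- n_individuals(panel)
  if (nrow(genotypes$counts) != n || nrow(covariates) != n)
    stop("row misalignment across panel, genotypes and covariates")
  if (!is.null(covariates$individual_id) &&
      !identical(as.character(covariates$individual_id), panel$ids)) {
    off <- covariates$individual_id[covariates$individual_id != panel$ids]
    stop("covariate rows misaligned with the shape panel; offending ids: ",
         paste(utils::head(off, 5), collapse = ", "))
  }
  D <- as.matrix(covariates[, cov_names])
  X <- flatten_coords(panel$coords)
  shape_res <- plsr_residualize(X, D, n_components)
  geno_res <- plsr_residualize(genotypes$counts, D, n_components)
  colnames(geno_res) <- colnames(genotypes$counts)
  corrected <- unflatten_coords(shape_res +
                                  matrix(colMeans(X), n, ncol(X), byrow = TRUE))
  structure(list(shape_residuals = shape_res,
                 shape_corrected = corrected,
                 genotype_residuals = geno_res,
                 covariates_used = cov_names,
                 cohort = panel$cohort[1],
                 ids = panel$ids),
            class = "residual_panel")
}
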