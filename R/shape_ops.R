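#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks to their
#' centroid — the standard geometric-morphometrics size measure, used here as
#' the "facial size" covariate.
#'
#' @param config `L x 3` coordinate matrix, `L >= 3`.
#' @return a non-negative scalar; 0 with a warning when all landmarks
#'   coincide.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 3L) stop("`config` needs at least 3 landmarks")
  cs <- sqrt(sum(sweep(config, 2, colMeans(config))^2))
  if (cs == 0) warning("degenerate configuration: all landmarks coincide")
  cs
}

#' Optimal rotation between two configurations
#'
#' The proper rotation (orthogonal, determinant +1 — reflections excluded)
#' that aligns configuration `X` onto `Y` in the least-squares sense, via the
#' singular value decomposition of the cross-covariance. Both configurations
#' should already be centred.
#'
#' @param X,Y `L x 3` coordinate matrices.
#' @return a `3 x 3` rotation matrix `R` minimizing `||X R - Y||`.
#' @export
opa_rotation <- function(X, Y) {
  M <- crossprod(X, Y)
  s <- svd(M)
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Generalized Procrustes superimposition
#'
#' Iteratively aligns all configurations of a panel to their evolving mean
#' shape: centroids are translated to the origin, each configuration is
#' rotated (rotation only, determinant +1) to the current mean, and the mean
#' is recomputed until its RMS change falls below `tol`. With
#' `with_scaling = TRUE` configurations are first rescaled to unit centroid
#' size (partial Procrustes superimposition).
#'
#' The mean is initialized as the arithmetic mean of the centred
#' configurations; this keeps a reflection-symmetric input set (as used by
#' [symmetrize()]) on a reflection-symmetric trajectory.
#'
#' @param panel a [shape_panel()] with at least two individuals.
#' @param with_scaling rescale every configuration to unit centroid size?
#' @param tol convergence tolerance on the RMS change of the mean shape.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   objective trace.
#' @return the aligned `shape_panel` (state `"superimposed"`), with
#'   attributes `mean_shape` (`L x 3`), `iterations`, and `objective_trace`
#'   (sum of squared distances to the mean per iteration, non-increasing).
#' @export
gpa <- function(panel, with_scaling = FALSE, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(panel, "shape_panel"))
  A <- panel$coords
  n <- dim(A)[1]
  if (n < 2L) stop("generalized Procrustes needs at least 2 individuals")
  for (i in seq_len(n)) {
    A[i, , ] <- sweep(A[i, , ], 2, colMeans(A[i, , ]))
    if (with_scaling) {
      cs <- sqrt(sum(A[i, , ]^2))
      if (cs == 0) stop("cannot scale a degenerate (zero-size) configuration")
      A[i, , ] <- A[i, , ] / cs
    }
  }
  m <- apply(A, c(2, 3), mean)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) A[i, , ] <- A[i, , ] %*% opa_rotation(A[i, , ], m)
    m_new <- apply(A, c(2, 3), mean)
    if (with_scaling) m_new <- m_new / sqrt(sum(m_new^2))
    trace <- c(trace, sum(sweep(A, c(2, 3), m_new)^2))
    delta <- sqrt(mean((m_new - m)^2))
    m <- m_new
    if (delta < tol) {
      out <- panel
      out$coords <- A
      out$state <- "superimposed"
      attr(out, "mean_shape") <- m
      attr(out, "iterations") <- it
      attr(out, "objective_trace") <- trace
      return(out)
    }
  }
  stop(paste0("generalized Procrustes did not converge in ", max_iter,
              " iterations; objective trace: ",
              paste(signif(utils::tail(trace, 5), 6), collapse = ", ")))
}

#' Symmetrize a panel of landmark configurations
#'
#' Creates the reflected-relabelled copy of every configuration (x-coordinate
#' negated, left/right landmark labels swapped via the symmetry map), jointly
#' superimposes originals and reflections with [gpa()], and averages each
#' original with its reflection. The result is invariant under
#' reflection-relabelling up to the superimposition tolerance; all downstream
#' shape analysis runs on these symmetrized configurations.
#'
#' @param panel a [shape_panel()].
#' @param pairs two-column integer matrix (`left`, `right`) of mirrored
#'   landmark pairs.
#' @param midline integer vector of on-plane landmarks; together with
#'   `pairs` it must cover every landmark exactly once.
#' @param with_scaling passed to [gpa()].
#' @return the symmetrized, superimposed `shape_panel` (state
#'   `"symmetrized"`), with the joint GPA `mean_shape` attribute.
#' @export
symmetrize <- function(panel, pairs, midline, with_scaling = FALSE) {
  stopifnot(inherits(panel, "shape_panel"))
  n <- n_individuals(panel); L <- n_landmarks(panel)
  perm <- reflection_permutation(pairs, midline, L)   # validates the map
  refl <- panel$coords[, perm, , drop = FALSE]
  refl[, , 1] <- -refl[, , 1]
  both <- array(0, dim = c(2L * n, L, 3))
  both[seq_len(n), , ] <- panel$coords
  both[n + seq_len(n), , ] <- refl
  joint <- gpa(shape_panel(both, ids = c(panel$ids, paste0(panel$ids, "_refl")),
                           cohort = panel$cohort[1]),
               with_scaling = with_scaling)
  out <- panel
  out$coords <- (joint$coords[seq_len(n), , , drop = FALSE] +
                   joint$coords[n + seq_len(n), , , drop = FALSE]) / 2
  out$state <- "symmetrized"
  attr(out, "mean_shape") <- attr(joint, "mean_shape")
  out
}

#' Mahalanobis quality flagging of landmark configurations
#'
#' Flags atypical individuals by the Mahalanobis distance between each
#' configuration and the panel mean, computed in a PCA-reduced shape space
#' (components covering `var_frac` of variance; the raw landmark covariance
#' is singular for dense configurations). Distances are standardized to
#' Z-scores over the panel and individuals with `z > z_threshold` are
#' flagged for inspection.
#'
#' @param panel a superimposed or symmetrized [shape_panel()].
#' @param z_threshold flagging threshold on the Z-score (default 2).
#' @param var_frac fraction of variance the retained PC space must explain.
#' @return a `QC report` data frame: `individual_id`, `mahalanobis_distance`,
#'   `z_score`, `flagged`.
#' @export
qc_flag <- function(panel, z_threshold = 2, var_frac = 0.98) {
  stopifnot(inherits(panel, "shape_panel"))
  X <- flatten_coords(panel$coords)
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (n - 1)
  pos <- ev > max(ev) * 1e-12
  m <- which(cumsum(ev[pos]) / sum(ev[pos]) >= var_frac)[1]
  if (n <= m + 1L)
    stop("too few individuals for the retained PC space; reduce `var_frac`")
  scores <- Xc %*% sv$v[, seq_len(m), drop = FALSE]
  d <- sqrt(rowSums(sweep(scores^2, 2, ev[seq_len(m)], "/")))
  z <- as.numeric(scale(d))
  data.frame(individual_id = panel$ids,
             mahalanobis_distance = d,
             z_score = z,
             flagged = z > z_threshold,
             stringsAsFactors = FALSE)
}
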