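#' Escoufier RV coefficient between two variable blocks
#'
#' The scalar association measure between two multivariate blocks:
#' \eqn{RV = tr(S_{xy} S_{yx}) / \sqrt{tr(S_{xx}^2) tr(S_{yy}^2)}}
#' with `S` the sample cross-covariance blocks of the column-centred data.
#' Lies in `[0, 1]`; invariant to orthogonal rotation of either block.
#'
#' @param X `N x p` matrix.
#' @param Y `N x q` matrix, same rows.
#' @return scalar in `[0, 1]`; defined as 0 (with a warning) when either
#'   block has zero variance.
#' @export
rv_coefficient <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("blocks must share rows")
  if (nrow(X) < 3L) stop("need at least 3 observations")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  # the 1/(n-1) covariance normalizations cancel between numerator and
  # denominator, so unnormalized cross-products suffice
  sxx <- sum(crossprod(Xc)^2); syy <- sum(crossprod(Yc)^2)
  if (sxx == 0 || syy == 0) {
    warning("zero-variance block; RV defined as 0")
    return(0)
  }
  sum(crossprod(Xc, Yc)^2) / sqrt(sxx * syy)
}

#' Landmark-by-landmark RV similarity matrix
#'
#' Computes the Escoufier RV coefficient between every pair of landmarks,
#' each treated as its 3-column (x, y, z) coordinate block, on the pooled,
#' corrected, aligned data. This structural-covariation matrix drives the
#' hierarchical segmentation.
#'
#' @param shape_residuals `N x 3L` matrix of corrected flattened coordinates
#'   (pooled across cohorts), columns in landmark-major x/y/z order.
#' @return an `L x L` symmetric matrix of class `rv_matrix`, unit diagonal,
#'   entries in `[0, 1]`.
#' @export
build_similarity <- function(shape_residuals) {
  X <- as.matrix(shape_residuals)
  if (any(!is.finite(X))) stop("non-finite coordinates in shape residuals")
  L <- ncol(X) / 3L
  if (L != round(L)) stop("column count must be a multiple of 3")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  C2 <- crossprod(Xc)^2                    # squared cross-covariance, common scale
  grp <- rep(seq_len(L), each = 3L)
  B <- rowsum(t(rowsum(C2, grp)), grp)     # block-wise Frobenius norms
  bd <- diag(B)
  if (any(bd == 0)) warning("zero-variance landmark(s); their RV set to 0")
  den <- sqrt(outer(bd, bd))
  RV <- ifelse(den > 0, B / den, 0)
  diag(RV) <- 1
  structure(RV, class = c("rv_matrix", "matrix"),
            computed_on = sprintf("pooled sample, N = %d, L = %d", nrow(X), L))
}

#' Hierarchical spectral segmentation of landmarks
#'
#' Recursively bipartitions the landmark set into a binary segment tree of
#' the given depth. At each node, a weighted graph is formed on the node's
#' landmarks with edges restricted to template-adjacent pairs and weighted by
#' RV similarity (so segments are both strongly covarying and spatially
#' contiguous); the normalized graph Laplacian's Fiedler vector provides the
#' bipartition (sign split, with a seeded 2-means fall-back on the 2D
#' spectral embedding and a balanced median cut as last resort). Children are
#' repaired to induce connected subgraphs.
#'
#' Node ids follow binary-heap numbering: root 1, children of `k` are `2k`
#' and `2k + 1`; level `l` holds nodes `2^l ... 2^{l+1} - 1`, so a tree of
#' depth `D` has `2^{D+1} - 1` nodes (63 for the default depth 5) and `2^D`
#' leaves.
#'
#' @param sim `L x L` RV similarity matrix (from [build_similarity()]).
#' @param adjacency `L x L` symmetric 0/1 landmark adjacency, connected.
#' @param depth tree depth `D >= 1` (default 5, i.e. 63 segments).
#' @param seed integer seed for the k-means fall-back.
#' @param min_size smallest admissible segment (default 3 landmarks, the
#'   minimum for per-segment Procrustes alignment).
#' @return an object of class `segment_tree`: list with `nodes` (data frame:
#'   `node_id`, `level`, `parent_id`), `landmarks` (list of 1-based index
#'   vectors keyed by node id), `depth`, `L`.
#' @export
hierarchical_spectral_cluster <- function(sim, adjacency, depth = 5L, seed = 1L,
                                          min_size = 3L) {
  L <- nrow(sim)
  stopifnot(nrow(adjacency) == L, ncol(adjacency) == L)
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  g_full <- igraph::graph_from_adjacency_matrix(1 * (adjacency > 0),
                                                mode = "undirected")
  if (igraph::components(g_full)$no != 1L)
    stop("adjacency graph must be connected on the full landmark set")
  W <- pmax(unclass(sim), 1e-6) * (adjacency > 0)   # keep masked graph connected
  diag(W) <- 0

  landmarks <- list()
  nodes <- data.frame(node_id = 1L, level = 0L, parent_id = NA_integer_)
  landmarks[["1"]] <- seq_len(L)
  for (lev in seq_len(depth)) {
    # each child must keep enough landmarks for its own remaining splits
    child_quota <- min_size * 2L^(depth - lev)
    for (pid in nodes$node_id[nodes$level == lev - 1L]) {
      idx <- landmarks[[as.character(pid)]]
      halves <- bipartition(W, adjacency, idx, child_quota,
                            seed = seed + 97L * pid)
      for (j in 1:2) {
        cid <- 2L * pid + (j - 1L)
        nodes <- rbind(nodes, data.frame(node_id = cid, level = lev,
                                         parent_id = pid))
        landmarks[[as.character(cid)]] <- sort(halves[[j]])
      }
    }
  }
  structure(list(nodes = nodes, landmarks = landmarks,
                 depth = as.integer(depth), L = L),
            class = "segment_tree")
}

#' @export
print.segment_tree <- function(x, ...) {
  cat(sprintf("<segment_tree> depth %d: %d segments (%d leaves) over %d landmarks\n",
              x$depth, nrow(x$nodes), sum(x$nodes$level == x$depth), x$L))
  invisible(x)
}

# Split one node's landmark set in two connected, min-size-respecting halves.
bipartition <- function(W, adjacency, idx, min_size, seed) {
  n <- length(idx)
  if (n < 2L * min_size)
    stop(sprintf(paste0("segment of %d landmarks cannot be split into two of ",
                        ">= %d; use a smaller tree depth"), n, min_size))
  Wn <- W[idx, idx, drop = FALSE]
  An <- adjacency[idx, idx, drop = FALSE] > 0
  d <- rowSums(Wn)
  d[d == 0] <- 1e-12
  Dm <- 1 / sqrt(d)
  Lsym <- diag(n) - (Dm * Wn) * rep(Dm, each = n)   # I - D^-1/2 W D^-1/2
  eig <- eigen(Lsym, symmetric = TRUE)
  fied <- eig$vectors[, n - 1L] * Dm                # back-transformed indicator
  embed2 <- cbind(fied, if (n >= 3L) eig$vectors[, n - 2L] * Dm else fied)

  connected_ok <- function(side) {
    g <- igraph::graph_from_adjacency_matrix(1 * An[side, side, drop = FALSE],
                                             mode = "undirected")
    igraph::components(g)$no == 1L
  }
  # Move stray components of each side to the other side until both connect.
  repair <- function(lab) {
    for (pass in 1:20) {
      moved <- FALSE
      for (side_val in c(TRUE, FALSE)) {
        side <- which(lab == side_val)
        if (length(side) == 0L) return(NULL)
        comp <- igraph::components(igraph::graph_from_adjacency_matrix(
          1 * An[side, side, drop = FALSE], mode = "undirected"))
        if (comp$no > 1L) {
          keep <- which.max(comp$csize)
          lab[side[comp$membership != keep]] <- !side_val
          moved <- TRUE
        }
      }
      if (!moved) return(lab)
    }
    NULL
  }
  try_labels <- function(lab) {
    if (length(unique(lab)) < 2L) return(NULL)
    lab <- repair(lab)
    if (is.null(lab)) return(NULL)
    if (sum(lab) < min_size || sum(!lab) < min_size) return(NULL)
    lab
  }

  # region-growing in Fiedler order: one side connected by construction,
  # balanced to n %/% 2; last-resort candidate
  region_grow <- function() {
    lab <- rep(FALSE, n)
    lab[which.min(fied)] <- TRUE
    while (sum(lab) < n %/% 2L) {
      frontier <- which(!lab & colSums(An[lab, , drop = FALSE]) > 0)
      if (!length(frontier)) break
      lab[frontier[which.min(fied[frontier])]] <- TRUE
    }
    lab
  }

  cands <- list(fied > 0)
  set.seed(seed)
  km <- tryCatch(stats::kmeans(embed2, centers = 2L, nstart = 5L),
                 error = function(e) NULL)
  if (!is.null(km)) cands <- c(cands, list(km$cluster == 1L))
  cands <- c(cands, list(rank(fied, ties.method = "first") <= n %/% 2L),
             list(region_grow()))
  for (lab in cands) {
    res <- try_labels(lab)
    if (!is.null(res)) return(list(idx[res], idx[!res]))
  }
  stop("could not bipartition segment into connected halves; use a smaller depth")
}

#' Per-segment Procrustes alignment and PCA with parallel analysis
#'
#' For every node of the segment tree, the segment's landmarks are
#' re-superimposed across the pooled individuals with [gpa()], a PCA is
#' fitted to the aligned, flattened coordinates, and the number of retained
#' components is chosen by Horn-style parallel analysis: components are kept
#' while the observed eigenvalue exceeds the `pa_percentile` quantile of
#' eigenvalues from `pa_reps` null datasets obtained by permuting each
#' column independently. A segment where no component survives retains one
#' component with a warning.
#'
#' All cohorts are pooled into a single PCA per segment, so every cohort
#' shares one shape space: stored scores are exactly the centred aligned
#' coordinates projected through the stored basis.
#'
#' @param coords pooled corrected configurations, `N x L x 3` array.
#' @param tree a [hierarchical_spectral_cluster()] segment tree.
#' @param cohort length-`N` cohort labels.
#' @param pa_reps parallel-analysis replicates (default 100).
#' @param pa_percentile null-eigenvalue quantile (default 0.95).
#' @param seed integer seed for the permutation null.
#' @param with_scaling passed to the per-segment [gpa()].
#' @param max_pc hard cap on the retained components per segment (default
#'   `Inf`). Superimposition and symmetrization leave the landmark noise
#'   correlated, so the permutation null lets many modest components through
#'   on large segments; downstream per-cohort canonical-correlation tests
#'   need `n` comfortably above the PC count, and the cap keeps the leading
#'   (largest-variance) components only. [run_pipeline()] sets it from the
#'   smallest cohort size.
#' @return an object of class `segment_pca`: list with `segments` (keyed by
#'   node id: `landmarks`, `basis` (3k x m, orthonormal), `center`,
#'   `scores` (N x m), `eigenvalues`, `retained`, `mean_config`), `cohort`,
#'   `tree`.
#' @export
segment_pca <- function(coords, tree, cohort, pa_reps = 100L,
                        pa_percentile = 0.95, seed = 1L, with_scaling = FALSE,
                        max_pc = Inf) {
  stopifnot(inherits(tree, "segment_tree"))
  n <- dim(coords)[1]
  if (length(cohort) != n) stop("`cohort` must label every pooled individual")
  segments <- list()
  set.seed(seed)
  for (key in as.character(tree$nodes$node_id)) {
    idx <- tree$landmarks[[key]]
    sub <- gpa(shape_panel(coords[, idx, , drop = FALSE], cohort = "pooled"),
               with_scaling = with_scaling)
    X <- flatten_coords(sub$coords)
    ctr <- colMeans(X)
    Xc <- sweep(X, 2, ctr)
    sv <- svd(Xc, nu = 0)
    ev <- sv$d^2 / (n - 1)
    k <- length(ev)
    null_ev <- matrix(0, pa_reps, k)
    for (r in seq_len(pa_reps)) {
      Xp <- apply(Xc, 2, sample)
      Xp <- sweep(Xp, 2, colMeans(Xp))
      vals <- eigen(crossprod(Xp) / (n - 1), symmetric = TRUE,
                    only.values = TRUE)$values
      null_ev[r, ] <- vals[seq_len(k)]
    }
    thr <- apply(null_ev, 2, stats::quantile, probs = pa_percentile)
    m <- 0L
    for (i in seq_len(k)) {
      if (ev[i] > thr[i]) m <- m + 1L else break
    }
    if (m == 0L) {
      warning(sprintf("segment %s: no component survives parallel analysis; retaining 1", key))
      m <- 1L
    }
    m <- as.integer(min(m, max_pc))
    basis <- sv$v[, seq_len(m), drop = FALSE]
    segments[[key]] <- list(
      landmarks = idx,
      basis = basis,
      center = ctr,
      scores = Xc %*% basis,
      eigenvalues = ev,
      retained = m,
      mean_config = attr(sub, "mean_shape"))
  }
  structure(list(segments = segments, cohort = cohort, tree = tree),
            class = "segment_pca")
}

#' @export
print.segment_pca <- function(x, ...) {
  ret <- vapply(x$segments, `[[`, integer(1), "retained")
  cat(sprintf("<segment_pca> %d segments, retained PCs %d-%d, N = %d pooled\n",
              length(x$segments), min(ret), max(ret), length(x$cohort)))
  invisible(x)
}
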