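#' Build a bilaterally symmetric synthetic landmark template
#'
#' Generates a face-like dense landmark template: points on a smoothly
#' deformed half-ellipsoid dome, mirrored across the sagittal plane `x = 0`.
#' The template carries everything the downstream pipeline needs from a
#' correspondence mask: coordinates, the left/right symmetry pairing with the
#' midline set, and a connected k-nearest-neighbour adjacency graph.
#'
#' Midline landmarks sit exactly on `x = 0`; every off-midline landmark has a
#' mirror partner obtained by negating its x-coordinate, so reflecting and
#' relabelling maps the template onto itself exactly.
#'
#' @param L number of landmarks (at least 20).
#' @param seed integer seed; the template is a deterministic function of
#'   `(L, seed)`.
#' @param k neighbours per landmark for the adjacency graph.
#' @return an object of class `template`: list with `coords` (`L x 3`),
#'   `pairs` (two-column integer matrix, columns `left`/`right`, 1-based),
#'   `midline` (integer vector), and `adjacency` (`L x L` symmetric 0/1
#'   matrix, connected).
#' @export
make_template <- function(L, seed = 1L, k = 6L) {
  if (!is.numeric(L) || L < 20L) stop("`L` must be at least 20")
  L <- as.integer(L)
  set.seed(seed)

  n_mid <- 4L + L %% 2L              # keeps L - n_mid even
  n_pair <- (L - n_mid) %/% 2L

  # parameter-space sample: u in (0, 1] for the right half, v in [-1, 1]
  u_r <- runif(n_pair, 0.06, 0.95)
  v_r <- runif(n_pair, -0.95, 0.95)
  u_m <- rep(0, n_mid)
  v_m <- seq(-0.9, 0.9, length.out = n_mid)

  dome <- function(u, v) {
    r2 <- (u / 1.05)^2 + (v / 1.05)^2
    z <- sqrt(pmax(0, 1 - r2))
    # smooth seeded deformation, even in u so the surface stays symmetric
    z + 0.15 * def_a * u^2 + 0.12 * def_b * v + 0.1 * def_c * v^2 +
      0.08 * def_d * u^2 * v
  }
  def_a <- rnorm(1); def_b <- rnorm(1); def_c <- rnorm(1); def_d <- rnorm(1)

  su <- 60; sv <- 80; sz <- 50      # arbitrary length units, face-like aspect
  mk <- function(u, v) cbind(x = su * u, y = sv * v, z = sz * dome(u, v))

  right <- mk(u_r, v_r)
  left <- right; left[, 1] <- -left[, 1]
  mid <- mk(u_m, v_m)

  coords <- rbind(mid, right, left)
  rownames(coords) <- NULL
  midline <- seq_len(n_mid)
  right_idx <- n_mid + seq_len(n_pair)
  left_idx <- n_mid + n_pair + seq_len(n_pair)
  pairs <- cbind(left = left_idx, right = right_idx)

  adjacency <- knn_adjacency(coords, k)
  structure(list(coords = coords, pairs = pairs, midline = midline,
                 adjacency = adjacency, L = L),
            class = "template")
}

#' @export
print.template <- function(x, ...) {
  cat(sprintf("<template> %d landmarks (%d symmetric pairs, %d midline), %d adjacency edges\n",
              x$L, nrow(x$pairs), length(x$midline), sum(x$adjacency) / 2))
  invisible(x)
}

# Symmetrized k-nearest-neighbour adjacency, forced connected by linking
# components through their closest landmark pair.
knn_adjacency <- function(coords, k) {
  L <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  adj <- matrix(0L, L, L)
  for (i in seq_len(L)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    adj[i, nb] <- 1L
  }
  adj <- 1L * ((adj + t(adj)) > 0)
  repeat {
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    if (comp$no == 1L) break
    main <- which(comp$membership == which.max(comp$csize))
    other <- which(comp$membership != comp$membership[main[1]])
    sub <- d[other, main, drop = FALSE]
    hit <- arrayInd(which.min(sub), dim(sub))
    i <- other[hit[1]]; j <- main[hit[2]]
    adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

# Permutation implementing the reflection relabelling: for each landmark, the
# index it maps to when left and right are swapped (midline maps to itself).
reflection_permutation <- function(pairs, midline, L) {
  perm <- seq_len(L)
  perm[pairs[, "left"]] <- pairs[, "right"]
  perm[pairs[, "right"]] <- pairs[, "left"]
  covered <- sort(c(pairs[, "left"], pairs[, "right"], midline))
  if (!identical(covered, seq_len(L)))
    stop("symmetry map must cover every landmark exactly once")
  perm
}

# Reflect a configuration across x = 0 and relabel left/right landmarks.
reflect_relabel <- function(config, pairs, midline) {
  perm <- reflection_permutation(pairs, midline, nrow(config))
  out <- config[perm, , drop = FALSE]
  out[, 1] <- -out[, 1]
  out
}
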