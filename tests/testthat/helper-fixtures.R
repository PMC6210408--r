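# Shared fixtures, built once per test run.

# small symmetric template used across files
tiny_template <- local({
  cache <- NULL
  function(L = 40, seed = 1) {
    key <- paste(L, seed)
    if (is.null(cache[[key]])) cache[[key]] <<- make_template(L, seed = seed)
    cache[[key]]
  }
})

# a panel of random configurations around a template
noise_panel <- function(template, n, sd = 1, seed = 1, cohort = "cohort_1") {
  set.seed(seed)
  L <- template$L
  A <- array(rep(template$coords, each = n), dim = c(n, L, 3)) +
    array(rnorm(n * L * 3, sd = sd), dim = c(n, L, 3))
  shape_panel(A, cohort = cohort)
}

# apply a random rigid motion to one configuration
rigid_jitter <- function(config, seed) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  config %*% (Rx %*% Ry %*% Rz) + matrix(rnorm(3, sd = 10), nrow(config), 3, byrow = TRUE)
}

# a one-node "tree" holding all landmarks, for isolated segment-PCA tests
single_node_tree <- function(k) {
  structure(list(nodes = data.frame(node_id = 1L, level = 0L,
                                    parent_id = NA_integer_),
                 landmarks = list(`1` = seq_len(k)),
                 depth = 0L, L = k),
            class = "segment_tree")
}

# symmetrized image of a per-landmark field under the template's reflection
symmetrize_field <- function(U, template) {
  perm <- segcca:::reflection_permutation(template$pairs, template$midline,
                                          template$L)
  Ur <- U[perm, , drop = FALSE]
  Ur[, 1] <- -Ur[, 1]
  (U + Ur) / 2
}

cosine_fields <- function(A, B) sum(A * B) / sqrt(sum(A^2) * sum(B^2))
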