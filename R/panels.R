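#' Construct a shape panel
#'
#' A shape panel is the package's container for a sample of dense 3D landmark
#' configurations in point-to-point correspondence: an `N x L x 3` array of
#' coordinates plus per-individual identifiers, a cohort label, and an
#' alignment-state flag tracking where the panel sits in the preprocessing
#' chain (`"raw"`, `"superimposed"` or `"symmetrized"`).
#'
#' @param coords numeric array of dimension `N x L x 3` (individuals,
#'   landmarks, x/y/z).
#' @param ids character vector of individual identifiers (default
#'   `"id_1" ... "id_N"`).
#' @param cohort single cohort label, recycled per individual.
#' @param state alignment state flag.
#' @return an object of class `shape_panel`.
#' @export
shape_panel <- function(coords, ids = NULL, cohort = "cohort_1",
                        state = c("raw", "superimposed", "symmetrized")) {
  state <- match.arg(state)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("`coords` must be an N x L x 3 array")
  if (any(!is.finite(coords)))
    stop("non-finite coordinates in shape panel")
  n <- dim(coords)[1]
  if (is.null(ids)) ids <- paste0("id_", seq_len(n))
  if (length(ids) != n) stop("`ids` length must match the number of individuals")
  structure(
    list(coords = coords, ids = as.character(ids),
         cohort = rep_len(as.character(cohort), n), state = state),
    class = "shape_panel"
  )
}

#' @export
print.shape_panel <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<shape_panel> %d individuals x %d landmarks x 3 (%s; cohorts: %s)\n",
              d[1], d[2], x$state, paste(unique(x$cohort), collapse = ", ")))
  invisible(x)
}

#' Number of individuals / landmarks in a shape panel
#' @param panel a `shape_panel`.
#' @return integer count.
#' @export
n_individuals <- function(panel) dim(panel$coords)[1]

#' @rdname n_individuals
#' @export
n_landmarks <- function(panel) dim(panel$coords)[2]

# Flatten an N x L x 3 array to N x 3L with columns x_0, y_0, z_0, x_1, ...
# (landmark-major, 0-based header convention used by the CSV writers).
flatten_coords <- function(coords) {
  n <- dim(coords)[1]; L <- dim(coords)[2]
  out <- matrix(aperm(coords, c(3, 2, 1)), nrow = n, ncol = 3L * L, byrow = TRUE)
  colnames(out) <- paste0(rep(c("x_", "y_", "z_"), L), rep(seq_len(L) - 1L, each = 3L))
  out
}

# Inverse of flatten_coords().
unflatten_coords <- function(mat) {
  n <- nrow(mat); L <- ncol(mat) / 3L
  aperm(array(t(mat), dim = c(3L, L, n)), c(3, 2, 1))
}

#' Construct a genotype panel
#'
#' Holds additive minor-allele counts (or dosages in `[0, 2]`) as an
#' individuals-by-SNPs matrix plus per-SNP metadata.
#'
#' @param counts numeric matrix, individuals x SNPs, values in `[0, 2]`.
#' @param meta data frame of SNP metadata with at least a `snp_id` column;
#'   built from column names when omitted.
#' @param ids individual identifiers.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(counts, meta = NULL, ids = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts > 2))
    stop("genotype counts must be finite and within [0, 2]")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("snp_", seq_len(ncol(counts)))
  if (is.null(meta))
    meta <- data.frame(snp_id = colnames(counts),
                       maf = colMeans(counts) / 2,
                       stringsAsFactors = FALSE)
  if (!all(colnames(counts) == meta$snp_id))
    stop("`meta$snp_id` must match the count matrix columns")
  if (is.null(ids)) ids <- paste0("id_", seq_len(nrow(counts)))
  rownames(counts) <- ids
  structure(list(counts = counts, meta = meta, ids = as.character(ids)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d SNPs (additive minor-allele codes)\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
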