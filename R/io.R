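# File dialects: landmarks as wide CSV (individual_id, x_0, y_0, z_0, ...;
# 0-based landmark indices in headers), genotypes and covariates as delimited
# tables, templates and segment trees as JSON. Every writer puts a "#" comment
# header naming the package version and (when given) the run seed; readers
# skip "#" lines.

io_header <- function(seed = NULL) {
  sprintf("# segcca %s%s",
          as.character(utils::packageVersion("segcca")),
          if (is.null(seed)) "" else sprintf("; seed=%d", as.integer(seed)))
}

#' Write / read a shape panel as wide CSV
#'
#' @param panel a [shape_panel()].
#' @param path output file.
#' @param seed optional seed recorded in the file header.
#' @return `read_landmarks()` returns a `shape_panel`; the writer returns
#'   `path` invisibly.
#' @export
write_landmarks <- function(panel, path, seed = NULL) {
  stopifnot(inherits(panel, "shape_panel"))
  X <- flatten_coords(panel$coords)
  df <- data.frame(individual_id = panel$ids, cohort = panel$cohort, X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  writeLines(io_header(seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty landmark file: ", path)
  coord_cols <- grep("^[xyz]_[0-9]+$", names(df), value = TRUE)
  L <- length(coord_cols) / 3L
  if (L < 1L || L != round(L))
    stop(sprintf("%s: malformed landmark columns (found %d coordinate columns)",
                 path, length(coord_cols)))
  expected <- paste0(rep(c("x_", "y_", "z_"), L), rep(seq_len(L) - 1L, each = 3L))
  if (!all(expected %in% names(df)))
    stop(sprintf("%s: expected columns x_0..z_%d in landmark-major order", path, L - 1L))
  X <- as.matrix(df[, expected])
  bad <- which(!stats::complete.cases(X) | !apply(is.finite(X), 1, all))
  if (length(bad))
    stop(sprintf("%s: non-finite coordinates in row(s) %s", path,
                 paste(utils::head(bad, 5), collapse = ", ")))
  cohort <- if ("cohort" %in% names(df)) df$cohort else "cohort_1"
  shape_panel(unflatten_coords(X), ids = df$individual_id, cohort = cohort)
}

#' Write / read a genotype panel
#'
#' TSV dialect: `individual_id` column plus one additive minor-allele count
#' column per SNP. `read_genotypes()` also accepts a VCF (via the vcfR
#' package): biallelic records only (multi-allelic records are skipped with a
#' warning), GT fields converted to alternate-allele counts and flipped to
#' minor-allele counts when the alternate allele frequency exceeds 0.5 (each
#' flip is logged), missing genotypes mean-imputed with per-SNP missingness
#' logged. SNPs below the minor-allele-frequency floor are excluded.
#'
#' @param panel a [genotype_panel()].
#' @param path output / input file (`.vcf` triggers VCF parsing on read).
#' @param seed optional seed recorded in the header.
#' @param maf_floor exclusion threshold on minor allele frequency
#'   (default 0.05).
#' @return `read_genotypes()` returns a `genotype_panel`; the writer returns
#'   `path` invisibly.
#' @export
write_genotypes <- function(panel, path, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- data.frame(individual_id = panel$ids, panel$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  writeLines(io_header(seed), con)
  utils::write.table(df, con, row.names = FALSE, quote = FALSE, sep = "\t")
  close(con)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, maf_floor = 0.05) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    panel <- read_genotypes_vcf(path)
  } else {
    df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("empty genotype file: ", path)
    counts <- as.matrix(df[, setdiff(names(df), "individual_id"), drop = FALSE])
    panel <- genotype_panel(counts, ids = df$individual_id)
  }
  maf <- colMeans(panel$counts) / 2
  drop_snp <- maf < maf_floor
  if (any(drop_snp)) {
    message("excluding ", sum(drop_snp), " SNP(s) with MAF < ", maf_floor, ": ",
            paste(colnames(panel$counts)[drop_snp], collapse = ", "))
    panel <- genotype_panel(panel$counts[, !drop_snp, drop = FALSE],
                            meta = panel$meta[!drop_snp, , drop = FALSE],
                            ids = panel$ids)
  }
  panel
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    warning("skipping ", sum(multi), " multi-allelic VCF record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  ids <- colnames(gt)
  alt_count <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/")
    vapply(a, function(al) {
      if (any(is.na(al)) || any(al == ".")) return(NA_real_)
      sum(al != "0")
    }, numeric(1))
  }
  counts <- t(apply(gt, 1, alt_count))
  snp_ids <- fix[, "ID"]
  snp_ids[is.na(snp_ids) | snp_ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(snp_ids) | snp_ids == "."]
  flipped <- logical(nrow(counts))
  minor <- fix[, "ALT"]; major <- fix[, "REF"]
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    n_miss <- sum(is.na(x))
    if (n_miss) {
      message(sprintf("%s: %d missing genotype(s) mean-imputed", snp_ids[i], n_miss))
      x[is.na(x)] <- mean(x, na.rm = TRUE)
    }
    if (mean(x) / 2 > 0.5) {
      message(sprintf("%s: ALT frequency %.2f > 0.5; coding flipped to REF allele",
                      snp_ids[i], mean(x) / 2))
      x <- 2 - x
      flipped[i] <- TRUE
      minor[i] <- fix[i, "REF"]; major[i] <- fix[i, "ALT"]
    }
    counts[i, ] <- x
  }
  counts <- t(counts)
  colnames(counts) <- snp_ids
  genotype_panel(counts,
                 meta = data.frame(snp_id = snp_ids, locus = fix[, "CHROM"],
                                   position = as.integer(fix[, "POS"]),
                                   minor_allele = minor, major_allele = major,
                                   flipped = flipped,
                                   maf = colMeans(counts) / 2,
                                   stringsAsFactors = FALSE),
                 ids = ids)
}

#' Write / read a covariate table as CSV
#' @param covariates data frame as produced by [simulate_cohorts()].
#' @param path file path.
#' @param seed optional seed recorded in the header.
#' @return the reader returns the data frame; the writer returns `path`
#'   invisibly.
#' @export
write_covariates <- function(covariates, path, seed = NULL) {
  con <- file(path, "w")
  writeLines(io_header(seed), con)
  utils::write.csv(covariates, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty covariate file: ", path)
  df
}

#' Write / read a template as JSON
#' @param template a [make_template()] object.
#' @param path file path.
#' @return the reader returns a `template`; the writer returns `path`
#'   invisibly.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "template"))
  edges <- which(template$adjacency > 0 & upper.tri(template$adjacency),
                 arr.ind = TRUE)
  jsonlite::write_json(
    list(coords = template$coords, pairs = template$pairs,
         midline = template$midline, edges = unname(edges), L = template$L),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- j$L
  adj <- matrix(0L, L, L)
  for (r in seq_len(nrow(j$edges))) {
    adj[j$edges[r, 1], j$edges[r, 2]] <- 1L
    adj[j$edges[r, 2], j$edges[r, 1]] <- 1L
  }
  pairs <- as.matrix(j$pairs); colnames(pairs) <- c("left", "right")
  structure(list(coords = as.matrix(j$coords), pairs = pairs,
                 midline = as.integer(j$midline), adjacency = adj, L = L),
            class = "template")
}

#' Serialize a segment tree to JSON
#' @param tree a [hierarchical_spectral_cluster()] segment tree.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_segment_tree <- function(tree, path) {
  stopifnot(inherits(tree, "segment_tree"))
  jsonlite::write_json(
    list(depth = tree$depth, L = tree$L, nodes = tree$nodes,
         landmarks = tree$landmarks),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-segment PC scores as TSV
#'
#' Long format: one row per (segment, individual, component) with the
#' pooled-basis score and the individual's cohort label.
#'
#' @param seg_pca a [segment_pca()] object.
#' @param path file path.
#' @param segments optional integer vector of node ids (default all).
#' @return `path`, invisibly.
#' @export
write_segment_scores <- function(seg_pca, path, segments = NULL) {
  stopifnot(inherits(seg_pca, "segment_pca"))
  keys <- names(seg_pca$segments)
  if (!is.null(segments)) keys <- intersect(keys, as.character(segments))
  rows <- lapply(keys, function(key) {
    sc <- seg_pca$segments[[key]]$scores
    data.frame(segment_id = as.integer(key),
               individual = rep(seq_len(nrow(sc)), ncol(sc)),
               cohort = rep(seg_pca$cohort, ncol(sc)),
               pc = rep(seq_len(ncol(sc)), each = nrow(sc)),
               score = as.vector(sc))
  })
  con <- file(path, "w")
  writeLines(io_header(), con)
  utils::write.table(do.call(rbind, rows), con, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  close(con)
  invisible(path)
}

#' Write a meta-analysis table as TSV
#' @param meta_table a [run_round_robin()] result.
#' @param path file path.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_meta_table <- function(meta_table, path, seed = NULL) {
  con <- file(path, "w")
  writeLines(io_header(seed), con)
  thr <- attr(meta_table, "threshold")
  if (!is.null(thr))
    writeLines(sprintf("# adjusted_threshold=%.6g", thr$adjusted_threshold), con)
  utils::write.table(as.data.frame(meta_table), con, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  close(con)
  invisible(path)
}

#' The candidate lead-SNP list
#'
#' Returns the shipped fixture of orofacial-cleft (NSCL/P) candidate
#' lead-SNPs assembled from published genome-wide association studies:
#' SNP id, genomic region, position (bp), the best reported association
#' p-value, and the annotated candidate gene where one is established.
#'
#' @return data frame with columns `snp_id`, `region`, `position_bp`,
#'   `reported_p`, `candidate_gene`.
#' @export
nsclp_lead_snps <- function() {
  path <- system.file("extdata", "nsclp_lead_snps.tsv", package = "segcca")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(df$snp_id))
  df
}
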