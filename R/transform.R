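#' @rdname css_normalize
#' @export
abundance_matrix <- function(values, transform) {
  values <- as.matrix(values)
  structure(values, transform = transform, class = c("abundance_matrix",
                                                     class(values)))
}

as_count_matrix <- function(x) {
  if (inherits(x, "otu_table")) x$counts else as.matrix(unclass(x))
}

#' Cumulative sum scaling (CSS) normalisation
#'
#' Each sample's counts are divided by the sum of its counts up to the
#' sample-specific quantile of its nonzero counts, then rescaled by the
#' median of those scaling factors so values stay on a count-like scale.
#'
#' @param table an [otu_table()] or counts matrix (samples x OTUs).
#' @param quantile quantile level of the nonzero counts, default 0.5.
#' @return an `abundance_matrix` with transform `"css"`; dropped all-zero
#'   samples are recorded in attribute `"dropped"`; attribute `"factors"`
#'   holds the per-sample scaling sums.
#' @export
css_normalize <- function(table, quantile = 0.5) {
  counts <- as_count_matrix(table)
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero sample(s): %s", sum(zero),
                    paste(rownames(counts)[zero], collapse = ", ")))
    counts <- counts[!zero, , drop = FALSE]
  }
  fac <- apply(counts, 1, function(x) {
    nz <- x[x > 0]
    q <- stats::quantile(nz, probs = quantile, type = 7, names = FALSE)
    sum(x[x <= q])
  })
  med <- stats::median(fac)
  out <- counts / fac * med
  am <- abundance_matrix(out, "css")
  attr(am, "factors") <- fac
  attr(am, "dropped") <- rownames(as_count_matrix(table))[zero]
  am
}

#' Hellinger transformation
#'
#' Square root of the per-sample relative abundance: entry
#' `sqrt(x / rowsum)`. Rows with zero total map to zero with a warning.
#'
#' @param x an [otu_table()], counts matrix or `abundance_matrix`.
#' @return an `abundance_matrix` with transform `"hellinger"`.
#' @export
hellinger_transform <- function(x) {
  m <- as_count_matrix(x)
  if (any(m < 0)) stop_input("Hellinger transform needs nonnegative input")
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning(sprintf("%d all-zero row(s) map to zeros", sum(tot == 0)))
    tot[tot == 0] <- 1
  }
  abundance_matrix(sqrt(m / tot), "hellinger")
}

#' Relative abundance (total-sum scaling)
#'
#' @param x an [otu_table()] or counts matrix.
#' @return an `abundance_matrix` with transform `"relative"`; all-zero rows
#'   stay zero.
#' @export
relative_abundance <- function(x) {
  m <- as_count_matrix(x)
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  abundance_matrix(m / tot, "relative")
}

#' Centered log-ratio (CLR) transform
#'
#' `log(count + pseudocount)` centered to zero mean within each sample; the
#' standard compositional preprocessing before covariance-network inference.
#'
#' @param table an [otu_table()] or counts matrix.
#' @param pseudocount value added before the log, default 1.
#' @return an `abundance_matrix` with transform `"clr"`; rows sum to 0.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  m <- as_count_matrix(table)
  if (any(m < 0)) stop_input("CLR transform needs nonnegative input")
  lg <- log(m + pseudocount)
  abundance_matrix(lg - rowMeans(lg), "clr")
}

#' Labelled community distance matrix
#'
#' Light wrapper around a symmetric matrix with zero diagonal, sample labels
#' and a metric tag; accepted by all ordination and permutation functions.
#'
#' @param m symmetric numeric matrix (or `dist`) with labels.
#' @param metric metric tag, e.g. `"bray"` or `"nei_pi"`.
#' @return an object of class `comm_dist` (a labelled matrix).
#' @export
comm_dist <- function(m, metric = "unknown") {
  if (inherits(m, "dist")) m <- as.matrix(m)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop_input("distance matrix must be square and symmetric")
  if (any(diag(m) != 0)) stop_input("distance matrix must have zero diagonal")
  if (any(m < 0)) stop_input("distances must be nonnegative")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  structure(m, metric = metric, class = c("comm_dist", "matrix", "array"))
}

#' @export
print.comm_dist <- function(x, ...) {
  cat(sprintf("comm_dist: %d samples, metric = %s\n", nrow(x),
              attr(x, "metric")))
  invisible(x)
}

#' Bray-Curtis dissimilarity
#'
#' `d(x, y) = sum|x - y| / sum(x + y)` between sample rows. Pairs of
#' all-zero rows get distance 0 with a warning.
#'
#' @param x an `abundance_matrix`, [otu_table()] or nonnegative matrix.
#' @return a [comm_dist()] with metric `"bray"`.
#' @export
bray_curtis <- function(x) {
  m <- as_count_matrix(x)
  if (any(m < 0)) stop_input("Bray-Curtis needs nonnegative input")
  num <- as.matrix(dist(m, method = "manhattan"))
  s <- rowSums(m)
  den <- outer(s, s, "+")
  if (any(s == 0)) warning("all-zero row(s): distances to them set to 0/1 convention")
  d <- num / ifelse(den == 0, 1, den)
  diag(d) <- 0
  comm_dist(d, "bray")
}

#' Write / read a square labelled distance matrix as TSV
#'
#' @param d a [comm_dist()].
#' @param path file path.
#' @return `write_distance` returns `path` invisibly; `read_distance`
#'   returns a [comm_dist()].
#' @export
write_distance <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), as.matrix(unclass(d)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance
#' @param metric metric tag for the matrix read back.
#' @export
read_distance <- function(path, metric = "unknown") {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  comm_dist(as.matrix(df), metric)
}
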