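# draw one permutation of 1..n, optionally restricted within strata blocks
restricted_perm <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  perm <- seq_len(n)
  for (lv in unique(strata)) {
    idx <- which(strata == lv)
    perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

# incremental orthonormal bases for the sequential (Type I) design:
# returns a list of basis-increment matrices, one per term
sequential_bases <- function(terms, data) {
  n <- nrow(data)
  q <- matrix(1 / sqrt(n), n, 1)  # intercept
  out <- vector("list", length(terms))
  for (j in seq_along(terms)) {
    mm <- tryCatch(
      model.matrix(stats::as.formula(paste("~", terms[j])), data),
      error = function(e)
        stop_input("term '%s' is constant or aliased with earlier terms",
                   terms[j]))
    mm <- mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
    r <- mm - q %*% (t(q) %*% mm)
    sv <- svd(r)
    keep <- sv$d > max(dim(r)) * max(sv$d, 0) * 1e-9
    if (!any(keep))
      stop_input("term '%s' is constant or aliased with earlier terms",
                 terms[j])
    dq <- sv$u[, keep, drop = FALSE]
    out[[j]] <- dq
    q <- cbind(q, dq)
  }
  names(out) <- terms
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Sequential (Type I) partitioning of a distance matrix among model terms
#' via the McArdle-Anderson identity: sums of squares are traces of hat
#' matrices applied to the Gower-centered inner-product matrix. Significance
#' comes from permuting sample identities, freely or within `strata`, and
#' recomputing the full sequential table for each permutation.
#'
#' @param formula a formula whose left side evaluates to a [comm_dist()],
#'   `dist` or square matrix, e.g. `d ~ timepoint + subpopulation`.
#' @param data data.frame holding the terms, rows aligned with the distance
#'   matrix.
#' @param n_perm number of permutations, default 999.
#' @param strata optional grouping (vector or column name in `data`);
#'   permutations never move a sample between strata.
#' @param seed integer seed for the permutation stream.
#' @return object of class `permanova`: data.frame with rows per term plus
#'   `Residual` and `Total`, columns `Df`, `SumOfSqs`, `R2`, `F`, `p`.
#' @export
permanova <- function(formula, data, n_perm = 999, strata = NULL, seed = 1) {
  d <- eval(formula[[2]], envir = data, enclos = environment(formula))
  d <- as.matrix(unclass(d))
  n <- nrow(d)
  if (nrow(data) != n) stop_input("data rows must align with distance matrix")
  terms <- attr(stats::terms(formula), "term.labels")
  if (!length(terms)) stop_input("no model terms given")
  if (!is.null(strata)) {
    if (is.character(strata) && length(strata) == 1) strata <- data[[strata]]
    if (length(strata) != n) stop_input("strata must align with samples")
    sizes <- table(strata)
    if (any(sizes < 2))
      stop_input("strata with singleton blocks: %s",
                 paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  bases <- sequential_bases(terms, data)
  df <- vapply(bases, ncol, 0L)
  df_res <- n - 1 - sum(df)
  if (df_res <= 0)
    stop_input("no residual degrees of freedom (model saturated)")
  g <- gower_center(d)
  q <- do.call(cbind, bases)
  idx <- rep(seq_along(bases), df)

  ss_terms <- function(qp) {
    # q'Gq summed per term block
    v <- colSums(qp * (g %*% qp))
    as.vector(rowsum(v, idx))
  }
  ss_total <- sum(diag(g))
  ss <- ss_terms(q)
  ss_res <- ss_total - sum(ss)
  f_obs <- (ss / df) / (ss_res / df_res)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    perm <- restricted_perm(n, strata)
    ssp <- ss_terms(q[perm, , drop = FALSE])
    fp <- (ssp / df) / ((ss_total - sum(ssp)) / df_res)
    exceed <- exceed + (fp >= f_obs - 1e-12)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  p <- (exceed + 1) / (n_perm + 1)

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(df, df_res, n - 1),
    SumOfSqs = c(ss, ss_res, ss_total),
    R2 = c(ss, ss_res, ss_total) / ss_total,
    F = c(f_obs, NA, NA),
    p = c(p, NA, NA))
  structure(tab, class = c("permanova", "data.frame"), n_perm = n_perm,
            strata = if (is.null(strata)) "none" else "restricted",
            seed = seed)
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (sequential SS, %d permutations, strata: %s)\n",
              attr(x, "n_perm"), attr(x, "strata")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a PERMANOVA table as TSV
#'
#' @param x a `permanova` object.
#' @param path output path.
#' @export
write_permanova <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Multivariate homogeneity of group dispersions
#'
#' Distances from each sample to its group centroid in the full principal
#' coordinate space (axes with negative eigenvalues contribute negatively to
#' the squared distance), followed by a one-way F test whose p-value comes
#' from permuting group labels.
#'
#' @param dist a [comm_dist()] or `dist`.
#' @param groups grouping vector aligned with samples; groups of size 1 are
#'   excluded with a warning.
#' @param n_perm number of permutations, default 999.
#' @param seed integer seed.
#' @return object of class `dispersion`: list with `distances` (per sample),
#'   `group_means`, `F`, `p`.
#' @export
dispersion_homogeneity <- function(dist, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(unclass(dist))
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop_input("need at least two groups")
  if (any(sizes < 2)) {
    warning(sprintf("excluding size-1 group(s): %s",
                    paste(names(sizes)[sizes < 2], collapse = ", ")))
    keep <- groups %in% names(sizes)[sizes >= 2]
    d <- d[keep, keep, drop = FALSE]
    groups <- groups[keep]
  }
  g <- gower_center(d)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol; neg <- e$values < -tol
  cpos <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  cneg <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
  z <- numeric(nrow(d))
  for (lv in unique(groups)) {
    idx <- groups == lv
    dp <- sweep(cpos[idx, , drop = FALSE], 2, colMeans(cpos[idx, , drop = FALSE]))
    dn <- sweep(cneg[idx, , drop = FALSE], 2, colMeans(cneg[idx, , drop = FALSE]))
    z[idx] <- sqrt(pmax(rowSums(dp^2) - rowSums(dn^2), 0))
  }
  f_stat <- function(z, groups) {
    m <- tapply(z, groups, mean); nn <- tapply(z, groups, length)
    ssb <- sum(nn * (m - mean(z))^2)
    ssw <- sum((z - m[groups])^2)
    k <- length(m)
    (ssb / (k - 1)) / (ssw / (length(z) - k))
  }
  f_obs <- f_stat(z, groups)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  b <- 0
  for (i in seq_len(n_perm))
    b <- b + (f_stat(z, groups[sample.int(length(groups))]) >= f_obs - 1e-12)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  structure(list(distances = setNames(z, rownames(d)),
                 groups = groups,
                 group_means = tapply(z, groups, mean),
                 F = f_obs, p = (b + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "dispersion")
}

#' @export
print.dispersion <- function(x, ...) {
  cat("Multivariate dispersion homogeneity\n")
  print(round(x$group_means, 4))
  cat(sprintf("F = %.4f, p = %.4g (%d permutations)\n", x$F, x$p, x$n_perm))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the lower triangles; the p-value comes from
#' jointly permuting the row/column order of the second matrix.
#'
#' @param d1,d2 [comm_dist()] (or `dist`/matrix) objects over the same
#'   samples in the same order.
#' @param n_perm number of permutations, default 999.
#' @param seed integer seed.
#' @return object of class `mantel`: list with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel <- function(d1, d2, n_perm = 999, seed = 1) {
  m1 <- as.matrix(unclass(d1)); m2 <- as.matrix(unclass(d2))
  if (!all(dim(m1) == dim(m2))) stop_input("distance matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop_input("distance matrices have mismatched sample labels")
  v1 <- as.vector(as.dist(m1)); v2 <- as.vector(as.dist(m2))
  if (sd(v1) == 0 || sd(v2) == 0)
    stop_input("zero variance in a distance triangle; Mantel r undefined")
  r_obs <- cor(v1, v2)
  n <- nrow(m1)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  b <- 0
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n)
    b <- b + (cor(v1, as.vector(as.dist(m2[perm, perm]))) >= r_obs - 1e-12)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  structure(list(r = r_obs, p = (b + 1) / (n_perm + 1), n_perm = n_perm,
                 seed = seed), class = "mantel")
}

#' @export
print.mantel <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}
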