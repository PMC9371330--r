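#' Genotype matrix of biallelic SNP dosages
#'
#' @param dosages numeric matrix in \{0, 1, 2\} (NA for missing), samples in
#'   rows, SNPs in columns; row names are sample ids.
#' @param snp_info optional data.frame with `snp`, `chrom`, `pos` aligned to
#'   columns.
#' @param maf_min minor-allele-frequency filter applied on construction,
#'   default 0.05.
#' @param miss_max maximum missing fraction per SNP, default 0.1.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_info = NULL, maf_min = 0.05,
                            miss_max = 0.1) {
  g <- as.matrix(dosages)
  if (!all(g[!is.na(g)] %in% 0:2))
    stop_input("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(g))) rownames(g) <- paste0("ind", seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- paste0("snp", seq_len(ncol(g)))
  miss <- colMeans(is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min & miss <= miss_max
  if (is.null(snp_info))
    snp_info <- data.frame(snp = colnames(g), chrom = "chr1",
                           pos = seq_len(ncol(g)))
  structure(list(dosages = g[, keep, drop = FALSE],
                 snp_info = snp_info[keep, , drop = FALSE],
                 freq = p[keep],
                 n_filtered = sum(!keep)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d filtered on load)\n",
              nrow(x$dosages), ncol(x$dosages), x$n_filtered))
  invisible(x)
}

#' Read genotypes from a dosage TSV or a minimal VCF
#'
#' The TSV layout is samples in rows (first column `sample_id`) and SNP ids
#' in the header. VCF input (uncompressed, GT-only, diploid biallelic) is
#' parsed with the vcfR package; missing genotypes `./.` become NA.
#'
#' @param path input file; `.vcf` triggers VCF parsing.
#' @param ... passed to [genotype_matrix()] (`maf_min`, `miss_max`).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, ...) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  if (grepl("\\.vcf$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop_input("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, 2, function(col) {
      a <- strsplit(col, "[/|]")
      vapply(a, function(x) {
        if (length(x) != 2 || any(x == ".")) return(NA_real_)
        sum(as.numeric(x))
      }, 0)
    })
    dos <- t(dos)  # vcfR: variants x samples -> samples x variants
    colnames(dos) <- rownames(gt)
    info <- data.frame(snp = rownames(gt),
                       chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v))
    genotype_matrix(dos, info, ...)
  } else {
    df <- read.delim(path, row.names = 1, check.names = FALSE)
    genotype_matrix(as.matrix(df), ...)
  }
}

#' Write genotypes as dosage TSV and/or minimal VCF
#'
#' @param g a [genotype_matrix()].
#' @param tsv_path,vcf_path output paths (either may be `NULL`).
#' @export
write_genotypes <- function(g, tsv_path = NULL, vcf_path = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(tsv_path)) {
    df <- data.frame(sample_id = rownames(g$dosages), g$dosages,
                     check.names = FALSE)
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(vcf_path)) {
    con <- file(vcf_path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(g$dosages)),
                       collapse = "\t")), con)
    gt_code <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(g$dosages))) {
      dos <- g$dosages[, j]
      gt <- ifelse(is.na(dos), "./.", gt_code[dos + 1])
      writeLines(paste(c(g$snp_info$chrom[j], g$snp_info$pos[j],
                         g$snp_info$snp[j], "A", "T", ".", "PASS", ".",
                         "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(c(tsv_path, vcf_path))
}

#' Nei's pi genetic distance
#'
#' Expected allele mismatch probability between two individuals, averaged
#' over loci non-missing in both:
#' \eqn{d_{ij} = \mathrm{mean}_l (g_i(2-g_j) + g_j(2-g_i)) / 4}.
#'
#' @param g a [genotype_matrix()].
#' @return a [comm_dist()] with metric `"nei_pi"`.
#' @export
nei_pi_distance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  G <- g$dosages
  M <- !is.na(G)
  A <- ifelse(M, G, 0)
  B <- ifelse(M, 2 - G, 0)
  num <- (A %*% t(B) + B %*% t(A)) / 4
  den <- M %*% t(M)
  if (any(den == 0))
    stop_input("sample pair(s) share no genotyped loci")
  d <- num / den
  diag(d) <- 0
  comm_dist((d + t(d)) / 2, "nei_pi")
}

#' Kinship (genomic relatedness) matrix
#'
#' VanRaden-style standardised cross-product: per locus,
#' \eqn{z = (g - 2p) / \sqrt{2p(1-p)}}, then \eqn{K = ZZ^T / m}. Missing
#' dosages are imputed to `2p`; monomorphic loci are dropped.
#'
#' @param g a [genotype_matrix()].
#' @return object of class `kinship_matrix` (symmetric matrix, attribute
#'   `"n_dropped"` counts monomorphic loci).
#' @export
kinship_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  G <- g$dosages
  p <- colMeans(G, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  G <- G[, keep, drop = FALSE]; p <- p[keep]
  for (j in which(colSums(is.na(G)) > 0))
    G[is.na(G[, j]), j] <- 2 * p[j]
  Z <- sweep(sweep(G, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  K <- Z %*% t(Z) / ncol(Z)
  structure(K, class = c("kinship_matrix", "matrix", "array"),
            n_dropped = sum(!keep), scaling = "vanraden")
}

# profiled REML log-likelihood for a single-random-effect model on the
# eigenbasis of K; h2 = sig_g^2 / (sig_g^2 + sig_e^2)
reml_loglik <- function(h2, lam, ystar, xstar) {
  v <- h2 * lam + (1 - h2)
  w <- 1 / v
  xtvx <- crossprod(xstar, xstar * w)
  xtvy <- crossprod(xstar, ystar * w)
  beta <- solve(xtvx, xtvy)
  r <- ystar - xstar %*% beta
  rss <- sum(r^2 * w)
  n <- length(ystar); p <- ncol(xstar)
  s2 <- rss / (n - p)
  -0.5 * ((n - p) * log(s2) + sum(log(v)) +
            determinant(xtvx, logarithm = TRUE)$modulus[1] + (n - p))
}

#' Pseudo-heritability by spectral REML
#'
#' Fits \eqn{y = X\beta + g + e}, \eqn{g \sim N(0, \sigma^2_g K)},
#' \eqn{e \sim N(0, \sigma^2_e I)}, by one-dimensional REML over
#' \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)} on the eigenbasis of
#' `K`. The standard error comes from the curvature of the REML
#' log-likelihood at the optimum.
#'
#' @param y numeric phenotype vector aligned with `K` (e.g. an ordination
#'   axis score per sample or genotype).
#' @param K a [kinship_matrix()] (or symmetric PSD matrix).
#' @param X optional fixed-covariate matrix (an intercept is always added).
#' @return object of class `heritability`: list with `h2`, `se`, `loglik`,
#'   `loglik0` (h2 = 0), `converged`, `boundary`.
#' @export
pseudo_heritability <- function(y, K, X = NULL) {
  if (!all(is.finite(y))) stop_input("phenotype must be finite")
  K <- as.matrix(unclass(K))
  if (length(y) != nrow(K)) stop_input("y and K are misaligned")
  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  U <- e$vectors
  Xf <- cbind(`(Intercept)` = rep(1, length(y)), X)
  ystar <- as.vector(crossprod(U, y))
  xstar <- crossprod(U, Xf)
  eps <- 1e-6
  opt <- optimize(reml_loglik, c(eps, 1 - eps), lam = lam, ystar = ystar,
                  xstar = xstar, maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  ll <- opt$objective
  ll0 <- reml_loglik(eps, lam, ystar, xstar)
  boundary <- h2 < 1e-3 || h2 > 1 - 1e-3
  # numerical curvature for the SE; guard boundary cases
  h <- 1e-4
  lo <- max(h2 - h, eps); hi <- min(h2 + h, 1 - eps)
  d2 <- (reml_loglik(hi, lam, ystar, xstar) - 2 * ll +
           reml_loglik(lo, lam, ystar, xstar)) / ((hi - h2) * (h2 - lo))
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  structure(list(h2 = h2, se = se, loglik = ll, loglik0 = ll0,
                 converged = TRUE, boundary = boundary),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("pseudo-heritability: h2 = %.3f +/- %s%s\n", x$h2,
              ifelse(is.na(x$se), "NA", sprintf("%.3f", x$se)),
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' Population-structure covariates from an SVD
#'
#' Top left singular vectors of the column-centered dosage matrix, or the
#' principal coordinates of a (double-centered) genetic distance matrix,
#' with their variance shares.
#'
#' @param x a [genotype_matrix()], dosage matrix, or [comm_dist()] of
#'   genetic distances.
#' @param n_pc number of components, default 10; truncated with a warning if
#'   it exceeds the available rank.
#' @return list with `covariates` (orthonormal columns) and `var_share`
#'   (nonincreasing).
#' @export
svd_covariates <- function(x, n_pc = 10) {
  if (inherits(x, "comm_dist") || (is.matrix(x) && isTRUE(all.equal(unname(x), unname(t(x)))) &&
                                   all(diag(as.matrix(x)) == 0))) {
    g <- gower_center(as.matrix(unclass(x)))
    e <- eigen(g, symmetric = TRUE)
    pos <- e$values > max(abs(e$values)) * 1e-9
    vecs <- e$vectors[, pos, drop = FALSE]
    shares <- e$values[pos] / sum(e$values[pos])
    rn <- rownames(as.matrix(unclass(x)))
  } else {
    m <- if (inherits(x, "genotype_matrix")) x$dosages else as.matrix(x)
    m <- scale(m, center = TRUE, scale = FALSE)
    s <- svd(m)
    pos <- s$d > max(s$d) * 1e-9
    vecs <- s$u[, pos, drop = FALSE]
    shares <- s$d[pos]^2 / sum(s$d[pos]^2)
    rn <- rownames(m)
  }
  if (n_pc > ncol(vecs)) {
    warning(sprintf("n_pc = %d exceeds rank %d; truncated", n_pc, ncol(vecs)))
    n_pc <- ncol(vecs)
  }
  covariates <- vecs[, seq_len(n_pc), drop = FALSE]
  rownames(covariates) <- rn
  colnames(covariates) <- paste0("PC", seq_len(n_pc))
  list(covariates = covariates, var_share = shares[seq_len(n_pc)])
}

#' Single-marker GWAS scan
#'
#' Ordinary least squares of the phenotype on intercept + covariates +
#' dosage, one SNP at a time, with a two-sided t-test on the dosage
#' coefficient. Missing dosages are mean-imputed; SNPs collinear with the
#' covariates yield NA and are counted.
#'
#' @param y numeric phenotype.
#' @param g a [genotype_matrix()] aligned with `y`.
#' @param covariates optional covariate matrix (e.g. from
#'   [svd_covariates()]).
#' @param alpha level for the FDR / Bonferroni thresholds, default 0.05.
#' @return object of class `gwas_result`: data.frame `snp`, `chrom`, `pos`,
#'   `beta`, `se`, `t`, `p`, `fdr_flag`, `bonf_flag`; attributes
#'   `lambda_gc`, `thresholds`, `n_collinear`.
#' @export
gwas_scan <- function(y, g, covariates = NULL, alpha = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  G <- g$dosages
  n <- length(y)
  if (nrow(G) != n) stop_input("y and genotypes are misaligned")
  if (sd(y) == 0) stop_input("constant phenotype: all tests degenerate")
  for (j in which(colSums(is.na(G)) > 0))
    G[is.na(G[, j]), j] <- mean(G[, j], na.rm = TRUE)
  M <- cbind(1, covariates)
  Q <- qr.Q(qr(M))
  ry <- y - Q %*% crossprod(Q, y)
  RG <- G - Q %*% crossprod(Q, G)
  gss <- colSums(RG^2)
  ok <- gss > max(gss) * 1e-12
  beta <- se <- tval <- p <- rep(NA_real_, ncol(G))
  beta[ok] <- colSums(RG[, ok, drop = FALSE] * as.vector(ry)) / gss[ok]
  dfree <- n - ncol(M) - 1
  rss <- sum(ry^2) - beta[ok]^2 * gss[ok]
  se[ok] <- sqrt(pmax(rss, 0) / dfree / gss[ok])
  tval[ok] <- beta[ok] / se[ok]
  p[ok] <- 2 * pt(abs(tval[ok]), dfree, lower.tail = FALSE)
  lambda_gc <- median(tval[ok]^2, na.rm = TRUE) / qchisq(0.5, 1)
  mt <- multiple_testing(p[ok], alpha)
  fdr_flag <- bonf_flag <- rep(NA, ncol(G))
  fdr_flag[ok] <- mt$fdr_flag; bonf_flag[ok] <- mt$bonf_flag
  out <- data.frame(snp = g$snp_info$snp, chrom = g$snp_info$chrom,
                    pos = g$snp_info$pos, beta = beta, se = se, t = tval,
                    p = p, fdr_flag = fdr_flag, bonf_flag = bonf_flag,
                    row.names = NULL)
  structure(out, class = c("gwas_result", "data.frame"),
            lambda_gc = lambda_gc, thresholds = mt$thresholds,
            n_collinear = sum(!ok), alpha = alpha)
}

#' Benjamini-Hochberg and Bonferroni discovery flags
#'
#' @param pvalues vector of p-values in (0, 1].
#' @param alpha family-wise / FDR level, default 0.05.
#' @return list with `fdr_flag`, `bonf_flag` (logical vectors) and
#'   `thresholds` (`fdr_cutoff` = largest flagged p or 0, `bonf_cutoff` =
#'   alpha / m).
#' @export
multiple_testing <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) stop_input("empty p-value vector")
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop_input("p-values must lie in (0, 1]")
  m <- length(pvalues)
  fdr_flag <- p.adjust(pvalues, "BH") <= alpha
  bonf_flag <- pvalues <= alpha / m
  list(fdr_flag = fdr_flag, bonf_flag = bonf_flag,
       thresholds = c(fdr_cutoff = if (any(fdr_flag)) max(pvalues[fdr_flag]) else 0,
                      bonf_cutoff = alpha / m))
}
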