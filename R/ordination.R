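# Gower double-centering of squared distances: G = -1/2 * J D^2 J
gower_center <- function(d) {
  d <- as.matrix(unclass(d))
  a <- -0.5 * d^2
  n <- nrow(d)
  rm <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm), 2, rm) + gm
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Eigendecomposition of the Gower-centered matrix \eqn{-\frac12 J D^2 J}.
#' Axes with negative eigenvalues are dropped (their magnitude is reported);
#' variance explained is computed over the positive eigenvalues.
#'
#' @param dist a [comm_dist()] or `dist`.
#' @param k number of axes to return; truncated with a warning if it exceeds
#'   the number of positive eigenvalues.
#' @return an object of class `ordination` with elements `points`
#'   (samples x k, centered), `eig` (positive eigenvalues), `var_explained`,
#'   `negative_eig`, `method = "pcoa"`.
#' @export
pcoa <- function(dist, k = 2) {
  d <- as.matrix(unclass(dist))
  g <- gower_center(d)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  if (k > sum(pos)) {
    warning(sprintf("k = %d exceeds %d positive eigenvalues; truncated",
                    k, sum(pos)))
    k <- sum(pos)
  }
  lam <- e$values[pos]
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), length(lam))
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCoA", seq_len(ncol(pts)))
  structure(list(points = pts[, seq_len(k), drop = FALSE],
                 all_points = pts,
                 eig = lam, var_explained = lam / sum(lam),
                 negative_eig = -e$values[e$values < -tol],
                 method = "pcoa", k = k),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination (%s): %d samples, %d axes", x$method,
              nrow(x$points), ncol(x$points)))
  if (x$method == "nmds")
    cat(sprintf(", stress-1 = %.4f%s", x$stress,
                if (isTRUE(x$converged)) "" else " (not converged)"))
  cat("\n")
  invisible(x)
}

#' @export
plot.ordination <- function(x, axes = c(1, 2), col = 1, ...) {
  plot(x$points[, axes[1]], x$points[, axes[2]],
       xlab = colnames(x$points)[axes[1]], ylab = colnames(x$points)[axes[2]],
       col = col, ...)
  invisible(x)
}

# lower-triangle vector of configuration distances
config_dist <- function(x) as.vector(dist(x))

# weak (primary) monotone regression of config distances on dissimilarity
# order: within tied dissimilarities, points are pre-sorted by distance so
# ties do not force a common fitted value
monotone_fit <- function(diss, cdist) {
  ord <- order(diss, cdist)
  fit <- numeric(length(diss))
  fit[ord] <- isoreg(cdist[ord])$yf
  fit
}

# Kruskal stress-1 of a configuration against dissimilarities
stress1 <- function(diss, cdist) {
  dhat <- monotone_fit(diss, cdist)
  sqrt(sum((cdist - dhat)^2) / sum(cdist^2))
}

#' Nonmetric multidimensional scaling (NMDS)
#'
#' Iterative minimisation of Kruskal's stress-1: configuration distances are
#' monotonically regressed onto the dissimilarity ranks (weak ties), then the
#' configuration is updated by a Guttman majorization step. The best of
#' `n_restarts` random starts plus one PCoA-seeded start is returned.
#'
#' @param dist a [comm_dist()] or `dist`.
#' @param k target dimension, default 2.
#' @param n_restarts random restarts in addition to the PCoA start.
#' @param max_iter,tol iteration cap and relative stress-change tolerance.
#' @param seed integer seed for the random starts.
#' @return an `ordination` with `points` (centered, principal-axis rotated),
#'   `stress`, `converged`, `n_restarts`, `seed`, and per-start stresses in
#'   `restart_stress`.
#' @export
nmds <- function(dist, k = 2, n_restarts = 20, max_iter = 200, tol = 1e-6,
                 seed = 1) {
  d <- as.matrix(unclass(dist))
  n <- nrow(d)
  if (n < k + 2) stop_input("need at least k + 2 samples for NMDS")
  diss <- as.vector(as.dist(d))
  starts <- vector("list", n_restarts + 1)
  p0 <- suppressWarnings(pcoa(comm_dist(d), k = min(k, n - 1)))$points
  if (ncol(p0) < k) p0 <- cbind(p0, matrix(0, n, k - ncol(p0)))
  starts[[1]] <- p0
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  for (i in seq_len(n_restarts))
    starts[[i + 1]] <- matrix(rnorm(n * k), n, k)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  run_one <- function(x) {
    x <- scale(x, scale = FALSE)
    cd <- config_dist(x)
    s <- stress1(diss, cd)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dhat <- monotone_fit(diss, cd)
      # Guttman transform: X+ = n^-1 B(X) X with b_ij = dhat_ij / d_ij(X)
      ratio <- ifelse(cd > 0, dhat / cd, 0)
      B <- matrix(0, n, n)
      B[lower.tri(B)] <- -ratio
      B <- B + t(B)
      diag(B) <- -rowSums(B)
      x_new <- (B %*% x) / n
      cd_new <- config_dist(x_new)
      s_new <- stress1(diss, cd_new)
      if (s_new > s) { converged <- TRUE; break }  # guarded: keep previous
      improve <- (s - s_new) / max(s, .Machine$double.eps)
      x <- x_new; cd <- cd_new; s <- s_new
      if (improve < tol) { converged <- TRUE; break }
    }
    list(points = x, stress = s, converged = converged)
  }

  runs <- lapply(starts, run_one)
  stresses <- vapply(runs, `[[`, 0, "stress")
  best <- runs[[which.min(stresses)]]
  # center and rotate to principal axes for a reproducible orientation
  pts <- scale(best$points, scale = FALSE)
  pts <- pts %*% svd(pts, nu = 0)$v
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = stress1(diss, config_dist(pts)),
                 converged = best$converged, method = "nmds", k = k,
                 n_restarts = n_restarts, seed = seed,
                 restart_stress = stresses, dissimilarity = diss),
            class = "ordination")
}

#' Shepard diagram data for an ordination
#'
#' Pairs every input dissimilarity with the corresponding ordination distance
#' and the monotone-regression fitted value used by stress-1.
#'
#' @param dist the dissimilarity matrix used to fit the ordination.
#' @param ordination an `ordination` (NMDS or PCoA).
#' @return data.frame with columns `dissimilarity`, `distance`, `fitted`,
#'   sorted by dissimilarity; recomputed stress-1 in attribute `"stress"`.
#' @export
shepard <- function(dist, ordination) {
  diss <- as.vector(as.dist(as.matrix(unclass(dist))))
  cd <- config_dist(ordination$points)
  fit <- monotone_fit(diss, cd)
  out <- data.frame(dissimilarity = diss, distance = cd, fitted = fit)
  out <- out[order(out$dissimilarity, out$distance), ]
  rownames(out) <- NULL
  attr(out, "stress") <- sqrt(sum((cd - fit)^2) / sum(cd^2))
  out
}
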