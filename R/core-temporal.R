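#' Rank OTUs by occupancy, then mean relative abundance
#'
#' Occupancy is the fraction of samples in which an OTU is present
#' (count > 0); ties are broken by mean relative abundance and then by OTU
#' id, so the ranking is invariant to sample and column order.
#'
#' @param table an [otu_table()] or counts matrix.
#' @return data.frame `otu_id`, `occupancy`, `mean_rel_abundance` in rank
#'   order.
#' @export
rank_occupancy_abundance <- function(table) {
  counts <- as_count_matrix(table)
  occ <- colMeans(counts > 0)
  rel <- relative_abundance(counts)
  mra <- colMeans(rel)
  ord <- order(-occ, -mra, colnames(counts))
  data.frame(otu_id = colnames(counts)[ord], occupancy = occ[ord],
             mean_rel_abundance = mra[ord], row.names = NULL)
}

#' Core-taxon selection by marginal beta-diversity contribution
#'
#' Walks the occupancy ranking; at each rank `k` the partial between-level
#' Bray-Curtis dissimilarity `BC_k` is the mean over between-level sample
#' pairs of the top-`k` OTUs' share of the Bray-Curtis numerator
#' (`sum_{o <= k} |x_o - y_o| / sum_all (x_o + y_o)` on relative
#' abundances). `BC_k` grows monotonically to the full between-level
#' dissimilarity, so the marginal contributions
#' `(BC_k - BC_{k-1}) / BC_full` are nonnegative and sum to one; OTUs are
#' included through the last rank whose contribution is at least
#' `increment`.
#'
#' @param table an [otu_table()].
#' @param factor metadata column name (or vector) with >= 2 levels, e.g.
#'   subpopulation or timepoint.
#' @param increment inclusion threshold on the marginal contribution,
#'   default 0.02 (the 2 percent rule).
#' @return object of class `core_set`: data.frame `otu_id`, `rank`,
#'   `contribution`, `included`; attributes `factor`, `stopping_rank`.
#' @export
select_core <- function(table, factor, increment = 0.02) {
  stopifnot(inherits(table, "otu_table"))
  f <- if (length(factor) == 1 && is.character(factor))
    table$sample_meta[[factor]] else factor
  f <- as.character(f)
  if (length(unique(f)) < 2) stop_input("core factor must have >= 2 levels")
  rel <- unclass(relative_abundance(table$counts))
  ranking <- rank_occupancy_abundance(table)
  ids <- ranking$otu_id
  n <- nrow(rel)
  between <- outer(f, f, "!=") & upper.tri(matrix(TRUE, n, n))
  den <- outer(rowSums(rel), rowSums(rel), "+")
  den[den == 0] <- 1
  bc_full <- mean((as.matrix(dist(rel, "manhattan")) / den)[between])
  num <- matrix(0, n, n)
  bc_prev <- 0
  contribution <- numeric(length(ids))
  for (k in seq_along(ids)) {
    x <- rel[, ids[k]]
    num <- num + abs(outer(x, x, "-"))
    bc_k <- mean((num / den)[between])
    contribution[k] <- (bc_k - bc_prev) / bc_full
    bc_prev <- bc_k
  }
  qualifying <- which(contribution >= increment)
  stopping <- if (length(qualifying)) max(qualifying) else 0L
  out <- data.frame(otu_id = ids, rank = seq_along(ids),
                    contribution = contribution,
                    included = seq_along(ids) <= stopping, row.names = NULL)
  structure(out, class = c("core_set", "data.frame"),
            factor = if (is.character(factor) && length(factor) == 1)
              factor else "custom",
            increment = increment, stopping_rank = stopping)
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set: %d of %d OTUs (factor: %s, increment %.3f)\n",
              sum(x$included), nrow(x), attr(x, "factor"),
              attr(x, "increment")))
  invisible(x)
}

#' Core OTU ids
#'
#' @param x a `core_set`.
#' @return character vector of included OTU ids in rank order.
#' @export
core_ids <- function(x) x$otu_id[x$included]

#' Intersection of two core sets
#'
#' @param a,b `core_set` objects (or character id vectors).
#' @return character vector: members of both cores, in `a`'s order.
#' @export
core_intersection <- function(a, b) {
  ia <- if (inherits(a, "core_set")) core_ids(a) else a
  ib <- if (inherits(b, "core_set")) core_ids(b) else b
  ia[ia %in% ib]
}

#' Per-OTU time explainability (sequential linear mixed model)
#'
#' Models each taxon's standardised relative abundance at times
#' `order+1 .. T` (stacked over subjects) with a random effect whose
#' covariance is a community kinship built from the per-OTU-standardised
#' community composition at the `order` preceding timepoints. Time
#' explainability is the REML variance fraction
#' \eqn{TE = \sigma^2_b / (\sigma^2_b + \sigma^2_e)}; significance uses a
#' likelihood-ratio test against \eqn{\sigma^2_b = 0} with the boundary
#' \eqn{\frac12\chi^2_0 + \frac12\chi^2_1} reference and Bonferroni
#' correction over tested OTUs.
#'
#' @param table an [otu_table()] of true samples.
#' @param subject,time metadata column names.
#' @param order Markov order (number of preceding timepoints), default 1.
#' @param alpha Bonferroni family level, default 0.05.
#' @return object of class `time_explainability`: data.frame `otu_id`, `te`,
#'   `lrt`, `p`, `significant`; attribute `skipped` lists untested OTUs.
#' @export
time_explainability <- function(table, subject = "genotype",
                                time = "timepoint", order = 1, alpha = 0.05) {
  stopifnot(inherits(table, "otu_table"))
  meta <- table$sample_meta
  rel <- unclass(relative_abundance(table$counts))
  times <- sort(unique(meta[[time]]))
  if (length(times) < order + 1)
    stop_input("need at least order + 1 timepoints")
  # stack response rows: subject x target-time pairs with a complete history
  resp_rows <- list(); hist_rows <- list()
  for (ti in seq(order + 1, length(times))) {
    tcur <- times[ti]
    prev <- times[(ti - order):(ti - 1)]
    cur_ids <- meta$sample_id[meta[[time]] == tcur]
    cur_sub <- meta[[subject]][match(cur_ids, meta$sample_id)]
    for (i in seq_along(cur_ids)) {
      hids <- vapply(prev, function(tp) {
        id <- meta$sample_id[meta[[time]] == tp & meta[[subject]] == cur_sub[i]]
        if (length(id) == 1) id else NA_character_
      }, "")
      if (anyNA(hids)) next
      resp_rows[[length(resp_rows) + 1]] <- cur_ids[i]
      hist_rows[[length(hist_rows) + 1]] <- hids
    }
  }
  if (!length(resp_rows)) stop_input("no subject has a complete history")
  resp_ids <- unlist(resp_rows)
  W <- do.call(rbind, lapply(hist_rows, function(h)
    as.vector(rel[h, , drop = FALSE])))
  sds <- apply(W, 2, sd)
  W <- scale(W[, sds > 0, drop = FALSE])
  K <- W %*% t(W) / ncol(W)
  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values, 0); U <- e$vectors
  xstar <- crossprod(U, matrix(1, nrow(K), 1))
  eps <- 1e-6

  early <- meta$sample_id[meta[[time]] %in% times[seq_len(length(times) - 1)]]
  tested <- list(); skipped <- character()
  for (j in seq_len(ncol(rel))) {
    oid <- colnames(rel)[j]
    if (all(rel[early, j] == 0)) { skipped <- c(skipped, oid); next }
    y <- rel[resp_ids, j]
    if (sd(y) == 0) { skipped <- c(skipped, oid); next }
    ystar <- as.vector(crossprod(U, as.vector(scale(y))))
    opt <- optimize(reml_loglik, c(eps, 1 - eps), lam = lam, ystar = ystar,
                    xstar = xstar, maximum = TRUE, tol = 1e-8)
    ll0 <- reml_loglik(eps, lam, ystar, xstar)
    lrt <- max(0, 2 * (opt$objective - ll0))
    p <- 0.5 * pchisq(lrt, 1, lower.tail = FALSE)
    tested[[oid]] <- c(te = opt$maximum, lrt = lrt, p = p)
  }
  tab <- as.data.frame(do.call(rbind, tested))
  tab <- data.frame(otu_id = names(tested), tab, row.names = NULL)
  m <- nrow(tab)
  tab$significant <- tab$p <= alpha / m
  structure(tab, class = c("time_explainability", "data.frame"),
            order = order, alpha = alpha, n_tested = m, skipped = skipped)
}

#' Indicator species analysis (IndVal)
#'
#' For each OTU and group, specificity `A` (the group's mean relative
#' abundance over the sum of group means) and fidelity `B` (occupancy within
#' the group) combine as `IndVal = sqrt(A * B)`. The max-group IndVal is
#' tested by permuting group labels; a z-score against the permutation
#' distribution and `p = (b + 1) / (n_perm + 1)` are reported.
#'
#' @param table an [otu_table()] or counts matrix.
#' @param groups grouping vector (or metadata column name) with >= 2 levels.
#' @param n_perm number of label permutations, default 999.
#' @param seed integer seed.
#' @return object of class `indval_result`: data.frame `otu_id`, `group`
#'   (argmax group), `A`, `B`, `indval`, `z`, `p`; all-zero OTUs are skipped.
#' @export
indval <- function(table, groups, n_perm = 999, seed = 1) {
  counts <- as_count_matrix(table)
  if (inherits(table, "otu_table") && length(groups) == 1 &&
      is.character(groups))
    groups <- table$sample_meta[[groups]]
  g <- as.character(groups)
  if (length(unique(g)) < 2) stop_input("need >= 2 groups")
  rel <- unclass(relative_abundance(counts))
  nz <- colSums(rel) > 0
  rel <- rel[, nz, drop = FALSE]
  pres <- rel > 0
  ng <- as.vector(table(g)[sort(unique(g))])
  stat_all <- function(g) {
    gm <- rowsum(rel, g) / as.vector(table(g)[sort(unique(g))])
    A <- sweep(gm, 2, colSums(gm), "/")
    B <- rowsum(pres + 0, g) / as.vector(table(g)[sort(unique(g))])
    sqrt(A * B)
  }
  iv_obs <- stat_all(g)
  best <- apply(iv_obs, 2, which.max)
  obs <- iv_obs[cbind(best, seq_len(ncol(iv_obs)))]
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  n <- length(g)
  perm_sum <- perm_sq <- numeric(length(obs)); b <- numeric(length(obs))
  for (i in seq_len(n_perm)) {
    ivp <- stat_all(g[sample.int(n)])
    mx <- apply(ivp, 2, max)
    perm_sum <- perm_sum + mx
    perm_sq <- perm_sq + mx^2
    b <- b + (mx >= obs - 1e-12)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  pm <- perm_sum / n_perm
  psd <- sqrt(pmax(perm_sq / n_perm - pm^2, 0) * n_perm / (n_perm - 1))
  gm <- rowsum(rel, g) / as.vector(table(g)[sort(unique(g))])
  A <- sweep(gm, 2, colSums(gm), "/")
  B <- rowsum(pres + 0, g) / as.vector(table(g)[sort(unique(g))])
  out <- data.frame(otu_id = colnames(rel),
                    group = rownames(iv_obs)[best],
                    A = A[cbind(best, seq_along(obs))],
                    B = B[cbind(best, seq_along(obs))],
                    indval = obs,
                    z = (obs - pm) / ifelse(psd > 0, psd, NA),
                    p = (b + 1) / (n_perm + 1), row.names = NULL)
  structure(out, class = c("indval_result", "data.frame"), n_perm = n_perm,
            seed = seed)
}
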