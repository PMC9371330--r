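# independent brute-force oracles used to cross-check the implementation

# sequential PERMANOVA by explicit hat matrices: H = X (X'X)^-1 X'
permanova_oracle <- function(d, data, terms) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% a %*% J
  hat <- function(X) X %*% solve(crossprod(X)) %*% t(X)
  ss <- df <- numeric(length(terms))
  H_prev <- hat(matrix(1, n, 1))
  rank_prev <- 1
  for (j in seq_along(terms)) {
    f <- stats::as.formula(paste("~", paste(terms[seq_len(j)], collapse = "+")))
    X <- stats::model.matrix(f, data)
    X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
    H <- hat(X)
    ss[j] <- sum(diag(H %*% G)) - sum(diag(H_prev %*% G))
    df[j] <- qr(X)$rank - rank_prev
    rank_prev <- qr(X)$rank
    H_prev <- H
  }
  ss_total <- sum(diag(G))
  ss_res <- ss_total - sum(ss)
  df_res <- n - rank_prev
  list(ss = ss, df = df, ss_res = ss_res, df_res = df_res,
       r2 = ss / ss_total, f = (ss / df) / (ss_res / df_res))
}

# Bray-Curtis by direct formula
bc_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)

# pool-adjacent-violators isotonic regression (unweighted, increasing)
pava_oracle <- function(y) {
  n <- length(y)
  val <- as.numeric(y); wt <- rep(1, n)
  i <- 1
  repeat {
    viol <- which(diff(val) < 0)
    if (!length(viol)) break
    j <- viol[1]
    new_val <- (val[j] * wt[j] + val[j + 1] * wt[j + 1]) / (wt[j] + wt[j + 1])
    val <- c(val[seq_len(j - 1)], new_val, val[-seq_len(j + 1)])
    wt <- c(wt[seq_len(j - 1)], wt[j] + wt[j + 1], wt[-seq_len(j + 1)])
  }
  rep(val, wt)
}

# one-sided Fisher p for over-representation in controls by hypergeometric tail
fisher_oracle <- function(k_c, n_c, k_s, n_s) {
  # P(X >= k_c) where X ~ Hypergeom(total present, total absent, n_c)
  k_tot <- k_c + k_s
  sum(stats::dhyper(k_c:min(n_c, k_tot), k_tot, n_c + n_s - k_tot, n_c))
}

# Benjamini-Hochberg by scanning every threshold
bh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  k_max <- 0
  for (k in seq_len(m)) if (p[ord[k]] <= alpha * k / m) k_max <- k
  flag <- rep(FALSE, m)
  if (k_max > 0) flag[ord[seq_len(k_max)]] <- TRUE
  flag
}

# mean point-to-path distance by dense sampling of the segments of y
trajectory_distance_oracle <- function(x, y, n_dense = 2000) {
  dense <- function(m) {
    if (nrow(m) == 1) return(m)
    do.call(rbind, lapply(seq_len(nrow(m) - 1), function(i) {
      t <- seq(0, 1, length.out = n_dense)
      outer(1 - t, m[i, ]) + outer(t, m[i + 1, ])
    }))
  }
  dy <- dense(y); dx <- dense(x)
  dird <- function(pts, dn) {
    mean(apply(pts, 1, function(p)
      min(sqrt(colSums((t(dn) - p)^2)))))
  }
  (dird(x, dy) + dird(y, dx)) / 2
}

# unweighted betweenness by enumerating all shortest paths (tiny graphs)
betweenness_oracle <- function(edges, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(v)
    c(edges$to[edges$from == v], edges$from[edges$to == v]))
  all_paths <- function(a, b) {
    # BFS collecting all shortest paths
    paths <- list(c(a)); found <- list(); best <- Inf
    while (length(paths)) {
      nxt <- list()
      for (p in paths) {
        v <- p[length(p)]
        if (v == b) { found <- c(found, list(p)); best <- length(p); next }
        if (length(p) >= best) next
        for (w in adj[[v]]) if (!w %in% p) nxt <- c(nxt, list(c(p, w)))
      }
      paths <- nxt
      if (length(found) && length(paths) &&
          length(paths[[1]]) > best) break
    }
    if (!length(found)) return(list())
    len <- vapply(found, length, 0)
    found[len == min(len)]
  }
  btw <- setNames(numeric(length(nodes)), nodes)
  pairs <- utils::combn(nodes, 2)
  for (k in seq_len(ncol(pairs))) {
    sp <- all_paths(pairs[1, k], pairs[2, k])
    if (!length(sp)) next
    for (p in sp) {
      inner <- setdiff(p, c(pairs[1, k], pairs[2, k]))
      btw[inner] <- btw[inner] + 1 / length(sp)
    }
  }
  btw
}

# small otu_table fixture
toy_table <- function(counts, groups = NULL, timepoints = NULL,
                      controls = NULL) {
  n <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("s%02d", 1:n)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("o%02d", seq_len(ncol(counts)))
  meta <- data.frame(sample_id = rownames(counts),
                     genotype = rownames(counts),
                     subpopulation = groups %||% rep("g1", n),
                     site = "toy",
                     timepoint = timepoints %||% rep(1L, n),
                     doy = 100, infected = FALSE,
                     is_control = controls %||% rep(FALSE, n))
  otu_table(counts, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cheap order-sensitive checksum for count matrices
digest_counts <- function(m)
  sum(as.numeric(m) * (seq_along(m) %% 97 + 1))

# 3 discriminating OTUs among 53; the other 50 are identical across groups
core_fixture <- function() {
  set.seed(23)
  n <- 20
  grp <- rep(c("A", "B"), each = n / 2)
  # background taxa are constant within each column (zero between-group
  # difference) and less abundant than the planted core, so the planted
  # OTUs lead the occupancy-abundance ranking
  flat <- matrix(rep(rep(8:14, length.out = 50), each = n), n, 50)
  discr <- cbind(ifelse(grp == "A", 60L, 5L),
                 ifelse(grp == "A", 4L, 50L),
                 ifelse(grp == "A", 40L, 2L))
  counts <- cbind(discr, flat)
  colnames(counts) <- c(sprintf("core%d", 1:3), sprintf("bg%02d", 1:50))
  rownames(counts) <- sprintf("s%02d", 1:n)
  toy_table(counts, groups = grp)
}

# fixed-depth table with one focal OTU that is an exact linear function of
# the previous timepoint's community (up to integer rounding), plus a slack
# OTU that pins every row total to `depth`
make_ar_table <- function(n_sub = 25, Tn = 4, n_base = 15, seed = 33,
                          depth = 5000L) {
  set.seed(seed)
  meta <- data.frame(sample_id = sprintf("s%03d", seq_len(n_sub * Tn)),
                     genotype = rep(sprintf("g%02d", seq_len(n_sub)), Tn),
                     timepoint = rep(seq_len(Tn), each = n_sub),
                     is_control = FALSE, infected = FALSE,
                     subpopulation = "x", site = "toy", doy = 1)
  base <- matrix(rpois(n_sub * Tn * n_base, 25) + 1L, n_sub * Tn, n_base)
  w <- runif(n_base)
  ar <- integer(n_sub * Tn)
  ar[meta$timepoint == 1] <- rpois(n_sub, 60)
  for (tp in 2:Tn)
    ar[meta$timepoint == tp] <-
      as.integer(round(base[meta$timepoint == tp - 1, , drop = FALSE] %*% w / 4))
  counts <- cbind(base, AR = ar)
  counts <- cbind(counts, slack = depth - rowSums(counts))
  stopifnot(all(counts >= 0))
  colnames(counts) <- c(sprintf("o%02d", seq_len(n_base)), "AR", "slack")
  rownames(counts) <- meta$sample_id
  otu_table(counts, meta)
}

# latent matrix with a planted 3-block correlation structure
block_clr <- function(n = 60, seed = 1, invert = FALSE) {
  set.seed(seed)
  blocks <- rep(1:3, each = 5)
  f <- matrix(rnorm(n * 3), n, 3)
  x <- sapply(seq_along(blocks), function(j)
    0.9 * f[, blocks[j]] + sqrt(1 - 0.81) * rnorm(n))
  if (invert) x[, seq(1, ncol(x), by = 2)] <- -x[, seq(1, ncol(x), by = 2)]
  colnames(x) <- sprintf("o%02d", seq_along(blocks))
  rownames(x) <- sprintf("s%02d", 1:n)
  x
}
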