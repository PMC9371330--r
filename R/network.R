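#' Stability-selected correlation network on CLR abundances
#'
#' Pearson correlations between OTUs on CLR-transformed data; an edge is
#' kept when `|r| >= r_thresh` in at least a `stability` fraction of random
#' sample subsamples. Edge sign and weight come from the full-data
#' correlation.
#'
#' @param clr an `abundance_matrix` from [clr_transform()] (or any numeric
#'   samples x OTUs matrix).
#' @param r_thresh absolute correlation threshold, default 0.35.
#' @param subsample fraction of samples drawn per subsample, default 0.8.
#' @param n_subsamples number of subsamples, default 50.
#' @param stability minimum fraction of subsamples supporting an edge,
#'   default 0.8.
#' @param seed integer seed.
#' @param timepoint optional label carried on the model.
#' @return object of class `comm_network`: list with `nodes`, `edges`
#'   (data.frame `from`, `to`, `weight`, `sign`, `stability`) and the
#'   inference parameters.
#' @export
infer_network <- function(clr, r_thresh = 0.35, subsample = 0.8,
                          n_subsamples = 50, stability = 0.8, seed = 1,
                          timepoint = NA) {
  m <- as.matrix(unclass(clr))
  n <- nrow(m)
  if (n < 10) stop_input("need >= 10 samples for network inference")
  ns <- floor(subsample * n)
  if (ns < 3) stop_input("subsample fraction leaves too few samples")
  keep_sd <- apply(m, 2, sd) > 0
  m_use <- m[, keep_sd, drop = FALSE]
  r_full <- suppressWarnings(cor(m_use))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  hits <- matrix(0, ncol(m_use), ncol(m_use))
  for (b in seq_len(n_subsamples)) {
    idx <- sample.int(n, ns)
    rs <- suppressWarnings(cor(m_use[idx, , drop = FALSE]))
    rs[is.na(rs)] <- 0
    hits <- hits + (abs(rs) >= r_thresh)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  stab <- hits / n_subsamples
  ut <- which(upper.tri(stab) & stab >= stability, arr.ind = TRUE)
  ids <- colnames(m_use)
  edges <- data.frame(from = ids[ut[, 1]], to = ids[ut[, 2]],
                      weight = r_full[ut],
                      sign = ifelse(r_full[ut] >= 0, "+", "-"),
                      stability = stab[ut], row.names = NULL)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = colnames(m), edges = edges,
                 params = list(r_thresh = r_thresh, subsample = subsample,
                               n_subsamples = n_subsamples,
                               stability = stability, seed = seed),
                 timepoint = timepoint),
            class = "comm_network")
}

#' @export
print.comm_network <- function(x, ...) {
  cat(sprintf("comm_network: %d nodes, %d edges (%d negative)%s\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign == "-"),
              if (is.na(x$timepoint)) "" else
                sprintf(" [timepoint %s]", x$timepoint)))
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    transform(net$edges, weight = abs(net$edges$weight)),
    directed = FALSE,
    vertices = data.frame(name = sort(net$nodes)))
  g
}

#' Detect network modules by greedy modularity maximisation
#'
#' Runs fast-greedy modularity optimisation (igraph) on the absolute edge
#' weights; vertices are ordered by id for a deterministic tie-break, and
#' isolated nodes each form their own module.
#'
#' @param net a [infer_network()] result.
#' @return list with `membership` (named integer vector over all nodes) and
#'   `modularity`.
#' @export
detect_modules <- function(net) {
  stopifnot(inherits(net, "comm_network"))
  if (!nrow(net$edges) && !length(net$nodes)) stop_input("empty graph")
  g <- as_igraph(net)
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  list(membership = setNames(as.integer(igraph::membership(cl)),
                             igraph::V(g)$name),
       modularity = max(cl$modularity))
}

#' Zi-Pi node roles
#'
#' Within-module degree z-score `Zi = (k_within - mean_module) / sd_module`
#' (0 when the module sd is 0) and participation coefficient
#' `Pi = 1 - sum_m (k_im / k_i)^2`. Role labels: network hub
#' (`Zi >= 2.5 & Pi >= 0.62`), module hub (`Zi >= 2.5 & Pi < 0.62`),
#' connector (`Zi < 2.5 & Pi >= 0.62`), else peripheral. Degree-zero nodes
#' are excluded and listed.
#'
#' @param net a [infer_network()] result.
#' @param modules a [detect_modules()] result (or named membership vector).
#' @param zi_cut,pi_cut role thresholds, defaults 2.5 and 0.62.
#' @return object of class `node_roles`: data.frame `otu_id`, `module`,
#'   `degree`, `zi`, `pi`, `role`; excluded isolated nodes in attribute
#'   `"isolated"`.
#' @export
zi_pi <- function(net, modules, zi_cut = 2.5, pi_cut = 0.62) {
  stopifnot(inherits(net, "comm_network"))
  memb <- if (is.list(modules)) modules$membership else modules
  edges <- net$edges
  nodes <- intersect(names(memb), net$nodes)
  deg <- setNames(numeric(length(nodes)), nodes)
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    deg[a] <- deg[a] + 1; deg[b] <- deg[b] + 1
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  isolated <- nodes[deg == 0]
  nodes <- nodes[deg > 0]
  k_within <- vapply(nodes, function(v)
    sum(memb[adj[[v]]] == memb[v]), 0)
  zi <- numeric(length(nodes)); names(zi) <- nodes
  for (mod in unique(memb[nodes])) {
    idx <- nodes[memb[nodes] == mod]
    mu <- mean(k_within[idx]); s <- sd(k_within[idx])
    zi[idx] <- if (is.na(s) || s == 0) 0 else (k_within[idx] - mu) / s
  }
  pi <- vapply(nodes, function(v) {
    km <- table(memb[adj[[v]]])
    1 - sum((km / deg[v])^2)
  }, 0)
  role <- ifelse(zi >= zi_cut & pi >= pi_cut, "network hub",
          ifelse(zi >= zi_cut, "module hub",
          ifelse(pi >= pi_cut, "connector", "peripheral")))
  out <- data.frame(otu_id = nodes, module = unname(memb[nodes]),
                    degree = unname(deg[nodes]),
                    zi = unname(zi), pi = unname(pi), role = role,
                    row.names = NULL)
  structure(out, class = c("node_roles", "data.frame"), isolated = isolated,
            zi_cut = zi_cut, pi_cut = pi_cut)
}

#' Per-guild network statistics
#'
#' Mean and SD of betweenness centrality (unweighted skeleton), degree and
#' within-module edge fraction per functional guild. For a list of networks
#' (one per timepoint) the per-timepoint guild means are averaged.
#'
#' @param net a `comm_network` or a list of them.
#' @param guild_table data.frame with `otu_id` and `guild`.
#' @param modules optional [detect_modules()] result(s); computed when
#'   missing.
#' @return data.frame `guild`, `betweenness_mean`, `betweenness_sd`,
#'   `degree_mean`, `degree_sd`, `within_module_mean`, `within_module_sd`
#'   (per timepoint: also `timepoint`).
#' @export
guild_summary <- function(net, guild_table, modules = NULL) {
  if (inherits(net, "comm_network")) {
    modules <- modules %||% detect_modules(net)
    g <- as_igraph(net)
    btw <- igraph::betweenness(g, weights = NA)
    deg <- igraph::degree(g)
    memb <- modules$membership
    wmf <- vapply(igraph::V(g)$name, function(v) {
      nb <- igraph::neighbors(g, v)$name
      if (!length(nb)) return(NA_real_)
      mean(memb[nb] == memb[v])
    }, 0)
    per_node <- data.frame(otu_id = igraph::V(g)$name,
                           betweenness = unname(btw), degree = unname(deg),
                           within_module = unname(wmf))
    per_node <- merge(per_node, guild_table[, c("otu_id", "guild")],
                      by = "otu_id")
    missing_guilds <- setdiff(unique(guild_table$guild),
                              unique(per_node$guild))
    if (length(missing_guilds))
      warning(sprintf("guild(s) with no nodes in graph: %s",
                      paste(missing_guilds, collapse = ", ")))
    agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                         sd = sd(v, na.rm = TRUE))
    out <- do.call(rbind, lapply(split(per_node, per_node$guild), function(d)
      data.frame(guild = d$guild[1],
                 betweenness_mean = mean(d$betweenness),
                 betweenness_sd = sd(d$betweenness),
                 degree_mean = mean(d$degree), degree_sd = sd(d$degree),
                 within_module_mean = mean(d$within_module, na.rm = TRUE),
                 within_module_sd = sd(d$within_module, na.rm = TRUE))))
    rownames(out) <- NULL
    return(out)
  }
  # list of networks: average per-timepoint guild means
  tabs <- lapply(seq_along(net), function(i) {
    s <- guild_summary(net[[i]], guild_table,
                       if (is.null(modules)) NULL else modules[[i]])
    s$timepoint <- net[[i]]$timepoint %||% i
    s
  })
  all_t <- do.call(rbind, tabs)
  out <- do.call(rbind, lapply(split(all_t, all_t$guild), function(d)
    data.frame(guild = d$guild[1],
               betweenness_mean = mean(d$betweenness_mean),
               betweenness_sd = sd(d$betweenness_mean),
               degree_mean = mean(d$degree_mean),
               degree_sd = sd(d$degree_mean),
               within_module_mean = mean(d$within_module_mean),
               within_module_sd = sd(d$within_module_mean))))
  rownames(out) <- NULL
  out
}

# edge-weight vector over the union of node pairs of two networks
edge_weight_union <- function(a, b) {
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  all_pairs <- union(key(a$edges), key(b$edges))
  wa <- setNames(a$edges$weight, key(a$edges))[all_pairs]
  wb <- setNames(b$edges$weight, key(b$edges))[all_pairs]
  wa[is.na(wa)] <- 0; wb[is.na(wb)] <- 0
  cbind(wa, wb)
}

net_distance <- function(a, b) {
  w <- edge_weight_union(a, b)
  if (!nrow(w)) return(0)
  if (nrow(w) < 2 || sd(w[, 1]) == 0 || sd(w[, 2]) == 0) return(1)
  1 - cor(w[, 1], w[, 2], method = "spearman")
}

#' Bootstrap-permutation comparison of two timepoint networks
#'
#' The network distance is 1 minus the Spearman correlation of edge weights
#' over the union of edges of the two inferred networks. The null
#' distribution comes from permuting the sample-to-timepoint assignment and
#' re-inferring both networks; a bootstrap CI resamples samples within each
#' timepoint.
#'
#' @param table_t1,table_t2 [otu_table()]s (or count matrices) for the two
#'   timepoints, with a shared OTU set (intersected with a warning
#'   otherwise).
#' @param n_boot bootstrap resamples, default 100.
#' @param n_perm label permutations, default 100.
#' @param seed integer seed.
#' @param ... passed to [infer_network()].
#' @return list with `distance`, `p`, `boot_ci` (2.5/97.5 percentiles),
#'   `n_perm`, `n_boot`.
#' @export
compare_networks <- function(table_t1, table_t2, n_boot = 100, n_perm = 100,
                             seed = 1, ...) {
  c1 <- as_count_matrix(table_t1); c2 <- as_count_matrix(table_t2)
  shared <- intersect(colnames(c1), colnames(c2))
  if (length(shared) < ncol(c1) || length(shared) < ncol(c2)) {
    warning("OTU sets differ; intersecting")
  }
  c1 <- c1[, shared, drop = FALSE]; c2 <- c2[, shared, drop = FALSE]
  infer <- function(counts, s) infer_network(clr_transform(counts),
                                             seed = s, ...)
  d_obs <- net_distance(infer(c1, seed), infer(c2, seed))
  pooled <- rbind(c1, c2)
  lab <- rep(1:2, c(nrow(c1), nrow(c2)))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  b <- 0
  for (i in seq_len(n_perm)) {
    pl <- lab[sample.int(length(lab))]
    dp <- net_distance(infer(pooled[pl == 1, , drop = FALSE], seed + i),
                       infer(pooled[pl == 2, , drop = FALSE], seed + i))
    b <- b + (dp >= d_obs - 1e-12)
  }
  boot <- vapply(seq_len(n_boot), function(i) {
    i1 <- sample.int(nrow(c1), replace = TRUE)
    i2 <- sample.int(nrow(c2), replace = TRUE)
    net_distance(infer(c1[i1, , drop = FALSE], seed + n_perm + i),
                 infer(c2[i2, , drop = FALSE], seed + n_perm + i))
  }, 0)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  list(distance = d_obs, p = (b + 1) / (n_perm + 1),
       boot_ci = quantile(boot, c(0.025, 0.975), names = FALSE),
       n_perm = n_perm, n_boot = n_boot)
}

#' Proportion of edges within and between taxonomic Classes
#'
#' For every unordered Class pair (including within-Class) and edge sign,
#' the fraction of all edges; proportions sum to 1. Unlabelled nodes pool
#' into `"Unknown"`.
#'
#' @param net a `comm_network`.
#' @param taxonomy data.frame with `otu_id` and `class` columns.
#' @return data.frame `class_a`, `class_b`, `sign`, `n`, `proportion`.
#' @export
class_edge_proportions <- function(net, taxonomy) {
  stopifnot(inherits(net, "comm_network"))
  if (!nrow(net$edges))
    return(data.frame(class_a = character(), class_b = character(),
                      sign = character(), n = integer(),
                      proportion = numeric()))
  cls <- setNames(as.character(taxonomy$class), taxonomy$otu_id)
  ca <- cls[net$edges$from]; cb <- cls[net$edges$to]
  ca[is.na(ca)] <- "Unknown"; cb[is.na(cb)] <- "Unknown"
  a <- pmin(ca, cb); b <- pmax(ca, cb)
  key <- paste(a, b, net$edges$sign, sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r"))
  out <- data.frame(class_a = parts[, 1], class_b = parts[, 2],
                    sign = parts[, 3], n = as.integer(tab),
                    proportion = as.numeric(tab) / nrow(net$edges),
                    row.names = NULL)
  out[order(-out$proportion), ]
}

#' Write a network as edge-list TSV and/or GraphML
#'
#' @param net a `comm_network`.
#' @param tsv_path,graphml_path output paths (either may be `NULL`).
#' @export
write_network <- function(net, tsv_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(net, "comm_network"))
  if (!is.null(tsv_path))
    write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(c(tsv_path, graphml_path))
}
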