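test_that("CLR transform centres log counts per sample", {
  r <- unclass(clr_transform(rbind(c(1, 1, 8))))
  expect_equal(as.vector(r), log(c(2, 2, 9)) - mean(log(c(2, 2, 9))))
  expect_equal(sum(r), 0)
  expect_equal(as.vector(unclass(clr_transform(rbind(c(4, 4, 4))))),
               c(0, 0, 0))
  set.seed(1)
  m <- matrix(rpois(40, 6), 4, 10)
  expect_equal(rowSums(unclass(clr_transform(m))), rep(0, 4))
  # doubling counts moves CLR by at most a pseudocount-sized epsilon
  big <- matrix(rpois(40, 500), 4, 10)
  delta <- unclass(clr_transform(2 * big)) - unclass(clr_transform(big))
  expect_lt(max(abs(delta)), 0.01)
})

test_that("network inference keeps planted edges and drops null ones", {
  x <- block_clr(seed = 2)
  net <- infer_network(x, seed = 1)
  blocks <- rep(1:3, each = 5)
  same_block <- outer(blocks, blocks, "==")
  idx <- cbind(match(net$edges$from, colnames(x)),
               match(net$edges$to, colnames(x)))
  expect_gte(mean(same_block[idx]), 0.9)       # block precision
  expect_true(all(net$edges$stability > 0 & net$edges$stability <= 1))
  expect_true(all(net$edges$sign %in% c("+", "-")))
  # a perfectly correlated pair is always found, with positive sign
  y <- cbind(a = rnorm(40), b = 0)
  y[, "b"] <- y[, "a"]
  y <- cbind(y, c = rnorm(40))
  rownames(y) <- sprintf("s%d", 1:40)
  net2 <- infer_network(y, seed = 3)
  e <- net2$edges[net2$edges$from == "a" & net2$edges$to == "b", ]
  expect_equal(nrow(e), 1)
  expect_equal(e$stability, 1)
  expect_equal(e$sign, "+")
  expect_error(infer_network(x[1:5, ]), ">= 10 samples")
})

test_that("inference is deterministic and sample-order invariant", {
  x <- block_clr(seed = 4)
  n1 <- infer_network(x, seed = 9)
  n2 <- infer_network(x, seed = 9)
  expect_identical(n1$edges, n2$edges)
  # the full-data edge set does not depend on row order (same seed draws
  # different subsamples, so compare against a stability-1 criterion)
  n3 <- infer_network(x[sample(nrow(x)), ], seed = 9)
  strong1 <- n1$edges[n1$edges$stability == 1, c("from", "to")]
  strong3 <- n3$edges[n3$edges$stability == 1, c("from", "to")]
  expect_gt(nrow(merge(strong1, strong3)) / max(nrow(strong1), 1), 0.9)
})

test_that("module detection separates disconnected cliques", {
  edges <- rbind(expand.grid(from = c("a1", "a2", "a3"),
                             to = c("a1", "a2", "a3")),
                 expand.grid(from = c("b1", "b2", "b3"),
                             to = c("b1", "b2", "b3")))
  edges <- edges[as.character(edges$from) < as.character(edges$to), ]
  edges$weight <- 1; edges$sign <- "+"; edges$stability <- 1
  net <- structure(list(nodes = c(paste0("a", 1:3), paste0("b", 1:3), "iso"),
                        edges = edges, params = list(), timepoint = NA),
                   class = "comm_network")
  mods <- detect_modules(net)
  memb <- mods$membership
  expect_equal(length(unique(memb[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(memb[c("b1", "b2", "b3")])), 1)
  expect_false(memb["a1"] == memb["b1"])
  expect_false(memb["iso"] %in% memb[c("a1", "b1")])  # singleton module
})

test_that("Zi-Pi roles follow their defining formulas", {
  # star-within-module: all edges inside -> Pi = 0
  edges <- data.frame(from = c("h", "h", "h", "x", "c", "c"),
                      to = c("m1", "m2", "m3", "y", "m1", "x"),
                      weight = 1, sign = "+", stability = 1)
  net <- structure(list(nodes = c("h", "m1", "m2", "m3", "x", "y", "c",
                                  "lonely"),
                        edges = edges, params = list(), timepoint = NA),
                   class = "comm_network")
  memb <- c(h = 1, m1 = 1, m2 = 1, m3 = 1, x = 2, y = 2, c = 2,
            lonely = 3)
  roles <- zi_pi(net, memb)
  expect_equal(roles$pi[roles$otu_id == "h"], 0)
  # node c: one edge to module 1, one to module 2 -> Pi = 1 - 2*(1/2)^2
  expect_equal(roles$pi[roles$otu_id == "c"], 0.5)
  expect_true("lonely" %in% attr(roles, "isolated"))
  expect_true(all(roles$pi >= 0 & roles$pi < 1))

  # a 20-node module with one hub wired to everything: hub Zi >= 2.5
  hub_edges <- data.frame(from = "hub", to = sprintf("n%02d", 1:20),
                          weight = 1, sign = "+", stability = 1)
  spoke <- data.frame(from = "n01", to = "n02", weight = 1, sign = "+",
                      stability = 1)
  net2 <- structure(list(nodes = c("hub", sprintf("n%02d", 1:20)),
                         edges = rbind(hub_edges, spoke),
                         params = list(), timepoint = NA),
                    class = "comm_network")
  memb2 <- setNames(rep(1, 21), net2$nodes)
  roles2 <- zi_pi(net2, memb2)
  hub_row <- roles2[roles2$otu_id == "hub", ]
  expect_gte(hub_row$zi, 2.5)
  expect_equal(hub_row$role, "module hub")
})

test_that("guild summaries mirror whole-graph statistics and oracles", {
  # star graph: the centre guild holds all betweenness
  edges <- data.frame(from = "centre", to = paste0("leaf", 1:4),
                      weight = 1, sign = "+", stability = 1)
  net <- structure(list(nodes = c("centre", paste0("leaf", 1:4)),
                        edges = edges, params = list(), timepoint = NA),
                   class = "comm_network")
  guilds <- data.frame(otu_id = net$nodes,
                       guild = c("A", rep("B", 4)))
  gs <- guild_summary(net, guilds)
  expect_gt(gs$betweenness_mean[gs$guild == "A"],
            gs$betweenness_mean[gs$guild == "B"])
  # one guild for all nodes equals whole-graph means
  one <- guild_summary(net, transform(guilds, guild = "all"))
  expect_equal(one$degree_mean, mean(c(4, 1, 1, 1, 1)))
  # brute-force betweenness oracle on a 6-node toy
  toy_edges <- data.frame(from = c("a", "b", "c", "d", "c", "e"),
                          to = c("b", "c", "d", "e", "e", "f"),
                          weight = 1, sign = "+", stability = 1)
  net3 <- structure(list(nodes = letters[1:6], edges = toy_edges,
                         params = list(), timepoint = NA),
                    class = "comm_network")
  g3 <- mycodyn:::as_igraph(net3)
  btw <- igraph::betweenness(g3, weights = NA)
  oracle <- betweenness_oracle(toy_edges, letters[1:6])
  expect_equal(unname(btw[letters[1:6]]), unname(oracle[letters[1:6]]))
})

test_that("class edge proportions partition the edge set", {
  taxonomy <- data.frame(otu_id = c("a", "b", "c", "d"),
                         class = c("Doth", "Doth", "Trem", "Trem"))
  edges <- data.frame(from = c("a", "a", "c", "a", "b"),
                      to = c("b", "c", "d", "d", "c"),
                      weight = c(0.5, -0.4, 0.6, 0.7, -0.5),
                      sign = c("+", "-", "+", "+", "-"),
                      stability = 1)
  net <- structure(list(nodes = c("a", "b", "c", "d"), edges = edges,
                        params = list(), timepoint = NA),
                   class = "comm_network")
  pr <- class_edge_proportions(net, taxonomy)
  expect_equal(sum(pr$proportion), 1, tolerance = 1e-12)
  expect_equal(pr$proportion[pr$class_a == "Doth" & pr$class_b == "Doth"],
               0.2)
  within_trem <- pr$class_a == "Trem" & pr$class_b == "Trem"
  expect_equal(sum(pr$proportion[within_trem]), 0.2)
  between <- pr$class_a == "Doth" & pr$class_b == "Trem"
  expect_equal(sum(pr$proportion[between]), 0.6)
  # bipartite graph: everything between classes
  bip <- net; bip$edges <- edges[c(2, 4, 5), ]
  pr2 <- class_edge_proportions(bip, taxonomy)
  expect_true(all(pr2$class_a == "Doth" & pr2$class_b == "Trem"))
  # unknown labels pool
  pr3 <- class_edge_proportions(net, taxonomy[1:2, ])
  expect_true("Unknown" %in% c(pr3$class_a, pr3$class_b))
})

test_that("network comparison separates identical from inverted structures", {
  c1 <- round(exp(block_clr(n = 50, seed = 11) + 3))
  cmp_same <- compare_networks(c1, c1, n_boot = 10, n_perm = 20, seed = 2)
  expect_lt(cmp_same$distance, 0.05)
  expect_gt(cmp_same$p, 0.5)
  # distance is symmetric in its arguments
  c2 <- round(exp(block_clr(n = 50, seed = 12, invert = TRUE) + 3))
  d12 <- compare_networks(c1, c2, n_boot = 5, n_perm = 5, seed = 3)$distance
  d21 <- compare_networks(c2, c1, n_boot = 5, n_perm = 5, seed = 3)$distance
  expect_equal(d12, d21, tolerance = 1e-12)
})
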