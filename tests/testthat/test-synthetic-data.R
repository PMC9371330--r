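test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(fst = 0), "fst")
  expect_error(sim_config(fst = 1.2), "fst")
  expect_error(sim_config(n_subpops = 1), "n_subpops")
  expect_error(sim_config(admix_fraction = 1.5), "admix_fraction")
  expect_error(simulate_genotypes(sim_config()), "seed")
})

test_that("simulation is deterministic given config and seed", {
  a <- simulate_dataset(sim_config(seed = 11, n_genotypes = 12, n_snps = 40,
                                   n_otus = 20))
  b <- simulate_dataset(sim_config(seed = 11, n_genotypes = 12, n_snps = 40,
                                   n_otus = 20))
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$truth$driver_otu_ids, b$truth$driver_otu_ids)
  c <- simulate_dataset(sim_config(seed = 12, n_genotypes = 12, n_snps = 40,
                                   n_otus = 20))
  expect_false(identical(a$table$counts, c$table$counts))
})

test_that("near-zero Fst leaves subpopulations undifferentiated", {
  g <- simulate_genotypes(sim_config(seed = 3, n_genotypes = 300,
                                     n_snps = 150, fst = 0.001,
                                     n_subpops = 2, admix_fraction = 0))
  sp <- attr(g, "subpopulation")
  f1 <- colMeans(g$dosages[sp == "pop1", ]) / 2
  f2 <- colMeans(g$dosages[sp == "pop2", ]) / 2
  # residual difference is binomial sampling noise, ~ sqrt(p q / n)
  expect_lt(mean(abs(f1 - f2)), 0.05)
})

test_that("structured genotypes separate on PC1 (silhouette oracle)", {
  skip_if_not_installed("cluster")
  g <- simulate_genotypes(sim_config(seed = 5, n_genotypes = 300,
                                     n_snps = 1000, n_subpops = 2,
                                     admix_fraction = 0))
  pc1 <- svd_covariates(g, n_pc = 1)$covariates[, 1]
  sp <- as.integer(factor(attr(g, "subpopulation")))
  sil <- cluster::silhouette(sp, dist(pc1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("simulated MAF never drops below the 5 percent floor", {
  g <- simulate_genotypes(sim_config(seed = 9, n_genotypes = 40,
                                     n_snps = 120))
  maf <- pmin(g$freq, 1 - g$freq)
  expect_true(all(maf >= 0.05))
  expect_true(all(g$dosages %in% 0:2))
})

test_that("contaminants are control-exclusive with full control prevalence", {
  ds <- simulate_dataset(sim_config(seed = 2, n_genotypes = 15, n_snps = 50,
                                    n_otus = 30, contam_n = 5))
  tab <- ds$table
  expect_length(ds$truth$contaminant_otu_ids, 5)
  ctrl <- tab$sample_meta$is_control
  contam <- tab$counts[, ds$truth$contaminant_otu_ids, drop = FALSE]
  expect_true(all(contam[ctrl, ] > 0))       # prevalence 1 in controls
  expect_true(all(contam[!ctrl, ] == 0))     # absent from true samples
  expect_length(intersect(ds$truth$contaminant_otu_ids,
                          ds$truth$driver_otu_ids), 0)
  expect_length(intersect(ds$truth$target_otu_ids,
                          ds$truth$driver_otu_ids), 0)
})

test_that("planted drift separates first and last timepoint centroids", {
  ds <- simulate_dataset(sim_config(seed = 4))
  tab <- decontaminate(ds$table)
  meta <- tab$sample_meta
  rel <- unclass(relative_abundance(tab$counts))
  c1 <- colMeans(rel[meta$timepoint == 1, ])
  c5 <- colMeans(rel[meta$timepoint == 5, ])
  between <- bc_oracle(c1, c5)
  within <- mean(vapply(c(1, 5), function(tp) {
    idx <- which(meta$timepoint == tp)
    pairs <- utils::combn(sample(idx, 12), 2)
    mean(vapply(seq_len(ncol(pairs)), function(k)
      bc_oracle(rel[pairs[1, k], ], rel[pairs[2, k], ]), 0))
  }, 0))
  expect_gt(between, within)
})

test_that("null simulation shows no timepoint signal in PERMANOVA", {
  cfg <- sim_config(seed = 8, n_genotypes = 20, n_snps = 50, n_otus = 40,
                    time_shift = 0, subpop_effect = 0,
                    causal_snp_effect = 0, host_effect = 0,
                    infect_fraction = 0)
  ds <- simulate_dataset(cfg)
  tab <- decontaminate(ds$table)
  d <- bray_curtis(hellinger_transform(tab$counts))
  pa <- permanova(d ~ factor(timepoint), data = tab$sample_meta,
                  n_perm = 199, seed = 1)
  expect_gt(pa$p[1], 0.05)
})

test_that("raising subpop_effect raises the final-timepoint between-group share", {
  share <- vapply(c(0.5, 1.5, 3), function(eff) {
    ds <- simulate_dataset(sim_config(seed = 6, n_genotypes = 30,
                                      n_snps = 50, n_otus = 40,
                                      subpop_effect = eff,
                                      admix_fraction = 0))
    lat <- ds$truth$latent
    meta <- ds$table$sample_meta
    meta <- meta[match(rownames(lat), meta$sample_id), ]
    last <- meta$timepoint == max(meta$timepoint)
    x <- lat[last, ]; grp <- meta$subpopulation[last]
    centre <- colMeans(x)
    tot <- sum(sweep(x, 2, centre)^2)
    btw <- sum(vapply(split(seq_len(nrow(x)), grp), function(i)
      length(i) * sum((colMeans(x[i, , drop = FALSE]) - centre)^2), 0))
    btw / tot
  }, 0)
  expect_true(all(diff(share) > 0))
})

test_that("truth reports round-trip through JSON and reproduce the table", {
  ds <- simulate_dataset(sim_config(seed = 13, n_genotypes = 10,
                                    n_snps = 30, n_otus = 15))
  path <- withr::local_tempfile(fileext = ".json")
  truth_report(ds$truth, path)
  rec <- read_truth(path)
  expect_identical(rec$target_otu_ids, ds$truth$target_otu_ids)
  expect_identical(rec$contaminant_otu_ids, ds$truth$contaminant_otu_ids)
  expect_equal(rec$true_h2, ds$truth$true_h2)
  # the recorded seed reproduces the table bit for bit
  ds2 <- simulate_dataset(sim_config(seed = rec$seed, n_genotypes = 10,
                                     n_snps = 30, n_otus = 15))
  expect_identical(digest_counts(ds2$table$counts),
                   digest_counts(ds$table$counts))
  # empty id sets serialise as empty arrays, not null
  t0 <- ds$truth; t0$target_otu_ids <- character()
  truth_report(t0, path)
  raw <- jsonlite::read_json(path)
  expect_true(is.list(raw$target_otu_ids) && length(raw$target_otu_ids) == 0)
  expect_identical(read_truth(path)$target_otu_ids, character())
})
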