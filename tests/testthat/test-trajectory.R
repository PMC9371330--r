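make_ts <- function(coords, subjects, times, groups = NULL) {
  ids <- sprintf("s%02d", seq_len(nrow(coords)))
  rownames(coords) <- ids
  meta <- data.frame(sample_id = ids, genotype = subjects,
                     timepoint = times,
                     subpopulation = groups %||% "all")
  build_trajectories(coords, meta, "genotype", "timepoint",
                     if (is.null(groups)) NULL else "subpopulation")
}

test_that("trajectories assemble in time order with gap flags", {
  co <- rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1), c(1, 1), c(2, 1))
  ts <- make_ts(co, rep(c("p1", "p2"), 3), rep(1:3, each = 2))
  expect_length(ts$paths, 2)
  expect_equal(nrow(ts$paths$p1), 3)
  # subject order invariance
  ts2 <- make_ts(co[c(5, 3, 1, 6, 2, 4), ],
                 rep(c("p1", "p2"), 3)[c(5, 3, 1, 6, 2, 4)],
                 rep(1:3, each = 2)[c(5, 3, 1, 6, 2, 4)])
  expect_equal(ts2$paths$p1, ts$paths$p1, ignore_attr = TRUE)
  # a missing middle timepoint spans the gap and is flagged
  ts3 <- make_ts(co[c(1, 2, 3, 4, 6), ],
                 c("p1", "p2", "p1", "p1", "p2"), c(1, 1, 2, 3, 3))
  expect_true("p2" %in% ts3$gap_subjects)
  expect_equal(nrow(ts3$paths$p2), 2)
  # duplicate subject x timepoint is an error
  expect_error(make_ts(co, rep("p1", 6), c(1, 1, 2, 2, 3, 3)), "duplicate")
  # single-timepoint subjects are dropped with a warning
  expect_warning(make_ts(co, c("a", "b", "a", "a", "c", "a"),
                         c(1, 1, 2, 3, 1, 4)), "< 2 timepoints")
})

test_that("trajectory metrics match hand geometry", {
  line <- make_ts(cbind(0:3, 0), rep("p", 4), 1:4)
  m <- trajectory_metrics(line)
  expect_equal(m$path_length, 3)
  expect_equal(m$net_displacement, 3)
  expect_equal(m$directionality, 1)
  expect_equal(m$n_reversals, 0)

  back <- make_ts(rbind(c(0, 0), c(1, 0), c(0, 0)), rep("p", 3), 1:3)
  mb <- trajectory_metrics(back)
  expect_true(is.na(mb$directionality))
  expect_true(is.na(mb$direction_angle))
  expect_equal(mb$n_reversals, 1)

  elbow <- make_ts(rbind(c(0, 0), c(1, 0), c(1, 1)), rep("p", 3), 1:3)
  me <- trajectory_metrics(elbow)
  expect_equal(me$path_length, 2)
  expect_equal(me$net_displacement, sqrt(2))
  expect_equal(attr(me, "turning_angles")$p, 90)
  expect_equal(me$direction_angle, 45)
})

test_that("mean trajectories are per-timepoint centroids", {
  co <- rbind(c(0, 0), c(0, 2), c(1, 0), c(1, 2), c(4, 1), c(6, 1))
  ts <- make_ts(co, c("a", "b", "a", "b", "a", "b"),
                c(1, 1, 2, 2, 3, 3), groups = rep("g1", 6))
  mt <- mean_trajectory(ts)
  expect_equal(mt$paths$g1,
               rbind(`1` = c(0, 1), `2` = c(1, 1), `3` = c(5, 1)),
               ignore_attr = TRUE)
  # single-subject group: the mean is the subject
  solo <- make_ts(co[1:3, ], rep("s", 3), 1:3, groups = rep("gs", 3))
  expect_equal(mean_trajectory(solo)$paths$gs, solo$paths$s,
               ignore_attr = TRUE)
  # mirror-image subjects average onto the fixed axis
  mir <- make_ts(rbind(c(0, 1), c(0, -1), c(2, 2), c(2, -2)),
                 c("u", "v", "u", "v"), c(1, 1, 2, 2),
                 groups = rep("g", 4))
  expect_equal(mean_trajectory(mir)$paths$g[, 2], c(`1` = 0, `2` = 0))
})

test_that("trajectory distance is a symmetrised point-to-segment mean", {
  a <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_equal(trajectory_distance(a, a), 0)
  b <- a; b[, 2] <- 0.7      # parallel offset
  expect_equal(trajectory_distance(a, b), 0.7)
  l_path <- rbind(c(0, 0), c(1, 0), c(1, 1))
  straight <- rbind(c(0, 0.2), c(1.4, 0.2))
  expect_equal(trajectory_distance(l_path, straight),
               trajectory_distance_oracle(l_path, straight),
               tolerance = 1e-3)
  # symmetry and nonnegativity on random paths
  set.seed(12)
  for (i in 1:20) {
    p1 <- matrix(rnorm(8), 4, 2); p2 <- matrix(rnorm(8), 4, 2)
    expect_equal(trajectory_distance(p1, p2), trajectory_distance(p2, p1))
    expect_gte(trajectory_distance(p1, p2), 0)
  }
})

test_that("group tests separate planted length differences", {
  ts <- make_ts(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(2, 0), c(2, 1),
                      c(0, 0), c(0, 2), c(1, 0), c(1, 2), c(2, 0), c(2, 2)),
                rep(c("a1", "a2", "a3", "b1", "b2", "b3"), each = 2),
                rep(1:2, 6),
                groups = rep(c("A", "B"), each = 6))
  tm <- trajectory_metrics(ts)
  expect_equal(sort(unique(tm$path_length)), c(1, 2))
  res <- trajectory_group_tests(tm, ts = ts)
  expect_lt(res$length_anova$table$p, 0.05)
  expect_equal(nrow(res$length_anova$tukey), 1)  # g(g-1)/2 pairs
  # identical subjects in every group: F = 0, p = 1
  same <- make_ts(rbind(c(0, 0), c(1, 1))[rep(1:2, 4), ],
                  rep(c("a1", "a2", "b1", "b2"), each = 2), rep(1:2, 4),
                  groups = rep(c("A", "B"), each = 4))
  res0 <- trajectory_group_tests(trajectory_metrics(same), ts = same)
  expect_equal(res0$length_anova$table$F, 0)
  expect_equal(res0$length_anova$table$p, 1)
})

test_that("influence is zero for empty OTUs and order-invariant", {
  set.seed(31)
  ds <- simulate_dataset(sim_config(seed = 31, n_genotypes = 12,
                                    n_snps = 30, n_otus = 20,
                                    n_drivers = 3, contam_n = 1))
  tab <- decontaminate(ds$table)
  tab <- subset_table(tab, samples = !tab$sample_meta$infected)
  tab$counts[, 5] <- 0L
  inf <- otu_removal_influence(tab)
  expect_equal(inf$influence[inf$otu_id == colnames(tab$counts)[5]], 0)
  expect_true(all(inf$influence >= 0))
  perm <- sample(ncol(tab$counts))
  tab2 <- tab; tab2$counts <- tab$counts[, perm]
  tab2$otu_meta <- tab$otu_meta[perm, ]
  inf2 <- otu_removal_influence(tab2)
  expect_equal(inf2$influence[match(inf$otu_id, inf2$otu_id)],
               inf$influence, tolerance = 1e-8)
})

test_that("a duplicated OTU column shares out its influence", {
  set.seed(17)
  ds <- simulate_dataset(sim_config(seed = 17, n_genotypes = 12,
                                    n_snps = 30, n_otus = 20,
                                    n_drivers = 2, contam_n = 1))
  tab <- decontaminate(ds$table)
  tab <- subset_table(tab, samples = !tab$sample_meta$infected)
  drv <- ds$truth$driver_otu_ids[1]
  inf0 <- otu_removal_influence(tab)
  base_infl <- inf0$influence[inf0$otu_id == drv]
  # split the driver into two identical half-copies
  half <- tab$counts[, drv] %/% 2L
  counts2 <- cbind(tab$counts[, setdiff(colnames(tab$counts), drv)],
                   dup1 = half, dup2 = tab$counts[, drv] - half)
  tab2 <- otu_table(counts2, tab$sample_meta)
  inf2 <- otu_removal_influence(tab2)
  expect_lt(inf2$influence[inf2$otu_id == "dup1"], base_infl)
  expect_lt(inf2$influence[inf2$otu_id == "dup2"], base_infl)
})
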