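test_that("tables round-trip through TSV and BIOM with identical content", {
  counts <- matrix(c(0, 3, 5, 2, 0, 7, 1, 1, 0), 3, 3,
                   dimnames = list(paste0("s", 1:3), paste0("o", 1:3)))
  tab <- toy_table(counts)
  ctsv <- withr::local_tempfile(fileext = ".tsv")
  mtsv <- withr::local_tempfile(fileext = ".tsv")
  write_table(tab, ctsv, mtsv)
  back <- load_table(ctsv, mtsv)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$sample_meta$subpopulation, tab$sample_meta$subpopulation)
  biom <- withr::local_tempfile(fileext = ".biom")
  write_biom_json(tab, biom)
  back2 <- load_table(biom, mtsv)
  expect_equal(back2$counts, tab$counts)
})

test_that("malformed inputs raise structured errors naming the offender", {
  counts <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  meta <- data.frame(sample_id = "a")
  expect_error(otu_table(counts, meta), "b")
  counts_neg <- counts; counts_neg[1, 1] <- -1
  meta2 <- data.frame(sample_id = c("a", "b"))
  expect_error(otu_table(counts_neg, meta2), "nonnegative")
  dup <- counts; rownames(dup) <- c("a", "a")
  expect_error(otu_table(dup, meta2), "duplicate")
  expect_error(load_table("nope.tsv", "nope2.tsv"), "no such file")
})

test_that("contaminant flagging is directional and matches the Fisher oracle", {
  # 10 controls, 50 samples; o1 control-exclusive, o2 sample-only,
  # o3 present in 4/5 of a 5-control design checked against the oracle
  counts <- matrix(0L, 60, 3,
                   dimnames = list(sprintf("s%02d", 1:60), c("o1", "o2", "o3")))
  counts[1:10, "o1"] <- 5L
  counts[11:60, "o2"] <- 5L
  tab <- toy_table(counts, controls = c(rep(TRUE, 10), rep(FALSE, 50)))
  rep <- flag_contaminants(tab, threshold = 0.1)
  expect_true(rep$flagged[rep$otu_id == "o1"])
  expect_false(rep$flagged[rep$otu_id == "o2"])  # never flagged: directionality
  expect_equal(rep$score[rep$otu_id == "o2"], 1)

  counts2 <- matrix(0L, 25, 1, dimnames = list(sprintf("t%02d", 1:25), "o1"))
  counts2[1:4, 1] <- 2L          # 4 of 5 controls
  counts2[6:7, 1] <- 2L          # 2 of 20 samples
  tab2 <- toy_table(counts2, controls = c(rep(TRUE, 5), rep(FALSE, 20)))
  rep2 <- flag_contaminants(tab2, threshold = 0.1)
  expect_equal(rep2$score, fisher_oracle(4, 5, 2, 20), tolerance = 1e-12)
  expect_identical(rep2$flagged, rep2$score < 0.1)
  expect_error(flag_contaminants(toy_table(counts2)), "control")
})

test_that("contaminant flagging recovers the planted set exactly", {
  ds <- simulate_dataset(sim_config(seed = 21, n_genotypes = 20,
                                    n_snps = 40, n_otus = 40))
  rep <- flag_contaminants(ds$table, threshold = 0.1)
  expect_setequal(rep$otu_id[rep$flagged], ds$truth$contaminant_otu_ids)
})

test_that("CSS normalisation matches hand-computed quantile sums", {
  counts <- rbind(s1 = c(2, 4, 6, 0),
                  s2 = c(1, 2, 3, 0),
                  s3 = c(10, 20, 30, 40))
  colnames(counts) <- paste0("o", 1:4)
  am <- css_normalize(counts, quantile = 0.5)
  # factors: sums of counts <= median of nonzero counts, per sample
  expected <- c(s1 = 2 + 4, s2 = 1 + 2, s3 = 10 + 20)
  expect_equal(attr(am, "factors"), expected)
  expect_equal(unclass(am), counts / expected * median(expected),
               ignore_attr = TRUE)

  # identical samples: normalisation is the identity
  same <- matrix(rep(c(3, 1, 8), each = 4), 4, 3,
                 dimnames = list(paste0("s", 1:4), paste0("o", 1:3)))
  expect_equal(unclass(css_normalize(same)), same, ignore_attr = TRUE)

  # scale equivariance: a doubled sample normalises to the original
  two <- rbind(a = c(5, 3, 2), b = 2 * c(5, 3, 2))
  colnames(two) <- paste0("o", 1:3)
  am2 <- css_normalize(two)
  expect_equal(unname(unclass(am2)[1, ]), unname(unclass(am2)[2, ]))

  # invariance to sample order
  ord <- css_normalize(counts[c(3, 1, 2), ])
  expect_equal(unclass(ord)[rownames(counts), ], unclass(am),
               ignore_attr = TRUE)

  expect_warning(css_normalize(rbind(z = c(0, 0, 0), s1 = c(1, 2, 3))),
                 "all-zero")
})

test_that("Hellinger transform has unit row sums of squares", {
  expect_equal(as.vector(unclass(hellinger_transform(rbind(c(1, 4, 4))))),
               c(1 / 3, 2 / 3, 2 / 3))
  single <- unclass(hellinger_transform(rbind(c(0, 9, 0))))
  expect_equal(as.vector(single), c(0, 1, 0))
  set.seed(1)
  m <- matrix(rpois(60, 4), 6, 10)
  h <- unclass(hellinger_transform(m))
  expect_equal(rowSums(h^2), rep(1, 6))
  expect_error(hellinger_transform(rbind(c(-1, 2))), "nonnegative")
})

test_that("Bray-Curtis matches hand arithmetic and stays a bounded semimetric", {
  m <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 3),
             d = c(0, 0, 5))
  d <- bray_curtis(m)
  expect_equal(unclass(d)["a", "b"], 4 / 12)
  expect_equal(unclass(d)["a", "c"], 0)
  expect_equal(unclass(d)["d", "a"],
               bc_oracle(c(0, 0, 5), c(1, 2, 3)))
  disjoint <- bray_curtis(rbind(c(2, 0), c(0, 3)))
  expect_equal(unclass(disjoint)[1, 2], 1)
  set.seed(42)
  for (i in 1:200) {
    x <- matrix(rpois(20, 3), 5, 4)
    dd <- unclass(bray_curtis(x))
    expect_true(all(dd >= 0 & dd <= 1))
    expect_equal(dd, t(dd))
    expect_true(all(diag(dd) == 0))
  }
})
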