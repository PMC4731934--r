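cfg <- analysis_config()

test_that("normalized SD matches hand arithmetic", {
  expect_equal(normalized_sd(rep(2, 7)), 0)
  expect_equal(normalized_sd(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(normalized_sd(c(1, 1, 1, 1, 1, 1, 4)), 0.7937254,
               tolerance = 1e-6)
  expect_true(is.na(normalized_sd(c(0, 0))))
  expect_true(is.na(normalized_sd(5)))
})

test_that("cv is scale invariant (property)", {
  set.seed(51)
  for (r in 1:20) {
    v <- stats::rlnorm(7, 0, 1)
    lam <- stats::runif(1, 0.1, 50)
    expect_equal(normalized_sd(v), normalized_sd(lam * v),
                 tolerance = 1e-10)
  }
})

test_that("inter-individual CV uses donor means and the detection filter", {
  meta <- make_meta21()
  expr <- matrix(0, nrow = 3, ncol = 21,
                 dimnames = list(c("hot", "dead", "chrXf"), meta$sample_id))
  # donor means (1,1,1,1,1,1,4): cv ~ 0.79
  for (d in 1:7) {
    cols <- sprintf("D%d_T%d", d, 1:3)
    expr["hot", cols] <- if (d == 7) 4 else 1
    expr["chrXf", cols] <- 2
  }
  chroms <- c(hot = "chr5", dead = "chr5", chrXf = "chrX")
  vt <- inter_individual(expr, meta, chroms, cfg)
  expect_setequal(vt$feature_id, "hot")  # dead undetected, chrX excluded
  expect_equal(vt$cv, 0.7937254, tolerance = 1e-6)
})

test_that("intra-individual CV is per donor across replicates", {
  meta <- make_meta21()
  expr <- matrix(1, nrow = 1, ncol = 21,
                 dimnames = list("f", meta$sample_id))
  expr["f", sprintf("D1_T%d", 1:3)] <- c(1, 2, 3)
  iv <- intra_individual(expr, meta, cfg = cfg)
  expect_equal(iv[donor_id == "D1", cv], sd(1:3) / 2, tolerance = 1e-10)
  expect_equal(iv[donor_id == "D2", cv], 0)
})

test_that("vectorised ANOVA matches aov on toy and random tables", {
  meta <- make_meta21()
  # strong donor effect
  expr <- matrix(NA_real_, nrow = 2, ncol = 21,
                 dimnames = list(c("var", "flat"), meta$sample_id))
  set.seed(52)
  for (d in 1:7) {
    cols <- sprintf("D%d_T%d", d, 1:3)
    expr["var", cols] <- (if (d == 7) 10 else 1) + stats::rnorm(3, 0, 0.1)
    expr["flat", cols] <- 5 + stats::rnorm(3, 0, 1)
  }
  an <- anova_donor(expr, meta)
  expect_lt(an[feature_id == "var", p], 1e-6)
  # oracle: stats::aov per feature
  donor_f <- factor(meta$donor_id[match(colnames(expr), meta$sample_id)])
  for (f in rownames(expr)) {
    fit <- summary(stats::aov(expr[f, ] ~ donor_f))[[1]]
    expect_equal(an[feature_id == f, p], fit[["Pr(>F)"]][1],
                 tolerance = 1e-10)
    expect_equal(an[feature_id == f, f_stat], fit[["F value"]][1],
                 tolerance = 1e-10)
  }
  # random 2-5 donor x 3 replicate tables against aov
  for (r in 1:10) {
    nd <- sample(2:5, 1)
    g <- factor(rep(seq_len(nd), each = 3))
    y <- stats::rnorm(3 * nd, mean = as.integer(g) * stats::runif(1, 0, 2))
    m2 <- sample_metadata(data.table::data.table(
      sample_id = sprintf("s%d", seq_along(y)),
      donor_id = sprintf("D%d", as.integer(g)),
      time_point = rep(1:3, nd), protocol = "ribo_depleted",
      total_mapped_reads = 1e7))
    em <- matrix(y, nrow = 1, dimnames = list("f", m2$sample_id))
    an2 <- anova_donor(em, m2)
    fit2 <- summary(stats::aov(y ~ g))[[1]]
    expect_equal(an2$p, fit2[["Pr(>F)"]][1], tolerance = 1e-9)
  }
})

test_that("degenerate ANOVA rows follow the documented conventions", {
  meta <- make_meta21()
  expr <- matrix(1, nrow = 2, ncol = 21,
                 dimnames = list(c("const", "sep"), meta$sample_id))
  # perfectly separated donors with zero within-donor variance
  for (d in 1:7) expr["sep", sprintf("D%d_T%d", d, 1:3)] <- d
  an <- anova_donor(expr, meta)
  expect_equal(an[feature_id == "const", p], 1)
  expect_equal(an[feature_id == "const", flag], "zero_variance")
  expect_equal(an[feature_id == "sep", p], 0)
})

test_that("BH matches the step-up definition and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(53)
  for (r in 1:10) {
    p <- stats::runif(sample(2:50, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # NA propagates without counting towards m
  p <- c(0.01, NA, 0.04)
  q <- bh_fdr(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], stats::p.adjust(p[c(1, 3)], "BH"))
})

test_that("fold change floors the minimum at the detection cutoff", {
  dm <- matrix(c(0.5, 2.6,   1, 1,   0, 1), nrow = 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("D1", "D2")))
  fc <- fold_change(dm, cfg)
  expect_equal(fc[["a"]], 5.2)
  expect_equal(fc[["b"]], 1)
  expect_equal(fc[["c"]], 1 / 0.2)  # min 0 floored at 0.2
  expect_error(fold_change(dm[, 1, drop = FALSE], cfg), "2 donors")
})

test_that("significance call combines all four criteria", {
  expect_true(call_significant(1e-7, 1e-6, 5.2, TRUE, cfg))
  expect_false(call_significant(0.001, 0.01, 2.5, TRUE, cfg))  # fc fails
  expect_false(call_significant(0.02, 0.01, 10, TRUE, cfg))    # p fails
  expect_false(call_significant(1e-7, 0.06, 10, TRUE, cfg))    # q fails
  expect_false(call_significant(1e-7, 1e-6, 10, FALSE, cfg))   # undetected
})

test_that("reproducibility classifies detection patterns", {
  meta <- make_meta21()
  expr <- matrix(1, nrow = 3, ncol = 21,
                 dimnames = list(c("all", "mixed", "onedonor"),
                                 meta$sample_id))
  expr["mixed", "D1_T1"] <- 0.1                    # mixed within D1
  for (d in 2:7) expr["onedonor", sprintf("D%d_T%d", d, 1:3)] <- 0.15
  rp <- reproducibility(expr, meta, cfg)
  pf <- rp$per_feature
  expect_true(pf[feature_id == "all", intra_reproducible])
  expect_true(pf[feature_id == "all", inter_reproducible])
  expect_false(pf[feature_id == "mixed", intra_reproducible])
  expect_true(pf[feature_id == "onedonor", intra_reproducible])
  expect_false(pf[feature_id == "onedonor", inter_reproducible])
})

test_that("equalized MWU: identity, null case and bit-stability", {
  a <- 1:100; b <- 51:150
  r1 <- equalized_mwu(a, b, cfg, seed = 99)
  r2 <- equalized_mwu(a, b, cfg, seed = 99)
  expect_identical(r1$p_values, r2$p_values)   # seed-pinned, bit-stable
  expect_equal(r1$mean_p, mean(r1$p_values))
  # equal sizes: subsampling is the identity, all repeats identical
  r3 <- equalized_mwu(1:50, 101:150, cfg, seed = 1)
  expect_equal(length(unique(r3$p_values)), 1L)
  # same values -> null; p well above any significance level
  set.seed(54)
  x <- stats::rlnorm(200)
  r4 <- equalized_mwu(x, x, cfg, seed = 2)
  expect_gt(r4$mean_p, 0.9)
  expect_error(equalized_mwu(1, 1:5, cfg), "two values")
  # oracle: equal-size case equals a direct wilcox.test
  direct <- suppressWarnings(
    stats::wilcox.test(1:50, 101:150, exact = FALSE)$p.value)
  expect_equal(r3$mean_p, direct, tolerance = 1e-12)
})

test_that("robust and variable lists follow the detection thresholds", {
  meta <- make_meta21()
  expr <- matrix(1.2, nrow = 4, ncol = 21,
                 dimnames = list(c("both", "neither", "robust_only", "low"),
                                 meta$sample_id))
  expr["neither", "D3_T2"] <- 0.19
  expr["robust_only", "D5_T1"] <- 0.8
  expr["low", ] <- 0.05
  bl <- build_lists(expr, NULL, meta, cfg = cfg)
  expect_true("both" %in% bl$robust &&
                "both" %in% bl$well_expressed_robust)
  expect_false("neither" %in% bl$robust)
  expect_false("neither" %in% bl$well_expressed_robust)
  expect_true("robust_only" %in% bl$robust)
  expect_false("robust_only" %in% bl$well_expressed_robust)
  expect_true(all(bl$well_expressed_robust %in% bl$robust))
})

test_that("synthetic CV recovery matches the lognormal identity", {
  set.seed(55)
  ds <- generate_dataset(default_class_params("lncRNA", n_loci = 150L),
                         default_class_params("mRNA", n_loci = 45L),
                         seed = 55)
  tt <- ds$truth_table
  for (cl in c("lncRNA", "mRNA")) {
    ids <- tt[class == cl, transcript_id]
    vt <- inter_individual(ds$expr$ribo[ids, ], ds$meta)
    target <- if (cl == "lncRNA") 0.29 else 0.15
    expect_lt(abs(stats::median(vt$cv) - target) / target, 0.15)
  }
})
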