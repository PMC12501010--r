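# Normalization, tau, and the rank-based tests.

test_that("median-of-ratios size factors match hand computations", {
  # two identical samples -> unit factors
  m <- matrix(c(5, 9, 3, 5, 9, 3), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # doubled library: geometric-mean reference splits the factor of two
  m2 <- rbind(g1 = c(10, 20), g2 = c(100, 200), g3 = c(4, 8))
  colnames(m2) <- c("s1", "s2")
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)
  # single sample -> factor 1
  m1 <- matrix(c(3, 7), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(size_factors(m1)), 1)
  # genes with zeros are excluded from the median
  m3 <- rbind(g1 = c(10, 20), g2 = c(0, 500), g3 = c(100, 200))
  colnames(m3) <- c("s1", "s2")
  expect_equal(unname(size_factors(m3)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)
  expect_error(size_factors(rbind(c(0, 5), c(5, 0))), "positive")
})

test_that("size factors agree with DESeq2's median-of-ratios estimates", {
  skip_if_not_installed("DESeq2")
  set.seed(42)
  m <- matrix(rnbinom(200 * 6, mu = 50, size = 5), nrow = 200,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  dds <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(size_factors(m)), unname(dds), tolerance = 1e-8)
})

test_that("scaling one sample scales its factor and fixes normalization", {
  set.seed(7)
  m <- matrix(rpois(50 * 4, 60) + 1, nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  f0 <- size_factors(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 5
  f1 <- size_factors(m2)
  # factors are defined up to the geometric-mean reference shift
  expect_equal(unname(f1[2] / f0[2] / (f1[1] / f0[1])), 5,
               tolerance = 1e-10)
  n1 <- normalize_counts(m2, f1)
  n0 <- normalize_counts(m, f0)
  expect_equal(n1 / n0, matrix(n1[1, 1] / n0[1, 1], 50, 4,
                               dimnames = dimnames(n1)),
               tolerance = 1e-10)
})

test_that("normalize_counts divides elementwise and validates factors", {
  m <- matrix(10, 1, 2, dimnames = list("g", c("a", "b")))
  expect_equal(unname(normalize_counts(m, c(2, 1))[1, ]), c(5, 10))
  expect_equal(normalize_counts(m, c(1, 1)), m)
  expect_error(normalize_counts(m, c(1, 0)), "positive")
  expect_error(normalize_counts(m, 1), "one size factor")
})

test_that("tau matches its definition and analytic limits", {
  expect_equal(tau_index(c(10, 0, 0, 0)), 1)
  expect_equal(tau_index(c(5, 5, 5, 5)), 0)
  expect_equal(tau_index(c(8, 4, 2, 2)), (0 + 0.5 + 0.75 + 0.75) / 3)
  expect_true(is.na(tau_index(c(0, 0, 0))))
  expect_error(tau_index(c(-1, 2)), "non-negative")
  expect_error(tau_index(5), "at least 2")
})

test_that("tau is scale-invariant and bounded on random profiles", {
  set.seed(1)
  for (i in 1:50) {
    p <- rexp(sample(2:8, 1))
    t1 <- tau_index(p)
    expect_true(t1 >= 0 && t1 <= 1)
    expect_equal(tau_index(p * runif(1, 0.1, 100)), t1, tolerance = 1e-12)
  }
})

test_that("planted tissue-specific genes are recovered via condition means", {
  sim <- simulate_pangenome(n_cultivars = 3, n_orthogroups = 60,
                            class_props = c(0.2, 0.7, 0.1), seed = 31)
  sim <- simulate_expression(sim, dispersion = 0.02,
                             prop_tissue_specific = 0.2, seed = 32)
  eb <- normalize_bundle(sim$counts)
  ts <- tissue_specificity(condition_means(eb))
  truth <- sim$truth$tissue_specific
  expect_gt(nrow(truth), 10)
  got <- ts[match(truth$gene, ts$gene), ]
  expect_gte(mean(got$specific & got$top_tissue == truth$tissue), 0.95)
  # a uniform gene never enters a tissue set
  expect_false(any(ts$specific[!is.na(ts$tau) & ts$tau < 0.8]))
})

test_that("Kruskal-Wallis handles identical groups, ties, and transforms", {
  kt <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kt$H, 0)
  expect_equal(kt$p_value, 1)
  # tie-corrected H against the hand formula on pooled midranks
  g <- list(c(1, 1, 1), c(1, 1, 2))
  r <- rank(unlist(g))
  n <- 6
  ties <- table(unlist(g))
  h_raw <- 12 / (n * (n + 1)) *
    sum(c(3, 3) * (tapply(r, rep(1:2, each = 3), mean) - (n + 1) / 2)^2)
  h_corr <- h_raw / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kruskal_wallis(g)$H, h_corr, tolerance = 1e-12)
  # H is invariant to monotone transforms of the pooled values
  g2 <- list(rnorm(5), rnorm(6) + 1, rnorm(4))
  expect_equal(kruskal_wallis(g2)$H,
               kruskal_wallis(lapply(g2, function(x) exp(x)))$H,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
})

test_that("Dunn post-hoc z and Bonferroni behave as specified", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  d <- dunn_posthoc(g)
  expect_true(all(d$p_adj == 1))
  # a shifted group separates from the identical pair
  g2 <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 100)
  d2 <- dunn_posthoc(g2)
  p_ident <- d2$p_adj[d2$group1 == "a" & d2$group2 == "b"]
  expect_true(all(d2$p_adj[d2$group2 == "c"] < p_ident))
  # Bonferroni never drops below the raw p
  expect_true(all(d2$p_adj >= d2$p_value))
  expect_error(dunn_posthoc(list(a = 1:3)), "two groups")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
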