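# Eigengenes, module distances, divergence threshold, triad module
# classes, metamodules.

test_that("eigengene of identical profiles explains all variance", {
  set.seed(18)
  prof <- rnorm(10)
  expr <- matrix(rep(prof, each = 5), nrow = 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  me <- module_eigengene(expr)
  expect_equal(me$var_explained, 1, tolerance = 1e-12)
  z <- scale(prof)[, 1]
  expect_equal(abs(cor(me$eigengene, prof)), 1, tolerance = 1e-12)
  # orientation: positive mean correlation with members
  expect_gt(cor(me$eigengene, prof), 0)
})

test_that("two anti-correlated genes still give a rank-1 module", {
  set.seed(19)
  prof <- rnorm(12)
  expr <- rbind(g1 = prof, g2 = -2 * prof + 3)
  colnames(expr) <- paste0("s", 1:12)
  me <- module_eigengene(expr)
  expect_equal(me$var_explained, 1, tolerance = 1e-12)
  # a two-factor module explains less than everything
  f2 <- rbind(g1 = rnorm(12), g2 = rnorm(12), g3 = rnorm(12))
  colnames(f2) <- paste0("s", 1:12)
  expect_lt(module_eigengene(f2)$var_explained, 1)
  # constant genes are dropped with a warning; all-constant errors
  expect_warning(module_eigengene(rbind(expr, g3 = rep(1, 12))), "constant")
  expect_error(suppressWarnings(
    module_eigengene(rbind(a = rep(1, 5), b = rep(2, 5)))), "non-constant")
})

test_that("module distance is 1 - Pearson r with the right limits", {
  e1 <- rnorm(10)
  egs <- rbind(m1 = e1, m2 = e1, m3 = -e1)
  d <- module_distance_matrix(egs)
  expect_equal(d["m1", "m2"], 0, tolerance = 1e-12)
  expect_equal(d["m1", "m3"], 2, tolerance = 1e-12)
  expect_equal(diag(d), c(m1 = 0, m2 = 0, m3 = 0))
  expect_equal(d, t(d))
  expect_error(module_distance_matrix(rbind(a = rep(1, 5), b = rnorm(5))),
               "constant")
})

test_that("divergence threshold is 85% of the median of row maxima", {
  d <- matrix(0, 3, 3, dimnames = list(paste0("m", 1:3), paste0("m", 1:3)))
  d["m1", "m2"] <- d["m2", "m1"] <- 0.2
  d["m1", "m3"] <- d["m3", "m1"] <- 0.9
  d["m2", "m3"] <- d["m3", "m2"] <- 0.8
  dm <- divergence_threshold(d, fraction = 0.85)
  expect_equal(unname(dm$per_module_max), c(0.9, 0.8, 0.9))
  expect_equal(dm$median_max, 0.9)
  expect_equal(dm$threshold, 0.765)
  # constant matrix: threshold is 0.85 c, also with only 2 modules
  d2 <- matrix(c(0, .4, .4, 0), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(divergence_threshold(d2)$threshold, 0.85 * 0.4)
})

test_that("triad module classes follow the threshold rule", {
  d <- matrix(0, 3, 3, dimnames = list(paste0("m", 1:3), paste0("m", 1:3)))
  d["m1", "m2"] <- d["m2", "m1"] <- 0.2
  d["m1", "m3"] <- d["m3", "m1"] <- 0.9
  d["m2", "m3"] <- d["m3", "m2"] <- 0.8
  dm <- divergence_threshold(d, fraction = 0.85)  # T = 0.765
  triads <- tibble::tibble(
    og = paste0("og", 1:4),
    module_A = c("m1", "m1", "m1", NA),
    module_B = c("m1", "m2", "m3", "m2"),
    module_D = c("m1", "m1", "m1", "m1"))
  got <- classify_triad_modules(triads, dm)
  expect_equal(got$module_class,
               c("same", "similar", "divergent", "incomplete"))
  # the partition covers every triad exactly once
  expect_equal(sum(table(got$module_class)), 4)
})

test_that("Dunn index and silhouette match brute force on small instances", {
  set.seed(20)
  for (i in 1:15) {
    n <- sample(5:10, 1)
    x <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(x))
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(1, 2)
    expect_equal(dunn_index(d, labels), oracle_dunn(d, labels),
                 tolerance = 1e-12)
    expect_equal(mean_silhouette(d, labels), oracle_silhouette(d, labels),
                 tolerance = 1e-12)
  }
})

test_that("silhouette agrees with cluster::silhouette", {
  skip_if_not_installed("cluster")
  set.seed(21)
  x <- matrix(rnorm(20 * 2), 20)
  d <- as.matrix(dist(x))
  labels <- kmeans(x, 3)$cluster
  mine <- mean_silhouette(d, labels)
  ref <- mean(cluster::silhouette(labels, dist(x))[, "sil_width"])
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("two well-separated factor groups give k = 2 exactly", {
  ms <- simulate_module_data(n_cultivars = 2, modules_per_cultivar = 4,
                             n_factors = 2, genes_per_module = 20,
                             noise_sd = 0.2, seed = 23)
  pooled <- do.call(rbind, lapply(ms$networks, function(nt) {
    module_eigengenes(nt$expr, nt$assignments)$eigengenes
  }))
  mm <- find_metamodules(pooled, k_range = 2:5)
  expect_equal(mm$k, 2)
  lab <- tidy(mm)
  truth <- ms$truth
  m <- merge(lab, truth, by.x = "eigengene", by.y = "module")
  tab <- table(m$metamodule, m$factor)
  expect_equal(sum(apply(tab, 1, max)), sum(tab))  # pure clusters
})

test_that("near-identical eigengenes degenerate to the minimum k", {
  set.seed(24)
  base <- rnorm(12)
  egs <- t(sapply(1:6, function(i) base + rnorm(12, 0, 1e-6)))
  rownames(egs) <- paste0("m", 1:6)
  expect_warning(mm <- find_metamodules(egs, k_range = 2:10), "clipped")
  expect_equal(mm$k, 2)
})

test_that("eigengene is stable under gene reordering and scaling", {
  set.seed(25)
  expr <- matrix(rnorm(6 * 10), 6,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  expr <- expr + rep(rnorm(10, 0, 2), each = 6)  # shared signal
  e1 <- module_eigengene(expr)$eigengene
  perm <- sample(6)
  e2 <- module_eigengene(expr[perm, ] * 7 + 3)$eigengene
  expect_equal(abs(cor(e1, e2)), 1, tolerance = 1e-10)
})
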