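# N-let construction, ternary centroid classification, stability.

test_that("build_nlets keeps only strict 1:1:1 orthogroups", {
  genes <- tibble::tibble(
    gene = c("c1_A_g1", "c1_B_g1", "c1_D_g1",
             "c2_A_g1", "c2_B_g1", "c2_D_g1",
             "c1_A_g2", "c1_A_g2b", "c1_B_g2", "c1_D_g2",
             "c2_A_g2", "c2_B_g2", "c2_D_g2"),
    cultivar = rep(c("c1", "c2", "c1", "c2"), c(3, 3, 4, 3)),
    chromosome = paste0("chr1", c("A", "B", "D", "A", "B", "D",
                                  "A", "A", "B", "D", "A", "B", "D")),
    subgenome = c("A", "B", "D", "A", "B", "D",
                  "A", "A", "B", "D", "A", "B", "D"))
  og <- tibble::tibble(og = rep(c("OG1", "OG2"), c(6, 7)),
                       cultivar = genes$cultivar, gene = genes$gene)
  nl <- build_nlets(og, genes)
  # OG1 is a clean triad in both cultivars; OG2 has two A genes in c1
  expect_equal(unique(nl$og), "OG1")
  expect_equal(nrow(nl), 2)
  expect_true(all(nl$microsyntenic))
  expect_equal(nl$gene_A[nl$cultivar == "c2"], "c2_A_g1")
})

test_that("planted n-lets are recovered and violations rejected", {
  sim <- simulate_pangenome(n_cultivars = 5, n_orthogroups = 120,
                            class_props = c(0.7, 0.25, 0.05), seed = 55)
  n_core <- sum(sim$truth$og_class$class == "core")
  # planted tandem copies break 1:1:1 for their families
  sim2 <- plant_tandem_arrays(sim, n_families = 10,
                              cultivars_per_family = 2, seed = 56)
  nl <- build_nlets(sim2$orthogroups, sim2$genes)
  broken <- unique(sim2$truth$tandems$family)
  expect_setequal(unique(nl$og),
                  setdiff(sim$truth$og_class$og[
                    sim$truth$og_class$class == "core"], broken))
  expect_equal(nrow(nl) %% 5, 0)
  expect_lt(dplyr::n_distinct(nl$og), n_core)
})

test_that("relative expression normalizes to the ternary simplex", {
  r <- relative_expression(10, 30, 60)
  expect_equal(c(r$rA, r$rB, r$rD, r$T), c(0.1, 0.3, 0.6, 100))
  r0 <- relative_expression(0, 0, 0)
  expect_equal(r0$T, 0)
  expect_true(all(is.na(c(r0$rA, r0$rB, r0$rD))))
  r3 <- relative_expression(5, 5, 5)
  expect_equal(r3$rA, 1 / 3)
  expect_error(relative_expression(-1, 2, 3), "non-negative")
})

test_that("centroid classification matches worked distances", {
  cls <- classify_bias(relative_expression(
    c(100 / 3, 80, 60), c(100 / 3, 10, 20), c(100 / 3, 10, 20)))
  expect_equal(as.character(cls$category),
               c("Balanced", "A-dominant", "Balanced"))
  expect_equal(cls$centroid_dist[1], 0)
  expect_equal(cls$centroid_dist[2], sqrt(0.04 + 0.01 + 0.01),
               tolerance = 1e-12)
  # (0.6,0.2,0.2): Balanced at 0.326 beats B-/D-suppressed at 0.374
  expect_equal(cls$centroid_dist[3], sqrt(sum((c(.6, .2, .2) - 1 / 3)^2)),
               tolerance = 1e-12)
  expect_equal(cls$`dist_B-suppressed`[3], sqrt(0.01 + 0.04 + 0.09),
               tolerance = 1e-12)
  # below the expression cutoff -> NotExpressed
  ne <- classify_bias(relative_expression(0.1, 0.1, 0.1),
                      not_expressed_cutoff = 0.5)
  expect_equal(as.character(ne$category), "NotExpressed")
})

test_that("classification equals the brute-force centroid oracle", {
  set.seed(9)
  pts <- matrix(rexp(3 * 500), ncol = 3)
  pts <- pts / rowSums(pts)
  rel <- relative_expression(pts[, 1], pts[, 2], pts[, 3])
  rel$T <- rep(10, nrow(pts))          # keep everything expressed
  got <- as.character(classify_bias(rel)$category)
  want <- apply(pts, 1, oracle_centroid_class)
  expect_identical(got, want)
})

test_that("classification is equivariant under subgenome permutation", {
  set.seed(10)
  pts <- matrix(rexp(3 * 200), ncol = 3)
  pts <- pts / rowSums(pts)
  rel <- relative_expression(pts[, 1], pts[, 2], pts[, 3]); rel$T <- 10
  base <- as.character(classify_bias(rel)$category)
  # swap A and D
  rel2 <- relative_expression(pts[, 3], pts[, 2], pts[, 1]); rel2$T <- 10
  swapped <- as.character(classify_bias(rel2)$category)
  map <- c("Balanced" = "Balanced",
           "A-dominant" = "D-dominant", "D-dominant" = "A-dominant",
           "B-dominant" = "B-dominant",
           "A-suppressed" = "D-suppressed",
           "D-suppressed" = "A-suppressed",
           "B-suppressed" = "B-suppressed")
  expect_identical(swapped, unname(map[base]))
})

test_that("stability partition is exhaustive, exclusive and correct", {
  mk <- function(og, cats) tibble::tibble(og = og, cultivar = paste0("c", seq_along(cats)),
                                          category = cats)
  bias <- dplyr::bind_rows(
    mk("og1", rep("Balanced", 9)),
    mk("og2", c(rep("Balanced", 8), "B-suppressed")),
    mk("og3", rep("A-dominant", 9)),
    mk("og4", rep("D-suppressed", 9)),
    mk("og5", rep("NotExpressed", 9)),
    mk("og6", c(rep("NotExpressed", 8), "Balanced")))
  sp <- stability_partition(bias)
  got <- setNames(as.character(sp$per_nlet$label), sp$per_nlet$og)
  expect_equal(unname(got[c("og1", "og2", "og3", "og4", "og5", "og6")]),
               c("stable-balanced", "dynamic", "stable-dominant",
                 "stable-suppressed", "not-expressed", "dynamic"))
  expect_equal(sum(sp$counts$n), 6)
  expect_equal(sp$dynamic_composition$n_nlets[
    sp$dynamic_composition$category == "Balanced"], 2)
  # a missing cultivar is an error naming the n-let
  expect_error(stability_partition(bias[-1, ]), "og1")
})

test_that("dynamic n-lets sit further from their centroid than stable ones", {
  sim <- simulate_pangenome(n_cultivars = 4, n_orthogroups = 150,
                            class_props = c(1, 0, 0), seed = 77)
  sim <- simulate_expression(sim, dispersion = 0.2, seed = 78)
  eb <- normalize_bundle(sim$counts)
  nb <- nlet_bias(build_nlets(sim$orthogroups, sim$genes),
                  condition_means(eb))
  truth <- sim$truth$nlet_stability
  dyn <- nb$centroid_dist[nb$og %in% truth$og[truth$label == "dynamic"]]
  stab <- nb$centroid_dist[nb$og %in%
                             truth$og[truth$label == "stable-balanced"]]
  expect_gt(mean(dyn, na.rm = TRUE), mean(stab, na.rm = TRUE))
})
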