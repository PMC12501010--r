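# Tandem array detection, balance, chaining, conservation.

mk_genes <- function(fams, cultivar = "c1", chromosome = "chr1A") {
  tibble::tibble(gene = paste0(cultivar, "_g", seq_along(fams)),
                 cultivar = cultivar, chromosome = chromosome,
                 start = seq_along(fams) * 1000, family = fams)
}

test_that("detection finds maximal same-family runs under the gap rule", {
  td <- detect_tandems(mk_genes(c("F1", "F1")))
  expect_equal(nrow(td), 1)
  expect_equal(td$kind, "TrueTandem")
  expect_equal(td$members[[1]], c("c1_g1", "c1_g2"))
  # one intervening gene is tolerated at max_gap = 1 but not 0
  g <- mk_genes(c("F1", "F2", "F1"))
  expect_equal(nrow(detect_tandems(g, max_gap = 1)), 1)
  expect_equal(nrow(detect_tandems(g, max_gap = 0)), 0)
  # longer runs become TandemArrays; genes without family are skipped
  g3 <- mk_genes(c("F1", "F1", NA, "F1", "F2"))
  td3 <- detect_tandems(g3, max_gap = 1)
  expect_equal(td3$kind[td3$family == "F1"], "TandemArray")
  expect_equal(td3$n_members[td3$family == "F1"], 3)
})

test_that("arrays are maximal and partition genes by kind", {
  set.seed(3)
  fams <- sample(sprintf("F%02d", 1:12), 60, replace = TRUE)
  td <- detect_tandems(mk_genes(fams), max_gap = 1)
  # no gene in two arrays
  all_members <- unlist(td$members)
  expect_equal(anyDuplicated(all_members), 0)
  expect_equal(sum(td$kind == "TrueTandem") + sum(td$kind == "TandemArray"),
               nrow(td))
  # maximality: the gene right before/after each run is a different family
  fam_of <- setNames(fams, paste0("c1_g", seq_along(fams)))
  for (i in seq_len(nrow(td))) {
    m <- td$members[[i]]
    idx <- as.integer(sub("c1_g", "", m))
    before <- idx[1] - 1; after <- idx[length(idx)] + 1
    if (before >= 1)
      expect_false(identical(fam_of[[before]], td$family[i]))
    if (after <= length(fams))
      expect_false(identical(fam_of[[after]], td$family[i]))
  }
})

test_that("planted tandem arrays are recovered exactly", {
  sim <- simulate_pangenome(n_cultivars = 4, n_orthogroups = 100,
                            class_props = c(0.8, 0.2, 0), seed = 41)
  sim <- plant_tandem_arrays(sim, n_families = 12,
                             cultivars_per_family = 2, seed = 42)
  fam <- dplyr::left_join(sim$genes,
                          dplyr::select(sim$orthogroups, gene, family = og),
                          by = "gene")
  td <- detect_tandems(fam, max_gap = 1)
  truth <- sim$truth$tandems
  expect_equal(nrow(td), nrow(truth))
  key <- function(df, m) paste(df$family, df$cultivar,
                               vapply(m, paste, "", collapse = ","))
  expect_setequal(key(td, td$members), key(truth, truth$members))
})

test_that("balance uses the 0.8 maximal-share rule and sole expression", {
  arrays <- tibble::tibble(
    array_id = c("t1", "t2", "t3", "t4"), cultivar = "c1",
    chromosome = "chr1A", family = paste0("F", 1:4),
    members = list(c("a1", "a2"), c("b1", "b2"), c("d1", "d2"),
                   c("e1", "e2")),
    n_members = 2, kind = "TrueTandem")
  cm <- tibble::tibble(
    gene = c("a1", "a2", "b1", "b2", "d1", "d2", "e1", "e2"),
    cultivar = "c1", tissue = "root",
    mean_norm = c(90, 10, 60, 40, 50, 0, 0, 0))
  ab <- array_balance(arrays, cm, cutoff = 0.8)
  expect_equal(ab$balance, c("unbalanced", "balanced", "unbalanced",
                             "not-expressed"))
  expect_equal(ab$max_share, c(0.9, 0.6, 1, NA))
})

test_that("chains need two cultivars and inherit a conservation label", {
  arrays <- tibble::tibble(
    array_id = paste0("t", 1:4),
    cultivar = c("c1", "c2", "c3", "c1"),
    chromosome = "chr1A",
    family = c("F1", "F1", "F1", "F2"),
    members = list("x", "x", "x", "x"),
    n_members = 2, kind = "TrueTandem",
    balance = c("balanced", "balanced", "unbalanced", "balanced"))
  ch <- chain_arrays(arrays)
  expect_equal(nrow(ch), 1)          # F2 is single-cultivar: no chain
  expect_equal(ch$n_cultivars, 3)
  cc <- chain_conservation(ch, arrays)
  expect_equal(cc$conservation, "variable")
  arrays$balance[3] <- "balanced"
  expect_equal(chain_conservation(ch, arrays)$conservation, "constant")
})

test_that("planted chains and conservation labels are recovered", {
  sim <- simulate_pangenome(n_cultivars = 5, n_orthogroups = 150,
                            class_props = c(0.9, 0.1, 0), seed = 43)
  sim <- plant_tandem_arrays(sim, n_families = 15,
                             cultivars_per_family = 3,
                             constant_fraction = 0.5, seed = 44)
  sim <- simulate_expression(sim, dispersion = 0.02, seed = 45)
  sim <- apply_tandem_balance(sim, dispersion = 0.02, seed = 46)
  eb <- normalize_bundle(sim$counts)
  cm <- condition_means(eb)
  fam <- dplyr::left_join(sim$genes,
                          dplyr::select(sim$orthogroups, gene, family = og),
                          by = "gene")
  arrays <- array_balance(detect_tandems(fam, max_gap = 1), cm)
  chains <- chain_conservation(chain_arrays(arrays), arrays)
  expect_equal(nrow(chains), 15)
  truth <- sim$truth$tandem_chains
  m <- merge(chains, truth, by = "family")
  expect_gte(mean(m$conservation.x == m$conservation.y), 14 / 15)
  # conservation partitions the chains
  expect_equal(sum(chains$conservation == "constant") +
                 sum(chains$conservation == "variable"), nrow(chains))
})
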