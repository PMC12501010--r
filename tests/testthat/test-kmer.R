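# Canonical k-mer index, coverage scores, windowed tracks, candidates.

test_that("index canonicalizes strands and excludes ambiguous bases", {
  idx <- build_kmer_index(c(chr = "ACGTACGT"), k = 5)
  # 4 positions; ACGTA is its own reverse complement's partner
  expect_true(kmer_present(idx, "ACGTA"))
  expect_true(all(kmer_present(idx, oracle_kmers("ACGTACGT", 5))))
  # reverse complement of a stored k-mer is found
  expect_true(kmer_present(idx, oracle_revcomp("ACGTA")))
  expect_false(kmer_present(idx, "AAAAA"))
  # k-mers containing N are neither stored nor queryable
  idxN <- build_kmer_index(c(chr = "ACGTNACGT"), k = 5)
  expect_equal(idxN$n_kmers, 0)
  expect_error(build_kmer_index("ACGT", k = 4), "odd")
})

test_that("index contents equal the enumeration oracle on random input", {
  set.seed(8)
  for (i in 1:10) {
    g <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    idx <- build_kmer_index(c(chr = g), k = 7)
    want <- unique(oracle_kmers(g, 7))
    expect_equal(idx$n_kmers, length(want))
    expect_true(all(kmer_present(idx, want)))
  }
})

test_that("coverage matches the naive set comparison and its limits", {
  set.seed(12)
  genome <- c(chr1 = random_dna_test(3000), chr2 = random_dna_test(2000))
  idx <- build_kmer_index(genome, k = 21)
  # self-contained gene scores 1; foreign gene scores 0
  gene_in <- substr(genome[["chr1"]], 501, 800)
  expect_equal(coverage_score(c(g = gene_in), idx)$score, 1)
  foreign <- random_dna_test(300)
  genes <- c(a = gene_in, b = foreign)
  got <- coverage_score(genes, idx)
  want <- vapply(genes, oracle_coverage, numeric(1), genome_seqs = genome,
                 k = 21)
  expect_equal(got$score, unname(want))
  # single SNP knocks out min(k, distance-to-edge) k-mers
  snp <- gene_in
  substr(snp, 1, 1) <- if (substr(snp, 1, 1) == "A") "C" else "A"
  sc <- coverage_score(c(s = snp), idx)
  expect_equal(sc$n_kmers, 300 - 21 + 1)
  expect_equal(sc$score, (280 - 1) / 280, tolerance = 1e-12)
  # too-short genes give NA
  expect_true(is.na(coverage_score(c(tiny = "ACGT"), idx)$score))
})

test_that("coverage is invariant to reverse-complementing the target", {
  set.seed(13)
  genome <- c(chr = random_dna_test(2000))
  genes <- setNames(substring(genome[["chr"]],
                              c(1, 501, 1001), c(300, 800, 1300)),
                    c("g1", "g2", "g3"))
  genes["g4"] <- random_dna_test(300)
  idx_f <- build_kmer_index(genome, k = 21)
  idx_r <- build_kmer_index(c(chr = oracle_revcomp(genome[["chr"]])), k = 21)
  expect_equal(coverage_score(genes, idx_f)$score,
               coverage_score(genes, idx_r)$score)
})

test_that("added substitutions never raise a nested gene's score", {
  set.seed(14)
  base <- random_dna_test(4000)
  gene <- substr(base, 1001, 1600)
  prev <- 1
  muts <- sort(sample(1001:1600, 30))
  for (m in seq(5, 30, by = 5)) {
    # apply the first m substitutions of a fixed nested set
    s <- strsplit(base, "")[[1]]
    s[muts[1:m]] <- chartr("ACGT", "CGTA", s[muts[1:m]])
    idx <- build_kmer_index(c(chr = paste(s, collapse = "")), k = 21)
    sc <- coverage_score(c(g = gene), idx)$score
    expect_lte(sc, prev)
    prev <- sc
  }
})

test_that("windowed profiles place genes by midpoint", {
  sc <- tibble::tibble(midpoint = c(1.5e6), score = 0.4)
  tr <- region_profile(sc, chrom_length = 4e6, window = 2e6, step = 1e6)
  expect_equal(tr$mean_score, c(0.4, 0.4, NA))
  # uniform scores give a flat track
  sc2 <- tibble::tibble(midpoint = seq(1e5, 3.9e6, by = 1e5), score = 1)
  tr2 <- region_profile(sc2, chrom_length = 4e6, window = 2e6, step = 5e5)
  expect_true(all(tr2$mean_score == 1))
  expect_warning(region_profile(sc, 4e6, window = 1e5, step = 2e5), "step")
})

test_that("candidate calling merges low windows and respects min_genes", {
  tr <- tibble::tibble(start = c(1, 11, 21, 31), end = c(10, 20, 30, 40),
                       n_genes = 2L, mean_score = c(0.9, 0.3, 0.2, 0.95))
  sc <- tibble::tibble(midpoint = c(12, 18, 25), score = c(0.3, 0.25, 0.2))
  cc <- call_candidates(tr, sc, score_threshold = 0.5, min_genes = 3)
  expect_equal(nrow(cc), 1)
  expect_equal(c(cc$start, cc$end), c(11, 30))
  expect_equal(cc$n_genes, 3)
  # nothing below threshold -> empty call set
  none <- call_candidates(dplyr::mutate(tr, mean_score = 0.9), sc, 0.5, 1)
  expect_equal(nrow(none), 0)
})

test_that("a planted divergent block is localized on synthetic genomes", {
  sim <- simulate_pangenome(n_cultivars = 2, n_orthogroups = 400,
                            class_props = c(1, 0, 0), seed = 61)
  sim <- simulate_genomes(sim, seed = 62)
  chr <- sim$genomes$cv02[["chr1A"]]
  len <- nchar(chr)
  blk <- c(round(len * 0.3), round(len * 0.55))
  pl <- plant_introgression(chr, blk[1], blk[2], divergence = 0.05,
                            seed = 63)
  sim$genomes$cv02[["chr1A"]] <- pl$sequence
  idx <- build_kmer_index(sim$genomes$cv02["chr1A"], k = 31,
                          cultivar = "cv02")
  ref <- dplyr::filter(sim$genes, cultivar == "cv01",
                       chromosome == "chr1A")
  ref$midpoint <- floor((ref$start + ref$end) / 2)
  sc <- coverage_score(gene_sequences(sim$genomes, ref), idx)
  sc$midpoint <- ref$midpoint
  inb <- ref$midpoint >= blk[1] & ref$midpoint <= blk[2]
  # expected intact fraction (1 - d)^k
  expect_equal(mean(sc$score[inb]), (1 - 0.05)^31, tolerance = 0.05)
  expect_equal(mean(sc$score[!inb]), 1)
  tr <- region_profile(sc, chrom_length = len, window = 2e4, step = 2e3)
  cc <- call_candidates(tr, sc, score_threshold = 0.5, min_genes = 3)
  expect_equal(nrow(cc), 1)
  expect_gte(interval_jaccard(cc$start, cc$end, blk[1], blk[2]), 0.7)
})

test_that("two distant planted blocks yield two candidate intervals", {
  sim <- simulate_pangenome(n_cultivars = 2, n_orthogroups = 400,
                            class_props = c(1, 0, 0), seed = 65)
  sim <- simulate_genomes(sim, seed = 66)
  chr <- sim$genomes$cv02[["chr1A"]]
  len <- nchar(chr)
  b1 <- c(round(len * 0.1), round(len * 0.25))
  b2 <- c(round(len * 0.65), round(len * 0.8))
  chr <- plant_introgression(chr, b1[1], b1[2], 0.05, seed = 67)$sequence
  chr <- plant_introgression(chr, b2[1], b2[2], 0.05, seed = 68)$sequence
  idx <- build_kmer_index(c(chr1A = chr), k = 31)
  ref <- dplyr::filter(sim$genes, cultivar == "cv01",
                       chromosome == "chr1A")
  ref$midpoint <- floor((ref$start + ref$end) / 2)
  sc <- coverage_score(gene_sequences(sim$genomes, ref), idx)
  sc$midpoint <- ref$midpoint
  tr <- region_profile(sc, chrom_length = len, window = 2e4, step = 2e3)
  cc <- call_candidates(tr, sc, score_threshold = 0.5, min_genes = 3)
  expect_equal(nrow(cc), 2)
})

test_that("divergence 0 leaves sequence identical; 1 changes every base", {
  s <- random_dna_test(500)
  expect_identical(plant_introgression(s, 100, 200, 0, seed = 1)$sequence, s)
  mut <- plant_introgression(s, 101, 200, 1, seed = 2)
  expect_equal(mut$truth$n_substituted, 100)
  a <- strsplit(s, "")[[1]]; b <- strsplit(mut$sequence, "")[[1]]
  expect_true(all(a[101:200] != b[101:200]))
  expect_identical(a[-(101:200)], b[-(101:200)])
  expect_error(plant_introgression(s, 400, 600, 0.1), "bounds")
})
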