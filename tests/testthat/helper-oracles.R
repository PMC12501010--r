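# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# nearest bias centroid by an explicit loop over all seven categories
oracle_centroid_class <- function(p) {
  cen <- pantriad::bias_centroids()
  best <- NULL; bestd <- Inf
  for (cat in rownames(cen)) {
    d <- 0
    for (j in 1:3) d <- d + (p[j] - cen[cat, j])^2
    d <- sqrt(d)
    if (d < bestd - 1e-15) { bestd <- d; best <- cat }
  }
  best
}

# one-sided (greater) Fisher p by full enumeration of all 2x2 tables with
# the observed margins
oracle_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, numeric(1))
  sum(prob[xs >= a])
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

# all k-mers of a sequence at every position (invalid ones dropped),
# canonicalized by string comparison with the reverse complement
oracle_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  km <- substring(seq, 1:(L - k + 1), k:L)
  km <- km[!grepl("[^ACGT]", km)]
  rc <- oracle_revcomp(km)
  ifelse(km <= rc, km, rc)
}

oracle_coverage <- function(gene, genome_seqs, k) {
  idx <- unique(unlist(lapply(genome_seqs, oracle_kmers, k = k)))
  q <- oracle_kmers(gene, k)
  if (length(q) == 0) return(NA_real_)
  mean(q %in% idx)
}

# Dunn index / silhouette by direct definition loops
oracle_dunn <- function(d, labels) {
  d <- as.matrix(d)
  n <- length(labels)
  min_between <- Inf; max_within <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (labels[i] == labels[j]) max_within <- max(max_within, d[i, j])
    else min_between <- min(min_between, d[i, j])
  }
  if (max_within == 0) return(Inf)
  min_between / max_within
}

oracle_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- length(labels)
  s <- numeric(n)
  for (i in 1:n) {
    same <- setdiff(which(labels == labels[i]), i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(d[i, same])
    b <- Inf
    for (k2 in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == k2]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# every concrete realization of an IUPAC consensus (small motifs only)
oracle_realizations <- function(consensus) {
  sets <- lapply(strsplit(consensus, "")[[1]], function(cc) {
    mask <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
              W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
              V = 7L, N = 15L)[[cc]]
    c("A", "C", "G", "T")[bitwAnd(mask, c(1L, 2L, 4L, 8L)) != 0]
  })
  apply(do.call(expand.grid, c(sets, stringsAsFactors = FALSE)), 1,
        paste, collapse = "")
}

# count motif occurrences by trying every realization at every offset
oracle_scan_count <- function(sequence, consensus) {
  real <- oracle_realizations(consensus)
  k <- nchar(consensus); L <- nchar(sequence)
  if (L < k) return(0L)
  subs <- substring(sequence, 1:(L - k + 1), k:L)
  sum(subs %in% real)
}

random_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a tiny deterministic expression bundle for io/stat tests
make_tiny_bundle <- function() {
  meta <- tidyr::expand_grid(cultivar = c("cvA", "cvB"),
                             tissue = c("root", "grain"),
                             replicate = 1:2) |>
    dplyr::mutate(sample = sprintf("%s_%s_r%d", cultivar, tissue, replicate))
  raw <- matrix(rpois(6 * nrow(meta), 50), nrow = 6,
                dimnames = list(paste0("g", 1:6), meta$sample))
  expression_bundle(raw, meta)
}
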