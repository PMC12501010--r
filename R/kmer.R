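# K-mer gene-coverage scans: score each gene of a reference cultivar
# against another cultivar's genome by the fraction of its k-mers present
# there, then window the scores along chromosomes and call candidate
# introgression intervals.

#' Build a canonical k-mer index of a genome
#'
#' Stores the canonical form (lexicographic minimum of forward and
#' reverse-complement) of every k-mer of every chromosome, so queries are
#' strand-agnostic. K-mers containing non-ACGT characters are excluded.
#' Membership is exact (sorted keys, binary search): no false positives.
#'
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param k odd k-mer length (default 51).
#' @param cultivar optional label carried in the index.
#' @return Object of class `kmer_index`.
#' @export
build_kmer_index <- function(genome, k = 51L, cultivar = NA_character_) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  assert_that(is.character(genome), "`genome` must be sequences")
  assert_that(is_count(k) && k >= 1 && k %% 2 == 1,
              "`k` must be an odd integer (canonical form is ambiguous for even k)")
  ptr <- kmer_index_build(unname(genome), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), cultivar = cultivar,
                 n_kmers = kmer_index_size(ptr)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %.0f canonical k-mers%s\n", x$k, x$n_kmers,
              if (is.na(x$cultivar)) "" else paste0(" (", x$cultivar, ")")))
  invisible(x)
}

#' Query k-mer membership
#'
#' @param index a [build_kmer_index()] result.
#' @param kmers character vector of length-k strings.
#' @return Logical vector; `NA` for strings of the wrong length.
#' @export
kmer_present <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  kmer_index_has(index$ptr, kmers)
}

#' K-mer coverage scores of gene sequences against a genome index
#'
#' Each gene contributes its (L - k + 1) overlapping k-mers; the score is
#' the fraction found in the target index (1 means every k-mer of the gene
#' occurs in the target genome). Genes shorter than k get `NA`.
#'
#' @param gene_seqs named character vector (or `DNAStringSet`) of gene
#'   sequences; names are gene ids.
#' @param index target-genome [build_kmer_index()].
#' @return Tibble `gene`, `target`, `n_kmers`, `n_hit`, `score`.
#' @export
coverage_score <- function(gene_seqs, index) {
  stopifnot(inherits(index, "kmer_index"))
  if (inherits(gene_seqs, "DNAStringSet")) {
    nm <- names(gene_seqs)
    gene_seqs <- as.character(gene_seqs)
    names(gene_seqs) <- nm
  }
  m <- kmer_coverage_scores(index$ptr, unname(gene_seqs))
  tibble(gene = names(gene_seqs) %||% as.character(seq_along(gene_seqs)),
         target = index$cultivar,
         n_kmers = as.vector(m[, "n_kmers"]),
         n_hit = as.vector(m[, "n_hit"]),
         score = ifelse(as.vector(m[, "n_kmers"]) == 0, NA_real_,
                        as.vector(m[, "score"])))
}

#' Windowed mean coverage track along a chromosome
#'
#' Genes are positioned by midpoint; each sliding window reports the mean
#' score of the genes it contains (empty windows give `NA`).
#'
#' @param scores tibble with `score` and gene positions `midpoint` (bp) —
#'   join of [coverage_score()] with gene models.
#' @param chrom_length chromosome length in bp.
#' @param window,step window and step sizes in bp (defaults 2 Mb / 5 kb).
#' @return Tibble `start`, `end` (1-based inclusive), `n_genes`,
#'   `mean_score`.
#' @export
region_profile <- function(scores, chrom_length, window = 2e6, step = 5e3) {
  if (step > window) warn("step exceeds window; track will skip genes")
  assert_that(all(c("midpoint", "score") %in% names(scores)),
              "`scores` needs `midpoint` and `score` columns")
  starts <- seq(1, max(1, chrom_length - window + 1), by = step)
  sc <- scores |> filter(!is.na(.data$score)) |> arrange(.data$midpoint)
  mids <- sc$midpoint
  vals <- sc$score
  lo <- findInterval(starts - 1, mids) + 1          # first gene >= start
  hi <- findInterval(starts + window - 1, mids)     # last gene <= end
  cs <- c(0, cumsum(vals))
  n <- pmax(0L, hi - lo + 1L)
  msum <- ifelse(n > 0, cs[hi + 1] - cs[lo], NA_real_)
  tibble(start = starts, end = pmin(starts + window - 1, chrom_length),
         n_genes = as.integer(n),
         mean_score = ifelse(n > 0, msum / n, NA_real_))
}

#' Call candidate introgression intervals from a coverage track
#'
#' Maximal runs of consecutive windows whose mean score falls below the
#' threshold are merged into intervals; intervals must contain at least
#' `min_genes` distinct scored genes.
#'
#' @param track output of [region_profile()].
#' @param scores the per-gene score table used to build the track (for the
#'   gene counts inside merged intervals).
#' @param score_threshold windows below this mean are candidate (default
#'   0.5).
#' @param min_genes minimal number of scored genes in an interval.
#' @return Tibble `start`, `end`, `n_windows`, `n_genes`, `mean_score`.
#' @export
call_candidates <- function(track, scores, score_threshold = 0.5,
                            min_genes = 3L) {
  low <- !is.na(track$mean_score) & track$mean_score < score_threshold
  if (!any(low)) {
    return(tibble(start = numeric(), end = numeric(),
                  n_windows = integer(), n_genes = integer(),
                  mean_score = numeric()))
  }
  r <- rle(low)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1
  runs <- which(r$values)
  out <- map(runs, function(i) {
    w <- begins[i]:ends[i]
    s <- min(track$start[w]); e <- max(track$end[w])
    inside <- !is.na(scores$score) &
      scores$midpoint >= s & scores$midpoint <= e
    tibble(start = s, end = e, n_windows = length(w),
           n_genes = sum(inside),
           mean_score = mean(scores$score[inside]))
  })
  list_rbind(out) |> filter(.data$n_genes >= min_genes)
}

#' Jaccard overlap of two intervals
#'
#' @param start1,end1,start2,end2 interval bounds (1-based inclusive).
#' @return Intersection length over union length.
#' @export
interval_jaccard <- function(start1, end1, start2, end2) {
  inter <- max(0, min(end1, end2) - max(start1, start2) + 1)
  uni <- (end1 - start1 + 1) + (end2 - start2 + 1) - inter
  inter / uni
}
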