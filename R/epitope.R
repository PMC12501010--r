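# CD-epitope analysis: reverse-translate peptide epitopes to degenerate
# IUPAC consensus motifs, scan gene sequences at 100% (degeneracy-aware)
# identity, weight normalized expression by occurrence counts, and extract
# TF co-expression edges.

# IUPAC nucleotide codes as ACGT bit masks (A=1, C=2, G=4, T=8).
IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

mask_to_iupac <- setNames(names(IUPAC_MASK)[order(IUPAC_MASK)],
                          sort(IUPAC_MASK))

seq_mask <- function(x, degenerate = FALSE) {
  chars <- strsplit(toupper(x), "")[[1]]
  if (degenerate) {
    m <- IUPAC_MASK[chars]
    assert_that(!anyNA(m), paste("invalid IUPAC code in motif:", x))
  } else {
    # concrete genome side: only ACGT carry information, anything else
    # (including N) matches no motif position
    m <- IUPAC_MASK[chars]
    m[is.na(m) | !chars %in% c("A", "C", "G", "T")] <- 0L
  }
  unname(m)
}

#' Reverse-translate a peptide to a degenerate consensus motif
#'
#' For each residue, the positionwise union of all its standard-table
#' codons is encoded as the minimal IUPAC code covering exactly that base
#' set, giving a nucleotide consensus of length 3x the peptide.
#'
#' @param peptide one-letter amino-acid string (20 standard residues).
#' @param name optional motif name.
#' @param group optional epitope group (e.g. "alpha-gliadin").
#' @return Tibble of class rows: `name`, `peptide`, `consensus`, `group`.
#' @examples
#' reverse_translate_consensus("M")$consensus  # "ATG"
#' reverse_translate_consensus("F")$consensus  # "TTY"
#' @export
reverse_translate_consensus <- function(peptide, name = peptide,
                                        group = NA_character_) {
  code <- Biostrings::GENETIC_CODE
  aas <- strsplit(toupper(peptide), "")[[1]]
  assert_that(all(aas %in% setdiff(unique(code), "*")),
              paste("unknown residue in peptide:", peptide))
  consensus <- map_chr(aas, function(aa) {
    codons <- names(code)[code == aa]
    masks <- vapply(1:3, function(i) {
      bases <- unique(substr(codons, i, i))
      sum(IUPAC_MASK[bases])
    }, integer(1))
    paste(mask_to_iupac[as.character(masks)], collapse = "")
  })
  tibble(name = name, peptide = toupper(peptide),
         consensus = paste(consensus, collapse = ""), group = group)
}

#' Scan a sequence for a degenerate consensus motif
#'
#' A position matches when every sequence base is a member of the IUPAC
#' class at the corresponding motif offset. The genome side must be
#' concrete: `N` (or any ambiguity code) in the sequence matches nothing.
#' Overlapping occurrences are all counted; the reverse strand is scanned
#' when `search_revcomp` is set (positions reported on the forward
#' strand).
#'
#' @param sequence nucleotide string to scan.
#' @param consensus IUPAC consensus motif string.
#' @param search_revcomp also scan the reverse complement.
#' @return Tibble `position` (1-based start), `strand`.
#' @export
scan_motif <- function(sequence, consensus, search_revcomp = FALSE) {
  m <- seq_mask(consensus, degenerate = TRUE)
  scan1 <- function(seq) {
    s <- seq_mask(seq, degenerate = FALSE)
    L <- length(s); k <- length(m)
    if (L < k) return(integer())
    ok <- rep(TRUE, L - k + 1)
    for (j in seq_len(k)) {
      sj <- s[j:(L - k + j)]
      ok <- ok & sj != 0L & bitwAnd(sj, m[j]) == sj
    }
    which(ok)
  }
  hits <- tibble(position = scan1(sequence), strand = "+")
  if (search_revcomp) {
    L <- nchar(sequence)
    k <- nchar(consensus)
    rc <- scan1(revcomp(sequence))
    hits <- bind_rows(hits,
                      tibble(position = L - k + 2 - rc, strand = "-"))
  }
  hits |> arrange(.data$position)
}

#' Count motif occurrences across genes and motifs
#'
#' @param gene_seqs named character vector of gene sequences.
#' @param motifs tibble from [reverse_translate_consensus()] (columns
#'   `name`, `consensus`, `group`).
#' @param search_revcomp forwarded to [scan_motif()].
#' @return Tibble `gene`, `motif`, `group`, `n_occurrences`.
#' @export
count_epitopes <- function(gene_seqs, motifs, search_revcomp = FALSE) {
  grid <- tidyr::expand_grid(gene = names(gene_seqs),
                             i = seq_len(nrow(motifs)))
  grid |>
    mutate(motif = motifs$name[.data$i],
           group = motifs$group[.data$i],
           n_occurrences = map2_int_local(.data$gene, .data$i, function(g, i) {
             nrow(scan_motif(gene_seqs[[g]], motifs$consensus[i],
                             search_revcomp))
           })) |>
    select("gene", "motif", "group", "n_occurrences")
}

map2_int_local <- function(x, y, f) {
  vapply(seq_along(x), function(i) as.integer(f(x[[i]], y[[i]])), integer(1))
}

#' Epitope-weighted expression scores
#'
#' Per-gene score = mean normalized count x number of epitope occurrences
#' in the gene, summed per epitope group and per (group, subgenome).
#'
#' @param occurrences output of [count_epitopes()].
#' @param gene_expr tibble `gene`, `expr` (mean normalized counts; e.g.
#'   from [condition_means()] averaged, or a single condition).
#' @param gene_subgenome tibble `gene`, `subgenome`; genes without a
#'   subgenome are excluded from the per-subgenome sums with a warning.
#' @return List with `per_gene` (gene, motif, group, score) and
#'   `per_group` (group, subgenome, total score).
#' @export
epitope_expression_score <- function(occurrences, gene_expr,
                                     gene_subgenome = NULL) {
  per_gene <- occurrences |>
    left_join(gene_expr, by = "gene") |>
    mutate(expr = ifelse(is.na(.data$expr), 0, .data$expr),
           score = .data$expr * .data$n_occurrences)
  if (!is.null(gene_subgenome)) {
    per_gene <- per_gene |> left_join(gene_subgenome, by = "gene")
    n_bad <- sum(is.na(per_gene$subgenome) & per_gene$score > 0)
    if (n_bad > 0)
      warn(sprintf("%d scored entries lack a subgenome; excluded from sums",
                   n_bad))
  } else {
    per_gene$subgenome <- NA_character_
  }
  per_group <- per_gene |>
    filter(!is.na(.data$subgenome)) |>
    summarise(score = sum(.data$score), .by = c("group", "subgenome")) |>
    arrange(.data$group, .data$subgenome)
  type_totals <- per_gene |>
    summarise(score = sum(.data$score), .by = "group") |>
    arrange(.data$group)
  list(per_gene = per_gene |> select("gene", "motif", "group",
                                     "n_occurrences", "expr", "score"),
       per_group = per_group, per_type = type_totals)
}

#' Co-expression edges between targets and candidate regulators
#'
#' Pearson correlation of log2-transformed normalized counts (values
#' above 1 normalized count retained before the log, as in grain TF
#' screens) between every target and every regulator, with two-sided p
#' from the t transform and BH adjustment across all tested pairs. Edges
#' are kept when r > `r_cutoff` and adjusted p < `p_cutoff`.
#'
#' @param target_expr matrix of normalized counts, targets x samples.
#' @param regulator_expr matrix, regulators x samples (same columns).
#' @param r_cutoff,p_cutoff edge filters (defaults 0.8, 0.01).
#' @param log2_transform apply `log2(x)` to values, keeping only profiles
#'   after masking counts <= 1 as missing (default TRUE).
#' @return Tibble `target`, `regulator`, `r`, `p_value`, `p_adj`,
#'   `retained`.
#' @export
coexpression_edges <- function(target_expr, regulator_expr,
                               r_cutoff = 0.8, p_cutoff = 0.01,
                               log2_transform = TRUE) {
  assert_that(ncol(target_expr) == ncol(regulator_expr),
              "target and regulator matrices need identical samples")
  tx <- as.matrix(target_expr); rx <- as.matrix(regulator_expr)
  if (log2_transform) {
    tx[tx <= 1] <- NA; rx[rx <= 1] <- NA
    tx <- log2(tx); rx <- log2(rx)
  }
  res <- list()
  for (i in seq_len(nrow(tx))) {
    for (j in seq_len(nrow(rx))) {
      x <- tx[i, ]; y <- rx[j, ]
      use <- !is.na(x) & !is.na(y)
      if (sum(use) < 3 || sd(x[use]) == 0 || sd(y[use]) == 0) {
        warn(sprintf("constant or too-short profile pair (%s, %s); skipped",
                     rownames(tx)[i], rownames(rx)[j]))
        next
      }
      r <- cor(x[use], y[use])
      n <- sum(use)
      tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p <- 2 * pt(-abs(tstat), df = n - 2)
      res[[length(res) + 1]] <- tibble(
        target = rownames(tx)[i], regulator = rownames(rx)[j],
        r = r, p_value = p)
    }
  }
  if (length(res) == 0) {
    return(tibble(target = character(), regulator = character(),
                  r = numeric(), p_value = numeric(), p_adj = numeric(),
                  retained = logical()))
  }
  list_rbind(res) |>
    mutate(p_adj = bh_adjust(.data$p_value),
           retained = .data$r > r_cutoff & .data$p_adj < p_cutoff) |>
    arrange(.data$target, .data$regulator)
}
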