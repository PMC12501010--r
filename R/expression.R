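#' Construct an expression bundle
#'
#' Pairs a raw count matrix (genes x samples, non-negative integers) with
#' its sample metadata sidecar. Size factors and normalized counts are
#' attached by [normalize_bundle()].
#'
#' @param raw numeric matrix of raw counts with gene row names and sample
#'   column names.
#' @param meta data frame with columns `sample`, `cultivar`, `tissue`,
#'   `replicate`; one row per column of `raw`.
#' @return A list of class `expression_bundle` with elements `raw`, `meta`,
#'   and (after normalization) `size_factors` and `normalized`.
#' @export
expression_bundle <- function(raw, meta) {
  assert_that(is.matrix(raw) && !is.null(rownames(raw)) &&
                !is.null(colnames(raw)),
              "`raw` must be a matrix with gene rownames and sample colnames")
  assert_that(all(is.na(raw) | raw >= 0), "counts must be non-negative")
  meta <- as_tibble(meta)
  need <- c("sample", "cultivar", "tissue", "replicate")
  assert_that(all(need %in% names(meta)),
              paste("metadata must have columns:", paste(need, collapse = ", ")))
  missing <- setdiff(colnames(raw), meta$sample)
  assert_that(length(missing) == 0,
              paste("samples missing from metadata:",
                    paste(head(missing, 5), collapse = ", ")))
  assert_that(!anyDuplicated(rownames(raw)), "duplicated gene id in counts")
  meta <- meta[match(colnames(raw), meta$sample), ]
  structure(list(raw = raw, meta = meta,
                 size_factors = NULL, normalized = NULL),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf("<expression_bundle> %d genes x %d samples (%d cultivars, %d tissues)%s\n",
              nrow(x$raw), ncol(x$raw),
              dplyr::n_distinct(x$meta$cultivar),
              dplyr::n_distinct(x$meta$tissue),
              if (is.null(x$normalized)) "" else ", normalized"))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed by the median-of-ratios
#' method: each gene with all-positive counts contributes the ratio of its
#' count to its geometric mean across samples, and a sample's factor is
#' the median of those ratios. This is the size-factor definition used for
#' count normalization throughout the package.
#'
#' @param raw count matrix (genes x samples); `NA` entries are ignored.
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- rbind(g1 = c(10, 20), g2 = c(100, 200), g3 = c(4, 8))
#' colnames(m) <- c("s1", "s2")
#' size_factors(m)  # c(0.7071, 1.4142)
#' @export
size_factors <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) == 1) return(setNames(1, colnames(raw)))
  use <- apply(raw, 1, function(x) all(!is.na(x) & x > 0))
  if (!any(use)) {
    abort(paste("no gene has positive counts in every sample;",
                "median-of-ratios is undefined (consider a pseudo-reference",
                "on a filtered gene set)"))
  }
  logm <- log(raw[use, , drop = FALSE])
  ref <- rowMeans(logm)                    # log geometric mean
  f <- apply(logm, 2, function(col) exp(median(col - ref)))
  setNames(f, colnames(raw))
}

#' Normalize counts by size factors
#'
#' @param raw count matrix (genes x samples).
#' @param factors positive per-sample factors, one per column.
#' @return Matrix of normalized counts, `raw` divided columnwise.
#' @export
normalize_counts <- function(raw, factors) {
  raw <- as.matrix(raw)
  assert_that(length(factors) == ncol(raw),
              "need one size factor per sample")
  assert_that(all(factors > 0), "size factors must be positive")
  sweep(raw, 2, factors, "/")
}

#' Normalize an expression bundle in place
#'
#' Computes size factors per cultivar (each cultivar's samples are
#' normalized against that cultivar's genes, mirroring per-assembly
#' alignment) and attaches `size_factors` and `normalized` to the bundle.
#'
#' @param bundle an [expression_bundle()].
#' @param per_cultivar normalize each cultivar's block separately (default
#'   `TRUE`); genes with `NA` in a sample never contribute to its factor.
#' @return The bundle with `size_factors` and `normalized` filled in.
#' @export
normalize_bundle <- function(bundle, per_cultivar = TRUE) {
  stopifnot(inherits(bundle, "expression_bundle"))
  raw <- bundle$raw
  sf <- setNames(rep(NA_real_, ncol(raw)), colnames(raw))
  groups <- if (per_cultivar) split(bundle$meta$sample, bundle$meta$cultivar)
            else list(all = colnames(raw))
  for (ss in groups) {
    block <- raw[, ss, drop = FALSE]
    keep <- rowSums(is.na(block)) == 0
    sf[ss] <- size_factors(block[keep, , drop = FALSE])
  }
  bundle$size_factors <- sf
  bundle$normalized <- normalize_counts(raw, sf)
  bundle
}

#' Mean normalized expression per condition
#'
#' Replicate means of the normalized counts for each (cultivar, tissue)
#' condition — the per-condition expression view used by tau, homoeolog
#' bias, and tandem balance.
#'
#' @param bundle a normalized [expression_bundle()].
#' @return Tibble with columns `gene`, `cultivar`, `tissue`, `mean_norm`.
#' @export
condition_means <- function(bundle) {
  stopifnot(inherits(bundle, "expression_bundle"))
  assert_that(!is.null(bundle$normalized),
              "bundle is not normalized; call normalize_bundle() first")
  norm <- bundle$normalized
  as_tibble(norm, rownames = "gene") |>
    pivot_longer(-"gene", names_to = "sample", values_to = "norm") |>
    inner_join(bundle$meta, by = "sample") |>
    filter(!is.na(.data$norm)) |>
    summarise(mean_norm = mean(.data$norm),
              .by = c("gene", "cultivar", "tissue"))
}

#' Tissue-specificity index (tau)
#'
#' tau = sum(1 - x_i) / (N - 1) where x_i is the per-condition expression
#' normalized by the gene's maximal expression over the N conditions.
#' tau is 1 for expression confined to a single condition and 0 for a
#' perfectly uniform profile.
#'
#' @param profile non-negative per-condition expression values (N >= 2).
#' @return tau in \[0, 1\], or `NA` for an all-zero profile.
#' @examples
#' tau_index(c(10, 0, 0, 0))  # 1
#' tau_index(c(5, 5, 5, 5))   # 0
#' tau_index(c(8, 4, 2, 2))   # 0.6667
#' @export
tau_index <- function(profile) {
  assert_that(length(profile) >= 2, "tau needs at least 2 conditions")
  assert_that(all(profile >= 0, na.rm = TRUE),
              "tau requires non-negative expression values")
  if (anyNA(profile)) return(NA_real_)
  m <- max(profile)
  if (m == 0) return(NA_real_)
  sum(1 - profile / m) / (length(profile) - 1)
}

#' Tissue-specific gene sets from condition means
#'
#' Computes tau per (gene, cultivar) over the chosen tissues and assigns
#' genes with tau at or above the threshold to the tissue of their maximal
#' mean expression.
#'
#' @param cond_means output of [condition_means()].
#' @param tissues tissues over which tau is computed; defaults to the four
#'   developmental tissues (flag_leaf, root, spike, grain).
#' @param threshold tau threshold (default 0.8).
#' @return Tibble with `gene`, `cultivar`, `tau`, `top_tissue`, `specific`.
#' @export
tissue_specificity <- function(cond_means, tissues = TAU_TISSUES,
                               threshold = 0.8) {
  check_fraction(threshold, "threshold")
  df <- cond_means |> filter(.data$tissue %in% tissues)
  assert_that(nrow(df) > 0, "no rows for the requested tissues")
  df |>
    summarise(tau = tau_index(.data$mean_norm),
              top_tissue = .data$tissue[which.max(.data$mean_norm)],
              .by = c("gene", "cultivar")) |>
    mutate(specific = !is.na(.data$tau) & .data$tau >= threshold,
           top_tissue = ifelse(is.na(.data$tau), NA_character_,
                               .data$top_tissue)) |>
    arrange(.data$gene, .data$cultivar)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with a chi-square approximation (k - 1 df), as applied
#' to compare expression-bias proportions across cultivars.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @return Tibble with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2,
              "need at least two groups")
  assert_that(all(lengths(groups) > 0), "groups must be non-empty")
  kt <- kruskal.test(groups)
  tibble(H = unname(kt$statistic), df = unname(kt$parameter),
         p_value = if (unname(kt$statistic) == 0) 1 else unname(kt$p.value),
         n = sum(lengths(groups)))
}

#' Dunn's post-hoc test
#'
#' Pairwise z statistics from pooled midranks with tie correction,
#' following a Kruskal-Wallis test; two-sided p values are Bonferroni
#' adjusted (multiplied by the number of comparisons, capped at 1) by
#' default.
#'
#' @param groups named list of numeric vectors.
#' @param adjust `"bonferroni"` (default), `"BH"`, or `"none"`.
#' @return Tibble with `group1`, `group2`, `z`, `p_value`, `p_adj`.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "BH", "none")) {
  adjust <- match.arg(adjust)
  assert_that(is.list(groups) && length(groups) >= 2,
              "need at least two groups")
  assert_that(all(lengths(groups) > 0), "groups must be non-empty")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)                                  # midranks
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  ni <- lengths(groups)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  base_var <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(seq_along(groups), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(base_var * (1 / ni[i] + 1 / ni[j]))
    if (se == 0) 0 else (rbar[i] - rbar[j]) / se
  })
  p <- 2 * pnorm(-abs(z))
  p_adj <- switch(adjust,
                  bonferroni = pmin(1, p * ncol(pairs)),
                  BH = p.adjust(p, "BH"),
                  none = p)
  tibble(group1 = names(groups)[pairs[1, ]],
         group2 = names(groups)[pairs[2, ]],
         z = as.numeric(z), p_value = as.numeric(p),
         p_adj = as.numeric(p_adj))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input p values must lie in
#' \[0, 1\].
#'
#' @param p numeric vector of p values.
#' @return Adjusted p values, capped at 1.
#' @export
bh_adjust <- function(p) {
  assert_that(all(!is.na(p) & p >= 0 & p <= 1),
              "p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
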