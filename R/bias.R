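# Homoeolog expression bias: 1:1:1 n-lets, relative subgenome expression,
# centroid classification into seven bias categories, stable/dynamic
# partition across cultivars.

#' Ternary centroids of the seven homoeolog bias categories
#'
#' Balanced sits at (1/3, 1/3, 1/3); X-dominant at the unit vector of
#' subgenome X; X-suppressed at 0 on X and 1/2 on the other two. Rows are
#' categories, columns the A/B/D expression fractions.
#'
#' @return 7 x 3 numeric matrix with category row names.
#' @export
bias_centroids <- function() {
  m <- rbind(
    "Balanced"     = c(1, 1, 1) / 3,
    "A-dominant"   = c(1, 0, 0),
    "B-dominant"   = c(0, 1, 0),
    "D-dominant"   = c(0, 0, 1),
    "A-suppressed" = c(0, .5, .5),
    "B-suppressed" = c(.5, 0, .5),
    "D-suppressed" = c(.5, .5, 0))
  colnames(m) <- SUBGENOMES
  m
}

#' Build 1:1:1 homoeolog n-lets from an orthogroup table
#'
#' Retains orthogroups with exactly one member gene per (cultivar,
#' subgenome) in every cultivar: a triad per cultivar, a "30-let" when ten
#' genomes contribute three genes each. Subgenome assignments come from
#' the gene models. Macrosyntenic means every member's chromosome maps to
#' its slot's subgenome in all cultivars; microsyntenic additionally
#' requires the same chromosome group in all cultivars.
#'
#' @param orthogroups tibble with columns `og`, `cultivar`, `gene`.
#' @param genes gene-model tibble with `gene`, `cultivar`, `chromosome`,
#'   `subgenome`.
#' @param cultivars cultivars that must all contribute a triad; defaults
#'   to every cultivar in `orthogroups`.
#' @return Tibble with one row per (og, cultivar): columns `og`,
#'   `cultivar`, `gene_A`, `gene_B`, `gene_D`, `macrosyntenic`,
#'   `microsyntenic`.
#' @export
build_nlets <- function(orthogroups, genes, cultivars = NULL) {
  cultivars <- cultivars %||% sort(unique(orthogroups$cultivar))
  g <- genes |> select("gene", g_cultivar = "cultivar",
                       "chromosome", "subgenome")
  memb <- orthogroups |>
    filter(.data$cultivar %in% cultivars) |>
    left_join(g, by = "gene")
  n_missing <- sum(is.na(memb$subgenome))
  if (n_missing > 0) {
    warn(sprintf("%d orthogroup members lack a subgenome assignment; excluded",
                 n_missing))
    memb <- memb |> filter(!is.na(.data$subgenome))
  }
  ok <- memb |>
    summarise(n = n(), .by = c("og", "cultivar", "subgenome")) |>
    summarise(one_each = all(.data$n == 1) &&
                length(unique(.data$subgenome)) == 3 &&
                dplyr::n_distinct(.data$cultivar) == length(cultivars),
              .by = "og") |>
    filter(.data$one_each)
  nlets <- memb |>
    filter(.data$og %in% ok$og) |>
    select("og", "cultivar", "subgenome", "gene", "chromosome") |>
    pivot_wider(names_from = "subgenome",
                values_from = c("gene", "chromosome"))
  # chromosome group = chromosome name with the subgenome letter removed
  chrom_group <- function(chr) sub("[ABD]", "", chr)
  nlets |>
    mutate(macrosyntenic = TRUE,
           microsyntenic =
             dplyr::n_distinct(chrom_group(.data$chromosome_A)) == 1 &
             dplyr::n_distinct(chrom_group(.data$chromosome_B)) == 1 &
             dplyr::n_distinct(chrom_group(.data$chromosome_D)) == 1,
           .by = "og") |>
    select("og", "cultivar", "gene_A", "gene_B", "gene_D",
           "macrosyntenic", "microsyntenic") |>
    arrange(.data$og, .data$cultivar)
}

#' Relative subgenome expression of a triad
#'
#' @param a,b,d non-negative mean normalized expression of the A, B and D
#'   homoeologs (vectorized).
#' @return Tibble with `rA`, `rB`, `rD` (fractions summing to 1 where the
#'   total is positive, `NA` otherwise) and total `T`.
#' @export
relative_expression <- function(a, b, d) {
  assert_that(all(c(a, b, d) >= 0, na.rm = TRUE),
              "expression values must be non-negative")
  tot <- a + b + d
  pos <- !is.na(tot) & tot > 0
  tibble(rA = ifelse(pos, a / tot, NA_real_),
         rB = ifelse(pos, b / tot, NA_real_),
         rD = ifelse(pos, d / tot, NA_real_),
         T = tot)
}

#' Classify triads by nearest ternary centroid
#'
#' A triad with total normalized expression below `not_expressed_cutoff`
#' is NotExpressed; otherwise its (rA, rB, rD) point is assigned to the
#' nearest of the seven category centroids by Euclidean distance. Exact
#' ties (measure zero) break by the fixed order Balanced < dominants <
#' suppressed.
#'
#' @param rel tibble from [relative_expression()] (columns `rA`, `rB`,
#'   `rD`, `T`).
#' @param not_expressed_cutoff total-expression cutoff (default 0.5).
#' @return `rel` with `category` (factor over the eight categories) and
#'   `centroid_dist` (distance to the assigned centroid; `NA` when
#'   NotExpressed) plus distances to all seven centroids in columns
#'   `dist_<category>`.
#' @export
classify_bias <- function(rel, not_expressed_cutoff = 0.5) {
  cen <- bias_centroids()
  pts <- as.matrix(rel[, c("rA", "rB", "rD")])
  # squared distances via ||x||^2 - 2 x.c + ||c||^2, rows = points
  d2 <- outer(rowSums(pts^2), rep(1, nrow(cen))) -
    2 * pts %*% t(cen) + outer(rep(1, nrow(pts)), rowSums(cen^2))
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  colnames(d) <- rownames(cen)
  ne <- is.na(rel$T) | rel$T < not_expressed_cutoff
  best <- apply(d, 1, function(x) {
    i <- which.min(x)                         # first minimum = fixed order
    if (length(i) == 0) 1L else i             # all-NA row (T = 0)
  })
  category <- rownames(cen)[best]
  category[ne] <- "NotExpressed"
  out <- rel
  out$category <- factor(category, levels = BIAS_LEVELS)
  out$centroid_dist <- ifelse(ne, NA_real_, d[cbind(seq_len(nrow(d)), best)])
  dd <- as_tibble(d)
  names(dd) <- paste0("dist_", rownames(cen))
  bind_cols(out, dd)
}

#' Per-cultivar bias table for a set of n-lets
#'
#' Computes, for every (n-let, cultivar), the mean normalized expression
#' of each homoeolog across conditions, the relative expression point and
#' the bias category.
#'
#' @param nlets output of [build_nlets()].
#' @param cond_means output of [condition_means()].
#' @param not_expressed_cutoff forwarded to [classify_bias()].
#' @param tissues optionally restrict to a tissue subset.
#' @return Tibble keyed by (`og`, `cultivar`) with expression, ternary
#'   coordinates, `category` and centroid distances.
#' @export
nlet_bias <- function(nlets, cond_means, not_expressed_cutoff = 0.5,
                      tissues = NULL) {
  cm <- cond_means
  if (!is.null(tissues)) cm <- cm |> filter(.data$tissue %in% tissues)
  gene_mean <- cm |> summarise(expr = mean(.data$mean_norm),
                               .by = c("gene", "cultivar"))
  look <- function(gene, cultivar) {
    v <- gene_mean$expr[match(paste(gene, cultivar),
                              paste(gene_mean$gene, gene_mean$cultivar))]
    ifelse(is.na(v), 0, v)
  }
  base <- nlets |>
    mutate(expr_A = look(.data$gene_A, .data$cultivar),
           expr_B = look(.data$gene_B, .data$cultivar),
           expr_D = look(.data$gene_D, .data$cultivar))
  rel <- relative_expression(base$expr_A, base$expr_B, base$expr_D)
  bind_cols(base, classify_bias(rel, not_expressed_cutoff)) |>
    arrange(.data$og, .data$cultivar)
}

#' Stable/dynamic partition of n-lets across cultivars
#'
#' An n-let whose bias category agrees in every cultivar is stable
#' (stable-balanced / stable-dominant / stable-suppressed according to the
#' shared category); NotExpressed in all cultivars is not-expressed; any
#' disagreement among expressed categories — including mixtures with
#' NotExpressed — is dynamic.
#'
#' @param bias per-cultivar bias table from [nlet_bias()] (needs `og`,
#'   `cultivar`, `category`).
#' @param cultivars cultivars that must all be present; defaults to all in
#'   `bias`.
#' @return Object of class `stability_partition`: a list with `per_nlet`
#'   (tibble `og`, `label`, `n_categories`), `counts` (tibble per label),
#'   and `dynamic_composition` (per category, number of dynamic n-lets
#'   showing it in at least one cultivar).
#' @export
stability_partition <- function(bias, cultivars = NULL) {
  cultivars <- cultivars %||% sort(unique(bias$cultivar))
  miss <- bias |>
    summarise(n = dplyr::n_distinct(.data$cultivar), .by = "og") |>
    filter(.data$n < length(cultivars))
  assert_that(nrow(miss) == 0,
              paste("n-lets missing cultivar categories:",
                    paste(head(miss$og, 5), collapse = ", ")))
  lab1 <- function(cats) {
    u <- unique(as.character(cats))
    if (length(u) > 1) return("dynamic")
    if (u == "NotExpressed") return("not-expressed")
    if (u == "Balanced") return("stable-balanced")
    if (grepl("dominant", u)) return("stable-dominant")
    "stable-suppressed"
  }
  per <- bias |>
    filter(.data$cultivar %in% cultivars) |>
    summarise(label = lab1(.data$category),
              n_categories = dplyr::n_distinct(.data$category),
              .by = "og") |>
    mutate(label = factor(.data$label, levels = STABILITY_LEVELS)) |>
    arrange(.data$og)
  counts <- per |> count(.data$label, .drop = FALSE, name = "n")
  dyn <- bias |>
    filter(.data$og %in% per$og[per$label == "dynamic"]) |>
    distinct(.data$og, .data$category) |>
    count(.data$category, name = "n_nlets") |>
    arrange(desc(.data$n_nlets))
  structure(list(per_nlet = per, counts = counts,
                 dynamic_composition = dyn,
                 n_nlets = nrow(per)),
            class = "stability_partition")
}

#' @export
print.stability_partition <- function(x, ...) {
  cat(sprintf("<stability_partition> %d n-lets\n", x$n_nlets))
  print(x$counts)
  invisible(x)
}

#' @rdname stability_partition
#' @param x a `stability_partition`.
#' @param ... unused.
#' @export
tidy.stability_partition <- function(x, ...) {
  x$counts |>
    mutate(percent = 100 * .data$n / sum(.data$n))
}

#' @rdname stability_partition
#' @export
glance.stability_partition <- function(x, ...) {
  n <- setNames(x$counts$n, as.character(x$counts$label))
  tibble(n_nlets = x$n_nlets,
         stable_balanced = n[["stable-balanced"]],
         stable_dominant = n[["stable-dominant"]],
         stable_suppressed = n[["stable-suppressed"]],
         dynamic = n[["dynamic"]],
         not_expressed = n[["not-expressed"]])
}
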