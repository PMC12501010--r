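# Core/shell/cloud classification of orthogroups and genes, exclusive
# presence-pattern intersections, and positional enrichment of
# cultivar-specific genes.

#' Classify orthogroups into core, shell and cloud
#'
#' An orthogroup present in all cultivars is core; in 2..(n-1) cultivars,
#' shell; in a single cultivar, cloud. Genes inherit their orthogroup's
#' class, and unclustered genes are cloud.
#'
#' @param orthogroups tibble with columns `og`, `cultivar`, `gene`.
#' @param n_cultivars total number of cultivars considered; defaults to
#'   the number present in `orthogroups`.
#' @param unclustered character vector of gene ids in no orthogroup (their
#'   cultivar is looked up in `gene_cultivar` when given).
#' @param gene_cultivar optional tibble `gene`, `cultivar` used to place
#'   unclustered genes for the per-cultivar proportions.
#' @return Object of class `pan_classification`: list with `og_class`
#'   (og, n_cultivars present, class), `gene_class` (gene, og, cultivar,
#'   class) and `proportions` (per cultivar, percent of genes per class).
#' @export
classify_pangenome <- function(orthogroups, n_cultivars = NULL,
                               unclustered = character(),
                               gene_cultivar = NULL) {
  n_cultivars <- n_cultivars %||% dplyr::n_distinct(orthogroups$cultivar)
  assert_that(n_cultivars >= 2, "need at least two cultivars")
  overlap <- intersect(unclustered, orthogroups$gene)
  assert_that(length(overlap) == 0,
              paste("unclustered genes also appear in orthogroups:",
                    paste(head(overlap, 5), collapse = ", ")))
  og_class <- orthogroups |>
    summarise(n_present = dplyr::n_distinct(.data$cultivar), .by = "og") |>
    mutate(class = case_when(
      .data$n_present >= n_cultivars ~ "core",
      .data$n_present > 1 ~ "shell",
      .data$n_present == 1 ~ "cloud")) |>
    arrange(.data$og)
  assert_that(all(og_class$n_present >= 1), "orthogroup with no members")
  gene_class <- orthogroups |>
    left_join(og_class |> select("og", "class"), by = "og") |>
    select("gene", "og", "cultivar", "class")
  if (length(unclustered) > 0) {
    uc <- tibble(gene = unclustered, og = NA_character_,
                 cultivar = NA_character_, class = "cloud")
    if (!is.null(gene_cultivar)) {
      uc$cultivar <- gene_cultivar$cultivar[match(uc$gene, gene_cultivar$gene)]
    }
    gene_class <- bind_rows(gene_class, uc)
  }
  gene_class <- gene_class |>
    mutate(class = factor(.data$class, levels = c("core", "shell", "cloud"))) |>
    arrange(.data$gene)
  proportions <- gene_class |>
    filter(!is.na(.data$cultivar)) |>
    count(.data$cultivar, .data$class, .drop = FALSE, name = "n") |>
    mutate(percent = 100 * .data$n / sum(.data$n), .by = "cultivar") |>
    arrange(.data$cultivar, .data$class)
  structure(list(og_class = og_class, gene_class = gene_class,
                 proportions = proportions, n_cultivars = n_cultivars),
            class = "pan_classification")
}

#' @export
print.pan_classification <- function(x, ...) {
  cat(sprintf("<pan_classification> %d orthogroups over %d cultivars\n",
              nrow(x$og_class), x$n_cultivars))
  print(count(x$og_class, .data$class))
  invisible(x)
}

#' @rdname classify_pangenome
#' @param x a `pan_classification`.
#' @param ... unused.
#' @export
tidy.pan_classification <- function(x, ...) x$proportions

#' @rdname classify_pangenome
#' @export
glance.pan_classification <- function(x, ...) {
  cl <- table(factor(x$og_class$class, c("core", "shell", "cloud")))
  tibble(n_orthogroups = nrow(x$og_class),
         n_cultivars = x$n_cultivars,
         core = as.integer(cl[["core"]]),
         shell = as.integer(cl[["shell"]]),
         cloud = as.integer(cl[["cloud"]]))
}

#' Exclusive presence-pattern intersections (UpSet counts)
#'
#' Counts each orthogroup under exactly one pattern: the exact set of
#' cultivars it is present in.
#'
#' @param orthogroups tibble with columns `og`, `cultivar`.
#' @return Tibble `pattern` (cultivars joined by `+`, sorted), `n_cultivars`,
#'   `n_orthogroups`; rows sorted by count descending, ties lexicographic.
#' @export
exclusive_intersections <- function(orthogroups) {
  orthogroups |>
    distinct(.data$og, .data$cultivar) |>
    summarise(pattern = paste(sort(unique(.data$cultivar)), collapse = "+"),
              n_cultivars = dplyr::n_distinct(.data$cultivar),
              .by = "og") |>
    count(.data$pattern, .data$n_cultivars, name = "n_orthogroups") |>
    arrange(desc(.data$n_orthogroups), .data$pattern)
}

#' Positional enrichment of a gene set in target regions
#'
#' One-sided Fisher's exact test (alternative: greater) that genes of
#' interest fall inside target regions more often than expected, from the
#' 2x2 table \[hits in, hits out; others in, others out\]. The odds ratio
#' is the sample odds ratio of the table, with a 0.5 continuity correction
#' applied to all cells only when some cell is zero.
#'
#' @param n_universe total number of genes.
#' @param n_in_regions number of genes falling in the target regions.
#' @param n_specific number of genes of interest.
#' @param n_specific_in number of genes of interest in the regions.
#' @return Tibble `odds_ratio`, `p_value`, plus the table cells.
#' @export
region_enrichment <- function(n_universe, n_in_regions, n_specific,
                              n_specific_in) {
  a <- n_specific_in
  b <- n_specific - n_specific_in
  c_ <- n_in_regions - n_specific_in
  d <- n_universe - n_specific - c_
  assert_that(all(c(a, b, c_, d) >= 0),
              "counts do not form a valid 2x2 contingency table")
  # upper tail of the hypergeometric: P(X >= a)
  p <- phyper(a - 1, n_specific, n_universe - n_specific, n_in_regions,
              lower.tail = FALSE)
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  tibble(odds_ratio = or, p_value = p,
         specific_in = a, specific_out = b,
         other_in = c_, other_out = d)
}

#' Overlap genes with regions
#'
#' Flags genes whose midpoint falls inside any region (1-based inclusive
#' coordinates on matching chromosomes of one cultivar).
#'
#' @param genes tibble with `gene`, `chromosome`, `start`, `end`.
#' @param regions tibble with `chromosome`, `start`, `end`.
#' @return `genes` with a logical `in_region` column.
#' @export
genes_in_regions <- function(genes, regions) {
  mid <- floor((genes$start + genes$end) / 2)
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    r <- regions[regions$chromosome == genes$chromosome[i], , drop = FALSE]
    any(mid[i] >= r$start & mid[i] <= r$end)
  }, logical(1))
  genes |> mutate(in_region = hit)
}
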