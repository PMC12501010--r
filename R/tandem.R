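# Tandem duplicate arrays: detection from gene order + family identity,
# expression balance, cross-cultivar chaining and chain conservation.

#' Detect tandem arrays from gene order
#'
#' Scans each chromosome's gene order for maximal runs of genes sharing a
#' family (orthogroup) id, allowing up to `max_gap` intervening
#' other-family genes between consecutive members. Runs of exactly two
#' members are TrueTandems; longer runs are TandemArrays.
#'
#' @param genes tibble with `gene`, `cultivar`, `chromosome`, `start` and
#'   a `family` column (e.g. orthogroup id); genes with `NA` family are
#'   skipped.
#' @param max_gap maximal number of intervening other-family genes
#'   (default 1).
#' @return Tibble with one row per array: `array_id`, `cultivar`,
#'   `chromosome`, `family`, `members` (list of gene ids in order),
#'   `n_members`, `kind`.
#' @export
detect_tandems <- function(genes, max_gap = 1L) {
  assert_that(is_count(max_gap) && max_gap >= 0, "`max_gap` must be >= 0")
  arrays <- list()
  ordered <- genes |> arrange(.data$cultivar, .data$chromosome, .data$start)
  for (key in split(seq_len(nrow(ordered)),
                    paste(ordered$cultivar, ordered$chromosome, sep = "\r"))) {
    chr <- ordered[key, ]
    fams <- chr$family
    n <- nrow(chr)
    # last position at which each family was seen, to extend runs across gaps
    open <- new.env(parent = emptyenv())   # family -> c(start_idx, last_idx)
    runs <- list()
    for (i in seq_len(n)) {
      f <- fams[i]
      if (is.na(f)) next
      prev <- open[[f]]
      if (!is.null(prev) && (i - prev[2] - 1) <= max_gap) {
        open[[f]] <- c(prev[1], i, prev[3] + 1L)
      } else {
        if (!is.null(prev) && prev[3] >= 2) runs[[length(runs) + 1]] <- prev
        open[[f]] <- c(i, i, 1L)
      }
    }
    for (f in ls(open)) {
      prev <- open[[f]]
      if (prev[3] >= 2) runs[[length(runs) + 1]] <- prev
    }
    for (r in runs) {
      idx <- r[1]:r[2]
      idx <- idx[!is.na(fams[idx]) & fams[idx] == fams[r[1]]]
      arrays[[length(arrays) + 1]] <- tibble(
        cultivar = chr$cultivar[1], chromosome = chr$chromosome[1],
        family = fams[r[1]], members = list(chr$gene[idx]),
        n_members = length(idx), first_start = chr$start[idx[1]])
    }
  }
  if (length(arrays) == 0) {
    return(tibble(array_id = character(), cultivar = character(),
                  chromosome = character(), family = character(),
                  members = list(), n_members = integer(),
                  kind = character()))
  }
  list_rbind(arrays) |>
    arrange(.data$cultivar, .data$chromosome, .data$first_start) |>
    mutate(array_id = sprintf("TA%05d", dplyr::row_number()),
           kind = ifelse(.data$n_members == 2, "TrueTandem", "TandemArray")) |>
    select("array_id", "cultivar", "chromosome", "family", "members",
           "n_members", "kind")
}

#' Expression balance of tandem arrays
#'
#' An array is unbalanced when one member carries at least `cutoff` of the
#' array's total mean normalized expression, or when exactly one member is
#' expressed at all; it is balanced otherwise. Arrays with no expressed
#' member are flagged `not-expressed` and excluded from balance counts.
#'
#' @param arrays output of [detect_tandems()].
#' @param cond_means output of [condition_means()] (mean normalized
#'   expression per gene and condition); member means are taken across all
#'   conditions of the array's cultivar.
#' @param cutoff maximal-share cutoff (default 0.8).
#' @return `arrays` with `max_share` and `balance` in
#'   {balanced, unbalanced, not-expressed}.
#' @export
array_balance <- function(arrays, cond_means, cutoff = 0.8) {
  check_fraction(cutoff, "cutoff")
  gene_mean <- cond_means |>
    summarise(expr = mean(.data$mean_norm), .by = c("gene", "cultivar"))
  lab <- function(members, cultivar) {
    e <- gene_mean$expr[match(paste(members, cultivar),
                              paste(gene_mean$gene, gene_mean$cultivar))]
    e[is.na(e)] <- 0
    if (all(e == 0)) return(list("not-expressed", NA_real_))
    share <- max(e) / sum(e)
    if (sum(e > 0) == 1 || share >= cutoff) list("unbalanced", share)
    else list("balanced", share)
  }
  res <- map2(arrays$members, arrays$cultivar, lab)
  arrays |>
    mutate(balance = map_chr(res, ~.x[[1]]),
           max_share = map_dbl(res, ~.x[[2]]))
}

#' Chain tandem arrays across cultivars
#'
#' Arrays in distinct cultivars sharing a family id form one chain; a
#' chain needs at least two cultivars, and a cultivar contributes at most
#' one array (the largest; ties to the leftmost on the chromosome).
#'
#' @param arrays (balanced) array table from [detect_tandems()] /
#'   [array_balance()].
#' @return Tibble with `chain_id`, `family`, `n_cultivars`, `array_ids`
#'   (list), `cultivars` (list).
#' @export
chain_arrays <- function(arrays) {
  if (nrow(arrays) == 0) {
    return(tibble(chain_id = character(), family = character(),
                  n_cultivars = integer(), array_ids = list(),
                  cultivars = list()))
  }
  picked <- arrays |>
    mutate(ord = dplyr::row_number()) |>
    slice_max(.data$n_members, n = 1, with_ties = TRUE,
              by = c("family", "cultivar")) |>
    slice_min(.data$ord, n = 1, by = c("family", "cultivar"))
  picked |>
    summarise(n_cultivars = dplyr::n_distinct(.data$cultivar),
              array_ids = list(.data$array_id),
              cultivars = list(.data$cultivar),
              .by = "family") |>
    filter(.data$n_cultivars >= 2) |>
    arrange(.data$family) |>
    mutate(chain_id = sprintf("CH%05d", dplyr::row_number())) |>
    select("chain_id", "family", "n_cultivars", "array_ids", "cultivars")
}

#' Conservation of expression balance along a chain
#'
#' A chain is `constant` when all its member arrays carry the same balance
#' label (all balanced or all unbalanced) and `variable` otherwise.
#' Member arrays flagged not-expressed count as a label of their own.
#'
#' @param chains output of [chain_arrays()].
#' @param arrays array table with `balance` labels ([array_balance()]).
#' @return `chains` with a `conservation` column.
#' @export
chain_conservation <- function(chains, arrays) {
  assert_that("balance" %in% names(arrays),
              "arrays lack balance labels; run array_balance() first")
  bal <- setNames(arrays$balance, arrays$array_id)
  cons <- map_chr(chains$array_ids, function(ids) {
    labs <- bal[ids]
    assert_that(all(!is.na(labs)),
                paste("array without balance label in chain:",
                      paste(ids[is.na(labs)], collapse = ", ")))
    if (length(unique(labs)) == 1) "constant" else "variable"
  })
  chains |> mutate(conservation = cons)
}
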