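# Co-expression module machinery downstream of network construction:
# eigengene extraction, inter-module Pearson distance, the divergence
# threshold (85% of the median of per-module maximum distances), triad
# same/similar/divergent classification, and metamodule detection across
# cultivar networks.

#' Module eigengene
#'
#' First principal axis of the module's standardized expression (genes
#' scaled to mean 0, sd 1 over samples), unit-norm over samples and
#' sign-oriented so that the mean correlation with member genes is
#' non-negative. Constant genes are dropped with a warning.
#'
#' @param expr matrix of member-gene expression, genes x samples (>= 2
#'   genes, >= 3 samples).
#' @return List with `eigengene` (named numeric over samples),
#'   `var_explained` (fraction), `n_genes`.
#' @export
module_eigengene <- function(expr) {
  expr <- as.matrix(expr)
  assert_that(ncol(expr) >= 3, "need >= 3 samples")
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("%d constant gene(s) dropped from module", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  assert_that(nrow(expr) >= 2, "need >= 2 non-constant member genes")
  z <- t(scale(t(expr)))                        # genes standardized
  sv <- svd(z)
  eig <- sv$v[, 1]
  # orient: mean correlation with member genes >= 0
  if (mean(cor(eig, t(z))) < 0) eig <- -eig
  names(eig) <- colnames(expr)
  list(eigengene = eig,
       var_explained = sv$d[1]^2 / sum(sv$d^2),
       n_genes = nrow(expr))
}

#' Eigengenes for every module of one cultivar network
#'
#' @param expr normalized expression matrix, genes x samples.
#' @param assignments tibble `gene`, `module` for one cultivar.
#' @param min_genes modules with fewer (non-constant) genes are skipped.
#' @return List with `eigengenes` (modules x samples matrix) and `info`
#'   (tibble `module`, `n_genes`, `var_explained`).
#' @export
module_eigengenes <- function(expr, assignments, min_genes = 2L) {
  mods <- sort(unique(assignments$module))
  rows <- list(); info <- list()
  for (m in mods) {
    gs <- intersect(assignments$gene[assignments$module == m],
                    rownames(expr))
    if (length(gs) < min_genes) next
    me <- module_eigengene(expr[gs, , drop = FALSE])
    rows[[m]] <- me$eigengene
    info[[m]] <- tibble(module = m, n_genes = me$n_genes,
                        var_explained = me$var_explained)
  }
  assert_that(length(rows) >= 1, "no module had enough member genes")
  list(eigengenes = do.call(rbind, rows), info = list_rbind(info))
}

#' Pairwise module distance matrix
#'
#' d_ij = 1 - Pearson r between module eigengenes; 0 for identical, 2 for
#' perfectly anti-correlated modules.
#'
#' @param eigengenes modules x samples matrix.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
module_distance_matrix <- function(eigengenes) {
  assert_that(nrow(eigengenes) >= 2, "need >= 2 modules")
  sds <- apply(eigengenes, 1, sd)
  assert_that(all(sds > 0), "constant eigengene: distance undefined")
  d <- 1 - cor(t(eigengenes))
  diag(d) <- 0
  d
}

#' Module-divergence threshold
#'
#' Per module, the maximum distance to any other module; M is the median
#' of those maxima and the threshold is `fraction x M`. Distances above
#' the threshold are divergent, below it similar.
#'
#' @param dist_matrix output of [module_distance_matrix()].
#' @param fraction similarity fraction (default 0.85).
#' @return Object of class `divergence_model`: list with `threshold`,
#'   `median_max`, `per_module_max` (named), `fraction`, `dist`.
#' @export
divergence_threshold <- function(dist_matrix, fraction = 0.85) {
  check_fraction(fraction, "fraction")
  assert_that(nrow(dist_matrix) >= 2, "need >= 2 modules")
  dm <- as.matrix(dist_matrix)
  diag(dm) <- NA
  mx <- apply(dm, 1, max, na.rm = TRUE)
  M <- median(mx)
  structure(list(threshold = fraction * M, median_max = M,
                 per_module_max = mx, fraction = fraction,
                 dist = as.matrix(dist_matrix)),
            class = "divergence_model")
}

#' @export
print.divergence_model <- function(x, ...) {
  cat(sprintf("<divergence_model> %d modules, median max distance %.4f, threshold %.4f (%.0f%%)\n",
              length(x$per_module_max), x$median_max, x$threshold,
              100 * x$fraction))
  invisible(x)
}

#' @rdname divergence_threshold
#' @param x a `divergence_model`.
#' @param ... unused.
#' @export
tidy.divergence_model <- function(x, ...) {
  tibble(module = names(x$per_module_max),
         max_distance = unname(x$per_module_max))
}

#' @rdname divergence_threshold
#' @export
glance.divergence_model <- function(x, ...) {
  tibble(n_modules = length(x$per_module_max),
         median_max = x$median_max, fraction = x$fraction,
         threshold = x$threshold)
}

#' Classify triads by their homoeologs' module placement
#'
#' Within one cultivar network: all three homoeologs in one module ->
#' `same`; spanning modules whose pairwise distances all stay at or below
#' the threshold -> `similar`; any pairwise distance above it ->
#' `divergent`; any unassigned homoeolog -> `incomplete`.
#'
#' @param triads tibble with `og` and module labels `module_A`,
#'   `module_B`, `module_D` (`NA` = unassigned).
#' @param model a [divergence_threshold()] result for the same network.
#' @return `triads` with `max_pair_dist` and `module_class`.
#' @export
classify_triad_modules <- function(triads, model) {
  stopifnot(inherits(model, "divergence_model"))
  d <- model$dist
  row1 <- function(ma, mb, md) {
    mods <- c(ma, mb, md)
    if (anyNA(mods)) return(tibble(max_pair_dist = NA_real_,
                                   module_class = "incomplete"))
    u <- unique(mods)
    if (length(u) == 1) return(tibble(max_pair_dist = 0,
                                      module_class = "same"))
    pr <- utils::combn(u, 2)
    mx <- max(d[cbind(pr[1, ], pr[2, ])])
    tibble(max_pair_dist = mx,
           module_class = if (mx > model$threshold) "divergent" else "similar")
  }
  extra <- list_rbind(pmap(list(triads$module_A, triads$module_B,
                                triads$module_D), row1))
  bind_cols(triads, extra)
}

# --- cluster validity indices (hand-rolled: defined on a dissimilarity) ---

#' Dunn index of a clustering
#'
#' Minimum between-cluster dissimilarity divided by the maximum
#' within-cluster diameter.
#'
#' @param d dissimilarity matrix.
#' @param labels cluster labels, one per row of `d`.
#' @return The Dunn index (Inf when all clusters are singletons).
#' @export
dunn_index <- function(d, labels) {
  d <- as.matrix(d)
  ks <- unique(labels)
  assert_that(length(ks) >= 2, "Dunn index needs >= 2 clusters")
  sep <- Inf; diam <- 0
  for (i in seq_along(ks)) {
    ii <- which(labels == ks[i])
    if (length(ii) > 1) diam <- max(diam, max(d[ii, ii]))
    for (j in seq_along(ks)) {
      if (j <= i) next
      jj <- which(labels == ks[j])
      sep <- min(sep, min(d[ii, jj]))
    }
  }
  if (diam == 0) return(Inf)
  sep / diam
}

#' Mean silhouette width of a clustering
#'
#' For each point, s = (b - a) / max(a, b) with a the mean dissimilarity
#' to its own cluster and b the smallest mean dissimilarity to another
#' cluster; singletons score 0.
#'
#' @param d dissimilarity matrix.
#' @param labels cluster labels.
#' @return Mean silhouette width over all points.
#' @export
mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- length(labels)
  ks <- unique(labels)
  assert_that(length(ks) >= 2, "silhouette needs >= 2 clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(ks, labels[i]), function(k2) {
      mean(d[i, labels == k2])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Detect metamodules across cultivar networks
#'
#' Pools module eigengenes from all cultivars (rows named
#' `cultivar:module`), computes the 1 - Pearson-r dissimilarity, clusters
#' by complete-linkage hierarchical clustering, and for each candidate k
#' cuts the tree and evaluates the mean silhouette width and Dunn index.
#' The chosen k maximizes the silhouette, with the Dunn index breaking
#' ties.
#'
#' @param eigengenes pooled matrix, module eigengenes x samples (columns
#'   condition-matched across cultivars).
#' @param k_range candidate numbers of metamodules (default 2:10; clipped
#'   to 2..n-1 with a warning if needed).
#' @param linkage hierarchical-clustering linkage (default "complete").
#' @return Object of class `metamodule_result`: list with `k`, `labels`
#'   (named), `quality` (tibble k, silhouette, dunn), `diss`, `tree`.
#' @export
find_metamodules <- function(eigengenes, k_range = 2:10,
                             linkage = "complete") {
  n <- nrow(eigengenes)
  assert_that(n >= 3, "need >= 3 eigengenes")
  kr <- sort(unique(as.integer(k_range)))
  if (any(kr < 2 | kr > n - 1)) {
    warn("k_range clipped to [2, n_eigengenes - 1]")
    kr <- kr[kr >= 2 & kr <= n - 1]
  }
  assert_that(length(kr) >= 1, "empty k_range after clipping")
  diss <- 1 - cor(t(eigengenes))
  diag(diss) <- 0
  tree <- hclust(as.dist(diss), method = linkage)
  qual <- map(kr, function(k) {
    labs <- cutree(tree, k = k)
    tibble(k = k,
           silhouette = mean_silhouette(diss, labs),
           dunn = dunn_index(diss, labs))
  }) |> list_rbind()
  best <- qual |>
    arrange(desc(.data$silhouette), desc(.data$dunn), .data$k) |>
    slice(1)
  labels <- cutree(tree, k = best$k)
  structure(list(k = best$k, labels = labels, quality = qual,
                 diss = diss, tree = tree),
            class = "metamodule_result")
}

#' @export
print.metamodule_result <- function(x, ...) {
  cat(sprintf("<metamodule_result> %d eigengenes -> %d metamodules\n",
              nrow(x$diss), x$k))
  print(x$quality)
  invisible(x)
}

#' @rdname find_metamodules
#' @param x a `metamodule_result`.
#' @param ... unused.
#' @export
tidy.metamodule_result <- function(x, ...) {
  tibble(eigengene = names(x$labels), metamodule = unname(x$labels))
}

#' @rdname find_metamodules
#' @export
glance.metamodule_result <- function(x, ...) {
  best <- x$quality[x$quality$k == x$k, ]
  tibble(n_eigengenes = nrow(x$diss), k = x$k,
         silhouette = best$silhouette, dunn = best$dunn)
}
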