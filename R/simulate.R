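# Synthetic pan-transcriptome generator. Emulates the structure the
# analysis assumes — 9+1 cultivars x 3 subgenomes, orthogroups with
# configurable core/shell/cloud proportions, negative-binomial counts over
# 6 tissues x 3 replicates with planted homoeolog-bias categories, planted
# tandem arrays, divergent introgression blocks, epitope occurrences and
# latent-factor module structure — with ground truth recorded for every
# planted feature.

#' Simulate a pan-genome skeleton
#'
#' Draws a presence pattern per orthogroup to match the requested
#' core/shell/cloud proportions (core: all cultivars; shell: a uniform
#' cardinality in 2..n-1 with cultivars chosen uniformly, or correlated
#' within `breeding_blocks`; cloud: one cultivar). Each present cultivar
#' receives one gene per subgenome, laid out in orthogroup order along one
#' chromosome per subgenome.
#'
#' @param n_cultivars number of cultivars (>= 2; default 10 = nine de novo
#'   cultivars plus a reference).
#' @param n_orthogroups number of orthogroups.
#' @param class_props length-3 proportions (core, shell, cloud) summing to
#'   1; defaults follow the pan-genome gene-class averages (62.5% core,
#'   36.6% shell, 0.9% cloud).
#' @param cultivars optional cultivar names.
#' @param gene_length,intergenic gene span and spacing in bp.
#' @param breeding_blocks optional list of cultivar-name vectors; a shell
#'   orthogroup is drawn from a block (its full member set) with
#'   probability `block_prob`, emulating breeding-programme sharing.
#' @param block_prob probability a shell orthogroup follows a block.
#' @param seed RNG seed.
#' @return Object of class `pan_sim`: list with `cultivars`, `genes`,
#'   `orthogroups`, `chrom_lengths`, `truth` and `params`.
#' @export
simulate_pangenome <- function(n_cultivars = 10, n_orthogroups = 1000,
                               class_props = c(core = 0.625,
                                               shell = 0.366,
                                               cloud = 0.009),
                               cultivars = NULL,
                               gene_length = 300, intergenic = 700,
                               breeding_blocks = NULL, block_prob = 0.5,
                               seed = 1) {
  assert_that(n_cultivars >= 2, "`n_cultivars` must be >= 2")
  assert_that(length(class_props) == 3 &&
                abs(sum(class_props) - 1) < 1e-9,
              "`class_props` must be 3 proportions summing to 1")
  cultivars <- cultivars %||% sprintf("cv%02d", seq_len(n_cultivars))
  assert_that(length(cultivars) == n_cultivars, "cultivar name mismatch")
  with_seed(seed, {
    cls <- sample(c("core", "shell", "cloud"), n_orthogroups,
                  replace = TRUE, prob = class_props)
    ogs <- sprintf("OG%06d", seq_len(n_orthogroups))
    presence <- map(seq_len(n_orthogroups), function(i) {
      switch(cls[i],
        core = cultivars,
        cloud = sample(cultivars, 1),
        shell = {
          if (!is.null(breeding_blocks) && runif(1) < block_prob) {
            blk <- breeding_blocks[[sample(length(breeding_blocks), 1)]]
            blk
          } else {
            card <- sample(2:(n_cultivars - 1), 1)
            sample(cultivars, card)
          }
        })
    })
    orthogroups <- tibble(og = rep(ogs, lengths(presence)),
                          cultivar = unlist(presence)) |>
      tidyr::expand_grid(subgenome = SUBGENOMES) |>
      mutate(gene = sprintf("%s_%s_%s", .data$cultivar, .data$subgenome,
                            sub("OG", "g", .data$og)))
    genes <- orthogroups |>
      arrange(.data$cultivar, .data$subgenome, .data$og) |>
      mutate(rank = dplyr::row_number(),
             .by = c("cultivar", "subgenome")) |>
      mutate(chromosome = paste0("chr1", .data$subgenome),
             start = (.data$rank - 1) * (gene_length + intergenic) + 1,
             end = .data$start + gene_length - 1,
             strand = "+", confidence = "HC") |>
      select("gene", "cultivar", "chromosome", "subgenome",
             "start", "end", "strand", "confidence")
    truth <- list(og_class = tibble(
      og = ogs, class = cls,
      n_present = lengths(presence),
      pattern = map_chr(presence, ~paste(sort(.x), collapse = "+"))))
    structure(list(cultivars = cultivars,
                   genes = genes,
                   orthogroups = orthogroups |>
                     select("og", "cultivar", "gene"),
                   chrom_lengths = genes |>
                     summarise(length = max(.data$end) + intergenic,
                               .by = c("cultivar", "chromosome")),
                   truth = truth,
                   params = list(n_cultivars = n_cultivars,
                                 n_orthogroups = n_orthogroups,
                                 class_props = class_props,
                                 gene_length = gene_length,
                                 intergenic = intergenic,
                                 seed = seed)),
              class = "pan_sim")
  })
}

#' @export
print.pan_sim <- function(x, ...) {
  cat(sprintf("<pan_sim> %d cultivars, %d orthogroups, %d genes%s\n",
              length(x$cultivars), nrow(x$truth$og_class), nrow(x$genes),
              if (is.null(x$counts)) "" else ", with expression"))
  invisible(x)
}

# Per-cultivar category distribution used for dynamic n-lets; balanced
# states dominate and B suppression is the commonest deviation, as seen
# in wheat 30-let surveys.
DYNAMIC_CATEGORY_PROBS <- c("Balanced" = 0.45,
                            "A-dominant" = 0.05, "B-dominant" = 0.05,
                            "D-dominant" = 0.05,
                            "A-suppressed" = 0.10, "B-suppressed" = 0.20,
                            "D-suppressed" = 0.10)

#' Simulate expression with planted homoeolog-bias categories
#'
#' Core orthogroups (one gene per subgenome in every cultivar) form
#' n-lets and receive a planted stability label; the per-cultivar bias
#' category determines the subgenome mean split (the category's ternary
#' centroid), and negative-binomial counts (var = mu + phi mu^2) are drawn
#' over `n_tissues` x `n_reps` samples per cultivar. Non-n-let genes get
#' independent baseline expression; a planted subset is tissue-specific.
#' Sample-level size factors are drawn log-uniformly from
#' `size_factor_range`.
#'
#' @param sim a [simulate_pangenome()] skeleton.
#' @param mean_range range of baseline total normalized expression per
#'   n-let (log-uniform draw).
#' @param dispersion negative-binomial dispersion phi (> 0).
#' @param stability_props planted proportions over
#'   stable-balanced / dynamic / stable-suppressed / stable-dominant /
#'   not-expressed; defaults follow the published 30-let partition
#'   (59.4 / 37.4 / 2.0 / 0.5 / 0.75%).
#' @param planted_bias optional explicit tibble `og`, `cultivar`,
#'   `category` overriding the random planting.
#' @param size_factor_range range of per-sample library-size factors.
#' @param n_tissues,n_reps design (defaults 6 tissues, 3 replicates).
#' @param tissue_spread log-normal sd multiplier of per-tissue effects
#'   (default 2: one sd spans a twofold change).
#' @param prop_tissue_specific fraction of non-n-let genes planted as
#'   strictly tissue-specific.
#' @param jitter_dynamic blend weight pulling dynamic n-lets' expression
#'   points from their centroid toward a random simplex point (0
#'   disables); the truth category is the nearest centroid of the blended
#'   point.
#' @param seed RNG seed.
#' @return `sim` with `$counts` (an [expression_bundle()]) and truth
#'   entries `nlet_stability`, `bias` (og x cultivar category) and
#'   `tissue_specific`.
#' @export
simulate_expression <- function(sim,
                                mean_range = c(30, 300),
                                dispersion = 0.05,
                                stability_props = c(
                                  "stable-balanced" = 0.594,
                                  "dynamic" = 0.374,
                                  "stable-suppressed" = 0.020,
                                  "stable-dominant" = 0.0045,
                                  "not-expressed" = 0.0075),
                                planted_bias = NULL,
                                size_factor_range = c(0.7, 1.4),
                                n_tissues = 6, n_reps = 3,
                                tissue_spread = 2,
                                prop_tissue_specific = 0.05,
                                jitter_dynamic = 0.2,
                                seed = 1) {
  stopifnot(inherits(sim, "pan_sim"))
  assert_that(dispersion > 0, "`dispersion` must be > 0")
  assert_that(n_tissues >= 1 && n_tissues <= length(TISSUES),
              sprintf("`n_tissues` must be in 1..%d", length(TISSUES)))
  tissues <- TISSUES[seq_len(n_tissues)]
  cultivars <- sim$cultivars
  with_seed(seed, {
    meta <- tidyr::expand_grid(cultivar = cultivars, tissue = tissues,
                               replicate = seq_len(n_reps)) |>
      mutate(sample = sprintf("%s_%s_r%d", .data$cultivar, .data$tissue,
                              .data$replicate))
    sf <- exp(runif(nrow(meta), log(size_factor_range[1]),
                    log(size_factor_range[2])))
    names(sf) <- meta$sample

    core_ogs <- sim$truth$og_class$og[sim$truth$og_class$class == "core"]
    if (is.null(planted_bias)) {
      stability_props <- stability_props / sum(stability_props)
      labels <- sample(names(stability_props), length(core_ogs),
                       replace = TRUE, prob = stability_props)
      cats7 <- names(DYNAMIC_CATEGORY_PROBS)
      bias <- map2(core_ogs, labels, function(og, lab) {
        cat_vec <- switch(lab,
          "stable-balanced" = rep("Balanced", length(cultivars)),
          "stable-dominant" = rep(sample(paste0(SUBGENOMES, "-dominant"), 1),
                                  length(cultivars)),
          "stable-suppressed" = rep(sample(paste0(SUBGENOMES, "-suppressed"), 1),
                                    length(cultivars)),
          "not-expressed" = rep("NotExpressed", length(cultivars)),
          "dynamic" = {
            v <- sample(cats7, length(cultivars), replace = TRUE,
                        prob = DYNAMIC_CATEGORY_PROBS)
            while (length(unique(v)) == 1) {
              v[sample(length(v), 1)] <- sample(setdiff(cats7, v[1]), 1)
            }
            v
          })
        tibble(og = og, cultivar = cultivars, category = cat_vec)
      }) |> list_rbind()
      nlet_stability <- tibble(og = core_ogs, label = labels)
    } else {
      bias <- planted_bias
      nlet_stability <- bias |>
        summarise(label = if (dplyr::n_distinct(.data$category) > 1) "dynamic"
                  else if (.data$category[1] == "NotExpressed") "not-expressed"
                  else if (.data$category[1] == "Balanced") "stable-balanced"
                  else if (grepl("dominant", .data$category[1])) "stable-dominant"
                  else "stable-suppressed",
                  .by = "og")
    }

    cen <- bias_centroids()
    # target expression shares per (og, cultivar): the planted category's
    # centroid, blended toward a random simplex point for dynamic n-lets
    # (dynamic triads sit away from the pure centroids); the truth
    # category is re-derived from the blended point, so it is always the
    # noiseless nearest-centroid classification
    shares <- cen[ifelse(bias$category == "NotExpressed", "Balanced",
                         bias$category), , drop = FALSE]
    rownames(shares) <- paste(bias$og, bias$cultivar)
    if (is.null(planted_bias) && jitter_dynamic > 0) {
      dyn_ogs <- nlet_stability$og[nlet_stability$label == "dynamic"]
      jdx <- which(bias$og %in% dyn_ogs & bias$category != "NotExpressed")
      if (length(jdx) > 0) {
        q <- matrix(rexp(3 * length(jdx)), ncol = 3)
        q <- q / rowSums(q)
        shares[jdx, ] <- (1 - jitter_dynamic) * shares[jdx, ] +
          jitter_dynamic * q
        rel <- relative_expression(shares[jdx, 1], shares[jdx, 2],
                                   shares[jdx, 3])
        bias$category[jdx] <-
          as.character(classify_bias(rel, not_expressed_cutoff = 0)$category)
      }
      # truth labels re-derived from the (possibly re-classified) categories
      nlet_stability <- bias |>
        summarise(label = {
          u <- unique(.data$category)
          if (length(u) > 1) "dynamic"
          else if (u == "NotExpressed") "not-expressed"
          else if (u == "Balanced") "stable-balanced"
          else if (grepl("dominant", u)) "stable-dominant"
          else "stable-suppressed"
        }, .by = "og")
    }
    base_total <- setNames(exp(runif(length(core_ogs), log(mean_range[1]),
                                     log(mean_range[2]))), core_ogs)
    genes <- sim$genes
    all_genes <- genes$gene
    raw <- matrix(NA_real_, nrow = length(all_genes), ncol = nrow(meta),
                  dimnames = list(all_genes, meta$sample))

    og_of <- setNames(sim$orthogroups$og, sim$orthogroups$gene)
    sub_of <- setNames(genes$subgenome, genes$gene)
    cult_of <- setNames(genes$cultivar, genes$gene)

    # planted tissue-specific genes among non-n-let genes
    non_nlet <- all_genes[!(og_of[all_genes] %in% core_ogs)]
    n_ts <- floor(prop_tissue_specific * length(non_nlet))
    ts_genes <- if (n_ts > 0) sample(non_nlet, n_ts) else character()
    ts_tissue <- setNames(sample(intersect(TAU_TISSUES, tissues),
                                 length(ts_genes), replace = TRUE),
                          ts_genes)

    bias_key <- setNames(bias$category, paste(bias$og, bias$cultivar))
    for (cv in cultivars) {
      ss <- meta$sample[meta$cultivar == cv]
      tiss <- meta$tissue[meta$cultivar == cv]
      gsel <- all_genes[cult_of[all_genes] == cv]
      mu <- matrix(0, nrow = length(gsel), ncol = length(ss),
                   dimnames = list(gsel, ss))
      ogs_g <- og_of[gsel]
      is_nlet <- ogs_g %in% core_ogs
      # per (og, tissue) effect shared by the three homoeologs
      u_ogs <- unique(ogs_g[is_nlet])
      t_eff <- matrix(exp(rnorm(length(u_ogs) * length(tissues),
                                0, log(tissue_spread))),
                      nrow = length(u_ogs),
                      dimnames = list(u_ogs, tissues))
      for (i in which(is_nlet)) {
        og <- ogs_g[i]
        cat_i <- bias_key[[paste(og, cv)]]
        share <- if (identical(cat_i, "NotExpressed")) 1 / 3
          else shares[paste(og, cv), sub_of[[gsel[i]]]]
        tot <- if (identical(cat_i, "NotExpressed")) 0.05
          else base_total[[og]]
        mu[i, ] <- tot * share * t_eff[og, tiss]
      }
      ni <- which(!is_nlet)
      if (length(ni) > 0) {
        base_g <- exp(runif(length(ni), log(mean_range[1]),
                            log(mean_range[2])))
        eff <- matrix(exp(rnorm(length(ni) * length(tissues),
                                0, log(tissue_spread))),
                      nrow = length(ni), dimnames = list(NULL, tissues))
        mu[ni, ] <- base_g * eff[, tiss]
        ts_here <- which(gsel %in% ts_genes)
        for (i in ts_here) {
          on <- tiss == ts_tissue[[gsel[i]]]
          mu[i, !on] <- 0
          mu[i, on] <- max(mean_range) # strong, single-tissue expression
        }
      }
      mu <- sweep(mu, 2, sf[ss], "*")
      raw[gsel, ss] <- rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }

    sim$counts <- expression_bundle(raw, meta)
    sim$truth$size_factors <- sf
    sim$truth$nlet_stability <- nlet_stability
    sim$truth$bias <- bias
    sim$truth$tissue_specific <- tibble(gene = ts_genes,
                                        tissue = unname(ts_tissue))
    sim$params$expression <- list(mean_range = mean_range,
                                  dispersion = dispersion,
                                  n_tissues = n_tissues, n_reps = n_reps,
                                  seed = seed)
    sim
  })
}

#' Plant tandem arrays into a skeleton
#'
#' Chooses orthogroup families and cultivars, inserts extra adjacent gene
#' copies of the family on the same chromosome (making runs of the
#' requested sizes), and records planted membership, the planted balance
#' of each array, and the planted chain conservation of each family.
#' Chromosome coordinates are re-spaced afterwards so gene order is the
#' planted order. Must be called before [simulate_expression()] if planted
#' balance is to drive counts.
#'
#' @param sim a [simulate_pangenome()] skeleton.
#' @param n_families number of tandem families to plant.
#' @param cultivars_per_family how many cultivars carry each family's
#'   array (recycled; >= 2 gives chains).
#' @param array_size copies per array (2 = TrueTandem; recycled).
#' @param constant_fraction fraction of families whose arrays share one
#'   balance label across cultivars (planted chain conservation; default
#'   0.53 as observed for wheat tandem chains).
#' @param balanced_fraction fraction of balanced arrays among constant
#'   chains (and per-array probability elsewhere).
#' @param seed RNG seed.
#' @return `sim` with extra genes, updated coordinates, and truth entries
#'   `tandems` (per planted array) and `tandem_chains` (per family).
#' @export
plant_tandem_arrays <- function(sim, n_families = 20,
                                cultivars_per_family = 3,
                                array_size = 2,
                                constant_fraction = 0.53,
                                balanced_fraction = 0.3,
                                seed = 1) {
  stopifnot(inherits(sim, "pan_sim"))
  with_seed(seed, {
    # families: core orthogroups, arrays planted on the A chromosome
    cand <- sim$truth$og_class$og[sim$truth$og_class$class == "core"]
    assert_that(length(cand) >= n_families,
                "not enough core orthogroups to plant tandem families")
    fams <- sort(sample(cand, n_families))
    cpf <- rep_len(cultivars_per_family, n_families)
    asz <- rep_len(array_size, n_families)
    constant <- runif(n_families) < constant_fraction
    chain_balance <- ifelse(runif(n_families) < balanced_fraction,
                            "balanced", "unbalanced")
    new_rows <- list(); truth_rows <- list(); chain_rows <- list()
    for (i in seq_len(n_families)) {
      cvs <- sample(sim$cultivars, cpf[i])
      labels <- if (constant[i]) rep(chain_balance[i], cpf[i]) else {
        l <- ifelse(runif(cpf[i]) < balanced_fraction,
                    "balanced", "unbalanced")
        while (length(unique(l)) == 1) {
          l[sample(cpf[i], 1)] <- setdiff(c("balanced", "unbalanced"),
                                          l[1])
        }
        l
      }
      sub_of <- setNames(sim$genes$subgenome, sim$genes$gene)
      for (j in seq_along(cvs)) {
        anchor <- sim$orthogroups |>
          filter(.data$og == fams[i], .data$cultivar == cvs[j],
                 sub_of[.data$gene] == "A")
        copies <- sprintf("%s_c%d", anchor$gene, seq_len(asz[i] - 1) + 1)
        new_rows[[length(new_rows) + 1]] <- tibble(
          og = fams[i], cultivar = cvs[j], gene = copies, subgenome = "A",
          anchor = anchor$gene)
        truth_rows[[length(truth_rows) + 1]] <- tibble(
          family = fams[i], cultivar = cvs[j],
          members = list(c(anchor$gene, copies)),
          n_members = asz[i], balance = labels[j])
      }
      chain_rows[[length(chain_rows) + 1]] <- tibble(
        family = fams[i], n_cultivars = cpf[i],
        conservation = if (constant[i]) "constant" else "variable")
    }
    new_rows <- list_rbind(new_rows)
    anchors <- sim$genes[match(new_rows$anchor, sim$genes$gene), ]
    added <- anchors |>
      mutate(gene = new_rows$gene,
             start = .data$start + seq_len(nrow(new_rows)) * 1e-3)
    genes <- bind_rows(sim$genes, added) |>
      arrange(.data$cultivar, .data$chromosome, .data$start) |>
      mutate(rank = dplyr::row_number(),
             .by = c("cultivar", "chromosome")) |>
      mutate(start = (.data$rank - 1) *
               (sim$params$gene_length + sim$params$intergenic) + 1,
             end = .data$start + sim$params$gene_length - 1) |>
      select(-"rank")
    sim$genes <- genes
    sim$orthogroups <- bind_rows(sim$orthogroups,
                                 new_rows |> select("og", "cultivar",
                                                    "gene"))
    sim$chrom_lengths <- genes |>
      summarise(length = max(.data$end) + sim$params$intergenic,
                .by = c("cultivar", "chromosome"))
    sim$truth$tandems <- list_rbind(truth_rows)
    sim$truth$tandem_chains <- list_rbind(chain_rows)
    sim
  })
}

#' Apply planted tandem balance to a simulated count matrix
#'
#' Rescales the planted arrays' member means so that balanced arrays have
#' equal member expression and unbalanced arrays concentrate 95% of the
#' array total on one member. Redraws the members' counts.
#'
#' @param sim a `pan_sim` with counts and planted tandems.
#' @param dispersion negative-binomial dispersion for the redraw.
#' @param total mean array-total normalized expression.
#' @param seed RNG seed.
#' @return `sim` with updated counts.
#' @export
apply_tandem_balance <- function(sim, dispersion = 0.05, total = 100,
                                 seed = 1) {
  stopifnot(inherits(sim, "pan_sim"), !is.null(sim$counts),
            !is.null(sim$truth$tandems))
  with_seed(seed, {
    raw <- sim$counts$raw
    meta <- sim$counts$meta
    sf <- sim$truth$size_factors
    td <- sim$truth$tandems
    for (i in seq_len(nrow(td))) {
      mem <- td$members[[i]]
      ss <- meta$sample[meta$cultivar == td$cultivar[i]]
      share <- if (td$balance[i] == "balanced") {
        rep(1 / length(mem), length(mem))
      } else {
        s <- rep(0.05 / (length(mem) - 1), length(mem))
        s[sample(length(mem), 1)] <- 0.95
        s
      }
      mu <- outer(share * total, sf[ss])
      raw[mem, ss] <- rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    sim$counts$raw <- raw
    sim$counts$normalized <- NULL
    sim$counts$size_factors <- NULL
    sim
  })
}

#' Generate genome sequences for a skeleton
#'
#' Orthologous genes share one ancestral sequence per (orthogroup,
#' subgenome) — identical across cultivars, so self- and cross-genome
#' k-mer coverage is 1 before any planted divergence — while intergenic
#' sequence is drawn independently per cultivar.
#'
#' @param sim a `pan_sim`.
#' @param seed RNG seed.
#' @return `sim` with `$genomes`: per cultivar, a named character vector
#'   of chromosome sequences.
#' @export
simulate_genomes <- function(sim, seed = 1) {
  stopifnot(inherits(sim, "pan_sim"))
  with_seed(seed, {
    gl <- sim$params$gene_length
    # one ancestral sequence per gene "slot": orthogroup x subgenome (and
    # per extra tandem copy id, so copies are identical too)
    slot <- sub("^[^_]+_", "", sim$genes$gene)      # strip cultivar prefix
    u_slots <- unique(slot)
    anc <- setNames(vapply(u_slots, function(s) random_dna(gl),
                           character(1)), u_slots)
    genomes <- list()
    for (cv in sim$cultivars) {
      g <- sim$genes |> filter(.data$cultivar == cv)
      chroms <- list()
      for (chr in sort(unique(g$chromosome))) {
        gc <- g |> filter(.data$chromosome == chr) |> arrange(.data$start)
        len <- sim$chrom_lengths$length[
          sim$chrom_lengths$cultivar == cv &
            sim$chrom_lengths$chromosome == chr]
        # build by concatenating intergenic gaps and ancestral gene bodies
        gaps <- gc$start - c(0, head(gc$end, -1)) - 1
        pieces <- character(2 * nrow(gc) + 1)
        for (i in seq_len(nrow(gc))) {
          pieces[2 * i - 1] <- if (gaps[i] > 0) random_dna(gaps[i]) else ""
          pieces[2 * i] <- anc[[sub("^[^_]+_", "", gc$gene[i])]]
        }
        tail_len <- len - gc$end[nrow(gc)]
        pieces[2 * nrow(gc) + 1] <- if (tail_len > 0) random_dna(tail_len)
          else ""
        chroms[[chr]] <- paste(pieces, collapse = "")
      }
      genomes[[cv]] <- unlist(chroms)
    }
    sim$genomes <- genomes
    sim
  })
}

#' Plant a divergent (introgression-like) block into a chromosome
#'
#' Substitutes bases i.i.d. at the given rate inside the interval,
#' leaving the rest of the sequence untouched.
#'
#' @param sequence chromosome sequence (character scalar).
#' @param start,end 1-based inclusive interval within the sequence.
#' @param divergence substitution rate in (0, 1].
#' @param seed RNG seed.
#' @return List with `sequence` (mutated) and `truth` (tibble `start`,
#'   `end`, `divergence`, `n_substituted`).
#' @export
plant_introgression <- function(sequence, start, end, divergence, seed = 1) {
  assert_that(divergence >= 0 && divergence <= 1,
              "`divergence` must be in [0, 1]")
  assert_that(start >= 1 && end <= nchar(sequence) && start <= end,
              "interval out of chromosome bounds")
  if (divergence == 0) {
    return(list(sequence = sequence,
                truth = tibble(start = start, end = end,
                               divergence = 0, n_substituted = 0L)))
  }
  with_seed(seed, {
    idx <- start:end
    hit <- idx[runif(length(idx)) < divergence]
    out <- sequence
    if (length(hit) > 0) {
      ds <- Biostrings::DNAString(sequence)
      old <- strsplit(as.character(ds[hit]), "")[[1]]
      bases <- c("A", "C", "G", "T")
      # substitute to a uniformly drawn different base
      shift <- sample(1:3, length(hit), replace = TRUE)
      oldi <- match(old, bases)
      newb <- bases[((oldi - 1 + shift) %% 4) + 1]
      newb[is.na(oldi)] <- old[is.na(oldi)]   # leave non-ACGT untouched
      out <- as.character(Biostrings::replaceLetterAt(
        ds, hit, paste(newb, collapse = "")))
    }
    list(sequence = out,
         truth = tibble(start = start, end = end, divergence = divergence,
                        n_substituted = length(hit)))
  })
}

#' Plant epitope motif occurrences into gene sequences
#'
#' Writes the requested number of non-overlapping concrete realizations
#' of a degenerate consensus into each designated gene, then verifies by
#' scanning that exactly that many occurrences are present (redrawing the
#' background on accidental extra matches).
#'
#' @param gene_seqs named character vector of gene sequences.
#' @param motifs tibble from [reverse_translate_consensus()].
#' @param copies tibble `gene`, `motif`, `n` requested occurrences.
#' @param seed RNG seed.
#' @return List with `gene_seqs` (modified) and `truth` (= `copies`).
#' @export
plant_epitope_genes <- function(gene_seqs, motifs, copies, seed = 1) {
  with_seed(seed, {
    realize <- function(consensus) {
      paste(vapply(strsplit(consensus, "")[[1]], function(cc) {
        bases <- c("A", "C", "G", "T")[bitwAnd(IUPAC_MASK[[cc]],
                                               c(1L, 2L, 4L, 8L)) != 0]
        sample(bases, 1)
      }, character(1)), collapse = "")
    }
    for (i in seq_len(nrow(copies))) {
      g <- copies$gene[i]
      mrow <- motifs[motifs$name == copies$motif[i], ]
      k <- nchar(mrow$consensus)
      n <- copies$n[i]
      L <- nchar(gene_seqs[[g]])
      assert_that(n * k <= L,
                  sprintf("%d copies of a %d-nt motif cannot fit in %s (%d nt)",
                          n, k, g, L))
      for (try in 1:10) {
        seqc <- strsplit(random_dna(L), "")[[1]]
        if (n > 0) {
          # non-overlapping starts on a k-spaced grid
          grid <- seq(1, L - k + 1, by = k)
          starts <- sort(sample(grid, n))
          for (s in starts) {
            seqc[s:(s + k - 1)] <- strsplit(realize(mrow$consensus), "")[[1]]
          }
        }
        cand <- paste(seqc, collapse = "")
        if (nrow(scan_motif(cand, mrow$consensus)) == n) break
        assert_that(try < 10, "could not realize the requested occurrence count")
      }
      gene_seqs[[g]] <- cand
    }
    list(gene_seqs = gene_seqs, truth = copies)
  })
}

#' Simulate latent-factor module structure across cultivar networks
#'
#' Each cultivar network gets `modules_per_cultivar` modules assigned
#' round-robin to `n_factors` latent factors (orthonormal random profiles
#' over the samples); module member genes load positively on their factor
#' plus Gaussian noise. Metamodules should recover the factor grouping.
#'
#' @param n_cultivars number of cultivar networks (default 4).
#' @param modules_per_cultivar modules per network (default 17, giving 68
#'   eigengenes at the default cultivar count).
#' @param n_factors latent factor count (default 6).
#' @param genes_per_module member genes per module.
#' @param n_samples samples per network (default 18 = 6 tissues x 3 reps).
#' @param noise_sd residual sd around the factor profile.
#' @param seed RNG seed.
#' @return List of class `module_sim`: per cultivar `expr` (genes x
#'   samples) and `assignments`, plus `truth` (module -> factor).
#' @export
simulate_module_data <- function(n_cultivars = 4, modules_per_cultivar = 17,
                                 n_factors = 6, genes_per_module = 30,
                                 n_samples = 18, noise_sd = 0.3, seed = 1) {
  assert_that(n_factors >= 2, "need >= 2 factors")
  assert_that(n_samples > n_factors, "need more samples than factors")
  with_seed(seed, {
    fac <- qr.Q(qr(matrix(rnorm(n_samples * n_factors), n_samples)))
    fac <- t(fac) * sqrt(n_samples)          # factors x samples, sd ~ 1
    cultivars <- sprintf("net%d", seq_len(n_cultivars))
    samples <- sprintf("s%02d", seq_len(n_samples))
    colnames(fac) <- samples
    out <- list(); truth <- list()
    for (ci in seq_along(cultivars)) {
      cv <- cultivars[ci]
      mods <- sprintf("%s_m%02d", cv, seq_len(modules_per_cultivar))
      factor_of <- ((seq_len(modules_per_cultivar) - 1) %% n_factors) + 1
      expr <- list(); assign <- list()
      for (mi in seq_along(mods)) {
        load <- runif(genes_per_module, 0.5, 1.5)
        e <- outer(load, fac[factor_of[mi], ]) +
          matrix(rnorm(genes_per_module * n_samples, 0, noise_sd),
                 genes_per_module)
        rownames(e) <- sprintf("%s_g%03d", mods[mi],
                               seq_len(genes_per_module))
        expr[[mi]] <- e
        assign[[mi]] <- tibble(gene = rownames(e), module = mods[mi])
      }
      out[[cv]] <- list(expr = do.call(rbind, expr),
                        assignments = list_rbind(assign))
      truth[[cv]] <- tibble(cultivar = cv, module = mods,
                            factor = factor_of)
    }
    structure(list(networks = out, truth = list_rbind(truth),
                   factors = fac,
                   params = list(n_cultivars = n_cultivars,
                                 modules_per_cultivar = modules_per_cultivar,
                                 n_factors = n_factors, seed = seed)),
              class = "module_sim")
  })
}
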