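# Pipeline orchestration: run every analysis stage in dependency order on
# a dataset bundle, writing one TSV per result table plus a JSON manifest.

#' Extract gene sequences from genome sequences
#'
#' @param genomes named list (per cultivar) of named chromosome sequences.
#' @param genes gene tibble (`gene`, `cultivar`, `chromosome`, `start`,
#'   `end`).
#' @return Named character vector of gene sequences.
#' @export
gene_sequences <- function(genomes, genes) {
  out <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    chr <- genomes[[genes$cultivar[i]]][[genes$chromosome[i]]]
    out[i] <- substr(chr, genes$start[i], genes$end[i])
  }
  setNames(out, genes$gene)
}

#' Simulate a complete dataset bundle
#'
#' Convenience wrapper chaining the generator stages: pan-genome skeleton,
#' planted tandem arrays, expression with planted bias, planted tandem
#' balance, genome sequences, a couple of target regions, planted epitope
#' occurrences and module assignments — everything [run_pipeline()]
#' consumes, with full ground truth attached.
#'
#' @param n_cultivars,n_orthogroups skeleton size.
#' @param with_genomes emit genome sequences (enables the k-mer and
#'   epitope stages).
#' @param n_module_cultivars cultivars given module assignments.
#' @param seed RNG seed; stage seeds are derived deterministically.
#' @param ... forwarded to [simulate_expression()].
#' @return A `pan_sim` usable as a dataset bundle.
#' @export
simulate_bundle <- function(n_cultivars = 6, n_orthogroups = 80,
                            with_genomes = TRUE, n_module_cultivars = 2,
                            seed = 1, ...) {
  sim <- simulate_pangenome(n_cultivars = n_cultivars,
                            n_orthogroups = n_orthogroups,
                            seed = child_seed(seed, "pangenome"))
  sim <- plant_tandem_arrays(sim, n_families = max(3, n_orthogroups %/% 20),
                             seed = child_seed(seed, "tandem"))
  sim <- simulate_expression(sim, seed = child_seed(seed, "expression"), ...)
  sim <- apply_tandem_balance(sim, seed = child_seed(seed, "balance"))
  if (with_genomes) {
    sim <- simulate_genomes(sim, seed = child_seed(seed, "genomes"))
    # target regions on the first cultivar's A chromosome
    len <- sim$chrom_lengths$length[sim$chrom_lengths$cultivar ==
                                      sim$cultivars[1]][1]
    sim$regions <- tibble(chromosome = "chr1A",
                          start = c(1, floor(len / 2)),
                          end = c(floor(len / 4), floor(len * 0.6)))
    sim$epitopes <- bind_rows(
      reverse_translate_consensus("PQPQLPY", name = "glia-a1",
                                  group = "alpha-gliadin"),
      reverse_translate_consensus("QQPFP", name = "glia-g1",
                                  group = "gamma-gliadin"))
  }
  # module assignments over expressed non-core genes
  mods <- list()
  cvs <- head(sim$cultivars, n_module_cultivars)
  core <- sim$truth$og_class$og[sim$truth$og_class$class == "core"]
  for (cv in cvs) {
    gs <- sim$orthogroups |>
      filter(.data$cultivar == cv, !(.data$og %in% core))
    gs <- head(gs$gene, 30)
    if (length(gs) >= 12) {
      mods[[cv]] <- tibble(cultivar = cv, gene = gs,
                           module = paste0("m", rep(1:3, length.out =
                                                      length(gs))))
    }
  }
  if (length(mods) > 0) sim$modules <- list_rbind(mods)
  sim
}

PIPELINE_STAGES <- c("normalize", "pangenome", "nlets", "bias", "tau",
                     "tandem", "kmer", "epitope", "network")

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — normalize, pangenome, nlets,
#' bias, tau, tandem, kmer, epitope, network — writing one TSV per result
#' table under `out_dir` plus `manifest.json` recording the configuration,
#' seed and per-stage status. Stages whose inputs are absent from the
#' bundle (genomes, epitopes, module assignments) are recorded as skipped;
#' a stage error aborts after writing a manifest naming the failed stage.
#'
#' @param bundle a `pan_sim` or `pan_bundle`.
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return Named list of result tibbles, invisibly.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pantriad_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- setNames(rep("pending", length(PIPELINE_STAGES)),
                     PIPELINE_STAGES)
  results <- list()
  env <- new.env()
  wtsv <- function(df, name) {
    readr::write_tsv(df, file.path(out_dir, paste0(name, ".tsv")))
    results[[name]] <<- df
  }
  finish <- function(failed = NULL, error = NULL) {
    manifest <- list(config = unclass(config),
                     seed = config$rng_seed,
                     stages = as.list(status),
                     failed_stage = failed, error = error)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  run_stage <- function(name, can_run, fn) {
    if (!can_run) { status[name] <<- "skipped"; return() }
    tryCatch({ fn(); status[name] <<- "completed" },
             error = function(e) {
               status[name] <<- "failed"
               finish(failed = name, error = conditionMessage(e))
               abort(sprintf("pipeline stage '%s' failed: %s", name,
                             conditionMessage(e)))
             })
  }

  run_stage("normalize", !is.null(bundle$counts), function() {
    env$eb <- normalize_bundle(bundle$counts)
    wtsv(tibble(sample = names(env$eb$size_factors),
                size_factor = unname(env$eb$size_factors)) |>
           arrange(.data$sample), "size_factors")
    wtsv(as_tibble(env$eb$normalized, rownames = "gene") |>
           arrange(.data$gene), "normalized")
    env$cm <- condition_means(env$eb)
  })

  run_stage("pangenome", TRUE, function() {
    pc <- classify_pangenome(bundle$orthogroups,
                             n_cultivars = length(bundle$cultivars))
    env$pan <- pc
    wtsv(pc$gene_class |> arrange(.data$gene), "panclass")
    wtsv(exclusive_intersections(bundle$orthogroups), "intersections")
    if (!is.null(bundle$regions)) {
      enr <- list()
      for (cv in bundle$cultivars) {
        g <- bundle$genes |> filter(.data$cultivar == cv)
        spec <- pc$gene_class |>
          filter(.data$cultivar == cv, .data$class == "cloud")
        hit <- genes_in_regions(g, bundle$regions)
        enr[[cv]] <- region_enrichment(
          n_universe = nrow(g),
          n_in_regions = sum(hit$in_region),
          n_specific = nrow(spec),
          n_specific_in = sum(hit$in_region[hit$gene %in% spec$gene])) |>
          mutate(cultivar = cv, .before = 1)
      }
      wtsv(list_rbind(enr) |> arrange(.data$cultivar), "enrichment")
    }
  })

  run_stage("nlets", TRUE, function() {
    env$nlets <- build_nlets(bundle$orthogroups, bundle$genes)
    wtsv(env$nlets, "nlets")
  })

  run_stage("bias", !is.null(bundle$counts), function() {
    nb <- nlet_bias(env$nlets, env$cm,
                    not_expressed_cutoff = config$not_expressed_cutoff)
    env$bias <- nb
    wtsv(nb |> select("og", "cultivar", "rA", "rB", "rD", "T",
                      "category", "centroid_dist") |>
           arrange(.data$og, .data$cultivar), "bias_per_cultivar")
    sp <- stability_partition(nb)
    env$stability <- sp
    wtsv(sp$per_nlet, "stability")
    wtsv(nb |> select("og", "cultivar", "rA", "rB", "rD") |>
           arrange(.data$og, .data$cultivar), "ternary_coords")
  })

  run_stage("tau", !is.null(bundle$counts), function() {
    tt <- intersect(TAU_TISSUES, unique(env$eb$meta$tissue))
    wtsv(tissue_specificity(env$cm, tissues = tt,
                            threshold = config$tau_threshold), "tau")
  })

  run_stage("tandem", !is.null(bundle$counts), function() {
    fam <- bundle$genes |>
      left_join(bundle$orthogroups |> select("gene", family = "og"),
                by = "gene")
    arrays <- detect_tandems(fam, max_gap = config$max_gap) |>
      array_balance(env$cm, cutoff = config$tandem_balance_cutoff)
    chains <- chain_arrays(arrays) |> chain_conservation(arrays)
    wtsv(arrays |>
           mutate(members = map_chr(.data$members, paste, collapse = ",")) |>
           arrange(.data$array_id), "tandems")
    wtsv(chains |>
           mutate(array_ids = map_chr(.data$array_ids, paste, collapse = ","),
                  cultivars = map_chr(.data$cultivars, paste, collapse = ",")) |>
           arrange(.data$chain_id), "chains")
  })

  run_stage("kmer", !is.null(bundle$genomes) && length(bundle$genomes) >= 2,
            function() {
    ref <- bundle$cultivars[1]
    ref_genes <- bundle$genes |> filter(.data$cultivar == ref) |>
      mutate(midpoint = floor((.data$start + .data$end) / 2))
    seqs <- gene_sequences(bundle$genomes, ref_genes)
    scores <- list()
    for (cv in setdiff(names(bundle$genomes), ref)) {
      idx <- build_kmer_index(bundle$genomes[[cv]], k = config$k,
                              cultivar = cv)
      scores[[cv]] <- coverage_score(seqs, idx)
    }
    sc <- list_rbind(scores) |> arrange(.data$gene, .data$target)
    wtsv(sc, "coverage_scores")
    mean_sc <- sc |>
      summarise(score = mean(.data$score, na.rm = TRUE), .by = "gene") |>
      left_join(ref_genes |> select("gene", "chromosome", "midpoint"),
                by = "gene")
    tracks <- list(); cands <- list()
    for (chr in sort(unique(mean_sc$chromosome))) {
      part <- mean_sc |> filter(.data$chromosome == chr)
      len <- max(bundle$genes$end[bundle$genes$cultivar == ref &
                                    bundle$genes$chromosome == chr])
      tr <- region_profile(part, chrom_length = len,
                           window = min(config$window, len),
                           step = config$step)
      tracks[[chr]] <- tr |> mutate(chromosome = chr, .before = 1)
      cc <- call_candidates(tr, part,
                            score_threshold = config$coverage_threshold)
      if (nrow(cc) > 0)
        cands[[chr]] <- cc |> mutate(chromosome = chr, .before = 1)
    }
    wtsv(list_rbind(tracks), "coverage_track")
    wtsv(if (length(cands)) list_rbind(cands) else
      tibble(chromosome = character(), start = numeric(), end = numeric(),
             n_windows = integer(), n_genes = integer(),
             mean_score = numeric()), "candidates")
  })

  run_stage("epitope",
            !is.null(bundle$epitopes) && !is.null(bundle$genomes) &&
              !is.null(bundle$counts), function() {
    seqs <- gene_sequences(bundle$genomes,
                           bundle$genes |>
                             filter(.data$cultivar %in%
                                      names(bundle$genomes)))
    occ <- count_epitopes(seqs, bundle$epitopes)
    expr <- env$cm |> summarise(expr = mean(.data$mean_norm), .by = "gene")
    sc <- epitope_expression_score(
      occ, expr, bundle$genes |> select("gene", "subgenome"))
    wtsv(occ |> filter(.data$n_occurrences > 0) |>
           arrange(.data$gene, .data$motif), "epitope_occurrences")
    wtsv(sc$per_group, "epitope_expression")
  })

  run_stage("network", !is.null(bundle$modules) && !is.null(bundle$counts),
            function() {
    pooled <- list(); dists <- list(); thr <- list(); triad_cls <- list()
    for (cv in sort(unique(bundle$modules$cultivar))) {
      ss <- env$eb$meta |> filter(.data$cultivar == cv)
      expr <- env$eb$normalized[, ss$sample, drop = FALSE]
      me <- module_eigengenes(expr,
                              bundle$modules |>
                                filter(.data$cultivar == cv))
      eg <- me$eigengenes
      colnames(eg) <- paste(ss$tissue, ss$replicate, sep = "_")
      pooled[[cv]] <- eg
      if (nrow(eg) >= 2) {
        d <- module_distance_matrix(eg)
        dm <- divergence_threshold(d, fraction = config$divergence_fraction)
        dists[[cv]] <- as_tibble(d, rownames = "module") |>
          mutate(cultivar = cv, .before = 1)
        thr[[cv]] <- glance(dm) |> mutate(cultivar = cv, .before = 1)
        if (!is.null(env$nlets)) {
          mod_of <- setNames(bundle$modules$module, bundle$modules$gene)
          tr <- env$nlets |> filter(.data$cultivar == cv) |>
            mutate(module_A = unname(mod_of[.data$gene_A]),
                   module_B = unname(mod_of[.data$gene_B]),
                   module_D = unname(mod_of[.data$gene_D]))
          triad_cls[[cv]] <- classify_triad_modules(tr, dm) |>
            select("og", "cultivar", "module_class", "max_pair_dist")
        }
      }
    }
    wtsv(list_rbind(dists), "module_distances")
    wtsv(list_rbind(thr), "thresholds")
    if (length(triad_cls))
      wtsv(list_rbind(triad_cls) |> arrange(.data$og, .data$cultivar),
           "triad_module_classes")
    all_eg <- do.call(rbind, pooled)
    eg_tab <- as_tibble(all_eg, rownames = "module") |>
      arrange(.data$module)
    wtsv(eg_tab, "eigengenes")
    if (nrow(all_eg) >= 4) {
      mm <- find_metamodules(all_eg,
                             k_range = config$metamodule_k_range)
      wtsv(tidy(mm) |> arrange(.data$eigengene), "metamodules")
    }
  })

  finish()
  invisible(results)
}
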