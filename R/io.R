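# Readers/writers for the standard formats (GFF3, FASTA, BED, TSV) and
# bundle assembly/validation. Gene tables use 1-based inclusive
# coordinates (the GFF3/GRanges convention); BED's 0-based half-open
# convention is converted at the boundary by rtracklayer.

#' Write gene models to GFF3
#'
#' @param genes tibble with `gene`, `chromosome`, `start`, `end`,
#'   `strand`, and optional `subgenome`, `confidence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene
  if ("subgenome" %in% names(genes))
    S4Vectors::mcols(gr)$subgenome <- genes$subgenome
  if ("confidence" %in% names(genes))
    S4Vectors::mcols(gr)$confidence <- genes$confidence
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with `gene` features carrying `ID` attributes.
#' @param cultivar cultivar label attached to the returned models.
#' @return Gene tibble (`gene`, `cultivar`, `chromosome`, `subgenome`,
#'   `start`, `end`, `strand`, `confidence`).
#' @export
read_gff3 <- function(path, cultivar = NA_character_) {
  assert_that(file.exists(path), paste("missing file:", path))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   # name the offending feature when spans are inverted
                   raw <- readr::read_tsv(path, comment = "#",
                                          col_names = FALSE,
                                          col_types = readr::cols(),
                                          progress = FALSE)
                   bad <- raw[[5]] < raw[[4]]
                   if (any(bad)) {
                     ids <- sub(".*ID=([^;]+).*", "\\1", raw[[9]][bad])
                     abort(paste("GFF3 feature with end < start:",
                                 paste(head(ids, 5), collapse = ", ")))
                   }
                   abort(conditionMessage(e))
                 })
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  ids <- as.character(mc$ID)
  assert_that(!anyDuplicated(ids), "duplicated gene id in GFF3")
  tibble(gene = ids,
         cultivar = cultivar,
         chromosome = as.character(GenomicRanges::seqnames(gr)),
         subgenome = if ("subgenome" %in% names(mc))
           as.character(mc$subgenome) else NA_character_,
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         confidence = if ("confidence" %in% names(mc))
           as.character(mc$confidence) else NA_character_)
}

#' Write/read FASTA sequences
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return `path` / named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), paste("missing file:", path))
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write/read an orthogroup table
#'
#' Canonical dialect: one row per (orthogroup, cultivar) with
#' comma-separated gene ids in the third column.
#'
#' @param orthogroups tibble `og`, `cultivar`, `gene`.
#' @param path TSV path.
#' @return `path` / long tibble `og`, `cultivar`, `gene`.
#' @export
write_orthogroups <- function(orthogroups, path) {
  orthogroups |>
    summarise(genes = paste(.data$gene, collapse = ","),
              .by = c("og", "cultivar")) |>
    arrange(.data$og, .data$cultivar) |>
    readr::write_tsv(path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_orthogroups
#' @export
read_orthogroups <- function(path) {
  assert_that(file.exists(path), paste("missing file:", path))
  readr::read_tsv(path, col_names = c("og", "cultivar", "genes"),
                  col_types = "ccc", progress = FALSE) |>
    mutate(gene = str_split(.data$genes, ",")) |>
    select(-"genes") |>
    unnest("gene")
}

#' Read an OrthoFinder Orthogroups.tsv
#'
#' Adapter for the OrthoFinder wide dialect: first column `Orthogroup`,
#' one column per species with ", "-separated gene ids.
#'
#' @param path Orthogroups.tsv path.
#' @return Long tibble `og`, `cultivar`, `gene`.
#' @export
read_orthofinder <- function(path) {
  assert_that(file.exists(path), paste("missing file:", path))
  wide <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  names(wide)[1] <- "og"
  wide |>
    pivot_longer(-"og", names_to = "cultivar", values_to = "genes") |>
    filter(!is.na(.data$genes), .data$genes != "") |>
    mutate(gene = str_split(.data$genes, ",\\s*")) |>
    select(-"genes") |>
    unnest("gene")
}

#' Write/read a count matrix with sample-metadata sidecar
#'
#' @param bundle an [expression_bundle()].
#' @param counts_path,meta_path TSV paths.
#' @return paths / an `expression_bundle`.
#' @export
write_counts <- function(bundle, counts_path, meta_path) {
  as_tibble(bundle$raw, rownames = "gene") |>
    readr::write_tsv(counts_path)
  readr::write_tsv(bundle$meta, meta_path)
  invisible(c(counts_path, meta_path))
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, meta_path) {
  assert_that(file.exists(counts_path), paste("missing file:", counts_path))
  assert_that(file.exists(meta_path), paste("missing file:", meta_path))
  df <- readr::read_tsv(counts_path, col_types = readr::cols(),
                        progress = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(),
                          progress = FALSE)
  expression_bundle(m, meta)
}

#' Write/read genomic regions as BED
#'
#' BED is 0-based half-open on disk; the in-memory tibble is 1-based
#' inclusive (conversion via rtracklayer).
#'
#' @param regions tibble `chromosome`, `start`, `end` (1-based inclusive).
#' @param path BED path.
#' @return `path` / regions tibble.
#' @export
write_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    regions$chromosome,
    IRanges::IRanges(start = regions$start, end = regions$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  assert_that(file.exists(path), paste("missing file:", path))
  gr <- rtracklayer::import(path, format = "bed")
  tibble(chromosome = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr))
}

#' Read an epitope peptide table
#'
#' @param path TSV with columns `name`, `peptide`, `group`.
#' @return Motif tibble with reverse-translated `consensus` column.
#' @export
read_epitopes <- function(path) {
  assert_that(file.exists(path), paste("missing file:", path))
  df <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  assert_that(all(c("name", "peptide", "group") %in% names(df)),
              "epitope table needs columns name, peptide, group")
  list_rbind(pmap(df, function(name, peptide, group, ...) {
    reverse_translate_consensus(peptide, name = name, group = group)
  }))
}

#' Write a simulated bundle to a directory
#'
#' Emits the full file set: per-cultivar GFF3 (and FASTA when genomes are
#' present), the orthogroup TSV, the count and metadata TSVs, optional
#' regions BED, and `truth.json`.
#'
#' @param sim a `pan_sim` (with counts).
#' @param dir output directory (created).
#' @return Named list of written paths.
#' @export
write_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (cv in sim$cultivars) {
    p <- file.path(dir, paste0(cv, ".gff3"))
    write_gff3(sim$genes |> filter(.data$cultivar == cv), p)
    paths[[paste0("gff3_", cv)]] <- p
    if (!is.null(sim$genomes)) {
      fp <- file.path(dir, paste0(cv, ".fa"))
      write_fasta(sim$genomes[[cv]], fp)
      paths[[paste0("fasta_", cv)]] <- fp
    }
  }
  paths$orthogroups <- file.path(dir, "orthogroups.tsv")
  write_orthogroups(sim$orthogroups, paths$orthogroups)
  if (!is.null(sim$counts)) {
    paths$counts <- file.path(dir, "counts.tsv")
    paths$samples <- file.path(dir, "samples.tsv")
    write_counts(sim$counts, paths$counts, paths$samples)
  }
  if (!is.null(sim$regions)) {
    paths$regions <- file.path(dir, "regions.bed")
    write_bed(sim$regions, paths$regions)
  }
  truth_json <- sim$truth
  truth_json$size_factors <- NULL
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  paths
}

#' Load and validate a dataset bundle
#'
#' @param gff3 named character vector of per-cultivar GFF3 paths (names =
#'   cultivars).
#' @param orthogroups orthogroup TSV path (canonical dialect), or an
#'   OrthoFinder `Orthogroups.tsv` when `orthofinder = TRUE`.
#' @param counts,samples count matrix and sample-metadata TSV paths.
#' @param fasta optional named vector of genome FASTA paths.
#' @param regions optional BED path.
#' @param epitopes optional epitope TSV path.
#' @param orthofinder treat `orthogroups` as OrthoFinder dialect.
#' @return A validated list of class `pan_bundle` with elements `genes`,
#'   `orthogroups`, `counts`, and optional `genomes`, `regions`,
#'   `epitopes`.
#' @export
load_bundle <- function(gff3, orthogroups, counts, samples,
                        fasta = NULL, regions = NULL, epitopes = NULL,
                        orthofinder = FALSE) {
  genes <- list_rbind(imap(as.list(gff3), function(p, cv) read_gff3(p, cv)))
  og <- if (orthofinder) read_orthofinder(orthogroups)
        else read_orthogroups(orthogroups)
  eb <- read_counts(counts, samples)
  bundle <- structure(
    list(cultivars = sort(unique(genes$cultivar)),
         genes = genes, orthogroups = og, counts = eb,
         genomes = if (!is.null(fasta))
           purrr::map(as.list(fasta), read_fasta) else NULL,
         regions = if (!is.null(regions)) read_bed(regions) else NULL,
         epitopes = if (!is.null(epitopes)) read_epitopes(epitopes)
           else NULL),
    class = "pan_bundle")
  validate_bundle(bundle)
  bundle
}

#' Validate a dataset bundle
#'
#' Checks that gene ids are unique; that every gene referenced by the
#' counts and the orthogroup table resolves to a gene model; that sample
#' metadata covers the counts; and that gene spans fit inside their
#' chromosome when sequence is present.
#'
#' @param bundle a `pan_bundle` (or `pan_sim`).
#' @return `bundle`, invisibly; aborts with offender lists otherwise.
#' @export
validate_bundle <- function(bundle) {
  genes <- bundle$genes
  dup <- genes$gene[duplicated(genes$gene)]
  assert_that(length(dup) == 0,
              paste("duplicated gene id:", paste(head(dup, 5), collapse = ", ")))
  if (!is.null(bundle$counts)) {
    unknown <- setdiff(rownames(bundle$counts$raw), genes$gene)
    assert_that(length(unknown) == 0,
                paste("genes in counts absent from gene models:",
                      paste(head(unknown, 5), collapse = ", ")))
  }
  unknown_og <- setdiff(bundle$orthogroups$gene, genes$gene)
  assert_that(length(unknown_og) == 0,
              paste("genes in orthogroups absent from gene models:",
                    paste(head(unknown_og, 5), collapse = ", ")))
  if (!is.null(bundle$genomes)) {
    for (cv in names(bundle$genomes)) {
      g <- genes |> filter(.data$cultivar == cv)
      lens <- nchar(bundle$genomes[[cv]])
      bad <- g$gene[g$end > lens[g$chromosome] | g$start < 1 |
                      is.na(lens[g$chromosome])]
      assert_that(length(bad) == 0,
                  paste("gene span outside chromosome:",
                        paste(head(bad, 5), collapse = ", ")))
    }
  }
  invisible(bundle)
}
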