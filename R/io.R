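#' Read a (multi-)FASTA file
#'
#' @param path FASTA path (optionally gzipped).
#' @return Named character vector of uppercased sequences, record order
#'   preserved; names truncated at the first whitespace.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA: ", path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  if (length(x) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  data.frame(id = unname(names(x)), seq = unname(as.character(x)),
             qual = unname(as.character(S4Vectors::mcols(x)$qualities)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTQ (Phred+33)
#'
#' `write_fastq()` after `read_fastq()` is the identity on valid records.
#'
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path Output path (a `.gz` suffix triggers compression).
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read and write BED intervals (0-based, half-open)
#'
#' @param path BED path.
#' @return data.frame with `contig`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x) <- c("contig", "start", "end", "name", "score", "strand")[seq_len(ncol(x))]
  x
}

#' @rdname read_bed
#' @param bed data.frame with at least `contig`, `start`, `end`.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read the tag database as TSV
#'
#' @param db A [build_tag_database()] object.
#' @param path Output TSV path.
#' @export
write_tagdb <- function(db, path) {
  utils::write.table(db$tags, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tagdb
#' @return `read_tagdb()` returns the tag data.frame (not a full database
#'   object; rebuild from the genome for alignment).
#' @export
read_tagdb <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a hit table as TSV
#'
#' One row per retained half-site with its aligned count, plus a header
#' comment carrying the stage totals.
#'
#' @param hits A `dalec_hits` table.
#' @param db The tag database the hits were aligned to.
#' @param path Output TSV path.
#' @export
write_hit_table <- function(hits, db, path) {
  ret <- which(db$tags$retained)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample=%s raw=%d parsed=%d aligned=%d",
                     hits$sample, hits$totals[["raw"]],
                     hits$totals[["parsed"]], hits$totals[["aligned"]]), con)
  utils::write.table(
    data.frame(half_site_id = db$tags$id[ret], contig = db$tags$contig[ret],
               pos = db$tags$site_pos[ret], strand = db$tags$strand[ret],
               count = hits$counts[ret]),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a synthetic study
#'
#' Orchestrates dataset generation, tag-database construction, read counting
#' for tissue and control, per-gene accessibility indices, expression-score
#' binning, cross-sample divergence, and the dyad metaprofile, writing every
#' result table plus a JSON manifest of stage parameters and counts.
#' Deterministic: identical configuration and seed reproduce identical
#' outputs.
#'
#' @param cfg A [synthetic_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with all in-memory results and `paths`.
#' @export
run_pipeline <- function(cfg = synthetic_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bundle <- generate_synthetic_dataset(cfg, file.path(outdir, "data"))
  genome <- read_fasta(bundle$paths[["genome"]])
  db <- build_tag_database(genome)
  write_tagdb(db, file.path(outdir, "tagdb.tsv"))
  tissue <- count_hits(bundle$paths[["tissue_fastq"]], db,
                       sample = cfg$tissue_label)
  control <- count_hits(bundle$paths[["control_fastq"]], db,
                        sample = cfg$control_label)
  write_hit_table(tissue, db, file.path(outdir, "hits_tissue.tsv"))
  write_hit_table(control, db, file.path(outdir, "hits_control.tsv"))
  genes <- bundle$annotation
  idx <- accessibility_index(tissue, control, genes, db)
  utils::write.table(idx, file.path(outdir, "accessibility_index.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bins <- sage_bin_averages(idx, data.frame(gene = genes$id, score = genes$score))
  utils::write.table(bins, file.path(outdir, "sage_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  div <- gene_divergence(tissue, control, genes, db)
  utils::write.table(div, file.path(outdir, "divergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  omap <- map_halfsites_to_offsets(bundle$anchors, db, W = 1000L)
  prof <- dyad_profile(tissue, omap, control = control)
  prof$smoothed <- moving_average(prof$value, 400L)
  utils::write.table(prof, file.path(outdir, "dyad_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = cfg$seed, n_genes = cfg$n_genes, n_molecules = cfg$n_molecules,
    tagdb_stage_counts = as.list(db$stage_counts),
    tissue_totals = as.list(tissue$totals),
    control_totals = as.list(control$totals)
  )
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(db = db, tissue = tissue, control = control, index = idx,
                 bins = bins, divergence = div, profile = prof,
                 manifest = manifest, paths = bundle$paths))
}
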