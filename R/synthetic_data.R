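#' Configuration for the synthetic study generator
#'
#' Describes a synthetic genome and study emulating the assay's conditions:
#' a single contig carrying non-overlapping genes with planted GATC sites,
#' phased nucleosomes with an upstream NDR around every TSS, a per-gene
#' accessibility multiplier positively coupled to a SAGE-like expression
#' score by a monotone link, and tissue plus in-vitro-control libraries.
#'
#' @param n_genes Number of genes.
#' @param gene_length Gene body length, bases.
#' @param intergenic Intergenic spacer length, bases.
#' @param margin Site-free margin at each contig end, bases.
#' @param site_spacing Planted GATC spacing within gene bodies, bases
#'   (jittered; random background GATCs also occur).
#' @param n_molecules Genome copies per sequencing library.
#' @param seed Master seed; sample streams are derived from it.
#' @param p_max_tissue,p_max_control Maximal per-strand methylation rates for
#'   the tissue exposure and the in-vitro control.
#' @param baseline Baseline accessibility outside protected regions.
#' @param mult_range Range of the per-gene accessibility multiplier.
#' @param expr_lambda_max Expression link: gene scores are Poisson with mean
#'   proportional to the gene's (rescaled) multiplier, up to this maximum.
#' @param nuc_model A [nucleosome_model()].
#' @param tissue_label,control_label Sample labels.
#' @return Object of class `dalec_synth_config`.
#' @export
synthetic_config <- function(n_genes = 50L, gene_length = 900L,
                             intergenic = 350L, margin = 200L,
                             site_spacing = 140L, n_molecules = 2000L,
                             seed = 1L, p_max_tissue = 0.8,
                             p_max_control = 0.9, baseline = 0.85,
                             mult_range = c(0.3, 0.95),
                             expr_lambda_max = 12,
                             nuc_model = nucleosome_model(),
                             tissue_label = "tissue",
                             control_label = "control") {
  stopifnot(n_genes >= 1L, gene_length > 0L, intergenic >= 0L,
            mult_range[1] > 0, mult_range[2] <= 1,
            mult_range[1] <= mult_range[2])
  structure(as.list(environment()), class = "dalec_synth_config")
}

# Deterministic per-sample seed below 2^31, derived from the master seed and
# the sample label, so each sample is independently reproducible.
sample_seed <- function(master_seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483647)
}

#' Build the synthetic genome, annotation, tracks and anchors
#'
#' Deterministic given `cfg$seed`. Genes are laid out sequentially and never
#' overlap; each receives a uniform latent activity `u`, an accessibility
#' multiplier linear in `u`, and a Poisson expression score with mean
#' `expr_lambda_max * u` (the monotone expression-accessibility link). Dyad
#' anchors are the first downstream nucleosome dyad of each gene,
#' strand-aware.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `genome` (named character), `annotation` (gene
#'   data.frame incl. `access_multiplier`, `score`), `tracks` (accessibility
#'   per contig), `anchors` (dyad anchor data.frame), `occupancy` (1 -
#'   track / baseline-scaling; the planted protection), `cfg`.
#' @export
synthetic_world <- function(cfg = synthetic_config()) {
  set.seed(sample_seed(cfg$seed, "world"))
  contig <- "chrS"
  pitch <- cfg$gene_length + cfg$intergenic
  contig_len <- 2L * cfg$margin + cfg$n_genes * pitch
  seq_chars <- sample(c("A", "C", "G", "T"), contig_len, TRUE)
  txStart <- cfg$margin + (seq_len(cfg$n_genes) - 1L) * pitch
  txEnd <- txStart + cfg$gene_length
  strand <- sample(c("+", "-"), cfg$n_genes, TRUE)
  u <- stats::runif(cfg$n_genes)
  mult <- cfg$mult_range[1] + diff(cfg$mult_range) * u
  score <- stats::rpois(cfg$n_genes, cfg$expr_lambda_max * u)
  # plant GATC sites through each gene body at jittered spacing
  for (g in seq_len(cfg$n_genes)) {
    at <- seq(txStart[g] + 30L, txEnd[g] - 30L, by = cfg$site_spacing)
    at <- at + sample(-15:15, length(at), TRUE)
    for (p in at) seq_chars[(p + 1L):(p + 4L)] <- c("G", "A", "T", "C")
  }
  genome <- stats::setNames(paste(seq_chars, collapse = ""), contig)
  annotation <- data.frame(id = sprintf("gene%03d", seq_len(cfg$n_genes)),
                           contig = contig, txStart = txStart, txEnd = txEnd,
                           strand = strand, access_multiplier = mult,
                           score = score, stringsAsFactors = FALSE)
  if (any(annotation$txEnd > contig_len)) stop("genes outside contig")
  track <- nucleosome_track(cfg$nuc_model, annotation, contig_len,
                            baseline = cfg$baseline)
  tss <- ifelse(strand == "-", txEnd - 1L, txStart)
  sgn <- ifelse(strand == "-", -1L, 1L)
  first_down <- min(cfg$nuc_model$dyads_rel[cfg$nuc_model$dyads_rel >= 0L])
  anchors <- data.frame(contig = contig, dyad = tss + sgn * first_down,
                        strand = strand, gene = annotation$id,
                        stringsAsFactors = FALSE)
  list(genome = genome, annotation = annotation,
       tracks = stats::setNames(list(track), contig),
       anchors = anchors, cfg = cfg)
}

#' Generate and write a complete synthetic dataset
#'
#' Writes genome FASTA, gene BED, expression TSV, dyad-anchor BED, tissue and
#' control FASTQs, and truth tables (per-half-site expected capture rates for
#' both exposures; per-gene planted accessibility multiplier and expression
#' score). Re-running with the same configuration reproduces the bundle
#' byte-identically.
#'
#' @param cfg A [synthetic_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the `synthetic_world()` components and a
#'   named vector `paths` of every written file.
#' @export
generate_synthetic_dataset <- function(cfg = synthetic_config(), outdir) {
  world <- synthetic_world(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             genes = file.path(outdir, "genes.bed"),
             expression = file.path(outdir, "expression.tsv"),
             anchors = file.path(outdir, "dyad_anchors.bed"),
             tissue_fastq = file.path(outdir, paste0("reads_", cfg$tissue_label, ".fastq")),
             control_fastq = file.path(outdir, paste0("reads_", cfg$control_label, ".fastq")),
             truth_capture = file.path(outdir, "truth_capture_rates.tsv"),
             truth_genes = file.path(outdir, "truth_genes.tsv"))
  write_fasta(world$genome, paths[["genome"]])
  ann <- world$annotation
  write_bed(data.frame(contig = ann$contig, start = ann$txStart,
                       end = ann$txEnd, name = ann$id, score = 0L,
                       strand = ann$strand), paths[["genes"]])
  utils::write.table(ann[, c("id", "score")], paths[["expression"]],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("gene", "score"))
  write_bed(data.frame(contig = world$anchors$contig,
                       start = world$anchors$dyad,
                       end = world$anchors$dyad + 1L,
                       name = world$anchors$gene, score = 0L,
                       strand = world$anchors$strand), paths[["anchors"]])
  for (role in c("tissue", "control")) {
    label <- cfg[[paste0(role, "_label")]]
    meth <- if (role == "tissue") methylation_config(cfg$p_max_tissue)
            else control_methylation_config(cfg$p_max_control)
    sim <- sim_config(n_molecules = cfg$n_molecules,
                      seed = sample_seed(cfg$seed, label),
                      sample_label = label)
    reads <- simulate_sample_reads(world$genome, world$tracks, meth, sim)
    write_fastq(reads, paths[[paste0(role, "_fastq")]])
  }
  truth <- rbind(
    cbind(sample = cfg$tissue_label,
          expected_capture_rate(world$genome, world$tracks,
                                methylation_config(cfg$p_max_tissue))),
    cbind(sample = cfg$control_label,
          expected_capture_rate(world$genome, world$tracks,
                                control_methylation_config(cfg$p_max_control)))
  )
  utils::write.table(truth, paths[["truth_capture"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ann[, c("id", "access_multiplier", "score")],
                     paths[["truth_genes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(world, list(paths = paths)))
}
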