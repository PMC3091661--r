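#' Nucleosome positioning model for the synthetic accessibility track
#'
#' Describes phased nucleosomes around transcription start sites: dyad
#' positions relative to the TSS (strand-aware), a protection half-width, an
#' occupancy depth, and a protected nucleosome-depleted-region (NDR) window
#' upstream of the first positioned nucleosome.
#'
#' @param dyads_rel Integer vector of dyad positions relative to the TSS
#'   (negative = upstream). Default: one upstream nucleosome at -180 and a
#'   downstream array phased every 180 bases starting at +35.
#' @param half_width Protection half-width around each dyad, bases.
#' @param depth Occupancy at the dyad, in \[0,1\].
#' @param ndr_window Window relative to the first (most upstream) dyad in
#'   which additional non-nucleosomal protection is applied.
#' @param ndr_protection Occupancy contributed by the NDR protection factor.
#' @return Object of class `dalec_nucleosome_model`.
#' @export
nucleosome_model <- function(dyads_rel = c(-180L, 35L, 215L, 395L, 575L),
                             half_width = 73L, depth = 0.9,
                             ndr_window = c(-225L, -75L),
                             ndr_protection = 0.5) {
  stopifnot(depth >= 0, depth <= 1, ndr_protection >= 0, ndr_protection <= 1,
            half_width >= 1)
  structure(list(dyads_rel = as.integer(sort(dyads_rel)),
                 half_width = as.integer(half_width), depth = depth,
                 ndr_window = as.integer(ndr_window),
                 ndr_protection = ndr_protection),
            class = "dalec_nucleosome_model")
}

#' Build a per-base accessibility track from a nucleosome model
#'
#' Accessibility is `1 - occupancy`. Occupancy is raised in a raised-cosine
#' bump of the configured depth within one half-width of every dyad, and by
#' the NDR protection factor within the NDR window upstream of the first
#' dyad. Dyads are placed relative to each gene's TSS, mirrored for
#' minus-strand genes. A per-gene accessibility multiplier (from the
#' annotation) scales the track across the gene body, and a global baseline
#' scales everything; the track is clamped to \[0,1\].
#'
#' @param model A [nucleosome_model()].
#' @param annotation data.frame with columns `txStart`, `txEnd`, `strand`, and
#'   optionally `access_multiplier` (default 1).
#' @param contig_len Contig length in bases.
#' @param baseline Baseline accessibility outside protected regions.
#' @return Numeric vector of length `contig_len` with values in \[0,1\].
#' @export
nucleosome_track <- function(model, annotation, contig_len, baseline = 0.85) {
  occ <- numeric(contig_len)
  add_bump <- function(occ, center, half_width, depth) {
    lo <- max(1L, center - half_width + 1L)
    hi <- min(contig_len, center + half_width + 1L)
    if (lo > hi) return(occ)
    x <- (lo:hi) - (center + 1L)
    bump <- depth * 0.5 * (1 + cos(pi * x / half_width))
    occ[lo:hi] <- pmax(occ[lo:hi], bump)
    occ
  }
  mult <- rep(1, contig_len)
  if (!is.null(annotation) && nrow(annotation) > 0L) {
    am <- if ("access_multiplier" %in% names(annotation)) annotation$access_multiplier else rep(1, nrow(annotation))
    for (g in seq_len(nrow(annotation))) {
      minus <- annotation$strand[g] == "-"
      tss <- if (minus) annotation$txEnd[g] - 1L else annotation$txStart[g]
      sgn <- if (minus) -1L else 1L
      for (d in model$dyads_rel) {
        occ <- add_bump(occ, tss + sgn * d, model$half_width, model$depth)
      }
      if (length(model$dyads_rel) > 0L) {
        ndr_abs <- sort(tss + sgn * (model$dyads_rel[1L] + model$ndr_window))
        lo <- max(1L, ndr_abs[1L] + 1L); hi <- min(contig_len, ndr_abs[2L] + 1L)
        if (lo <= hi) occ[lo:hi] <- pmax(occ[lo:hi], model$ndr_protection)
      }
      glo <- annotation$txStart[g] + 1L; ghi <- annotation$txEnd[g]
      mult[glo:ghi] <- am[g]
    }
  }
  pmin(1, pmax(0, baseline * mult * (1 - occ)))
}

#' Methylation exposure configuration
#'
#' Each strand of each GATC site is methylated independently with probability
#' `p_max` times the mean accessibility over the site's four bases. The
#' in-vitro control treats deproteinised DNA: accessibility is forced to 1
#' everywhere and a slightly higher maximal rate applies.
#'
#' @param p_max Probability that a fully accessible GATC strand is methylated
#'   during the exposure (tissue default 0.8).
#' @param force_full_access If TRUE, accessibility is taken as 1 at every site
#'   (in-vitro control).
#' @return Object of class `dalec_methylation_config`.
#' @export
methylation_config <- function(p_max = 0.8, force_full_access = FALSE) {
  stopifnot(p_max >= 0, p_max <= 1)
  structure(list(p_max = p_max, force_full_access = force_full_access),
            class = "dalec_methylation_config")
}

#' @rdname methylation_config
#' @export
control_methylation_config <- function(p_max = 0.9) {
  methylation_config(p_max = p_max, force_full_access = TRUE)
}

#' Simulation run configuration
#'
#' @param n_molecules Genome copies simulated per sample.
#' @param seed RNG seed; fully determines the output.
#' @param read_length Emitted read length (default 36).
#' @param error_rate Per-base uniform substitution error rate (default 0).
#' @param min_capture_duplex Below this duplex length (bases) a fragment
#'   yields only one captured end, chosen uniformly (default 24: the 20-base
#'   type IIS reach plus the 4-base site).
#' @param sequencing_fraction Probability that a captured end is actually
#'   sequenced (default 1: every capture is observed). Real libraries sample
#'   a small fraction of an excess of input molecules, which makes per-site
#'   counts near-Poisson; set this below 1 to emulate that regime.
#' @param chunk_size Molecules simulated per vectorised chunk.
#' @param sample_label Sample name recorded in outputs.
#' @return Object of class `dalec_sim_config`.
#' @export
sim_config <- function(n_molecules = 2000L, seed = 1L, read_length = 36L,
                       error_rate = 0, min_capture_duplex = 24L,
                       sequencing_fraction = 1, chunk_size = 1000L,
                       sample_label = "sample") {
  stopifnot(n_molecules >= 0L, read_length > 0L, error_rate >= 0, error_rate <= 1,
            sequencing_fraction >= 0, sequencing_fraction <= 1)
  structure(list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
                 read_length = as.integer(read_length), error_rate = error_rate,
                 min_capture_duplex = as.integer(min_capture_duplex),
                 sequencing_fraction = sequencing_fraction,
                 chunk_size = as.integer(chunk_size),
                 sample_label = sample_label),
            class = "dalec_sim_config")
}

# Per-site double-methylation (cut) probability and per-strand probability.
site_meth_prob <- function(sequence, sites, track, meth) {
  if (length(sites) == 0L) return(numeric(0))
  if (meth$force_full_access) {
    acc <- rep(1, length(sites))
  } else {
    acc <- vapply(sites, function(p) mean(track[(p + 1L):(p + 4L)]), numeric(1))
  }
  meth$p_max * acc
}

#' Simulate per-molecule, per-site, per-strand methylation states
#'
#' Explicit molecule-level sampler used for small-scale work and for checking
#' the vectorised library simulator. Each strand of each site is methylated
#' independently with probability `p_max * mean(track over the site)`.
#'
#' @param sequence Contig sequence (single string).
#' @param sites 0-based GATC positions.
#' @param track Accessibility track (length = contig length), ignored for the
#'   control configuration.
#' @param meth A [methylation_config()].
#' @param n Number of molecules.
#' @param seed RNG seed.
#' @return List of molecules; each is a data.frame with `site_pos`, `top`,
#'   `bottom` (logical methylation states).
#' @export
simulate_molecules <- function(sequence, sites, track, meth, n, seed = 1L) {
  p <- site_meth_prob(sequence, sites, track, meth)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    data.frame(site_pos = sites,
               top = stats::runif(length(sites)) < p,
               bottom = stats::runif(length(sites)) < p)
  })
}

#' Methylation-sensitive cutting predicates
#'
#' Dpn I cuts only GATC methylated on both strands; Mbo I only unmethylated
#' GATC; Sau3A I cuts regardless of methylation.
#'
#' @param top,bottom Logical vectors of per-strand methylation states.
#' @return Logical vector: does the enzyme cut each site?
#' @export
dpnI_cuts <- function(top, bottom) top & bottom

#' @rdname dpnI_cuts
#' @export
mboI_cuts <- function(top, bottom) !top & !bottom

#' @rdname dpnI_cuts
#' @export
sau3aI_cuts <- function(top, bottom) rep(TRUE, length(top))

#' Digest one molecule with Dpn I
#'
#' Cuts blunt at `site_pos + 2` of every doubly-methylated site. Fragments are
#' returned in genomic order with their flanking cut sites (NA at molecule
#' ends) and the indices of internal (uncut, hence never doubly-methylated)
#' sites.
#'
#' @param molecule One element of [simulate_molecules()] output.
#' @param contig_len Molecule (contig) length.
#' @return data.frame with `start`, `end` (0-based half-open), `left_site`,
#'   `right_site` (0-based GATC positions of the flanking cuts, NA at molecule
#'   ends) and a list-column `internal_sites` of 0-based positions.
#' @export
dpnI_digest <- function(molecule, contig_len) {
  cut_pos <- molecule$site_pos[dpnI_cuts(molecule$top, molecule$bottom)]
  bounds <- c(0L, cut_pos + 2L, contig_len)
  left_site <- c(NA_integer_, cut_pos)
  right_site <- c(cut_pos, NA_integer_)
  keep <- bounds[-length(bounds)] < bounds[-1L]
  frags <- data.frame(start = bounds[-length(bounds)][keep],
                      end = bounds[-1L][keep],
                      left_site = left_site[keep],
                      right_site = right_site[keep])
  frags$internal_sites <- lapply(seq_len(nrow(frags)), function(i) {
    s <- molecule$site_pos
    s[!(s %in% cut_pos) & s + 2L > frags$start[i] & s + 2L < frags$end[i]]
  })
  frags
}

#' Capture the ends of digested fragments
#'
#' Each Dpn I cut end of a fragment yields one readout: the oriented half-site
#' entering the fragment (minus tag of the left flanking site, plus tag of the
#' right flanking site) with a captured length drawn from the type IIS slop
#' distribution. Molecule-terminal ends are not capturable. If the fragment
#' duplex is shorter than `min_capture_duplex`, exactly one of the two ends is
#' captured, chosen uniformly, implementing the undercount at proximal sites.
#'
#' @param fragments Output of [dpnI_digest()].
#' @param linkers A [linker_set()].
#' @param cfg A [sim_config()].
#' @return data.frame of readouts: `site_pos`, `strand`, `length`.
#' @export
capture_fragment_ends <- function(fragments, linkers = linker_set(),
                                  cfg = sim_config()) {
  out_site <- integer(0); out_strand <- character(0)
  for (i in seq_len(nrow(fragments))) {
    cand_site <- c(fragments$left_site[i], fragments$right_site[i])
    cand_strand <- c("-", "+")
    ok <- !is.na(cand_site)
    cand_site <- cand_site[ok]; cand_strand <- cand_strand[ok]
    if (length(cand_site) == 0L) next
    duplex <- fragments$end[i] - fragments$start[i]
    if (length(cand_site) == 2L && duplex < cfg$min_capture_duplex) {
      pick <- sample.int(2L, 1L)
      cand_site <- cand_site[pick]; cand_strand <- cand_strand[pick]
    }
    out_site <- c(out_site, cand_site)
    out_strand <- c(out_strand, cand_strand)
  }
  lens <- as.integer(names(linkers$mme_slop))
  data.frame(site_pos = out_site, strand = out_strand,
             length = if (length(out_site)) sample(lens, length(out_site), TRUE, linkers$mme_slop) else integer(0))
}

#' Emit sequencing reads from captured readouts
#'
#' The read runs from the sequencing primer in linker B across the captured
#' genomic portion and into linker A: genomic portion (reverse complement of
#' the captured top-strand insert, therefore ending in GA at the original
#' GATC) followed by the reverse complement of linker A's top strand,
#' truncated to the read length. Optional uniform substitution errors;
#' constant Phred+33 qualities.
#'
#' @param readouts data.frame from [capture_fragment_ends()].
#' @param sequence Contig sequence.
#' @param linkers A [linker_set()].
#' @param cfg A [sim_config()].
#' @return data.frame with `id`, `seq`, `qual`; readouts whose genomic portion
#'   would run off the contig are dropped.
#' @export
emit_reads <- function(readouts, sequence, linkers = linker_set(),
                       cfg = sim_config()) {
  portion <- read_portion(sequence, readouts$site_pos, readouts$strand,
                          readouts$length)
  keep <- which(!is.na(portion))
  if (length(keep) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  seqs <- substr(paste0(portion[keep], linkers$read_linker_suffix),
                 1L, cfg$read_length)
  seqs <- apply_seq_errors(seqs, cfg$error_rate)
  data.frame(id = sprintf("read_%d_%s_%d", readouts$site_pos[keep],
                          readouts$strand[keep], seq_along(seqs)),
             seq = seqs,
             qual = strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}

# Genomic portion of a read for a half-site capture of given length.
# Plus half-site at t: genome[t+2-L, t+2) (top strand; ends in GA).
# Minus half-site at s: revcomp(genome[s+2, s+2+L)) (ends in GA).
read_portion <- function(sequence, site_pos, strand, len) {
  n <- length(site_pos)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  L <- nchar(sequence)
  plus <- strand == "+"
  ok_p <- plus & (site_pos + 2L - len >= 0L)
  out[ok_p] <- substr(rep(sequence, sum(ok_p)),
                      site_pos[ok_p] + 3L - len[ok_p], site_pos[ok_p] + 2L)
  ok_m <- !plus & (site_pos + 2L + len <= L)
  if (any(ok_m)) {
    out[ok_m] <- revcomp(substr(rep(sequence, sum(ok_m)),
                                site_pos[ok_m] + 3L,
                                site_pos[ok_m] + 2L + len[ok_m]))
  }
  out
}

apply_seq_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  bases <- c("A", "C", "G", "T")
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  seqs
}

#' Simulate a full sequencing sample in vectorised chunks
#'
#' Fast path of the simulator: double-methylation (cut) events are drawn
#' directly with probability `p_site^2` per molecule and site (per-strand
#' draws are independent, so this is distributionally identical to the
#' molecule-level sampler), fragments between consecutive cuts are captured at
#' both ends (one end, chosen uniformly, when the duplex is shorter than
#' `min_capture_duplex`), slop lengths are drawn, captures are thinned by the
#' sequencing fraction, and reads are emitted. Reads are delivered chunk-wise
#' to a callback so arbitrarily deep samples never materialise at once.
#'
#' @param genome Named character vector of contig sequences.
#' @param tracks Named list of accessibility tracks (one per contig); ignored
#'   for control configurations.
#' @param meth A [methylation_config()].
#' @param sim A [sim_config()]; `sim$seed` determines the output completely.
#' @param linkers A [linker_set()].
#' @param callback Function called as `callback(chunk)` with a data.frame of
#'   columns `id`, `seq`, `qual`, `truth_site` (0-based position),
#'   `truth_strand`, `truth_contig`. If NULL, all chunks are collected and
#'   returned.
#' @return If `callback` is NULL, the full read data.frame; otherwise (invisibly)
#'   the number of reads emitted.
#' @export
simulate_sample_reads <- function(genome, tracks, meth, sim = sim_config(),
                                  linkers = linker_set(), callback = NULL) {
  genome <- as_genome(genome)
  collect <- is.null(callback)
  acc <- if (collect) list() else NULL
  total <- 0L
  set.seed(sim$seed)
  lens <- as.integer(names(linkers$mme_slop))
  for (ctg in names(genome)) {
    seqc <- genome[[ctg]]
    sites <- scan_gatc_sites(seqc)
    if (length(sites) == 0L) next
    p <- site_meth_prob(seqc, sites, tracks[[ctg]], meth)
    p_cut <- p^2
    # precompute full reads per (site, strand, slop length)
    reads_tab <- precompute_reads(seqc, sites, lens, linkers, sim$read_length)
    S <- length(sites)
    done <- 0L
    while (done < sim$n_molecules) {
      nm <- min(sim$chunk_size, sim$n_molecules - done)
      ro <- chunk_readouts(nm, sites, p_cut, sim$min_capture_duplex)
      if (sim$sequencing_fraction < 1 && length(ro$site_idx) > 0L) {
        seqd <- stats::runif(length(ro$site_idx)) < sim$sequencing_fraction
        ro <- lapply(ro, `[`, seqd)
      }
      if (length(ro$site_idx) > 0L) {
        L_idx <- sample.int(length(lens), length(ro$site_idx), TRUE,
                            linkers$mme_slop)
        seqs <- reads_tab$reads[cbind(ro$site_idx, ro$strand_idx +
                                        2L * (L_idx - 1L))]
        keep <- !is.na(seqs)
        seqs <- apply_seq_errors(seqs[keep], sim$error_rate)
        if (length(seqs) > 0L) {
          chunk <- data.frame(
            id = sprintf("%s_m%d_r%d", sim$sample_label, done + ro$mol[keep],
                         total + seq_along(seqs)),
            seq = seqs,
            qual = strrep("I", nchar(seqs)),
            truth_site = sites[ro$site_idx[keep]],
            truth_strand = c("+", "-")[ro$strand_idx[keep]],
            truth_contig = ctg,
            stringsAsFactors = FALSE
          )
          total <- total + nrow(chunk)
          if (collect) acc[[length(acc) + 1L]] <- chunk else callback(chunk)
        }
      }
      done <- done + nm
    }
  }
  if (collect) {
    if (length(acc) == 0L) {
      return(data.frame(id = character(0), seq = character(0),
                        qual = character(0), truth_site = integer(0),
                        truth_strand = character(0), truth_contig = character(0),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, acc)
  } else {
    invisible(total)
  }
}

# One chunk of molecules: returns captured readouts as parallel vectors
# (mol index within chunk, site index, strand index 1=+, 2=-).
chunk_readouts <- function(nm, sites, p_cut, min_duplex) {
  S <- length(sites)
  cut <- stats::runif(nm * S) < rep(p_cut, each = nm)
  idx <- which(cut)
  if (length(idx) == 0L) {
    return(list(mol = integer(0), site_idx = integer(0), strand_idx = integer(0)))
  }
  mol <- ((idx - 1L) %% nm) + 1L
  site <- ((idx - 1L) %/% nm) + 1L
  ord <- order(mol, site)
  mol <- mol[ord]; site <- site[ord]
  n <- length(mol)
  # every cut contributes a plus readout (right end of the fragment to its
  # left) and a minus readout (left end of the fragment to its right), except
  # collisions on short inter-cut fragments
  plus_keep <- rep(TRUE, n); minus_keep <- rep(TRUE, n)
  if (n > 1L) {
    same <- mol[-1L] == mol[-n]
    duplex <- sites[site[-1L]] - sites[site[-n]]
    short <- which(same & duplex < min_duplex)
    if (length(short) > 0L) {
      coin <- stats::runif(length(short)) < 0.5
      minus_keep[short] <- coin        # left end of the short fragment
      plus_keep[short + 1L] <- !coin   # right end of the short fragment
    }
  }
  list(mol = c(mol[plus_keep], mol[minus_keep]),
       site_idx = c(site[plus_keep], site[minus_keep]),
       strand_idx = c(rep(1L, sum(plus_keep)), rep(2L, sum(minus_keep))))
}

# Precompute complete reads for each (site, strand, slop length); NA where the
# genomic portion would run off the contig. Matrix indexed [site, strand + 2*(L-1)].
precompute_reads <- function(sequence, sites, lens, linkers, read_length) {
  S <- length(sites)
  reads <- matrix(NA_character_, nrow = S, ncol = 2L * length(lens))
  for (li in seq_along(lens)) {
    L <- lens[li]
    portion_p <- read_portion(sequence, sites, rep("+", S), rep(L, S))
    portion_m <- read_portion(sequence, sites, rep("-", S), rep(L, S))
    okp <- !is.na(portion_p)
    okm <- !is.na(portion_m)
    reads[okp, 1L + 2L * (li - 1L)] <-
      substr(paste0(portion_p[okp], linkers$read_linker_suffix), 1L, read_length)
    reads[okm, 2L + 2L * (li - 1L)] <-
      substr(paste0(portion_m[okm], linkers$read_linker_suffix), 1L, read_length)
  }
  list(reads = reads)
}

#' Analytic expected capture rates per half-site
#'
#' For each half-site, the expected number of captures per molecule: the
#' probability that its site is doubly methylated (cut), discounted for
#' capture collisions with neighbouring sites closer than the minimum capture
#' duplex (when the nearest cut on the facing side is within that distance,
#' the end is captured with probability 1/2).
#'
#' @param genome Named character vector of contig sequences.
#' @param tracks Named list of accessibility tracks.
#' @param meth A [methylation_config()].
#' @param sim A [sim_config()] (supplies `min_capture_duplex`).
#' @return data.frame: `contig`, `site_pos`, `strand`, `expected_rate`.
#' @export
expected_capture_rate <- function(genome, tracks, meth, sim = sim_config()) {
  genome <- as_genome(genome)
  out <- list()
  for (ctg in names(genome)) {
    sites <- scan_gatc_sites(genome[[ctg]])
    if (length(sites) == 0L) next
    p_cut <- site_meth_prob(genome[[ctg]], sites, tracks[[ctg]], meth)^2
    S <- length(sites)
    collide_left <- numeric(S)   # P(nearest cut left within min duplex), for plus tags
    collide_right <- numeric(S)  # same to the right, for minus tags
    for (i in seq_len(S)) {
      lft <- which(sites < sites[i] & sites[i] - sites < sim$min_capture_duplex)
      rgt <- which(sites > sites[i] & sites - sites[i] < sim$min_capture_duplex)
      collide_left[i] <- 1 - prod(1 - p_cut[lft])
      collide_right[i] <- 1 - prod(1 - p_cut[rgt])
    }
    out[[ctg]] <- data.frame(
      contig = ctg,
      site_pos = rep(sites, 2L),
      strand = rep(c("+", "-"), each = S),
      expected_rate = c(p_cut * (1 - 0.5 * collide_left),
                        p_cut * (1 - 0.5 * collide_right)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
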