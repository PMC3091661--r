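#' Scan a contig for GATC sites
#'
#' Returns every occurrence of the (palindromic) DAM target tetramer GATC on
#' the forward strand of a contig; because the motif is its own reverse
#' complement, one scan covers both strands. Occurrences cannot self-overlap.
#'
#' @param sequence Contig sequence as a single character string (A/C/G/T/N).
#' @return Integer vector of 0-based start positions of each GATC, sorted.
#' @export
scan_gatc_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 4L) return(integer(0))
  m <- Biostrings::matchPattern("GATC", Biostrings::DNAString(sequence))
  as.integer(BiocGenerics::start(m)) - 1L
}

#' Extract the two oriented half-site tags of each GATC site
#'
#' Each GATC site carries two capturable tags: the plus tag is the 16 bases
#' immediately upstream of the site on the forward strand; the minus tag is
#' the reverse complement of the 16 bases immediately downstream of the site.
#' Tags whose 16-base context runs off the contig end, or whose context (or
#' site) contains an ambiguous base, are flagged `edge_truncated` and are
#' never retained.
#'
#' @param contig Contig name.
#' @param sequence Contig sequence (single character string).
#' @param sites Integer vector of 0-based GATC start positions.
#' @return data.frame with one row per emitted tag: `contig`, `site_pos`,
#'   `strand` ("+"/"-"), `tag16`, and logical flag columns `edge_truncated`,
#'   `nonunique`, `proximal_excluded`, `on_exclusion_list` (the last three
#'   initialised to FALSE).
#' @export
extract_half_site_tags <- function(contig, sequence, sites) {
  len <- nchar(sequence)
  n <- length(sites)
  if (n == 0L) {
    return(data.frame(contig = character(0), site_pos = integer(0),
                      strand = character(0), tag16 = character(0),
                      edge_truncated = logical(0), nonunique = logical(0),
                      proximal_excluded = logical(0),
                      on_exclusion_list = logical(0),
                      stringsAsFactors = FALSE))
  }
  pos <- as.integer(sites)
  # plus tag: [pos-16, pos) ; minus tag: revcomp of [pos+4, pos+20)
  plus_ok <- pos >= 16L
  minus_ok <- pos + 20L <= len
  plus_tag <- ifelse(plus_ok, substr(rep(sequence, n), pos - 15L, pos), NA_character_)
  minus_ctx <- ifelse(minus_ok, substr(rep(sequence, n), pos + 5L, pos + 20L), NA_character_)
  minus_tag <- minus_ctx
  minus_tag[!is.na(minus_ctx)] <- revcomp(minus_ctx[!is.na(minus_ctx)])
  has_n <- function(x) !is.na(x) & grepl("[^ACGT]", x)
  site_seq <- substr(rep(sequence, n), pos + 1L, pos + 4L)
  site_bad <- grepl("[^ACGT]", site_seq)
  plus_trunc <- !plus_ok | has_n(plus_tag) | site_bad
  minus_trunc <- !minus_ok | has_n(minus_tag) | site_bad
  plus_tag[plus_trunc] <- NA_character_
  minus_tag[minus_trunc] <- NA_character_
  out <- data.frame(
    contig = contig,
    site_pos = c(pos, pos),
    strand = rep(c("+", "-"), each = n),
    tag16 = c(plus_tag, minus_tag),
    edge_truncated = c(plus_trunc, minus_trunc),
    nonunique = FALSE,
    proximal_excluded = FALSE,
    on_exclusion_list = FALSE,
    stringsAsFactors = FALSE
  )
  out[order(out$site_pos, out$strand), , drop = FALSE]
}

#' Filter configuration for the tag database
#'
#' @param proximal_threshold Two adjacent GATC sites closer than this many
#'   bases (gap measured from the end of the first GATC to the start of the
#'   second, strictly less than) have their inward-facing tag pair excluded.
#'   Default 20.
#' @param exclusion_sequences Character vector of sequences (e.g. vector or
#'   ribosomal repeats); any tag whose 20-mer (tag16 + GATC) occurs in one of
#'   them on either strand is excluded.
#' @return An object of class `dalec_filter_config`.
#' @export
filter_config <- function(proximal_threshold = 20L, exclusion_sequences = character(0)) {
  stopifnot(proximal_threshold >= 0L)
  structure(list(proximal_threshold = as.integer(proximal_threshold),
                 exclusion_sequences = toupper(exclusion_sequences)),
            class = "dalec_filter_config")
}

#' Flag tags whose 16-mer occurs more than once genome-wide
#'
#' Uniqueness is assessed over the union of all full-length plus and minus
#' tags of all contigs; edge-truncated tags (no valid 16-mer) do not enter
#' the multiset.
#'
#' @param tags Tag data.frame from [extract_half_site_tags()] (all contigs
#'   row-bound).
#' @return The tag data.frame with `nonunique` updated.
#' @export
mark_nonunique <- function(tags) {
  ok <- !tags$edge_truncated
  counts <- table(tags$tag16[ok])
  dup <- names(counts)[counts > 1L]
  tags$nonunique <- ok & tags$tag16 %in% dup
  tags
}

#' Flag the inward-facing tag pair of proximal GATC site pairs
#'
#' When two adjacent sites on a contig lie within the proximal threshold
#' (gap = pos2 - (pos1 + 4) strictly below the threshold), only one of the two
#' facing ends of the short intervening fragment can be captured per molecule,
#' undercounting both. The minus tag of the first site and the plus tag of the
#' second site are therefore excluded.
#'
#' @param tags Tag data.frame (all contigs).
#' @param cfg A [filter_config()].
#' @return The tag data.frame with `proximal_excluded` updated.
#' @export
mark_proximal <- function(tags, cfg = filter_config()) {
  tags$proximal_excluded <- FALSE
  for (ctg in unique(tags$contig)) {
    idx <- tags$contig == ctg
    pos <- sort(unique(tags$site_pos[idx]))
    if (length(pos) < 2L) next
    gap <- pos[-1L] - (pos[-length(pos)] + 4L)
    close_pair <- which(gap < cfg$proximal_threshold)
    if (length(close_pair) == 0L) next
    minus_of <- pos[close_pair]       # first site of each close pair
    plus_of <- pos[close_pair + 1L]   # second site
    tags$proximal_excluded[idx & tags$strand == "-" &
                             tags$site_pos %in% minus_of] <- TRUE
    tags$proximal_excluded[idx & tags$strand == "+" &
                             tags$site_pos %in% plus_of] <- TRUE
  }
  tags
}

#' Flag tags whose 20-mer occurs in an exclusion sequence
#'
#' The full captured 20-mer (tag16 followed by GATC) is searched against each
#' exclusion sequence and its reverse complement; any occurrence flags the tag.
#'
#' @param tags Tag data.frame.
#' @param cfg A [filter_config()] supplying `exclusion_sequences`.
#' @return The tag data.frame with `on_exclusion_list` updated.
#' @export
mark_excluded <- function(tags, cfg = filter_config()) {
  tags$on_exclusion_list <- FALSE
  if (length(cfg$exclusion_sequences) == 0L) return(tags)
  haystack <- c(cfg$exclusion_sequences, revcomp(cfg$exclusion_sequences))
  ok <- which(!tags$edge_truncated)
  if (length(ok) == 0L) return(tags)
  mers <- paste0(tags$tag16[ok], "GATC")
  hit <- rep(FALSE, length(mers))
  for (h in haystack) {
    todo <- which(!hit)
    if (length(todo) == 0L) break
    hit[todo] <- vapply(mers[todo], function(m) grepl(m, h, fixed = TRUE), logical(1))
  }
  tags$on_exclusion_list[ok] <- hit
  tags
}

#' Build the filtered in-silico tag database for a genome
#'
#' Runs the full pipeline: GATC scan, half-site tag extraction, genome-wide
#' uniqueness filter, exclusion-list filter, and proximal-site filter, in that
#' order. A tag is retained iff it carries no flag; per-stage counts are
#' recorded for auditability. Deterministic for fixed inputs.
#'
#' @param genome Named character vector of contig sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param cfg A [filter_config()].
#' @return An object of class `dalec_tagdb`: list with `tags` (data.frame with
#'   stable integer `id`, flags and `retained` column), `sites` (data.frame of
#'   contig/pos), `retained_lookup` (named integer vector tag16 -> row index),
#'   `contig_lengths`, `cfg`, `stage_counts`.
#' @export
build_tag_database <- function(genome, cfg = filter_config()) {
  genome <- as_genome(genome)
  stopifnot(length(genome) > 0L)
  site_list <- lapply(genome, scan_gatc_sites)
  tag_list <- mapply(function(nm, seq, sites) extract_half_site_tags(nm, seq, sites),
                     names(genome), genome, site_list, SIMPLIFY = FALSE)
  tags <- do.call(rbind, tag_list)
  rownames(tags) <- NULL
  sites <- data.frame(
    contig = rep(names(genome), lengths(site_list)),
    pos = unlist(site_list, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  n_all <- nrow(tags)
  tags <- mark_nonunique(tags)
  tags <- mark_excluded(tags, cfg)
  tags <- mark_proximal(tags, cfg)
  tags$retained <- !(tags$edge_truncated | tags$nonunique |
                       tags$proximal_excluded | tags$on_exclusion_list)
  tags <- cbind(id = seq_len(n_all), tags)
  ret_tags <- tags$tag16[tags$retained]
  if (anyDuplicated(ret_tags)) {
    stop("internal consistency failure: duplicate retained tag16 after uniqueness filter")
  }
  lookup <- structure(which(tags$retained), names = ret_tags)
  structure(list(
    tags = tags,
    sites = sites,
    retained_lookup = lookup,
    contig_lengths = vapply(genome, nchar, integer(1)),
    cfg = cfg,
    stage_counts = c(
      sites = nrow(sites),
      extracted = n_all,
      edge_truncated = sum(tags$edge_truncated),
      nonunique = sum(tags$nonunique),
      on_exclusion_list = sum(tags$on_exclusion_list),
      proximal_excluded = sum(tags$proximal_excluded),
      retained = sum(tags$retained)
    )
  ), class = "dalec_tagdb")
}

#' @export
print.dalec_tagdb <- function(x, ...) {
  cat("DAM half-site tag database\n")
  cat("  contigs:", length(x$contig_lengths),
      " total bp:", sum(x$contig_lengths), "\n")
  cat("  GATC sites:", x$stage_counts[["sites"]],
      " tags extracted:", x$stage_counts[["extracted"]], "\n")
  cat("  flagged: edge", x$stage_counts[["edge_truncated"]],
      "| nonunique", x$stage_counts[["nonunique"]],
      "| exclusion-list", x$stage_counts[["on_exclusion_list"]],
      "| proximal", x$stage_counts[["proximal_excluded"]], "\n")
  cat("  retained:", x$stage_counts[["retained"]], "\n")
  invisible(x)
}

#' Count GATC occurrences across a genome assembly
#'
#' Convenience census used to check an assembly's haploid DAM site count.
#'
#' @param fasta Path to a (multi-)FASTA file.
#' @return Total number of GATC occurrences across all records.
#' @export
gatc_site_census <- function(fasta) {
  genome <- read_fasta(fasta)
  sum(vapply(genome, function(s) length(scan_gatc_sites(s)), integer(1)))
}

#' Average fold coverage per half-site
#'
#' Ratio of uniquely aligned tag count to the number of capturable half-sites:
#' two half-sites per GATC site, times ploidy.
#'
#' @param unique_tags Number of uniquely aligned tags.
#' @param sites_haploid Number of GATC sites per haploid genome.
#' @param ploidy Genome copy number (default 2, diploid).
#' @return Fold coverage (numeric).
#' @export
average_fold_coverage <- function(unique_tags, sites_haploid, ploidy = 2) {
  unique_tags / (sites_haploid * 2 * ploidy)
}

# Coerce genome inputs to a named uppercase character vector.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else {
    out <- genome
  }
  stopifnot(is.character(out))
  if (is.null(names(out)) || any(names(out) == "")) {
    names(out) <- paste0("contig", seq_along(out))
  }
  toupper(out)
}
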