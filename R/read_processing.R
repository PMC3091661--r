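#' Parse raw reads into 16-nt half-site tags
#'
#' Locates the earliest exact occurrence of the first 15 bases of the read's
#' linker suffix (the reverse complement of linker A's top strand). The prefix
#' before it is the genomic portion; parsing succeeds iff that portion is
#' 18-21 bases long, ends in "GA" (the remnant of the cleaved GATC), and
#' contains no ambiguous base. The tag is the 16 bases immediately upstream of
#' the terminal GA.
#'
#' @param seqs Character vector of read sequences.
#' @param linkers A [linker_set()].
#' @return data.frame with `tag16` (NA unless parsed), `parsed_length`
#'   (genomic-portion length, NA if no linker found), and `status`, one of
#'   `parsed`, `no_linker`, `bad_length`, `no_GA_terminus`, `ambiguous_base`.
#' @export
parse_reads <- function(seqs, linkers = linker_set()) {
  n <- length(seqs)
  if (n == 0L) {
    return(data.frame(tag16 = character(0), parsed_length = integer(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  seed <- substr(linkers$read_linker_suffix, 1L, 15L)
  hit <- regexpr(seed, seqs, fixed = TRUE)
  plen <- ifelse(hit > 0L, as.integer(hit) - 1L, NA_integer_)
  portion <- ifelse(hit > 0L, substr(seqs, 1L, pmax(plen, 0L)), NA_character_)
  status <- rep("parsed", n)
  status[hit <= 0L] <- "no_linker"
  bad_len <- !is.na(plen) & (plen < 18L | plen > 21L)
  status[status == "parsed" & bad_len] <- "bad_length"
  no_ga <- !is.na(portion) &
    substr(portion, pmax(plen - 1L, 1L), plen) != "GA"
  status[status == "parsed" & no_ga] <- "no_GA_terminus"
  ambig <- !is.na(portion) & grepl("[^ACGT]", portion)
  status[status == "parsed" & ambig] <- "ambiguous_base"
  ok <- status == "parsed"
  tag16 <- rep(NA_character_, n)
  tag16[ok] <- substr(portion[ok], plen[ok] - 17L, plen[ok] - 2L)
  data.frame(tag16 = tag16, parsed_length = plen, status = status,
             stringsAsFactors = FALSE)
}

#' Align parsed tags to the retained tag database by exact match
#'
#' A hit requires a perfect 16-nucleotide match against a retained database
#' tag; because every database tag is constrained to be followed by GATC in
#' the genome and is unique genome-wide, a hit implies a unique 20-nt perfect
#' genomic match. No mismatches are tolerated.
#'
#' @param tag16 Character vector of parsed 16-mers (NA allowed).
#' @param db A [build_tag_database()] object.
#' @return Integer vector of half-site ids (rows of `db$tags`), NA for misses.
#' @export
align_tags <- function(tag16, db) {
  row <- unname(db$retained_lookup[tag16])
  ifelse(is.na(row), NA_integer_, db$tags$id[row])
}

#' Count aligned reads per half-site
#'
#' Streams reads through [parse_reads()] and [align_tags()]; every aligned
#' read increments its half-site count (no deduplication: the assay's signal
#' is per-molecule capture frequency). Totals are recorded at each stage.
#'
#' Duplicate read sequences are collapsed internally before parsing and the
#' results re-expanded by multiplicity; this is an exact optimisation, not an
#' approximation.
#'
#' @param reads Character vector of read sequences, a data.frame with a `seq`
#'   column, or a path to a FASTQ file (optionally gzipped).
#' @param db A [build_tag_database()] object.
#' @param sample Sample label.
#' @param linkers A [linker_set()].
#' @return Object of class `dalec_hits`: list with `sample`, `counts` (integer
#'   vector indexed by `db$tags$id`, zero for unretained half-sites), `totals`
#'   (`raw`, `parsed`, `aligned`) and `parse_stats` (named counts by status).
#' @export
count_hits <- function(reads, db, sample = "sample", linkers = linker_set()) {
  ht <- new_hit_table(db, sample)
  accumulate_hits(ht, reads, db, linkers)
}

#' @rdname count_hits
#' @param ht An existing `dalec_hits` object to accumulate into.
#' @export
accumulate_hits <- function(ht, reads, db, linkers = linker_set()) {
  if (is.character(reads) && length(reads) == 1L &&
      (file.exists(reads) || grepl("\\.(fastq|fq)(\\.gz)?$", reads))) {
    reads <- read_fastq(reads)$seq
  } else if (is.data.frame(reads)) {
    reads <- reads$seq
  }
  stopifnot(is.character(reads))
  if (length(reads) == 0L) return(ht)
  uniq <- unique(reads)
  mult <- tabulate(match(reads, uniq), nbins = length(uniq))
  parsed <- parse_reads(uniq, linkers)
  ids <- align_tags(parsed$tag16, db)
  ht$totals["raw"] <- ht$totals["raw"] + length(reads)
  for (st in unique(parsed$status)) {
    ht$parse_stats[st] <- (if (st %in% names(ht$parse_stats)) ht$parse_stats[[st]] else 0L) +
      sum(mult[parsed$status == st])
  }
  ht$totals["parsed"] <- ht$totals["parsed"] + sum(mult[parsed$status == "parsed"])
  hitrows <- which(!is.na(ids))
  ht$totals["aligned"] <- ht$totals["aligned"] + sum(mult[hitrows])
  if (length(hitrows) > 0L) {
    add <- tapply(mult[hitrows], ids[hitrows], sum)
    idx <- as.integer(names(add))
    ht$counts[idx] <- ht$counts[idx] + as.integer(add)
  }
  ht
}

#' @rdname count_hits
#' @export
new_hit_table <- function(db, sample = "sample") {
  structure(list(sample = sample,
                 counts = integer(nrow(db$tags)),
                 totals = c(raw = 0L, parsed = 0L, aligned = 0L),
                 parse_stats = integer(0)),
            class = "dalec_hits")
}

#' @export
print.dalec_hits <- function(x, ...) {
  cat("DALEC hit table for sample '", x$sample, "'\n", sep = "")
  cat("  raw:", x$totals[["raw"]], " parsed:", x$totals[["parsed"]],
      " aligned:", x$totals[["aligned"]], "\n")
  cat("  half-sites hit:", sum(x$counts > 0L), "\n")
  invisible(x)
}

#' Simulate a sample and count its hits in one streamed pass
#'
#' Convenience wrapper composing [simulate_sample_reads()] with
#' [accumulate_hits()] chunk by chunk, so deep libraries never hold all reads
#' in memory. Also accumulates the true capture counts per half-site from the
#' simulator's ground truth.
#'
#' @inheritParams simulate_sample_reads
#' @param db A [build_tag_database()] for the same genome.
#' @return List with `hits` (a `dalec_hits`) and `truth` (data.frame `contig`,
#'   `site_pos`, `strand`, `captures`: true per-half-site capture counts).
#' @export
simulate_hit_table <- function(genome, tracks, meth, db, sim = sim_config(),
                               linkers = linker_set()) {
  ht <- new_hit_table(db, sim$sample_label)
  key <- paste(db$tags$contig, db$tags$site_pos, db$tags$strand)
  truth_counts <- integer(nrow(db$tags))
  cb <- function(chunk) {
    ht <<- accumulate_hits(ht, chunk$seq, db, linkers)
    tkey <- paste(chunk$truth_contig, chunk$truth_site, chunk$truth_strand)
    m <- match(tkey, key)
    tt <- table(m[!is.na(m)])
    idx <- as.integer(names(tt))
    truth_counts[idx] <<- truth_counts[idx] + as.integer(tt)
  }
  simulate_sample_reads(genome, tracks, meth, sim, linkers, callback = cb)
  truth <- data.frame(contig = db$tags$contig, site_pos = db$tags$site_pos,
                      strand = db$tags$strand, captures = truth_counts,
                      stringsAsFactors = FALSE)
  list(hits = ht, truth = truth)
}
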