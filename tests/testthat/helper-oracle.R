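# Brute-force oracles, written directly from the method description and kept
# independent of the package implementation.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# sliding-window scan for the GATC tetramer; 0-based positions
oracle_scan_gatc <- function(seq) {
  n <- nchar(seq)
  if (n < 4L) return(integer(0))
  pos <- integer(0)
  for (i in 0:(n - 4L)) {
    if (substr(seq, i + 1L, i + 4L) == "GATC") pos <- c(pos, i)
  }
  pos
}

# full retained-tag set computed by direct enumeration: two 16-nt tags per
# site, drop tags without full context, drop 16-mers seen more than once,
# drop tags whose 20-mer occurs in an exclusion sequence (either strand),
# drop the inward-facing pair of sites with gap < threshold
oracle_retained_tags <- function(seq, proximal = 20L, exclusions = character(0)) {
  sites <- oracle_scan_gatc(seq)
  tags <- list()
  for (p in sites) {
    if (p >= 16L) {
      t16 <- substr(seq, p - 15L, p)
      tags[[length(tags) + 1L]] <- list(pos = p, strand = "+", tag16 = t16)
    }
    if (p + 20L <= nchar(seq)) {
      t16 <- oracle_revcomp(substr(seq, p + 5L, p + 20L))
      tags[[length(tags) + 1L]] <- list(pos = p, strand = "-", tag16 = t16)
    }
  }
  all16 <- vapply(tags, function(t) t$tag16, character(1))
  keep <- rep(TRUE, length(tags))
  for (i in seq_along(tags)) {
    if (sum(all16 == tags[[i]]$tag16) > 1L) keep[i] <- FALSE
    if (grepl("[^ACGT]", tags[[i]]$tag16)) keep[i] <- FALSE
    mer <- paste0(tags[[i]]$tag16, "GATC")
    for (e in exclusions) {
      if (grepl(mer, e, fixed = TRUE) ||
          grepl(mer, oracle_revcomp(e), fixed = TRUE)) keep[i] <- FALSE
    }
  }
  if (length(sites) > 1L) {
    for (j in seq_len(length(sites) - 1L)) {
      if (sites[j + 1L] - (sites[j] + 4L) < proximal) {
        for (i in seq_along(tags)) {
          if (tags[[i]]$pos == sites[j] && tags[[i]]$strand == "-") keep[i] <- FALSE
          if (tags[[i]]$pos == sites[j + 1L] && tags[[i]]$strand == "+") keep[i] <- FALSE
        }
      }
    }
  }
  out <- tags[keep]
  data.frame(pos = vapply(out, `[[`, integer(1), "pos"),
             strand = vapply(out, `[[`, character(1), "strand"),
             tag16 = vapply(out, `[[`, character(1), "tag16"),
             stringsAsFactors = FALSE)
}

# number of occurrences of tag16 followed by GATC on either genome strand
oracle_tag_matches <- function(tag16, seq) {
  mer <- paste0(tag16, "GATC")
  count_occ <- function(pat, s) {
    n <- 0L; from <- 1L
    repeat {
      i <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
      if (i < 0L) break
      n <- n + 1L
      from <- from + as.integer(i)
    }
    n
  }
  count_occ(mer, seq) + count_occ(mer, oracle_revcomp(seq))
}

random_genome <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}
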