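test_that("GATC scanning finds literal motif occurrences", {
  expect_equal(scan_gatc_sites("AAGATCTT"), 2L)
  expect_equal(scan_gatc_sites("GATCGATC"), c(0L, 4L))
  expect_equal(scan_gatc_sites(""), integer(0))
  expect_equal(scan_gatc_sites("ACG"), integer(0))
})

test_that("GATC scan agrees with a sliding-window brute force on random sequence", {
  g <- random_genome(10000L, seed = 11L)
  expect_equal(scan_gatc_sites(g), oracle_scan_gatc(g))
})

test_that("half-site tags follow the oriented 16-mer definition", {
  g <- "ACGTACGTACGTACGTGATCTTTTAAAACCCCGGGG"
  tags <- extract_half_site_tags("c", g, scan_gatc_sites(g))
  plus <- tags[tags$strand == "+", ]
  minus <- tags[tags$strand == "-", ]
  expect_equal(plus$tag16, "ACGTACGTACGTACGT")
  expect_equal(minus$tag16, "CCCCGGGGTTTTAAAA")
  expect_false(any(tags$edge_truncated))
})

test_that("insufficient context truncates tags instead of erroring", {
  g <- "AAGATCTTTTTTTTTTTTTTTTTTTTTTTTTT"  # GATC at pos 2
  tags <- extract_half_site_tags("c", g, scan_gatc_sites(g))
  expect_true(tags$edge_truncated[tags$strand == "+"])
  expect_false(tags$edge_truncated[tags$strand == "-"])
  g2 <- "ACGTACGTACGTACGNGATCTTTTAAAACCCCGGGG"  # N in plus context
  tags2 <- extract_half_site_tags("c", g2, scan_gatc_sites(g2))
  expect_true(tags2$edge_truncated[tags2$strand == "+"])
})

test_that("plus tags equal the mirrored minus tags of the reverse-complemented genome", {
  g <- random_genome(5000L, seed = 12L)
  rc <- oracle_revcomp(g)
  tags <- extract_half_site_tags("c", g, scan_gatc_sites(g))
  tags_rc <- extract_half_site_tags("c", rc, scan_gatc_sites(rc))
  interior <- !tags$edge_truncated
  # mirrored coordinate of a site start: L - 4 - pos
  key <- paste(nchar(g) - 4L - tags$site_pos,
               ifelse(tags$strand == "+", "-", "+"), tags$tag16)
  key_rc <- paste(tags_rc$site_pos, tags_rc$strand, tags_rc$tag16)
  expect_true(all(key[interior] %in% key_rc))
})

test_that("uniqueness flagging matches a multiset count of 16-mers", {
  ctx <- "TTGACCATGCAAGGCT"
  g <- paste0("CCCCCCCCCCCCCCCC", ctx, "GATC", "AAACCCGGGTTTAAACCCGGGTTTAAACC",
              ctx, "GATC", "GGGGGGGGGGGGGGGGGGGG")
  db <- build_tag_database(c(c1 = g))
  dup_rows <- db$tags$tag16 == ctx
  expect_true(all(db$tags$nonunique[dup_rows]))
  g2 <- random_genome(50000L, seed = 13L)
  tags <- mark_nonunique(extract_half_site_tags("c", g2, scan_gatc_sites(g2)))
  full <- !tags$edge_truncated
  counts <- table(tags$tag16[full])
  expect_equal(tags$nonunique[full],
               as.vector(counts[tags$tag16[full]] > 1L))
  expect_false(any(tags$nonunique[!full]))
})

test_that("proximal filter excludes exactly the inward-facing pair below the gap threshold", {
  mk <- function(gap) {
    pad <- random_genome(40L, seed = 5L)
    paste0(pad, "GATC", strrep("A", gap), "GATC", pad)
  }
  g <- mk(10L)  # sites at 40 and 54, gap 10
  sites <- scan_gatc_sites(g)
  tags <- mark_proximal(extract_half_site_tags("c", g, sites), filter_config())
  flagged <- tags[tags$proximal_excluded, ]
  expect_equal(nrow(flagged), 2L)
  expect_true(all(paste(flagged$site_pos, flagged$strand) %in%
                    c(paste(sites[1], "-"), paste(sites[2], "+"))))
  g20 <- mk(20L)  # boundary: gap exactly 20 is kept (strict <)
  tags20 <- mark_proximal(extract_half_site_tags("c", g20, scan_gatc_sites(g20)),
                          filter_config())
  expect_false(any(tags20$proximal_excluded))
  iso <- paste0(random_genome(30L, 6L), "GATC", random_genome(30L, 7L))
  tiso <- mark_proximal(extract_half_site_tags("c", iso, scan_gatc_sites(iso)),
                        filter_config())
  expect_false(any(tiso$proximal_excluded))
})

test_that("exclusion-list flagging equals brute-force substring search", {
  g <- random_genome(20000L, seed = 14L)
  tags <- extract_half_site_tags("c", g, scan_gatc_sites(g))
  none <- mark_excluded(tags, filter_config())
  expect_false(any(none$on_exclusion_list))
  # one exclusion sequence equal to a tag 20-mer, one random decoy
  full <- which(!tags$edge_truncated)
  mer <- paste0(tags$tag16[full[3]], "GATC")
  cfg <- filter_config(exclusion_sequences = c(mer, random_genome(500L, 15L)))
  marked <- mark_excluded(tags, cfg)
  for (i in full) {
    expect_equal(marked$on_exclusion_list[i],
                 grepl(paste0(tags$tag16[i], "GATC"), mer, fixed = TRUE) ||
                   oracle_tag_matches(tags$tag16[i], cfg$exclusion_sequences[2]) > 0)
  }
})

test_that("full database pipeline is conservative and matches the brute-force oracle", {
  g <- random_genome(30000L, seed = 16L)
  db <- build_tag_database(c(chr = g))
  # count conservation: retained + union-flagged = all
  flagged <- with(db$tags, edge_truncated | nonunique | proximal_excluded |
                    on_exclusion_list)
  expect_equal(sum(db$tags$retained) + sum(flagged), nrow(db$tags))
  expect_lte(sum(db$tags$retained), 2L * nrow(db$sites))
  ora <- oracle_retained_tags(g)
  got <- db$tags[db$tags$retained, ]
  expect_setequal(paste(got$site_pos, got$strand, got$tag16),
                  paste(ora$pos, ora$strand, ora$tag16))
})

test_that("database of a reverse-complemented genome mirrors the original", {
  g <- random_genome(20000L, seed = 17L)
  db <- build_tag_database(c(chr = g))
  db_rc <- build_tag_database(c(chr = oracle_revcomp(g)))
  expect_setequal(db$tags$tag16[db$tags$retained],
                  db_rc$tags$tag16[db_rc$tags$retained])
})

test_that("hand-countable proximal cluster retains the expected tags", {
  # three sites, gaps 8 and 30: inward pair of the close pair removed
  g <- paste0(random_genome(30L, 8L), "GATC", strrep("C", 8L), "GATC",
              strrep("T", 30L), "GATC", random_genome(30L, 9L))
  db <- build_tag_database(c(chr = g))
  sites <- db$sites$pos
  expect_equal(length(sites), 3L)
  ret <- db$tags[db$tags$retained, ]
  # site1 minus and site2 plus are gone; everything else retained
  expect_setequal(paste(ret$site_pos, ret$strand),
                  c(paste(sites[1], "+"), paste(sites[2], "-"),
                    paste(sites[3], "+"), paste(sites[3], "-")))
})

test_that("GATC census totals across multi-record FASTA", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(a = "GATCGATCAAA", b = "TTGATCTT"), tmp)
  expect_equal(gatc_site_census(tmp), 3L)
})
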