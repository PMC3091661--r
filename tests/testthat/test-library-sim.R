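test_that("accessibility track reflects planted nucleosomes", {
  ann <- data.frame(txStart = 0L, txEnd = 1000L, strand = "+",
                    access_multiplier = 1)
  flat <- nucleosome_track(nucleosome_model(dyads_rel = integer(0),
                                            ndr_protection = 0),
                           ann, 1000L, baseline = 1)
  expect_equal(flat, rep(1, 1000L))
  m <- nucleosome_model(dyads_rel = 500L, depth = 0.9, ndr_protection = 0)
  tr <- nucleosome_track(m, ann, 1000L, baseline = 1)
  expect_equal(which.min(tr), 501L)
  expect_equal(min(tr), 0.1, tolerance = 1e-9)
  outside <- c(1:(501L - 80L), (501L + 80L):1000L)
  expect_true(all(tr[outside] == 1))
})

test_that("phased nucleosome array yields occupancy autocorrelation at the spacing", {
  ann <- data.frame(txStart = 500L, txEnd = 2500L, strand = "+",
                    access_multiplier = 1)
  m <- nucleosome_model(dyads_rel = seq(100L, 1900L, by = 180L),
                        ndr_protection = 0)
  tr <- nucleosome_track(m, ann, 3000L, baseline = 1)
  occ <- 1 - tr[601:2300]
  ac <- stats::acf(occ, lag.max = 200L, plot = FALSE)$acf[, 1, 1]
  expect_gt(ac[181L], ac[91L])   # lag 180 beats lag 90
  expect_gt(ac[181L], ac[136L])  # and the midpoint lag
})

test_that("methylation sampling follows per-strand independent Bernoulli rates", {
  g <- paste0(strrep("A", 20L), "GATC", strrep("T", 20L))
  sites <- scan_gatc_sites(g)
  none <- simulate_molecules(g, sites, rep(0, nchar(g)),
                             methylation_config(0.8), n = 50L, seed = 1L)
  expect_false(any(vapply(none, function(m) any(m$top | m$bottom), logical(1))))
  full <- simulate_molecules(g, sites, rep(1, nchar(g)),
                             methylation_config(0.9), n = 4000L, seed = 2L)
  frac_double <- mean(vapply(full, function(m) m$top & m$bottom, logical(1)))
  se <- sqrt(0.81 * 0.19 / 4000)
  expect_lt(abs(frac_double - 0.81), 4 * se)
})

test_that("methylation-sensitive cutting predicates implement the isoschizomer logic", {
  top <- c(TRUE, TRUE, FALSE, FALSE)
  bottom <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(dpnI_cuts(top, bottom), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(mboI_cuts(top, bottom), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(sau3aI_cuts(top, bottom), rep(TRUE, 4L))
})

test_that("restriction digest cuts doubly-methylated sites and protects internal ones", {
  mol <- data.frame(site_pos = c(100L, 200L, 300L),
                    top = c(TRUE, TRUE, TRUE),
                    bottom = c(TRUE, FALSE, TRUE))
  fr <- dpnI_digest(mol, 400L)
  expect_equal(fr$start, c(0L, 102L, 302L))
  expect_equal(fr$end, c(102L, 302L, 400L))
  expect_equal(fr$internal_sites[[2]], 200L)  # hemimethylated site protected
  expect_equal(sum(fr$end - fr$start), 400L)
  none <- dpnI_digest(transform(mol, bottom = FALSE), 400L)
  expect_equal(nrow(none), 1L)
  expect_equal(c(none$start, none$end), c(0L, 400L))
  all_cut <- dpnI_digest(transform(mol, bottom = TRUE), 400L)
  expect_equal(nrow(all_cut), 3L + 1L)
  # conservation: fragment lengths tile the molecule
  expect_equal(sum(all_cut$end - all_cut$start), 400L)
  # protection: no fragment contains a doubly-methylated internal site
  expect_true(all(lengths(all_cut$internal_sites) == 0L))
})

test_that("fragment-end capture yields one readout per cut end, one total for short duplexes", {
  fr <- data.frame(start = 102L, end = 302L, left_site = 100L, right_site = 300L)
  fr$internal_sites <- list(integer(0))
  set.seed(1)
  ro <- capture_fragment_ends(fr, cfg = sim_config())
  expect_equal(nrow(ro), 2L)
  expect_setequal(paste(ro$site_pos, ro$strand), c("100 -", "300 +"))
  short <- data.frame(start = 102L, end = 114L, left_site = 100L,
                      right_site = 112L)
  short$internal_sites <- list(integer(0))
  n_per <- replicate(200L, nrow(capture_fragment_ends(short, cfg = sim_config())))
  expect_true(all(n_per == 1L))
  # terminal fragment: single cut end captured
  term <- data.frame(start = 0L, end = 102L, left_site = NA_integer_,
                     right_site = 100L)
  term$internal_sites <- list(integer(0))
  rt <- capture_fragment_ends(term, cfg = sim_config())
  expect_equal(paste(rt$site_pos, rt$strand), "100 +")
})

test_that("type IIS slop lengths follow the configured distribution", {
  fr <- data.frame(start = 102L, end = 302L, left_site = 100L, right_site = 300L)
  fr$internal_sites <- list(integer(0))
  set.seed(7)
  lens <- unlist(replicate(5000L, capture_fragment_ends(fr)$length,
                           simplify = FALSE))
  emp <- table(factor(lens, levels = 19:21)) / length(lens)
  expect_equal(as.numeric(emp), c(0.15, 0.70, 0.15), tolerance = 0.03)
})

test_that("doubly-linkered molecule has the published geometry and amplifies", {
  ins20 <- paste0(strrep("ACGT", 4L), "CTGA")
  asm <- assemble_library_molecule(ins20)
  expect_equal(nchar(asm$top_strand), 116L)
  expect_equal(nchar(asm$bottom_strand), 71L)
  expect_true(asm$amplifiable)
  asm21 <- assemble_library_molecule(paste0("T", ins20))
  expect_equal(nchar(asm21$top_strand), 117L)
  expect_equal(nchar(asm21$bottom_strand), 72L)
  # non-default linker that breaks primer annealing is flagged
  bad <- linker_set(linkerA_top = paste0("T", linker_set()$linkerA_top))
  expect_false(assemble_library_molecule(ins20, bad)$amplifiable)
})

test_that("emitted reads are the reverse-complement assembly ending in the linker", {
  g <- "ACGTACGTACGTACGTGATCTTTTAAAACCCCGGGG"
  ro <- data.frame(site_pos = 16L, strand = "+", length = 18L)
  rd <- emit_reads(ro, g, cfg = sim_config())
  expect_equal(substr(rd$seq, 1L, 18L), "ACGTACGTACGTACGTGA")
  expect_equal(substr(rd$seq, 19L, 36L), "GTCGGAACATAGTGTACT")
  expect_equal(nchar(rd$seq), 36L)
  # error rate 0: genomic prefix matches the genome exactly for every slop
  g2 <- paste0(g, "ACGTT")  # room for the longest minus-strand capture
  for (L in 19:21) {
    rom <- data.frame(site_pos = 16L, strand = "-", length = L)
    rdm <- emit_reads(rom, g2, cfg = sim_config())
    expect_equal(substr(rdm$seq, 1L, L),
                 oracle_revcomp(substr(g2, 19L, 18L + L)))
  }
  # a capture whose genomic portion runs off the contig is dropped, not padded
  off <- emit_reads(data.frame(site_pos = 16L, strand = "-", length = 21L),
                    g, cfg = sim_config())
  expect_equal(nrow(off), 0L)
})

test_that("vectorised sampler matches analytic capture expectations", {
  st <- small_study()
  n <- 2000L
  res <- simulate_hit_table(st$world$genome, st$world$tracks,
                            control_methylation_config(), st$db,
                            sim = sim_config(n_molecules = n, seed = 5L))
  exp_rate <- expected_capture_rate(st$world$genome, st$world$tracks,
                                    control_methylation_config())
  key <- paste(exp_rate$contig, exp_rate$site_pos, exp_rate$strand)
  tkey <- paste(res$truth$contig, res$truth$site_pos, res$truth$strand)
  e <- exp_rate$expected_rate[match(tkey, key)] * n
  obs <- res$truth$captures
  interior <- e > 100
  z <- (obs[interior] - e[interior]) / sqrt(e[interior])
  expect_lt(mean(abs(z)), 2)          # typical deviation is binomial-sized
  expect_lt(abs(mean(z)), 0.2)        # and unbiased
  # readouts never exceed two per cut, so total <= 2 * molecules * sites
  expect_lte(sum(obs), 2L * n * nrow(st$db$sites))
})

test_that("expected capture rate is monotone in accessibility", {
  st <- small_study()
  rate <- expected_capture_rate(st$world$genome, st$world$tracks,
                                methylation_config(0.8))
  acc <- vapply(rate$site_pos, function(p) {
    mean(st$world$tracks[[1]][(p + 1L):(p + 4L)])
  }, numeric(1))
  ord <- order(acc)
  # rates sorted by accessibility are non-decreasing up to collision discounts
  expect_gt(stats::cor(acc, rate$expected_rate, method = "spearman"), 0.95)
})

test_that("synthetic dataset bundle is deterministic and complete", {
  cfg <- synthetic_config(n_genes = 4L, gene_length = 600L, n_molecules = 40L,
                          seed = 31L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- generate_synthetic_dataset(cfg, d1)
  b2 <- generate_synthetic_dataset(cfg, d2)
  for (nm in names(b1$paths)) {
    expect_equal(unname(tools::md5sum(b1$paths[[nm]])),
                 unname(tools::md5sum(b2$paths[[nm]])),
                 label = paste("bundle file", nm))
  }
  # genes never overlap
  ann <- b1$annotation
  expect_true(all(ann$txStart[-1L] >= ann$txEnd[-nrow(ann)]))
})

test_that("zero-molecule bundle still writes valid empty libraries and truth tables", {
  cfg <- synthetic_config(n_genes = 3L, gene_length = 500L, n_molecules = 0L,
                          seed = 32L)
  d <- withr::local_tempdir()
  b <- generate_synthetic_dataset(cfg, d)
  reads <- read_fastq(b$paths[["tissue_fastq"]])
  expect_equal(nrow(reads), 0L)
  truth <- read.table(b$paths[["truth_capture"]], header = TRUE, sep = "\t")
  expect_gt(nrow(truth), 0L)
  expect_true(all(truth$expected_rate >= 0 & truth$expected_rate <= 1))
})
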