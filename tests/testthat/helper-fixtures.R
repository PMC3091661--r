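# Shared fixtures, built once per test run and memoised. The deep-coverage
# study (10,000 molecules per sample) backs the parameter-recovery,
# flat-control and phasing checks; the many-gene null study backs the
# p-value calibration check.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 40 genes, ~50 kb, deep sequencing of tissue and in-vitro control
deep_study <- function() {
  memo("deep_study", function() {
    cfg <- synthetic_config(n_genes = 40L, gene_length = 900L,
                            intergenic = 350L, seed = 20260921L)
    world <- synthetic_world(cfg)
    db <- build_tag_database(world$genome)
    tissue <- simulate_hit_table(
      world$genome, world$tracks, methylation_config(cfg$p_max_tissue), db,
      sim = sim_config(n_molecules = 10000L,
                       seed = sample_seed_fixture(cfg$seed, "tissue"),
                       sample_label = "tissue"))
    control <- simulate_hit_table(
      world$genome, world$tracks, control_methylation_config(cfg$p_max_control), db,
      sim = sim_config(n_molecules = 10000L,
                       seed = sample_seed_fixture(cfg$seed, "control"),
                       sample_label = "control"))
    list(cfg = cfg, world = world, db = db,
         tissue = tissue$hits, tissue_truth = tissue$truth,
         control = control$hits, control_truth = control$truth)
  })
}

# 150 short genes, two independent in-vitro control libraries
null_study <- function() {
  memo("null_study", function() {
    cfg <- synthetic_config(n_genes = 150L, gene_length = 500L,
                            intergenic = 200L, site_spacing = 120L,
                            seed = 4177L)
    world <- synthetic_world(cfg)
    db <- build_tag_database(world$genome)
    # sparse sequencing (each capture observed with probability 0.1) puts the
    # libraries in the near-Poisson regime the conditional test assumes
    make_ctl <- function(label) {
      simulate_hit_table(
        world$genome, world$tracks, control_methylation_config(cfg$p_max_control),
        db, sim = sim_config(n_molecules = 1500L,
                             seed = sample_seed_fixture(cfg$seed, label),
                             sequencing_fraction = 0.1,
                             sample_label = label))$hits
    }
    list(cfg = cfg, world = world, db = db,
         ctl_a = make_ctl("ctl_a"), ctl_b = make_ctl("ctl_b"))
  })
}

# mirrors the package's per-sample seed derivation without touching internals
sample_seed_fixture <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647)
}

# small deterministic world for cheap unit tests
small_study <- function() {
  memo("small_study", function() {
    cfg <- synthetic_config(n_genes = 6L, gene_length = 700L,
                            intergenic = 250L, n_molecules = 300L,
                            seed = 99L)
    world <- synthetic_world(cfg)
    db <- build_tag_database(world$genome)
    list(cfg = cfg, world = world, db = db)
  })
}

# mean planted accessibility at each anchor-relative offset, strand-aware
profile_track_average <- function(world, offsets) {
  tr <- world$tracks[[1L]]
  n <- length(tr)
  vapply(offsets, function(d) {
    pos <- ifelse(world$anchors$strand == "-",
                  world$anchors$dyad - d, world$anchors$dyad + d)
    pos <- pos[pos >= 0L & pos < n]
    if (length(pos) == 0L) return(NA_real_)
    mean(tr[pos + 1L])
  }, numeric(1))
}
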