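---
title: "Models and methods behind dalec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dalec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dalec)
```

## The assay in one paragraph

A bacterial adenine methyltransferase (DAM) expressed in a chosen tissue
methylates GATC sites in proportion to their chromatin accessibility. Dpn I
cleaves only sites methylated on both strands; ligation of a branched linker
carrying an Mme I site to each blunt cut, followed by Mme I digestion,
releases ~20 bp of flanking genomic sequence, which is ligated to a second
linker and sequenced. A read therefore reports one *half-site*: one of the
two oriented 16-nt contexts of a GATC. Counts of reads per half-site,
normalised against a naked-DNA control methylated in vitro, measure
accessibility. This package implements the tag database, a forward simulator
of the whole protocol, read parsing and alignment, gene-level quantification,
and nucleosome dyad metaprofiles.

## Coordinates and conventions

All coordinates are 0-based, half-open; BED output follows the same
convention. A GATC site is identified by the start of the tetramer; its
*midpoint* (`site_pos + 2`, the Dpn I blunt-cut position) is used wherever a
single position is needed (gene-body membership, metaprofile offsets),
regardless of half-site strand, since both half-sites of a site report the
same cleavage event.

## Tag database

Per site, the plus tag is `genome[pos-16, pos)` and the minus tag is the
reverse complement of `genome[pos+4, pos+20)`. Filters run in a fixed order —
genome-wide uniqueness, exclusion list, proximal sites — with per-stage
counts logged; a tag is retained iff it carries no flag.

Decisions taken where the design was open:

- **Edge and ambiguity handling.** Sites whose 16-nt context runs off the
  contig or contains a non-ACGT base are flagged `edge_truncated` and
  silently dropped rather than treated as errors: they are a property of the
  assembly, not of the input.
- **Uniqueness** is assessed on the multiset of all full-length 16-mers from
  both strands of all contigs. Truncated tags have no valid 16-mer and do not
  enter the multiset.
- **Proximal rule.** For consecutive sites with gap `pos2 - (pos1 + 4)`
  strictly below 20 bp, only the inward-facing pair (minus tag of the first
  site, plus tag of the second) is excluded: capture competition concerns the
  short *intervening* fragment, while the outward-facing ends are unaffected.
  The threshold is configurable. More elaborate near-threshold rules (e.g.
  capture bias of the type IIS enzyme slightly above 20 bp) are not
  modelled.
- **Exclusion list** matching uses the full captured 20-mer (tag + GATC)
  against both strands of each exclusion sequence. No default exclusion list
  ships: the vector/ribosomal sets are study-specific inputs.

A retained hit is a perfect 16-nt match, but because every database tag is
constrained to be followed by GATC and is unique genome-wide, it is
effectively a unique, perfect 20-nt genomic match.

## Protocol simulator

The simulator is the package's test bed: it produces reads *and* the ground
truth they were drawn from.

- **Methylation.** Each strand of each site is methylated independently with
  probability `p_max * a`, where `a` is the mean accessibility over the
  site's four bases. This is the simplest model consistent with partial
  digestion patterns; no kinetic model is attempted. Defaults: `p_max = 0.8`
  for tissue exposure, `0.9` with accessibility forced to 1 for the in-vitro
  control (deproteinised DNA is uniformly accessible to the enzyme).
- **Cutting.** Dpn I cuts iff both strands are methylated; hemimethylated
  sites are protected (the enzyme's residual activity on hemimethylated DNA,
  ~60-fold slower, is ignored by default). Companion predicates implement
  Mbo I (unmethylated only) and Sau3A I (always) for isoschizomer
  simulations. Consequently no fragment ever contains a doubly-methylated
  internal site, mirroring the cloning observation that fragments carry full
  methylation at both ends with unmethylated or hemimethylated sites inside.
- **Capture.** Only Dpn I-generated blunt ends are capturable; molecule ends
  are not. Each cut end yields the half-site entering the fragment. When the
  fragment duplex is shorter than 24 bp (the 20-bp type IIS reach plus the
  site), the two linkers compete and exactly one end is captured, uniformly
  at random — reproducing the proximal undercount that motivates the database
  filter. The captured length follows the Mme I cut-distance slop
  distribution `{19: 0.15, 20: 0.70, 21: 0.15}`, spanning the parser's
  accepted range.
- **Reads.** A read is the reverse complement of the captured top-strand
  insert (hence it ends in `GA` at the original GATC) followed by the reverse
  complement of linker A's top strand, truncated to 36 nt (Genome Analyzer I
  geometry), with Phred+33 qualities and optional uniform substitution
  errors (off by default, as the parser tolerates none).
- **Fast path.** The chunked sampler draws double-methylation events directly
  with probability `p^2` per molecule and site — distributionally identical
  to the per-strand sampler, since captures depend only on cut events — and
  precomputes the finite set of possible reads per (half-site, strand, slop).
  Tests verify it against the analytic expected capture rates.
- **Sequencing as sampling.** `sim_config(sequencing_fraction = f)` thins
  captures binomially. With `f = 1` (default) the simulator is a complete
  observer of `n_molecules` genome copies, which is convenient for
  truth-table checks but makes per-half-site counts Binomial(n, p≈0.8) —
  markedly underdispersed relative to Poisson. Real libraries sequence a tiny
  sample of an enormous molecule pool, so counts are near-Poisson; analyses
  whose statistics assume that regime (notably the between-library
  divergence test) should simulate with `f` well below 1, as the null
  calibration study does (`f = 0.1`).
- **Reproducibility.** Every sample derives its RNG stream from a master seed
  plus a label hash (kept below 2^31), so samples are independently
  reproducible and a fixed configuration yields a byte-identical bundle.

## Synthetic study generator

`synthetic_world()` lays out non-overlapping genes on one contig (default 50
genes of 900 bp with 350-bp spacers), plants GATC sites through gene bodies
at ~140-bp jittered spacing on top of the random-sequence background (~1 per
256 bp), and assigns each gene a latent activity `u ~ Uniform(0,1)` that
drives both its accessibility multiplier (linear in `u`, range 0.3–0.95) and
its SAGE-like expression score (Poisson with mean `12u`) — the monotone
expression–accessibility link the binning analysis is expected to recover.
Accessibility is `baseline * multiplier * (1 - occupancy)` clamped to [0,1],
with baseline 0.85; occupancy comes from raised-cosine nucleosome bumps
(half-width 73 bp, depth 0.9) at dyads −180, +35, +215, +395, +575 relative
to the TSS (strand-aware), plus a protected NDR window (protection 0.5) at
[−225, −75] relative to the first dyad, emulating the observed accessibility
valley upstream of promoters. Dyad anchors for metaprofiles are each gene's
+35 dyad.

What the generator does **not** emulate: PCR amplification bias and
duplicates, quality-score error profiles, transgene mosaicism or mixed
tissues, chromosome-scale accessibility domains, and a realistic genome
(repeats, base composition, ~100 Mb scale). Passing tests therefore show the
*pipeline* is correct and the *statistics* are calibrated under the stated
generative model, not that any biological conclusion transfers to real data.

## Quantification

- Counts are normalised to hits per million aligned reads before any ratio,
  making every statistic invariant to library scaling.
- The gene filter — at least four half-sites in the gene body each hit at
  least once in at least one sample of the comparison — follows the looser of
  the readings of the published filter wording; the choice is recorded here
  and in the function documentation. Genes with zero control coverage are
  excluded rather than pseudocounted, avoiding unbounded indices.
- The divergence test is the exact conditional binomial: given `x + y`, `x`
  is Binomial with success probability `N1/(N1+N2)` under equivalence, and
  the p-value is the doubled smaller tail capped at 1. The published analysis
  names only a significance level; this choice is the natural exact test for
  sequence-tag counts and is pluggable behind the same interface. The
  boundary curve reports, per total, the smallest imbalance that is both
  ≥ 2-fold and significant; significance dominates at small totals (no
  boundary exists), the fold criterion at large totals.
- Expression binning uses exact scores 0–8 plus a "9+" aggregate.

## Metaprofiles

Offsets are `midpoint - dyad`, sign-flipped for minus-strand anchors; the
half-width defaults to 1,000 bp. The profile value at an offset is total
hits over total half-sites at that offset — normalising accessibility by DAM
site density — and is undefined (never zero) where no half-site maps.
Anchors closer than twice the half-width both receive their shared
half-sites; the multiplicity is reported, not deduplicated. The moving
average (default 400-nt window) skips undefined offsets in both numerator
and denominator and truncates at the edges. Both raw and control-normalised
profiles are emitted, since either may be wanted downstream.

## Problem sizes and numerical choices

The test suite and the acceptance script validate on: a 40-gene / ~50-kb
study at 10,000 molecules per sample for parameter recovery (Spearman of
planted multiplier vs recovered index), control flatness (profile
coefficient of variation), and phasing recovery; a 150-gene / ~105-kb study
at 1,500 molecules with `sequencing_fraction = 0.1` for null calibration of
the divergence test; and ≤ 50-kb random genomes for brute-force oracle
equivalence of the tag database and alignment. These sizes were chosen so a
full validation runs in minutes on a laptop while keeping every estimate's
sampling error well inside its acceptance margin.

Degenerate inputs are defined, not errors: empty sequences scan to empty
site lists, zero-molecule simulations yield valid empty libraries with
complete truth tables, offsets without half-sites are NA, and genes without
retained half-sites have undefined means. Ties in the capture-collision rule
are broken by a fair coin; the proximal threshold is a strict inequality.

## Known limitations

- Alignment is exact 16-mer lookup by design; reads with sequencing errors
  in the tag are lost, not rescued (the real pipeline behaved the same).
- The WS170-specific numbers (site census, filtered tag count) depend on the
  assembly and on unpublished exclusion lists and near-threshold proximal
  criteria; the package reproduces the rules, not those exact counts.
- Hemimethylated leak-through of Dpn I, PCR artefacts, and Mme I sequence
  preference are not modelled.
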