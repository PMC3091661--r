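# dalec

Tissue-specific chromatin accessibility profiling from DAM methylation
footprints, with a full forward simulator of the molecular protocol.

## The problem and the method

Most genome-wide chromatin assays need the cell type of interest purified in
bulk. An alternative is to express bacterial DNA adenine methyltransferase
(DAM) from a tissue-specific promoter: in the living cell, DAM methylates the
adenine of GATC wherever chromatin leaves the site accessible, so the
methylation pattern is an in-vivo accessibility record written into the DNA
of just that tissue. The record is read out by **asymmetric ligation end
capture**: Dpn I cleaves only GATC sites methylated on *both* strands; a
branched linker carrying an Mme I site is ligated to each blunt cut; Mme I
then releases ~20 bp of flanking genomic DNA, which is ligated to a second
linker and sequenced. Each read therefore reports one *half-site* — one of
the two oriented 16-nt contexts flanking a GATC — and counts of reads per
half-site measure local accessibility.

The computational side implemented here:

- **Tag database** — every GATC site of a genome yields up to two 16-nt tags
  (`5'-N16-GATC-3'` upstream on each strand). Tags are filtered for
  genome-wide uniqueness, membership in an exclusion list (vector/ribosomal
  repeats), and proximity (two sites with an inter-site gap < 20 bp compete
  for capture of the short intervening fragment, so the inward-facing tag
  pair is dropped). A hit requires a perfect 16-nt match, and since every
  database tag is constrained to be followed by GATC, this is effectively a
  perfect 20-nt genomic match.
- **Read grammar** — a read parses iff it has the structure
  `5'-N16-19 GA-3'` followed by the reverse complement of linker A's top
  strand; the tag is the 16 nt immediately upstream of the terminal GA.
- **Accessibility index** — per gene *g*, with per-million-normalised counts
  `h_i` over the retained half-sites in the gene body,

  `index(g) = mean_i h_i(tissue) / mean_i h_i(control)`

  where the control is naked genomic DNA methylated in vitro (accessibility
  ≡ 1). Genes qualify only when ≥ 4 half-sites were hit in at least one
  sample of the comparison.
- **Divergence between samples** — for gene counts x, y in two libraries of
  sizes N1, N2, an exact conditional binomial test (doubled smaller tail of
  Binomial(x+y, N1/(N1+N2))), with boundary curves for "≥ 2-fold and
  p < 0.05".
- **Dyad metaprofiles** — hits accumulated by offset from positioned
  nucleosome dyads, normalised by the number of DAM half-sites at each
  offset, optionally control-normalised and smoothed with a 400-nt moving
  average. An in-vitro control is flat; chromatin oscillates with valleys at
  dyads and peaks in linkers.
- **Protocol simulator** — per-molecule, per-strand Bernoulli methylation
  driven by an accessibility track; Dpn I/Mbo I/Sau3A I cutting logic;
  linker/Mme I capture geometry with cut-distance slop; read emission — so
  every analysis stage can be validated against planted ground truth.

## Worked example

```r
library(dalec)

cfg   <- synthetic_config(n_genes = 8, n_molecules = 1500, seed = 42)
world <- synthetic_world(cfg)          # genome, genes, accessibility, anchors
db    <- build_tag_database(world$genome)
db
#> DAM half-site tag database
#>   contigs: 1  total bp: 10400
#>   GATC sites: 92  tags extracted: 184
#>   flagged: edge 0 | nonunique 0 | exclusion-list 0 | proximal 20
#>   retained: 164

tissue  <- simulate_hit_table(world$genome, world$tracks, methylation_config(0.8), db,
             sim = sim_config(n_molecules = 1500, seed = 11, sample_label = "muscle"))$hits
control <- simulate_hit_table(world$genome, world$tracks, control_methylation_config(), db,
             sim = sim_config(n_molecules = 1500, seed = 12, sample_label = "naked_dna"))$hits
tissue
#> DALEC hit table for sample 'muscle'
#>   raw: 36642  parsed: 36642  aligned: 35258
#>   half-sites hit: 163

idx <- accessibility_index(tissue, control, world$annotation, db)
head(idx, 4)
#>      gene n_half_sites tissue_mean control_mean index   (planted)
#> 1 gene001           18      937.53      6057.72  0.15        0.31
#> 2 gene002           16     7843.96      6097.94  1.29        0.92
#> 3 gene003           16     2113.00      6080.67  0.35        0.47
#> 4 gene004           20    10430.26      6080.54  1.72        0.90
```

The recovered index tracks each gene's planted accessibility multiplier
(Spearman 0.83 in this tiny run; > 0.9 at the 10,000-molecule depth used in
the test suite). The 1384 reads lost between `parsed` and `aligned` come
from half-sites removed by the proximal filter — the assay's designed
undercount at crowded sites.

A command-line front end for all stages (tag database, simulation, counting,
quantification, metaprofiles, full pipeline) is in `inst/scripts/dalec.R`.

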