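#' Mean normalised hits per half-site over a gene
#'
#' Averages library-size-normalised counts (hits per million aligned reads)
#' over the retained half-sites whose GATC midpoint (`site_pos + 2`) lies in
#' `[txStart, txEnd)` on the gene's contig.
#'
#' @param hits A `dalec_hits` table.
#' @param gene One-row data.frame (or list) with `contig`, `txStart`, `txEnd`.
#' @param db The tag database the hits were aligned to.
#' @return List with `n_half_sites` and `mean_hits` (NA if the gene spans no
#'   retained half-site).
#' @export
gene_mean_hits <- function(hits, gene, db) {
  idx <- gene_halfsite_rows(gene, db)
  if (length(idx) == 0L) return(list(n_half_sites = 0L, mean_hits = NA_real_))
  scaled <- hits$counts[idx] / hits$totals[["aligned"]] * 1e6
  list(n_half_sites = length(idx), mean_hits = mean(scaled))
}

# Row indices (into db$tags) of retained half-sites within a gene body.
gene_halfsite_rows <- function(gene, db) {
  which(db$tags$retained &
          db$tags$contig == gene$contig &
          db$tags$site_pos + 2L >= gene$txStart &
          db$tags$site_pos + 2L < gene$txEnd)
}

#' Control-normalised accessibility index per gene
#'
#' For each gene, the ratio of its mean normalised hits per half-site in the
#' tissue sample to the same quantity in the in-vitro methylated naked-DNA
#' control. Genes qualify only if at least `min_sites` half-sites within the
#' gene were each hit at least once in at least one sample of the comparison
#' set; genes with zero control coverage are excluded (no pseudocounts).
#'
#' @param tissue,control `dalec_hits` tables aligned to the same database.
#' @param genes data.frame of gene models: `id`, `contig`, `txStart`, `txEnd`,
#'   `strand`.
#' @param db The tag database.
#' @param min_sites Minimum number of qualifying half-sites (default 4).
#' @param comparison Optional list of additional `dalec_hits` tables whose
#'   coverage also counts towards the `min_sites` filter (the filter set
#'   always includes `tissue` and `control`).
#' @return data.frame: `gene`, `n_half_sites`, `tissue_mean`, `control_mean`,
#'   `index`, `qualifies`.
#' @export
accessibility_index <- function(tissue, control, genes, db, min_sites = 4L,
                                comparison = list()) {
  tables <- c(list(tissue, control), comparison)
  hit_any <- Reduce(`|`, lapply(tables, function(h) h$counts > 0L))
  res <- lapply(seq_len(nrow(genes)), function(g) {
    gene <- genes[g, ]
    idx <- gene_halfsite_rows(gene, db)
    n_hit <- sum(hit_any[idx])
    tm <- gene_mean_hits(tissue, gene, db)$mean_hits
    cm <- gene_mean_hits(control, gene, db)$mean_hits
    qual <- n_hit >= min_sites && !is.na(cm) && cm > 0
    data.frame(gene = gene$id, n_half_sites = length(idx),
               tissue_mean = tm, control_mean = cm,
               index = if (qual) tm / cm else NA_real_,
               qualifies = qual, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-gene raw tag counts
#'
#' Sums raw aligned counts over the retained half-sites within each gene body;
#' the per-gene unit used for cross-sample divergence scatter plots.
#'
#' @inheritParams accessibility_index
#' @param hits A `dalec_hits` table.
#' @return Integer vector named by gene id.
#' @export
gene_tag_counts <- function(hits, genes, db) {
  out <- vapply(seq_len(nrow(genes)), function(g) {
    sum(hits$counts[gene_halfsite_rows(genes[g, ], db)])
  }, numeric(1))
  names(out) <- genes$id
  out
}

#' Exact conditional divergence test for a pair of tag counts
#'
#' Conditional on the total `x + y`, `x` is binomial with success probability
#' `N1 / (N1 + N2)` under the null of equivalent representation. The p-value
#' is the doubled smaller exact tail (capped at 1). The fold change is
#' computed on per-million-normalised counts.
#'
#' @param x,y Raw counts in samples 1 and 2.
#' @param N1,N2 Library sizes (total aligned counts) of samples 1 and 2.
#' @return List with `fold` (>= 1; Inf when one count is zero) and `p`.
#' @export
divergence_test <- function(x, y, N1, N2) {
  stopifnot(N1 > 0, N2 > 0)
  if (x + y == 0) return(list(fold = NA_real_, p = NA_real_))
  pr <- N1 / (N1 + N2)
  lower <- stats::pbinom(x, x + y, pr)
  upper <- stats::pbinom(x - 1, x + y, pr, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  xn <- x / N1
  yn <- y / N2
  fold <- if (xn == 0 || yn == 0) Inf else max(xn / yn, yn / xn)
  list(fold = fold, p = p)
}

#' Divergence test applied to every gene of a sample pair
#'
#' @inheritParams gene_tag_counts
#' @param hits1,hits2 `dalec_hits` tables for the two samples.
#' @return data.frame: `gene`, `x`, `y`, `fold`, `p`.
#' @export
gene_divergence <- function(hits1, hits2, genes, db) {
  x <- gene_tag_counts(hits1, genes, db)
  y <- gene_tag_counts(hits2, genes, db)
  N1 <- hits1$totals[["aligned"]]
  N2 <- hits2$totals[["aligned"]]
  res <- mapply(function(xi, yi) unlist(divergence_test(xi, yi, N1, N2)), x, y)
  data.frame(gene = genes$id, x = unname(x), y = unname(y),
             fold = unname(res["fold", ]), p = unname(res["p", ]),
             stringsAsFactors = FALSE)
}

#' Boundary curve of significant two-fold divergence
#'
#' For each total `t = x + y` up to `t_max`, the smallest imbalance that is
#' both at least `fold`-fold different (on per-million-normalised counts) and
#' significant at level `alpha` under [divergence_test()]. Returned as the
#' `(x, y)` pairs of the upper and lower boundary branches, suitable for
#' over-plotting a gene scatter. At small totals the significance criterion
#' dominates and no boundary point exists; at large totals the fold criterion
#' dominates and the boundary ratio approaches `fold`.
#'
#' @param N1,N2 Library sizes.
#' @param fold Minimum fold change (default 2).
#' @param alpha Significance level (default 0.05).
#' @param t_max Largest total examined.
#' @return data.frame: `total`, `branch` ("upper"/"lower"), `x`, `y`.
#' @export
divergence_boundary <- function(N1, N2, fold = 2, alpha = 0.05, t_max = 200L) {
  rows <- list()
  for (t in seq_len(t_max)) {
    xs <- 0:t
    crit <- vapply(xs, function(x) {
      d <- divergence_test(x, t - x, N1, N2)
      d$fold >= fold && d$p < alpha
    }, logical(1))
    centre <- t * N1 / (N1 + N2)
    up <- xs[crit & xs > centre]
    lo <- xs[crit & xs < centre]
    if (length(up) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(total = t, branch = "upper",
                                              x = min(up), y = t - min(up))
    }
    if (length(lo) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(total = t, branch = "lower",
                                              x = max(lo), y = t - max(lo))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(total = integer(0), branch = character(0),
                      x = integer(0), y = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bin accessibility indices by expression score
#'
#' Genes are binned by their exact SAGE-style expression score from 0 to
#' `cap - 1`, with an aggregate `"9+"`-style bin for scores of `cap` and
#' above; the mean accessibility index and gene count are reported per bin.
#'
#' @param indices data.frame with columns `gene` and `index` (NAs dropped).
#' @param expression data.frame with columns `gene` and `score` (non-negative
#'   integers).
#' @param cap Scores >= `cap` are aggregated (default 9).
#' @return data.frame: `bin` (label), `score_floor`, `mean_index`, `n_genes`.
#' @export
sage_bin_averages <- function(indices, expression, cap = 9L) {
  m <- merge(indices[!is.na(indices$index), c("gene", "index")],
             expression[, c("gene", "score")], by = "gene")
  stopifnot(all(m$score >= 0))
  lab <- ifelse(m$score >= cap, paste0(cap, "+"), as.character(m$score))
  levels <- c(as.character(0:(cap - 1L)), paste0(cap, "+"))
  lab <- factor(lab, levels = levels)
  mean_index <- tapply(m$index, lab, mean)
  n <- tapply(m$index, lab, length)
  keep <- !is.na(mean_index)
  data.frame(bin = levels[keep],
             score_floor = c(0:(cap - 1L), cap)[keep],
             mean_index = unname(mean_index[keep]),
             n_genes = unname(as.integer(n[keep])),
             stringsAsFactors = FALSE)
}
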