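#' Map retained half-sites to offsets around dyad anchors
#'
#' Each retained half-site whose GATC midpoint `m = site_pos + 2` lies within
#' `W` bases of an anchor dyad contributes at offset `m - dyad` for plus
#' anchors and `dyad - m` for minus anchors (orientation follows the gene
#' strand). Anchors closer than `2W` to one another all contribute; the
#' resulting multiplicity is retained, not deduplicated.
#'
#' @param anchors data.frame with `contig`, `dyad` (0-based), `strand`.
#' @param db A [build_tag_database()] object.
#' @param W Half-width of the window, bases (default 1000).
#' @return Object of class `dalec_offset_map`: list with `W`, `offsets`
#'   (-W..W), `site_count` (half-sites per offset, multiplicity included) and
#'   `pairs` (data.frame `offset_idx`, `tag_row`).
#' @export
map_halfsites_to_offsets <- function(anchors, db, W = 1000L) {
  W <- as.integer(W)
  offs <- (-W):W
  site_count <- integer(2L * W + 1L)
  pair_off <- list(); pair_row <- list()
  ret <- which(db$tags$retained)
  mid <- db$tags$site_pos[ret] + 2L
  ctg <- db$tags$contig[ret]
  for (a in seq_len(nrow(anchors))) {
    on_ctg <- which(ctg == anchors$contig[a])
    d <- mid[on_ctg] - anchors$dyad[a]
    if (anchors$strand[a] == "-") d <- -d
    keep <- abs(d) <= W
    if (!any(keep)) next
    oi <- d[keep] + W + 1L
    pair_off[[length(pair_off) + 1L]] <- oi
    pair_row[[length(pair_row) + 1L]] <- ret[on_ctg[keep]]
    tab <- tabulate(oi, nbins = 2L * W + 1L)
    site_count <- site_count + tab
  }
  structure(list(W = W, offsets = offs, site_count = site_count,
                 pairs = data.frame(offset_idx = unlist(pair_off),
                                    tag_row = unlist(pair_row))),
            class = "dalec_offset_map")
}

#' Dyad-anchored accessibility profile
#'
#' At each offset, the total hit count of the half-sites mapping there divided
#' by the number of half-sites at that offset (normalising to local DAM-site
#' density). Offsets with no half-site are undefined (NA), never zero. An
#' in-vitro control yields an essentially flat profile; chromatin samples
#' oscillate between valleys at nucleosome dyads and peaks in linkers.
#'
#' @param hits A `dalec_hits` table.
#' @param offset_map A [map_halfsites_to_offsets()] object.
#' @param control Optional control `dalec_hits`; if given, a
#'   `norm_value` column (tissue value / control value per offset) is added.
#' @return data.frame: `offset`, `hit_sum`, `site_count`, `value`, and
#'   optionally `norm_value`.
#' @export
dyad_profile <- function(hits, offset_map, control = NULL) {
  n_off <- length(offset_map$offsets)
  hs <- numeric(n_off)
  if (nrow(offset_map$pairs) > 0L) {
    sums <- tapply(hits$counts[offset_map$pairs$tag_row],
                   offset_map$pairs$offset_idx, sum)
    hs[as.integer(names(sums))] <- as.numeric(sums)
  }
  value <- ifelse(offset_map$site_count > 0L, hs / offset_map$site_count, NA_real_)
  out <- data.frame(offset = offset_map$offsets, hit_sum = hs,
                    site_count = offset_map$site_count, value = value)
  if (!is.null(control)) {
    cv <- dyad_profile(control, offset_map)$value
    out$norm_value <- ifelse(!is.na(cv) & cv > 0, out$value / cv, NA_real_)
  }
  out
}

#' Centred moving average that skips undefined offsets
#'
#' Mean over the defined values within a centred window of the given width;
#' undefined (NA) offsets are omitted from both numerator and denominator, and
#' edges use the truncated window. A window of 1 is the identity.
#'
#' @param values Numeric vector (NAs allowed).
#' @param window Window width in offsets (default 400); the window spans
#'   `floor(window/2)` positions on each side.
#' @return Numeric vector of smoothed values (NA where no defined value falls
#'   in the window).
#' @export
moving_average <- function(values, window = 400L) {
  stopifnot(window >= 1L)
  h <- as.integer(window %/% 2L)
  if (h == 0L) return(values)
  n <- length(values)
  v <- ifelse(is.na(values), 0, values)
  d <- as.numeric(!is.na(values))
  cv <- c(0, cumsum(v))
  cd <- c(0, cumsum(d))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  num <- cv[hi + 1L] - cv[lo]
  den <- cd[hi + 1L] - cd[lo]
  ifelse(den > 0, num / den, NA_real_)
}
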