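#' Binary retention of mapped sites
#'
#' A mapped source-species site is *retained* when some target-species site
#' overlaps strictly more than `cfg$retention_frac` (default 10%) of the
#' lifted span, or the lifted span overlaps strictly more than that
#' fraction of the target site ("or vice versa"). The boundary is strict:
#' an overlap of exactly 10% of both widths is not retention.
#'
#' @param mapped Mapped-site table from [map_sites()]; every row must have
#'   `status == "mapped"` (filter first), otherwise an error is raised.
#' @param human_sites Target-species site data frame — either the same
#'   factor only or the union of both factors, depending on whether
#'   cross-factor retention classes are wanted.
#' @param cfg An [analysis_config()].
#' @return A list: `retained`, logical per row of `mapped`; `hits`, a data
#'   frame of qualifying (mapped row, human row) pairs with overlap lengths
#'   — the basis for retained-as-factor labels.
#' @export
binary_retention <- function(mapped, human_sites, cfg = analysis_config()) {
  if (nrow(mapped) && any(mapped$status != "mapped")) {
    stop("binary_retention() requires mapped sites only; filter on status")
  }
  spans <- lifted_spans(mapped)
  hits <- overlap_hits(spans, human_sites)
  if (nrow(hits)) {
    w_span <- interval_width(spans)[hits$a_idx]
    w_h <- interval_width(human_sites)[hits$b_idx]
    qual <- hits$olap > cfg$retention_frac * w_span |
      hits$olap > cfg$retention_frac * w_h
    hits <- hits[qual, , drop = FALSE]
  }
  retained <- logical(nrow(mapped))
  retained[unique(hits$a_idx)] <- TRUE
  names(hits) <- c("mapped_idx", "human_idx", "olap")
  list(retained = retained, hits = hits)
}

# Lifted spans of a mapped-site table as an interval data frame.
lifted_spans <- function(mapped) {
  data.frame(chrom = mapped$h_chrom, start = mapped$h_start,
             end = mapped$h_end, stringsAsFactors = FALSE)
}

#' Target-species-specific sites
#'
#' Target-species sites that fail the 10%-either-way overlap test against
#' *every* lifted source site are specific to the target species; these are
#' the candidate compensating sites for turnover and the "gained" sites
#' counted near genes.
#'
#' @param human_sites Target-species site data frame (typically one
#'   factor).
#' @param mapped Mapped-site table (same factor); rows with other statuses
#'   are ignored.
#' @param cfg An [analysis_config()].
#' @return Logical vector over `human_sites` rows: `TRUE` = specific.
#' @export
human_specific_sites <- function(human_sites, mapped,
                                 cfg = analysis_config()) {
  m <- mapped[mapped$status == "mapped", , drop = FALSE]
  specific <- rep(TRUE, nrow(human_sites))
  if (nrow(m) == 0L || nrow(human_sites) == 0L) return(specific)
  spans <- lifted_spans(m)
  hits <- overlap_hits(human_sites, spans)
  if (nrow(hits)) {
    w_h <- interval_width(human_sites)[hits$a_idx]
    w_s <- interval_width(spans)[hits$b_idx]
    qual <- hits$olap > cfg$retention_frac * w_h |
      hits$olap > cfg$retention_frac * w_s
    specific[unique(hits$a_idx[qual])] <- FALSE
  }
  specific
}

#' Turnover detection for non-retained mapped sites
#'
#' A lost site is a *turnover* event when a target-species-specific site of
#' the same factor lies within `cfg$turnover_max_dist` (midpoint to
#' midpoint, inclusive — "max 10 kb") of the lifted span on the same
#' chromosome.
#'
#' @param mapped Mapped-site table rows that failed binary retention
#'   (status `"mapped"`).
#' @param human_specific Target-species-specific site data frame (same
#'   factor; see [human_specific_sites()]).
#' @param cfg An [analysis_config()].
#' @return Logical vector over `mapped` rows.
#' @export
detect_turnover <- function(mapped, human_specific,
                            cfg = analysis_config()) {
  if (nrow(mapped) && any(mapped$status != "mapped")) {
    stop("detect_turnover() requires mapped sites only")
  }
  out <- logical(nrow(mapped))
  if (!nrow(mapped) || !nrow(human_specific)) return(out)
  spans <- lifted_spans(mapped)
  mids_m <- midpoint(spans)
  mids_h <- midpoint(human_specific)
  for (ch in unique(spans$chrom)) {
    hi <- sort(mids_h[human_specific$chrom == ch])
    if (!length(hi)) next
    mi <- which(spans$chrom == ch)
    lo <- findInterval(mids_m[mi] - cfg$turnover_max_dist - 1, hi)
    hi_n <- findInterval(mids_m[mi] + cfg$turnover_max_dist, hi)
    out[mi] <- hi_n > lo
  }
  out
}

#' Classify the fate of every mapped site
#'
#' Partitions uniquely mapped source sites into `retained`, `turnover` and
#' `lost`. Retention is decided against `human_sites` (pass the union of
#' both factors' target sites to allow cross-factor retention classes;
#' `retained_as` then records which factors' sites matched). Turnover is
#' decided per factor against that factor's target-specific sites, computed
#' from the same mapped table. Sites with a non-`mapped` status keep
#' `fate = NA`.
#'
#' @param mapped Mapped-site table from [map_sites()] (any mix of factors
#'   and statuses).
#' @param human_sites Target-species site data frame covering the factors
#'   present in `mapped`.
#' @param cfg An [analysis_config()].
#' @return `mapped` with added columns `fate`
#'   (`retained`/`turnover`/`lost`/`NA`) and `retained_as` (comma-separated
#'   factor names, `""` when not retained).
#' @export
classify_fates <- function(mapped, human_sites, cfg = analysis_config()) {
  validate_sites(human_sites)
  fate <- rep(NA_character_, nrow(mapped))
  retained_as <- rep("", nrow(mapped))
  ok <- which(mapped$status == "mapped")
  if (!length(ok)) {
    mapped$fate <- fate
    mapped$retained_as <- retained_as
    return(mapped)
  }
  m <- mapped[ok, , drop = FALSE]
  br <- binary_retention(m, human_sites, cfg)
  fate[ok[br$retained]] <- "retained"
  if (nrow(br$hits)) {
    fac <- human_sites$factor[br$hits$human_idx]
    ra <- tapply(fac, br$hits$mapped_idx,
                 function(x) paste(sort(unique(x)), collapse = ","))
    retained_as[ok[as.integer(names(ra))]] <- as.character(ra)
  }
  # turnover, per factor, among the non-retained mapped sites
  for (tf in unique(m$factor)) {
    hf <- human_sites[human_sites$factor == tf, , drop = FALSE]
    mf_idx <- which(m$factor == tf)
    spec <- human_specific_sites(hf, m[mf_idx, , drop = FALSE], cfg)
    cand <- mf_idx[!br$retained[mf_idx]]
    if (!length(cand)) next
    to <- detect_turnover(m[cand, , drop = FALSE],
                          hf[spec, , drop = FALSE], cfg)
    fate[ok[cand]] <- ifelse(to, "turnover", "lost")
  }
  mapped$fate <- fate
  mapped$retained_as <- retained_as
  mapped
}

#' 75th percentile of site widths
#'
#' The enrichment window width for a factor: the 75th percentile of that
#' factor's target-species site widths (linear interpolation between order
#' statistics), rounded to the nearest integer.
#'
#' @param sites Non-empty site data frame.
#' @return Integer width (nt).
#' @examples
#' s <- binding_sites("chr1", c(0, 1000, 2000, 3000),
#'                    c(100, 1200, 2300, 3400))
#' window_width_75th(s)  # 325
#' @export
window_width_75th <- function(sites) {
  if (nrow(sites) == 0L) stop("window_width_75th() needs a non-empty site set")
  round(stats::quantile(interval_width(sites), 0.75, type = 7,
                        names = FALSE))
}

#' Count tags in a centred window
#'
#' The window of width `width` centred on `center` is
#' `[center - floor(width/2), center - floor(width/2) + width)`; for odd
#' widths the extra base falls on the right. Tags are single positions; a
#' chromosome absent from the track counts 0.
#'
#' @param track A `"tag_track"`.
#' @param chrom Chromosome.
#' @param center Window centre position.
#' @param width Window width in nt (>= 1).
#' @return Integer tag count.
#' @export
count_tags_in_window <- function(track, chrom, center, width) {
  stopifnot(width >= 1)
  pos <- track[[chrom]]
  if (is.null(pos) || !length(pos)) return(0L)
  a <- center - floor(width / 2)
  b <- a + width
  findInterval(b - 1, pos) - findInterval(a - 1, pos)
}

#' Sample random genomic windows
#'
#' Window centres are drawn uniformly over the genome: a chromosome is
#' chosen with probability proportional to its length, then the centre is
#' uniform over the positions where the window fits entirely.
#'
#' @param genome Chromosome-length data frame (`chrom`, `length`).
#' @param width Window width (nt).
#' @param n Number of windows.
#' @return Data frame `chrom`, `center`.
#' @export
sample_random_windows <- function(genome, width, n) {
  fit <- genome$length >= width
  if (!any(fit)) stop("window width ", width,
                      " exceeds every chromosome length")
  g <- genome[fit, , drop = FALSE]
  ci <- sample.int(nrow(g), n, replace = TRUE, prob = g$length)
  lo <- floor(width / 2)
  # centre range so that [center-lo, center-lo+width) stays on-chromosome
  centers <- lo + floor(stats::runif(n) * (g$length[ci] - width + 1))
  data.frame(chrom = g$chrom[ci], center = centers,
             stringsAsFactors = FALSE)
}

#' Random-expectation tag count
#'
#' Mean tag count over `n` random windows of the given width; the sample is
#' seeded so one draw can be shared by every site of a factor/width, which
#' keeps per-site fold changes comparable and reproducible.
#'
#' @param track A `"tag_track"`.
#' @param genome Chromosome-length data frame.
#' @param width Window width (nt).
#' @param n Number of random windows (default 2000).
#' @param seed Integer seed for the window sample.
#' @return Mean count (numeric scalar).
#' @export
random_expectation <- function(track, genome, width, n = 2000L, seed = 1L) {
  wins <- with_seed(seed, sample_random_windows(genome, width, n))
  counts <- vapply(seq_len(nrow(wins)), function(i) {
    count_tags_in_window(track, wins$chrom[i], wins$center[i], width)
  }, numeric(1))
  mean(counts)
}

#' Tag-enrichment log2 fold change of mapped sites
#'
#' The continuous, threshold-free retention measure: for each lifted span,
#' tags are counted in a window of width `width` centred on the span
#' midpoint and compared with the random expectation,
#' `log2((observed + k) / (expected + k))` with pseudo-count
#' `k = cfg$pseudocount` guarding against small counts. Lost regions score
#' near 0; retained regions score high.
#'
#' @param mapped Mapped-site table rows with `status == "mapped"`.
#' @param track Target-species `"tag_track"` for the factor.
#' @param genome Target-species chromosome-length data frame.
#' @param width Window width (nt), typically [window_width_75th()] of the
#'   factor's target-species sites or the configured default.
#' @param cfg An [analysis_config()].
#' @param seed Seed for the shared random-window sample.
#' @param expected Optional precomputed random expectation; when `NULL`
#'   (default) it is computed with [random_expectation()] using
#'   `cfg$n_random_regions` windows.
#' @return Numeric vector of log2 fold changes per row of `mapped`.
#' @export
enrichment_log2fc <- function(mapped, track, genome, width,
                              cfg = analysis_config(), seed = 1L,
                              expected = NULL) {
  if (nrow(mapped) && any(mapped$status != "mapped")) {
    stop("enrichment_log2fc() requires mapped sites only")
  }
  if (is.null(expected)) {
    expected <- random_expectation(track, genome, width,
                                   cfg$n_random_regions, seed)
  }
  spans <- lifted_spans(mapped)
  mids <- midpoint(spans)
  obs <- vapply(seq_len(nrow(spans)), function(i) {
    count_tags_in_window(track, spans$chrom[i], mids[i], width)
  }, numeric(1))
  log2((obs + cfg$pseudocount) / (expected + cfg$pseudocount))
}

#' Near-equal quantile bins of a numeric vector
#'
#' Ranks values ascending (ties broken by stable input order) and cuts the
#' ranking into `k` groups of near-equal size: sizes differ by at most 1
#' and the larger groups come first. Bin 1 holds the lowest values.
#'
#' @param values Numeric vector with at least `k` elements.
#' @param k Number of bins (default 4, i.e. quartile groups).
#' @return Integer bin label (1..k) per value.
#' @examples
#' quartile_bins(c(5, 1, 8, 3, 7, 2, 6, 4))
#' @export
quartile_bins <- function(values, k = 4L) {
  n <- length(values)
  if (n < k) stop("need at least k values to form k bins")
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  bins <- integer(n)
  bins[order(values)] <- rep(seq_len(k), sizes)  # order() is stable
  bins
}
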