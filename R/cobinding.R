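#' Remove the widest binding sites
#'
#' Peak callers occasionally merge nearby binding events or noise into
#' implausibly wide regions; the widest fraction of sites is therefore
#' dropped before analysis. The cut point is the `1 - frac` quantile of
#' site widths (linear interpolation between order statistics); sites whose
#' width strictly exceeds it are removed and the order of survivors is
#' preserved.
#'
#' @param sites Site data frame.
#' @param frac Fraction to remove, in `[0, 1)`. Default 0.05.
#' @return The filtered site data frame.
#' @examples
#' s <- binding_sites("chr1", 0:9 * 1000, 0:9 * 1000 + 100 + 0:9 * 30)
#' nrow(filter_widest(s, 0.2))
#' @export
filter_widest <- function(sites, frac = 0.05) {
  validate_sites(sites)
  if (nrow(sites) == 0L) return(sites)
  stopifnot(frac >= 0, frac < 1)
  w <- interval_width(sites)
  cut <- stats::quantile(w, probs = 1 - frac, type = 7, names = FALSE)
  sites[w <= cut, , drop = FALSE]
}

#' High-confidence sites by overlap with an independent site set
#'
#' Keeps the ChIP-seq sites corroborated by at least 1 nt overlap with any
#' region of an independent experiment (e.g. ChIP-chip) in the same
#' species; coordinates are untouched.
#'
#' @param seq_sites ChIP-seq site data frame (returned subset).
#' @param ref_sites Independent reference regions (site or interval data
#'   frame).
#' @return Subset of `seq_sites`.
#' @export
high_confidence_intersect <- function(seq_sites, ref_sites) {
  validate_sites(seq_sites)
  validate_intervals(ref_sites, "reference region")
  hits <- overlap_hits(seq_sites, ref_sites)
  seq_sites[sort(unique(hits$a_idx)), , drop = FALSE]
}

#' Classify sites as factor-only or co-bound ("overlapping")
#'
#' Labels every CEBPA and PPARG site by whether it is overlapped by a site
#' of the other factor. Labels are per site and per factor: each factor's
#' threshold applies to the site's *own* width, so a CEBPA site can be
#' "overlapping" while its PPARG partner is not. In `mouse` mode the
#' thresholds are a width fraction (>= 1% of the CEBPA site's width, >= 10%
#' of the PPARG site's width — PPARG peaks are narrower); in `human` mode
#' (sites already restricted to orthologous regions) the criterion relaxes
#' to >= 1 nt for both factors. `overlap_fraction` is taken over the single
#' best partner site, since empirically overlaps are near-binary.
#'
#' @param cebpa CEBPA site data frame.
#' @param pparg PPARG site data frame (same species).
#' @param cfg An [analysis_config()].
#' @param mode `"mouse"` (width-fraction thresholds) or `"human"`
#'   (1-nt threshold).
#' @return A list with elements `cebpa` and `pparg` (data frames `site_id`,
#'   `label` in `CEBPA_only`/`PPARG_only`/`overlapping`,
#'   `overlap_fraction`), and `counts`, the Venn-style tally
#'   `c(cebpa_only, cebpa_overlapping, pparg_only, pparg_overlapping)`.
#' @export
classify_cobinding <- function(cebpa, pparg, cfg = analysis_config(),
                               mode = c("mouse", "human")) {
  mode <- match.arg(mode)
  validate_sites(cebpa)
  validate_sites(pparg)
  hits <- overlap_hits(cebpa, pparg)

  best <- function(n, idx, olap) {
    out <- numeric(n)
    if (length(idx)) {
      mx <- tapply(olap, idx, max)
      out[as.integer(names(mx))] <- as.numeric(mx)
    }
    out
  }
  best_c <- best(nrow(cebpa), hits$a_idx, hits$olap)  # nt
  best_p <- best(nrow(pparg), hits$b_idx, hits$olap)

  frac_c <- if (nrow(cebpa)) best_c / interval_width(cebpa) else numeric(0)
  frac_p <- if (nrow(pparg)) best_p / interval_width(pparg) else numeric(0)

  if (mode == "mouse") {
    ov_c <- frac_c >= cfg$cobind_frac_cebpa
    ov_p <- frac_p >= cfg$cobind_frac_pparg
  } else {
    ov_c <- best_c >= cfg$human_cobind_min_nt
    ov_p <- best_p >= cfg$human_cobind_min_nt
  }

  lab_c <- ifelse(ov_c, "overlapping", "CEBPA_only")
  lab_p <- ifelse(ov_p, "overlapping", "PPARG_only")
  list(
    cebpa = data.frame(site_id = cebpa$site_id, label = lab_c,
                       overlap_fraction = frac_c, stringsAsFactors = FALSE),
    pparg = data.frame(site_id = pparg$site_id, label = lab_p,
                       overlap_fraction = frac_p, stringsAsFactors = FALSE),
    counts = c(cebpa_only = sum(!ov_c), cebpa_overlapping = sum(ov_c),
               pparg_only = sum(!ov_p), pparg_overlapping = sum(ov_p))
  )
}
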