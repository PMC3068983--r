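#' Analysis configuration
#'
#' Collects every tunable constant of the cross-species retention analysis in
#' one validated list, so that each downstream operation documents its
#' thresholds in a single place.
#'
#' @param width_filter_frac Fraction of the widest binding sites removed
#'   before any analysis (peak callers occasionally merge nearby events into
#'   implausibly wide regions). Default 0.05.
#' @param cobind_frac_cebpa Minimum fraction of a CEBPA site's own width that
#'   must be overlapped by a PPARG site for the CEBPA site to count as
#'   co-bound ("overlapping") in the source species. Default 0.01.
#' @param cobind_frac_pparg Same threshold for PPARG sites, whose peaks are
#'   typically narrower; default 0.10 of the PPARG site's own width.
#' @param human_cobind_min_nt In the target species the co-binding criterion
#'   relaxes to a minimum nucleotide overlap (default 1 nt), because the
#'   orthology mapping already constrains both sites to the same region.
#' @param min_match Minimum fraction of a site's bases that must lie inside
#'   alignment-chain blocks for a cross-species lift to succeed (the
#'   inter-species liftover setting). Default 0.1.
#' @param back_overlap_frac Reciprocality requirement: the back-lifted image
#'   of a mapped site must overlap at least this fraction of the original
#'   site. Default 0.90.
#' @param retention_frac Binary retention threshold: a lifted site is
#'   retained when a target-species site overlaps strictly more than this
#'   fraction of the lifted span, or vice versa. Default 0.10 (strict `>`).
#' @param turnover_max_dist Maximum midpoint-to-midpoint distance (nt,
#'   inclusive) between a lost lifted site and a compensating
#'   target-species-specific site for a turnover call. Default 10000.
#' @param cluster_window Maximum TSS-to-site-midpoint distance (nt,
#'   inclusive) for assigning a site to a gene/expression cluster.
#'   Default 100000.
#' @param tss_lift_flank Half-width (nt) of the interval around a TSS lifted
#'   when searching for gene orthologs. Default 50.
#' @param tss_ortholog_max_dist Maximum distance (nt, inclusive) between a
#'   lifted TSS and the nearest target-species TSS for an ortholog pairing.
#'   Default 5000.
#' @param gain_window Window (nt, inclusive) around a TSS within which
#'   target-species-specific ("gained") sites are counted per gene.
#'   Default 50000.
#' @param n_random_regions Number of random genomic windows used to estimate
#'   the expected ChIP tag count. Default 2000.
#' @param pseudocount Pseudo-count added to both observed and expected tag
#'   counts before the log2 fold change. Default 1.
#' @param enrich_window_cebpa,enrich_window_pparg Enrichment window widths
#'   (nt), the 75th percentile of target-species site widths per factor;
#'   defaults 520 (CEBPA) and 605 (PPARG) are the values estimated from the
#'   real adipocyte data and are recomputed from data by
#'   [window_width_75th()] when target-species sites are available.
#' @param pwm_threshold_frac Consensus-site threshold as a fraction of each
#'   position weight matrix's scoring range. Default 0.80.
#' @param tss_profile_bin Bin width (nt) for TSS-centred site-density
#'   profiles. Default 10000.
#'
#' @return A list of class `"analysis_config"`.
#' @examples
#' cfg <- analysis_config()
#' cfg$retention_frac
#' @export
analysis_config <- function(width_filter_frac = 0.05,
                            cobind_frac_cebpa = 0.01,
                            cobind_frac_pparg = 0.10,
                            human_cobind_min_nt = 1L,
                            min_match = 0.1,
                            back_overlap_frac = 0.90,
                            retention_frac = 0.10,
                            turnover_max_dist = 10000L,
                            cluster_window = 100000L,
                            tss_lift_flank = 50L,
                            tss_ortholog_max_dist = 5000L,
                            gain_window = 50000L,
                            n_random_regions = 2000L,
                            pseudocount = 1,
                            enrich_window_cebpa = 520L,
                            enrich_window_pparg = 605L,
                            pwm_threshold_frac = 0.80,
                            tss_profile_bin = 10000L) {
  cfg <- list(
    width_filter_frac = width_filter_frac,
    cobind_frac_cebpa = cobind_frac_cebpa,
    cobind_frac_pparg = cobind_frac_pparg,
    human_cobind_min_nt = as.integer(human_cobind_min_nt),
    min_match = min_match,
    back_overlap_frac = back_overlap_frac,
    retention_frac = retention_frac,
    turnover_max_dist = as.integer(turnover_max_dist),
    cluster_window = as.integer(cluster_window),
    tss_lift_flank = as.integer(tss_lift_flank),
    tss_ortholog_max_dist = as.integer(tss_ortholog_max_dist),
    gain_window = as.integer(gain_window),
    n_random_regions = as.integer(n_random_regions),
    pseudocount = pseudocount,
    enrich_window_cebpa = as.integer(enrich_window_cebpa),
    enrich_window_pparg = as.integer(enrich_window_pparg),
    pwm_threshold_frac = pwm_threshold_frac,
    tss_profile_bin = as.integer(tss_profile_bin)
  )
  fracs <- c("cobind_frac_cebpa", "cobind_frac_pparg", "min_match",
             "back_overlap_frac", "retention_frac", "pwm_threshold_frac")
  for (f in fracs) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        cfg[[f]] <= 0 || cfg[[f]] > 1) {
      stop(sprintf("'%s' must be a single fraction in (0, 1]", f))
    }
  }
  if (width_filter_frac < 0 || width_filter_frac >= 1) {
    stop("'width_filter_frac' must lie in [0, 1)")
  }
  dists <- c("turnover_max_dist", "cluster_window", "tss_lift_flank",
             "tss_ortholog_max_dist", "gain_window", "enrich_window_cebpa",
             "enrich_window_pparg", "tss_profile_bin")
  for (d in dists) {
    if (cfg[[d]] <= 0L) stop(sprintf("'%s' must be > 0", d))
  }
  if (cfg$n_random_regions < 1L) stop("'n_random_regions' must be >= 1")
  structure(cfg, class = "analysis_config")
}

#' Enrichment window width for a factor
#'
#' @param cfg An [analysis_config()].
#' @param tf Factor name, `"CEBPA"` or `"PPARG"`.
#' @return Window width in nt.
#' @export
enrich_window <- function(cfg, tf) {
  tf <- match.arg(tf, c("CEBPA", "PPARG"))
  if (tf == "CEBPA") cfg$enrich_window_cebpa else cfg$enrich_window_pparg
}

#' Co-binding overlap threshold for a factor (source-species rule)
#' @inheritParams enrich_window
#' @return Fraction of the site's own width.
#' @export
cobind_threshold <- function(cfg, tf) {
  tf <- match.arg(tf, c("CEBPA", "PPARG"))
  if (tf == "CEBPA") cfg$cobind_frac_cebpa else cfg$cobind_frac_pparg
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}
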