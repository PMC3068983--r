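#' Assign expression-cluster labels to binding sites
#'
#' Sites are associated with genes by TSS-to-site-midpoint distance within
#' `cfg$cluster_window` (default 100 kb, inclusive). The default rule
#' labels a site with the cluster (1-4) of the *closest clustered* gene —
#' an unclustered gene nearer by does not win. If genes are in range but
#' none is clustered the site gets label 5 ("constitutive genes"); if no
#' TSS is in range, label 6 ("distal sites"). The alternative rule
#' `"nearest_gene"` labels by the closest gene regardless of cluster
#' membership (5 when that gene is unclustered); both give very similar
#' downstream pictures. Distance ties are broken toward the smaller TSS
#' coordinate.
#'
#' @param sites Site data frame.
#' @param genes Gene data frame (see [read_genes()]).
#' @param cfg An [analysis_config()].
#' @param rule `"nearest_clustered"` (default) or `"nearest_gene"`.
#' @return Integer vector of labels 1-6 per site.
#' @export
assign_cluster <- function(sites, genes, cfg = analysis_config(),
                           rule = c("nearest_clustered", "nearest_gene")) {
  rule <- match.arg(rule)
  mids <- midpoint(sites)
  out <- integer(nrow(sites))
  gsplit <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(nrow(sites))) {
    gi <- gsplit[[sites$chrom[i]]]
    if (is.null(gi)) { out[i] <- 6L; next }
    d <- abs(genes$tss[gi] - mids[i])
    inw <- d <= cfg$cluster_window
    if (!any(inw)) { out[i] <- 6L; next }
    gi <- gi[inw]
    d <- d[inw]
    cl <- genes$cluster[gi]
    pick <- function(sel) {
      cand <- which(sel)
      cand <- cand[order(d[cand], genes$tss[gi[cand]])]
      cand[1L]
    }
    if (rule == "nearest_clustered") {
      clustered <- cl != "none"
      out[i] <- if (any(clustered)) as.integer(cl[pick(clustered)]) else 5L
    } else {
      j <- pick(rep(TRUE, length(gi)))
      out[i] <- if (cl[j] == "none") 5L else as.integer(cl[j])
    }
  }
  out
}

#' Find target-species gene orthologs by TSS liftover
#'
#' For each source gene the interval TSS +/- `cfg$tss_lift_flank` (default
#' 50 nt) is lifted through the chains; genes whose flank cannot be lifted
#' are tallied `unlifted`. A lifted gene is paired with the target gene
#' whose TSS is closest to the lifted interval's midpoint and at most
#' `cfg$tss_ortholog_max_dist` (default 5 kb) away; otherwise it is tallied
#' `no_nearby_gene`. The ortholog inherits the source gene's cluster label.
#'
#' @param mouse_genes Source gene data frame.
#' @param fwd Source-to-target chain blocks.
#' @param human_genes Target gene data frame.
#' @param cfg An [analysis_config()].
#' @return A list: `pairs` (data frame `gene_id`, `ortholog_id`,
#'   `distance`, `cluster`) and `tally`
#'   (`c(paired, unlifted, no_nearby_gene)`).
#' @export
lift_tss_orthologs <- function(mouse_genes, fwd, human_genes,
                               cfg = analysis_config()) {
  hsplit <- split(seq_len(nrow(human_genes)), human_genes$chrom)
  pairs <- list()
  unlifted <- 0L
  no_nearby <- 0L
  for (i in seq_len(nrow(mouse_genes))) {
    g <- mouse_genes[i, ]
    lf <- lift_interval(fwd, g$chrom, g$tss - cfg$tss_lift_flank,
                        g$tss + cfg$tss_lift_flank, cfg$min_match)
    if (lf$status != "mapped") { unlifted <- unlifted + 1L; next }
    mid <- floor((lf$start + lf$end) / 2)
    hi <- hsplit[[lf$chrom]]
    if (is.null(hi)) { no_nearby <- no_nearby + 1L; next }
    d <- abs(human_genes$tss[hi] - mid)
    inw <- d <= cfg$tss_ortholog_max_dist
    if (!any(inw)) { no_nearby <- no_nearby + 1L; next }
    cand <- hi[inw]
    dc <- d[inw]
    j <- cand[order(dc, human_genes$tss[cand])][1L]
    pairs[[length(pairs) + 1L]] <- data.frame(
      gene_id = g$gene_id, ortholog_id = human_genes$gene_id[j],
      distance = min(dc), cluster = g$cluster, stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_id = character(0), ortholog_id = character(0),
               distance = numeric(0), cluster = character(0))
  list(pairs = pairs,
       tally = c(paired = nrow(pairs), unlifted = unlifted,
                 no_nearby_gene = no_nearby))
}

#' TSS-centred site-density profile
#'
#' The region +/- `cfg$cluster_window` around each TSS is divided into
#' `cfg$tss_profile_bin`-wide bins (default 20 bins of 10 kb); site
#' midpoints are counted per bin and averaged across genes. Bins are
#' oriented by gene strand, upstream first.
#'
#' @param genes Non-empty gene data frame (typically one expression
#'   cluster).
#' @param sites Site data frame.
#' @param cfg An [analysis_config()].
#' @return Data frame `bin_start` (oriented offset of the bin's upstream
#'   edge, nt), `mean_sites`.
#' @export
tss_site_profile <- function(genes, sites, cfg = analysis_config()) {
  if (nrow(genes) == 0L) stop("tss_site_profile() needs a non-empty gene set")
  w <- cfg$cluster_window
  b <- cfg$tss_profile_bin
  nb <- as.integer(2 * w / b)
  mids <- midpoint(sites)
  counts <- matrix(0, nrow(genes), nb)
  for (i in seq_len(nrow(genes))) {
    sel <- sites$chrom == genes$chrom[i]
    if (!any(sel)) next
    rel <- mids[sel] - genes$tss[i]
    if (genes$strand[i] == "-") rel <- -rel
    rel <- rel[rel >= -w & rel < w]
    if (!length(rel)) next
    bin <- floor((rel + w) / b) + 1
    tb <- tabulate(bin, nbins = nb)
    counts[i, ] <- tb
  }
  data.frame(bin_start = seq(-w, w - b, by = b),
             mean_sites = colMeans(counts))
}

#' Gained (target-specific) sites per gene and per cluster
#'
#' Counts, per target gene, the target-species-specific site midpoints
#' within `cfg$gain_window` (default 50 kb, inclusive) of the TSS, and
#' summarises the counts per expression cluster as a normalised histogram.
#'
#' @param genes Target gene data frame.
#' @param human_specific Target-species-specific site data frame.
#' @param cfg An [analysis_config()].
#' @return A list: `per_gene` (data frame `gene_id`, `cluster`, `n_sites`)
#'   and `histogram` (data frame `cluster`, `n_sites`, `fraction`; each
#'   cluster's fractions sum to 1).
#' @export
gained_sites_per_gene <- function(genes, human_specific,
                                  cfg = analysis_config()) {
  mids <- midpoint(human_specific)
  n_sites <- integer(nrow(genes))
  for (ch in unique(genes$chrom)) {
    hm <- sort(mids[human_specific$chrom == ch])
    gi <- which(genes$chrom == ch)
    if (!length(hm)) next
    lo <- findInterval(genes$tss[gi] - cfg$gain_window - 1, hm)
    hi <- findInterval(genes$tss[gi] + cfg$gain_window, hm)
    n_sites[gi] <- hi - lo
  }
  per_gene <- data.frame(gene_id = genes$gene_id, cluster = genes$cluster,
                         n_sites = n_sites, stringsAsFactors = FALSE)
  hist <- do.call(rbind, lapply(split(per_gene, per_gene$cluster),
                                function(d) {
    tb <- table(d$n_sites)
    data.frame(cluster = d$cluster[1L], n_sites = as.integer(names(tb)),
               fraction = as.numeric(tb) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(hist) <- NULL
  list(per_gene = per_gene, histogram = hist)
}
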