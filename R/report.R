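#' Run the full cross-species retention pipeline on a fixture directory
#'
#' Reads the standard fixture layout (see [fixture_paths()]), then runs
#' every stage: width filtering, co-binding classification in both
#' species, reciprocal chain mapping, fate classification
#' (retained/turnover/lost), tag-enrichment log2 fold changes against a
#' seeded random-region null, gene/expression-cluster assignment,
#' binding-strength quartiles, consensus-motif scanning of the orthologous
#' region sequences, mouse-human identity scoring, TSS ortholog mapping,
#' TSS-centred site profiles and gained-site counts. Deterministic for a
#' given `seed`.
#'
#' @param dir Fixture directory.
#' @param cfg An [analysis_config()].
#' @param seed Integer seed for the random-region enrichment null.
#' @param pwms Named list of `"pwm_model"`s (`CEBPA`, `PPARG`); default
#'   [default_pwms()].
#' @return A list of stage outputs (see [run_report()]).
#' @export
run_pipeline <- function(dir, cfg = analysis_config(), seed = 1L,
                         pwms = default_pwms(cfg)) {
  p <- fixture_paths(dir)
  tfs <- c("CEBPA", "PPARG")

  mouse <- lapply(stats::setNames(tfs, tfs), function(tf) {
    filter_widest(read_sites(p$mouse_sites[[tf]], tf, "mouse"),
                  cfg$width_filter_frac)
  })
  human <- lapply(stats::setNames(tfs, tfs), function(tf) {
    filter_widest(read_sites(p$human_sites[[tf]], tf, "human"),
                  cfg$width_filter_frac)
  })
  cobind_mouse <- classify_cobinding(mouse$CEBPA, mouse$PPARG, cfg, "mouse")
  cobind_human <- classify_cobinding(human$CEBPA, human$PPARG, cfg, "human")

  fwd <- read_chain_tsv(p$chains_fwd)
  rev <- read_chain_tsv(p$chains_rev)
  genome_human <- read_genome(p$genome_human)

  mapped <- do.call(rbind, lapply(tfs, function(tf) {
    map_sites(mouse[[tf]], fwd, rev, cfg)
  }))
  human_all <- rbind(human$CEBPA, human$PPARG)
  fates <- classify_fates(mapped, human_all, cfg)

  # continuous retention measure: per-factor window + shared random null
  fates$log2fc <- NA_real_
  enrich_width <- stats::setNames(numeric(2), tfs)
  for (k in seq_along(tfs)) {
    tf <- tfs[k]
    track <- read_tag_track(p$tags_human[[tf]])
    w <- if (nrow(human[[tf]])) window_width_75th(human[[tf]]) else
      enrich_window(cfg, tf)
    enrich_width[tf] <- w
    sel <- which(fates$factor == tf & fates$status == "mapped")
    if (length(sel)) {
      fates$log2fc[sel] <- enrichment_log2fc(
        fates[sel, , drop = FALSE], track, genome_human, w, cfg,
        seed = seed + k)
    }
  }

  genes_mouse <- read_genes(p$genes_mouse)
  genes_human <- read_genes(p$genes_human)
  fates$cluster <- assign_cluster(fates, genes_mouse, cfg)

  fates$strength_quartile <- NA_integer_
  for (tf in tfs) {
    sel <- which(fates$factor == tf & fates$status == "mapped")
    if (length(sel) >= 4L) {
      fates$strength_quartile[sel] <- quartile_bins(fates$tag_count[sel])
    }
  }

  fates$cobind <- NA_character_
  lab <- rbind(
    data.frame(site_id = cobind_mouse$cebpa$site_id,
               label = cobind_mouse$cebpa$label, stringsAsFactors = FALSE),
    data.frame(site_id = cobind_mouse$pparg$site_id,
               label = cobind_mouse$pparg$label, stringsAsFactors = FALSE))
  fates$cobind <- lab$label[match(fates$site_id, lab$site_id)]

  # consensus motifs in the human orthologous regions
  motifs <- NULL
  if (file.exists(p$regions) && length(readLines(p$regions, n = 1L))) {
    seqs <- Biostrings::readDNAStringSet(p$regions)
    motifs <- data.frame(
      site_id = sub("\\s.*$", "", names(seqs)),
      has_cebpa = vapply(as.character(seqs), function(s)
        has_consensus(s, pwms$CEBPA)$flag, logical(1), USE.NAMES = FALSE),
      has_pparg = vapply(as.character(seqs), function(s)
        has_consensus(s, pwms$PPARG)$flag, logical(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
    fates$has_cebpa <- motifs$has_cebpa[match(fates$site_id,
                                              motifs$site_id)]
    fates$has_pparg <- motifs$has_pparg[match(fates$site_id,
                                              motifs$site_id)]
  } else {
    fates$has_cebpa <- NA
    fates$has_pparg <- NA
  }

  # mouse-human identity of the aligned regions
  if (file.exists(p$alignments) &&
      length(readLines(p$alignments, n = 1L))) {
    aln <- read_aligned_fasta(p$alignments)
    aln$identity <- vapply(seq_len(nrow(aln)), function(i)
      identity_score(aln$seq1[i], aln$seq2[i]), numeric(1))
    fates$identity <- aln$identity[match(fates$site_id, aln$pair_id)]
  } else {
    fates$identity <- NA_real_
  }
  fates$identity_quartile <- NA_integer_
  for (tf in tfs) {
    sel <- which(fates$factor == tf & !is.na(fates$identity))
    if (length(sel) >= 4L) {
      fates$identity_quartile[sel] <- quartile_bins(fates$identity[sel])
    }
  }

  # human-specific sites (per factor) and gained-site counts near genes
  specific <- lapply(stats::setNames(tfs, tfs), function(tf) {
    hf <- human[[tf]]
    hf[human_specific_sites(hf, fates[fates$factor == tf, , drop = FALSE],
                            cfg), , drop = FALSE]
  })
  gained <- lapply(specific, function(sp)
    gained_sites_per_gene(genes_human, sp, cfg))

  tss_orth <- lift_tss_orthologs(genes_mouse, fwd, genes_human, cfg)

  profiles <- lapply(stats::setNames(as.character(1:4), paste0("cluster",
                                                               1:4)),
                     function(cl) {
    g <- genes_mouse[genes_mouse$cluster == cl, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    tss_site_profile(g, mouse$PPARG, cfg)
  })

  list(mouse_sites = mouse, human_sites = human,
       cobind_mouse = cobind_mouse, cobind_human = cobind_human,
       fates = fates, enrich_width = enrich_width, motifs = motifs,
       specific = specific, gained = gained, tss_orthologs = tss_orth,
       profiles = profiles, genes_mouse = genes_mouse,
       genes_human = genes_human, cfg = cfg, seed = seed)
}

.need <- function(pipe, what) {
  if (is.null(pipe[[what]])) {
    stop("report stage missing upstream table: ", what)
  }
  pipe[[what]]
}

#' Assemble the report tables from pipeline output
#'
#' Produces the summary tables of the analysis: co-binding (Venn) counts
#' in both species, mapping statistics with mapped percentages, the
#' retained/turnover/lost breakdown per factor, enrichment summaries by
#' fate, and the cross-tabulations of retention against expression
#' cluster, binding strength, co-binding class, consensus-motif presence
#' and sequence identity — each with a two-sided Fisher contrast, plus a
#' p-value table with a Benjamini-Hochberg column (informational only; no
#' output is gated on it). Regeneration from the same inputs is
#' byte-identical.
#'
#' @param pipe Output of [run_pipeline()].
#' @return Named list of data frames.
#' @export
run_report <- function(pipe) {
  fates <- .need(pipe, "fates")
  cobm <- .need(pipe, "cobind_mouse")
  cobh <- .need(pipe, "cobind_human")
  tfs <- c("CEBPA", "PPARG")

  venn <- rbind(
    data.frame(species = "mouse", class = names(cobm$counts),
               n = as.integer(cobm$counts), stringsAsFactors = FALSE),
    data.frame(species = "human", class = names(cobh$counts),
               n = as.integer(cobh$counts), stringsAsFactors = FALSE))

  mapping <- do.call(rbind, lapply(tfs, function(tf) {
    f <- fates[fates$factor == tf, , drop = FALSE]
    det <- nrow(f)
    mp <- sum(f$status == "mapped")
    data.frame(factor = tf, detected = det, mapped = mp,
               unaligned = sum(f$status == "unaligned"),
               ambiguous = sum(f$status == "ambiguous"),
               below_min_match = sum(f$status == "below_min_match"),
               failed_reciprocal = sum(f$status == "failed_reciprocal"),
               mapped_pct = mapped_percentage(det, mp),
               stringsAsFactors = FALSE)
  }))

  retention <- do.call(rbind, lapply(tfs, function(tf) {
    f <- fates[fates$factor == tf & fates$status == "mapped", ,
               drop = FALSE]
    n <- nrow(f)
    data.frame(
      factor = tf, n_mapped = n,
      retained = sum(f$fate == "retained"),
      turnover = sum(f$fate == "turnover"),
      lost = sum(f$fate == "lost"),
      frac_retained = if (n) sum(f$fate == "retained") / n else NA_real_,
      frac_turnover = if (n) sum(f$fate == "turnover") / n else NA_real_,
      frac_lost = if (n) sum(f$fate == "lost") / n else NA_real_,
      retained_same_factor = sum(grepl(tf, f$retained_as, fixed = TRUE)),
      stringsAsFactors = FALSE)
  }))

  mapped_f <- fates[fates$status == "mapped", , drop = FALSE]
  enr <- do.call(rbind, lapply(tfs, function(tf) {
    f <- mapped_f[mapped_f$factor == tf, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    v <- violin_summary(f$log2fc, f$fate)
    cbind(factor = tf, v, stringsAsFactors = FALSE)
  }))

  pvals <- list()
  xtab <- function(tf, groups, comparison, name) {
    f <- mapped_f[mapped_f$factor == tf, , drop = FALSE]
    g <- groups(f)
    keep <- !is.na(g)
    ct <- crosstab_retention(f[keep, , drop = FALSE], g[keep], comparison)
    pvals[[paste(name, tf, sep = "_")]] <<- ct$fisher_p
    cbind(factor = tf, ct$table, fisher_p = ct$fisher_p,
          stringsAsFactors = FALSE)
  }
  cluster_tab <- do.call(rbind, lapply(tfs, function(tf)
    xtab(tf, function(f) f$cluster,
         list(a = c("3", "4"), b = c("1", "2", "5", "6")), "cluster")))
  strength_tab <- do.call(rbind, lapply(tfs, function(tf)
    xtab(tf, function(f) f$strength_quartile,
         list(a = "4", b = c("1", "2", "3")), "strength")))
  cobind_tab <- do.call(rbind, lapply(tfs, function(tf)
    xtab(tf, function(f) f$cobind,
         list(a = "overlapping", b = paste0(tf, "_only")), "cobind")))
  consensus_tab <- NULL
  identity_tab <- NULL
  if (!all(is.na(mapped_f$has_cebpa))) {
    consensus_tab <- do.call(rbind, lapply(tfs, function(tf)
      xtab(tf, function(f) {
        flag <- if (tf == "CEBPA") f$has_cebpa else f$has_pparg
        ifelse(flag, "consensus", "no_consensus")
      }, list(a = "consensus", b = "no_consensus"), "consensus")))
  }
  if (!all(is.na(mapped_f$identity))) {
    identity_tab <- do.call(rbind, lapply(tfs, function(tf)
      xtab(tf, function(f) f$identity_quartile,
           list(a = "4", b = c("1", "2", "3")), "identity")))
  }

  pv <- data.frame(contrast = names(pvals),
                   p = as.numeric(unlist(pvals)),
                   stringsAsFactors = FALSE)
  pv$p_bh <- stats::p.adjust(pv$p, method = "BH")

  gained_hist <- do.call(rbind, lapply(tfs, function(tf) {
    g <- .need(pipe, "gained")[[tf]]
    cbind(factor = tf, g$histogram, stringsAsFactors = FALSE)
  }))

  profiles <- .need(pipe, "profiles")
  prof_tab <- do.call(rbind, lapply(names(profiles), function(nm) {
    if (is.null(profiles[[nm]])) return(NULL)
    cbind(cluster = nm, profiles[[nm]], stringsAsFactors = FALSE)
  }))

  orth <- .need(pipe, "tss_orthologs")
  orth_tab <- data.frame(outcome = names(orth$tally),
                         n = as.integer(orth$tally),
                         stringsAsFactors = FALSE)

  list(venn_counts = venn, mapping_summary = mapping,
       retention_summary = retention, enrichment_summary = enr,
       cluster_crosstab = cluster_tab, strength_crosstab = strength_tab,
       cobind_crosstab = cobind_tab, consensus_crosstab = consensus_tab,
       identity_crosstab = identity_tab, pvalues = pv,
       gained_histogram = gained_hist, tss_profiles = prof_tab,
       tss_ortholog_tally = orth_tab)
}

#' Write a report bundle to disk
#'
#' One TSV per table plus a combined `report.json`; numeric formatting is
#' fixed so regeneration from identical inputs is byte-identical.
#'
#' @param report Output of [run_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report)) {
    if (is.null(report[[nm]])) next
    write_tsv(report[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
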