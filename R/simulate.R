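#' Simulation configuration
#'
#' Parameters of the synthetic two-genome fixture generator. Defaults
#' describe a miniature version of the mouse/human adipocyte study: two
#' 5-Mb chromosomes, 2000 sites per factor with discrete widths 150-350 nt,
#' a 36% co-binding fraction, 75% of sites mappable (20% in unalignable
#' regions, 5% in duplicated regions that lift ambiguously), fates
#' retained 20% / turnover 10% / lost 70% of mappable sites, human site
#' strength 32 tags against a background of 4 tags per 520-nt window, and
#' mouse-human identity targets 0.8 / 0.7 / 0.6 for retained / turnover /
#' lost regions.
#'
#' @param seed Integer seed; every random choice in the generator flows
#'   from it (mandatory).
#' @param n_chroms,chrom_len Number and length (nt) of chromosomes; the
#'   two genomes share chromosome names.
#' @param n_sites Mouse sites per factor.
#' @param cobind_frac Fraction of each factor's mouse sites that are
#'   co-bound (planted as overlapping cross-factor pairs).
#' @param frac_unalignable Fraction of sites placed in unalignable
#'   segments (lift status `unaligned`).
#' @param frac_ambiguous Fraction of sites placed in duplicated segments
#'   covered by two chains (lift status `ambiguous`).
#' @param fate_fracs Named fractions (`retained`, `lost`, `turnover`)
#'   summing to 1, applied to the mappable sites.
#' @param n_human_extra Additional human-only sites per factor (gains).
#' @param n_genes Mouse genes; cluster labels per `cluster_fracs`.
#' @param cluster_fracs Named fractions for cluster labels
#'   `1`,`2`,`3`,`4`,`none`.
#' @param cluster_boost Probability that a cluster-3/4 gene is placed near
#'   a retained site rather than uniformly (plants the
#'   retention-near-upregulated-genes association; 0 = no association).
#' @param frac_gene_unlifted Fraction of genes whose TSS flank is placed
#'   in unalignable sequence.
#' @param frac_gene_no_ortholog Fraction of genes lifted but with no human
#'   gene nearby.
#' @param lambda_bg Background tag rate (tags/nt) in both genomes.
#' @param human_site_strength Expected tag count planted on each human
#'   site.
#' @param mouse_strength_mu,mouse_strength_size Negative-binomial mean and
#'   size for mouse site tag counts.
#' @param motif_prob Named probabilities (per fate class) that a mapped
#'   region carries the factor's own consensus motif.
#' @param cross_motif_prob Probability of carrying the other factor's
#'   motif.
#' @param identity_target Named mouse-human identity targets per fate
#'   class.
#' @param region_len Length (nt) of the sequence extracted around each
#'   orthologous region.
#' @param site_widths Candidate site widths (nt). A discrete set whose top
#'   class holds well over 5% of sites keeps the 95th width percentile at
#'   the maximum, so the routine widest-site filter removes nothing from a
#'   clean fixture and planted guarantees survive the full pipeline.
#' @param n_indels,indel_max Count and maximum size (nt) of insertions or
#'   deletions planted between sites on each chromosome.
#' @param gene_min_space Minimum spacing (nt) between gene TSSs
#'   (best-effort, strict for no-ortholog genes so their lifted TSS stays
#'   clear of other human genes).
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_chroms = 2L,
                       chrom_len = 5e6,
                       n_sites = 2000L,
                       cobind_frac = 0.36,
                       frac_unalignable = 0.2,
                       frac_ambiguous = 0.05,
                       fate_fracs = c(retained = 0.2, lost = 0.7,
                                      turnover = 0.1),
                       n_human_extra = 300L,
                       n_genes = 400L,
                       cluster_fracs = c(`1` = 0.08, `2` = 0.08, `3` = 0.08,
                                         `4` = 0.08, none = 0.68),
                       cluster_boost = 0.5,
                       frac_gene_unlifted = 0.08,
                       frac_gene_no_ortholog = 0.04,
                       lambda_bg = 4 / 520,
                       human_site_strength = 32,
                       mouse_strength_mu = 30,
                       mouse_strength_size = 2,
                       motif_prob = c(retained = 0.8, turnover = 0.4,
                                      lost = 0.3),
                       cross_motif_prob = 0.1,
                       identity_target = c(retained = 0.8, turnover = 0.7,
                                           lost = 0.6),
                       region_len = 500L,
                       site_widths = seq(150L, 350L, by = 50L),
                       n_indels = 15L,
                       indel_max = 50L,
                       gene_min_space = 8000L) {
  if (missing(seed)) stop("sim_config() requires a seed")
  stopifnot(abs(sum(fate_fracs) - 1) < 1e-9,
            all(fate_fracs >= 0),
            all(names(fate_fracs) %in% c("retained", "lost", "turnover")),
            frac_unalignable >= 0, frac_ambiguous >= 0,
            frac_unalignable + frac_ambiguous < 1,
            cobind_frac >= 0, cobind_frac <= 1,
            abs(sum(cluster_fracs) - 1) < 1e-9,
            lambda_bg >= 0, region_len >= 100,
            all(identity_target > 0), all(identity_target <= 1))
  structure(list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_len = chrom_len, n_sites = as.integer(n_sites),
    cobind_frac = cobind_frac, frac_unalignable = frac_unalignable,
    frac_ambiguous = frac_ambiguous, fate_fracs = fate_fracs,
    n_human_extra = as.integer(n_human_extra),
    n_genes = as.integer(n_genes), cluster_fracs = cluster_fracs,
    cluster_boost = cluster_boost,
    frac_gene_unlifted = frac_gene_unlifted,
    frac_gene_no_ortholog = frac_gene_no_ortholog,
    lambda_bg = lambda_bg, human_site_strength = human_site_strength,
    mouse_strength_mu = mouse_strength_mu,
    mouse_strength_size = mouse_strength_size,
    motif_prob = motif_prob, cross_motif_prob = cross_motif_prob,
    identity_target = identity_target, region_len = as.integer(region_len),
    site_widths = as.integer(site_widths), n_indels = as.integer(n_indels),
    indel_max = as.integer(indel_max),
    gene_min_space = as.integer(gene_min_space)),
    class = "sim_config")
}

# Largest-remainder apportionment of n into named integer counts.
alloc_counts <- function(n, fracs) {
  raw <- n * fracs
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(cnt), names(fracs))
}

# Split per-category totals between a sub-population of size n_part and
# the remainder, proportionally, keeping both sides non-negative and the
# category totals exact.
.alloc_split <- function(n_part, total) {
  if (sum(total) == 0L || n_part == 0L) {
    part <- stats::setNames(integer(length(total)), names(total))
    return(list(part = part, rest = total))
  }
  part <- alloc_counts(n_part, total / sum(total))
  part <- pmin(part, total)
  while (sum(part) < n_part) {
    j <- which.max(total - part)
    part[j] <- part[j] + 1L
  }
  list(part = part, rest = total - part)
}

#' Simulate ChIP tag tracks
#'
#' Background tags per chromosome are Poisson with rate
#' `lambda_bg * length`, placed uniformly; each site adds
#' `Poisson(strength)` tags uniformly over its span.
#'
#' @param sites Site data frame; per-site strengths are taken from
#'   `strengths` (default: the `tag_count` column).
#' @param lambda_bg Background rate, tags/nt (>= 0).
#' @param genome Chromosome-length data frame.
#' @param strengths Expected tag count per site.
#' @return A `"tag_track"`.
#' @export
simulate_tags <- function(sites, lambda_bg, genome,
                          strengths = sites$tag_count) {
  stopifnot(lambda_bg >= 0, nrow(sites) == length(strengths))
  chrom <- character(0)
  pos <- numeric(0)
  for (i in seq_len(nrow(genome))) {
    n_bg <- stats::rpois(1, lambda_bg * genome$length[i])
    if (n_bg > 0) {
      chrom <- c(chrom, rep(genome$chrom[i], n_bg))
      pos <- c(pos, floor(stats::runif(n_bg) * genome$length[i]))
    }
  }
  if (nrow(sites)) {
    k <- stats::rpois(nrow(sites), strengths)
    idx <- rep(seq_len(nrow(sites)), k)
    if (length(idx)) {
      chrom <- c(chrom, sites$chrom[idx])
      w <- sites$end[idx] - sites$start[idx]
      pos <- c(pos, sites$start[idx] + floor(stats::runif(length(idx)) * w))
    }
  }
  tag_track(chrom, pos)
}

#' Mutate a sequence to a target identity
#'
#' Substitutes bases (always to a different base) at positions sampled
#' uniformly outside the protected intervals, using exactly
#' `round((1 - target) * nchar(seq))` substitutions so the realised
#' ungapped identity equals the target up to rounding. Planted motif
#' intervals are typically protected so consensus content survives.
#'
#' @param seq DNA string.
#' @param target Target identity in `(0, 1]`.
#' @param protect Optional data frame `start`, `end` (1-based inclusive)
#'   of intervals that must not be mutated.
#' @return Mutated sequence string.
#' @export
mutate_to_identity <- function(seq, target, protect = NULL) {
  stopifnot(target > 0, target <= 1)
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1L]]
  prot <- integer(0)
  if (!is.null(protect) && nrow(protect)) {
    if (any(protect$start < 1) || any(protect$end > n)) {
      stop("protected interval outside sequence")
    }
    prot <- unlist(mapply(function(a, b) a:b, protect$start, protect$end,
                          SIMPLIFY = FALSE))
  }
  cand <- setdiff(seq_len(n), prot)
  n_sub <- round((1 - target) * n)
  if (n_sub > length(cand)) {
    stop("target identity unreachable given protected intervals")
  }
  if (n_sub > 0) {
    idx <- sample(cand, n_sub)
    bases <- c("A", "C", "G", "T")
    code <- match(chars[idx], bases)
    # shift by 1-3 positions in base space: always a different base
    chars[idx] <- bases[((code - 1L + sample.int(3L, n_sub,
                                                 replace = TRUE)) %% 4L) + 1L]
  }
  paste(chars, collapse = "")
}

#' Canonical file names of a fixture directory
#'
#' @param dir Fixture directory.
#' @return Named list of paths.
#' @export
fixture_paths <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(
    mouse_sites = c(CEBPA = p("mouse_sites_CEBPA.bed"),
                    PPARG = p("mouse_sites_PPARG.bed")),
    human_sites = c(CEBPA = p("human_sites_CEBPA.bed"),
                    PPARG = p("human_sites_PPARG.bed")),
    chains_fwd = p("chains_mouse_to_human.tsv"),
    chains_rev = p("chains_human_to_mouse.tsv"),
    genome_mouse = p("genome_mouse.tsv"),
    genome_human = p("genome_human.tsv"),
    genes_mouse = p("genes_mouse.tsv"),
    genes_human = p("genes_human.tsv"),
    tags_mouse = c(CEBPA = p("tags_mouse_CEBPA.bed"),
                   PPARG = p("tags_mouse_PPARG.bed")),
    tags_human = c(CEBPA = p("tags_human_CEBPA.bed"),
                   PPARG = p("tags_human_PPARG.bed")),
    regions = p("regions_human.fa"),
    alignments = p("alignments_mouse_human.fa"),
    truth = p("ground_truth.json"),
    config = p("sim_config.yaml"))
}

#' Generate a complete synthetic two-genome fixture
#'
#' Writes a full fixture — site BEDs for both species and factors,
#' forward/reverse chain block TSVs, gene tables, tag tracks, orthologous
#' region FASTA and pairwise alignments — together with the ground truth
#' of every planted quantity, and returns the truth in memory.
#'
#' Construction guarantees (all by deliberate placement, not chance):
#' sites planted `unaligned`/`ambiguous` fail the lift for exactly that
#' reason; every planted-retained site has a same-factor human partner
#' overlapping ~70% of its true image; every planted-turnover site has a
#' human-specific site 2-8 kb (midpoint distance) from its image and no
#' overlapping human site; planted-lost sites have no human site within
#' 20 kb. The two genomes differ by planted insertions/deletions and
#' duplicated segments, so lifts are exercised non-trivially. All files
#' are plain text and byte-identical across runs with the same seed.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param write_sequences Generate region sequences/alignments (the
#'   slowest part); disable for mapping/retention-only fixtures.
#' @return A list: `dir`, `paths` ([fixture_paths()]), `truth` (lists
#'   `sites`, `human_sites`, `genes`, `gene_tally`), `cfg`.
#' @export
generate_fixture <- function(cfg, dir, write_sequences = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- fixture_paths(dir)
  with_seed(cfg$seed, {
    res <- .build_fixture(cfg, paths, write_sequences)
  })
  yaml::write_yaml(unclass(cfg), paths$config)
  c(list(dir = dir, paths = paths), res, list(cfg = cfg))
}

# ---- generator internals ---------------------------------------------------

.build_fixture <- function(cfg, paths, write_sequences) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  margin <- 30000
  zone_gap <- 25000
  pitch_dense <- 1500
  pitch_turnover <- 9500

  ## 1. unit bookkeeping: exact per-factor status and fate counts ------------
  n_pairs <- round(cfg$cobind_frac * cfg$n_sites)
  n_singles <- cfg$n_sites - n_pairs
  status_fracs <- c(mapped = 1 - cfg$frac_unalignable - cfg$frac_ambiguous,
                    unaligned = cfg$frac_unalignable,
                    ambiguous = cfg$frac_ambiguous)
  st_total <- alloc_counts(cfg$n_sites, status_fracs)
  st_split <- .alloc_split(n_pairs, st_total)
  st_pair <- st_split$part
  st_single <- st_split$rest

  fate_total <- alloc_counts(st_total[["mapped"]], cfg$fate_fracs)
  fate_split <- .alloc_split(st_pair[["mapped"]], fate_total)
  fate_pair <- fate_split$part
  fate_single <- fate_split$rest

  unit_rows <- function(type, status_alloc, fate_alloc) {
    status <- rep(names(status_alloc), status_alloc)
    fate <- rep(NA_character_, length(status))
    fate[status == "mapped"] <- rep(names(fate_alloc), fate_alloc)
    data.frame(type = type, status = status, fate = fate,
               stringsAsFactors = FALSE)
  }
  units <- rbind(
    unit_rows("pair", st_pair, fate_pair),
    unit_rows("single_CEBPA", st_single, fate_single),
    unit_rows("single_PPARG", st_single, fate_single),
    data.frame(type = rep(c("extra_CEBPA", "extra_PPARG"),
                          each = cfg$n_human_extra),
               status = NA_character_, fate = NA_character_,
               stringsAsFactors = FALSE))
  units$zone <- ifelse(!is.na(units$fate) & units$fate == "retained", 1L,
                ifelse(!is.na(units$fate) & units$fate == "turnover", 2L,
                ifelse(grepl("^extra", units$type), 3L, 4L)))
  units <- units[order(units$zone, sample.int(nrow(units))), , drop = FALSE]
  units$unit_id <- paste0("u", seq_len(nrow(units)))

  ## 2. spatial layout: zones along the chromosomes --------------------------
  n_u <- nrow(units)
  units$chrom <- NA_character_
  units$pos <- NA_real_
  units$wA <- sample(cfg$site_widths, n_u, replace = TRUE)
  units$wB <- sample(cfg$site_widths, n_u, replace = TRUE)
  units$shift <- floor(0.4 * units$wA)
  ext <- ifelse(units$type == "pair",
                pmax(units$wA, units$shift + units$wB), units$wA)
  pitch <- ifelse(units$zone == 2L, pitch_turnover, pitch_dense)
  ci <- 1L
  cursor <- margin
  prev_zone <- units$zone[1L]
  for (i in seq_len(n_u)) {
    if (units$zone[i] != prev_zone) {
      cursor <- cursor + zone_gap
      prev_zone <- units$zone[i]
    }
    if (cursor + ext[i] > cfg$chrom_len - margin) {
      ci <- ci + 1L
      if (ci > cfg$n_chroms) {
        stop("infeasible sim_config: sites do not fit on the genome")
      }
      cursor <- margin
    }
    units$chrom[i] <- chroms[ci]
    units$pos[i] <- cursor
    cursor <- cursor + ext[i] + pitch[i]
  }
  units$end <- units$pos + ext

  ## 3. mouse sites -----------------------------------------------------------
  msite <- local({
    pair <- units[units$type == "pair", , drop = FALSE]
    sc <- units[units$type == "single_CEBPA", , drop = FALSE]
    sp <- units[units$type == "single_PPARG", , drop = FALSE]
    rbind(
      data.frame(unit_id = pair$unit_id, factor = "CEBPA",
                 chrom = pair$chrom, start = pair$pos,
                 end = pair$pos + pair$wA, status = pair$status,
                 fate = pair$fate, cobound = TRUE,
                 stringsAsFactors = FALSE),
      data.frame(unit_id = pair$unit_id, factor = "PPARG",
                 chrom = pair$chrom, start = pair$pos + pair$shift,
                 end = pair$pos + pair$shift + pair$wB,
                 status = pair$status, fate = pair$fate, cobound = TRUE,
                 stringsAsFactors = FALSE),
      data.frame(unit_id = sc$unit_id, factor = "CEBPA", chrom = sc$chrom,
                 start = sc$pos, end = sc$pos + sc$wA, status = sc$status,
                 fate = sc$fate, cobound = FALSE, stringsAsFactors = FALSE),
      data.frame(unit_id = sp$unit_id, factor = "PPARG", chrom = sp$chrom,
                 start = sp$pos, end = sp$pos + sp$wA, status = sp$status,
                 fate = sp$fate, cobound = FALSE, stringsAsFactors = FALSE))
  })
  msite <- msite[order(msite$chrom, msite$start, msite$factor), ,
                 drop = FALSE]
  msite$site_id <- paste0("m_", msite$factor, "_",
                          stats::ave(seq_len(nrow(msite)), msite$factor,
                                     FUN = seq_along))
  msite$tag_count <- stats::rnbinom(nrow(msite),
                                    size = cfg$mouse_strength_size,
                                    mu = cfg$mouse_strength_mu)

  ## 4. chains ---------------------------------------------------------------
  unalign <- local({
    ua <- units[!is.na(units$status) & units$status == "unaligned", ,
                drop = FALSE]
    if (!nrow(ua)) {
      data.frame(chrom = character(0), start = numeric(0),
                 end = numeric(0), dq = numeric(0))
    } else {
      data.frame(chrom = ua$chrom, start = ua$pos - 150,
                 end = ua$end + 150, dq = 0, stringsAsFactors = FALSE)
    }
  })
  # indels between units: deletions become unaligned slivers (human side
  # skips dq bases fewer), insertions shift the offset at a point
  events <- unalign
  inserts <- data.frame(chrom = character(0), pos = numeric(0),
                        size = numeric(0))
  for (ch in chroms) {
    uc <- units[units$chrom == ch, , drop = FALSE]
    if (nrow(uc) < 2L) next
    gap_lo <- uc$end[-nrow(uc)] + 200
    gap_hi <- uc$pos[-1L] - 200
    ok <- which(gap_hi - gap_lo > 2500)
    if (!length(ok)) next
    take <- ok[sort(sample.int(length(ok), min(cfg$n_indels, length(ok))))]
    for (g in take) {
      p <- floor((gap_lo[g] + gap_hi[g]) / 2)
      sz <- sample.int(cfg$indel_max, 1)
      if (stats::runif(1) < 0.5) {
        inserts <- rbind(inserts, data.frame(chrom = ch, pos = p,
                                             size = sz))
      } else {
        events <- rbind(events, data.frame(chrom = ch, start = p,
                                           end = p + sz, dq = -sz))
      }
    }
  }

  fwd <- list()
  human_len <- stats::setNames(numeric(length(chroms)), chroms)
  for (ch in chroms) {
    ev <- events[events$chrom == ch, , drop = FALSE]
    ins <- inserts[inserts$chrom == ch, , drop = FALSE]
    brk <- rbind(
      if (nrow(ev)) data.frame(start = ev$start, end = ev$end, dq = ev$dq),
      if (nrow(ins)) data.frame(start = ins$pos, end = ins$pos,
                                dq = ins$size))
    if (is.null(brk)) brk <- data.frame(start = numeric(0),
                                        end = numeric(0), dq = numeric(0))
    brk <- brk[order(brk$start), , drop = FALSE]
    s <- 0
    off <- 0
    for (j in seq_len(nrow(brk))) {
      if (brk$start[j] > s) {
        fwd[[length(fwd) + 1L]] <- data.frame(
          chain_id = paste0("main_", ch), src_chrom = ch, src_start = s,
          src_end = brk$start[j], tgt_chrom = ch, tgt_start = s + off,
          tgt_end = brk$start[j] + off, tgt_strand = "+",
          stringsAsFactors = FALSE)
      }
      # dq < 0: deletion in human; dq > 0: insertion in human; dq = 0:
      # unalignable in both genomes (offset unchanged)
      off <- off + brk$dq[j]
      s <- brk$end[j]
    }
    fwd[[length(fwd) + 1L]] <- data.frame(
      chain_id = paste0("main_", ch), src_chrom = ch, src_start = s,
      src_end = cfg$chrom_len, tgt_chrom = ch, tgt_start = s + off,
      tgt_end = cfg$chrom_len + off, tgt_strand = "+",
      stringsAsFactors = FALSE)
    human_len[ch] <- cfg$chrom_len + off
  }
  fwd <- do.call(rbind, fwd)

  # duplicated (decoy) chains make planted-ambiguous units lift ambiguously
  amb <- units[!is.na(units$status) & units$status == "ambiguous", ,
               drop = FALSE]
  if (nrow(amb)) {
    dec_cursor <- stats::setNames(human_len + 50000, names(human_len))
    dec <- vector("list", nrow(amb))
    for (i in seq_len(nrow(amb))) {
      ch <- amb$chrom[i]
      w <- (amb$end[i] + 50) - (amb$pos[i] - 50)
      dec[[i]] <- data.frame(
        chain_id = paste0("dup_", amb$unit_id[i]), src_chrom = ch,
        src_start = amb$pos[i] - 50, src_end = amb$end[i] + 50,
        tgt_chrom = ch, tgt_start = dec_cursor[ch],
        tgt_end = dec_cursor[ch] + w, tgt_strand = "+",
        stringsAsFactors = FALSE)
      dec_cursor[ch] <- dec_cursor[ch] + w + 500
    }
    fwd <- rbind(fwd, do.call(rbind, dec))
    for (ch in names(human_len)) {
      human_len[ch] <- max(human_len[ch], dec_cursor[ch]) + 10000
    }
  } else {
    human_len <- human_len + 10000
  }
  fwd <- fwd[order(fwd$src_chrom, fwd$src_start, fwd$chain_id), ,
             drop = FALSE]
  rev <- invert_chains(fwd)
  main <- fwd[startsWith(fwd$chain_id, "main_"), , drop = FALSE]

  genome_mouse <- data.frame(chrom = chroms,
                             length = rep(cfg$chrom_len, length(chroms)))
  genome_human <- data.frame(chrom = chroms,
                             length = as.numeric(human_len[chroms]))

  ## 5. true images of mapped/ambiguous mouse sites --------------------------
  msite$img_chrom <- NA_character_
  msite$img_start <- NA_real_
  msite$img_end <- NA_real_
  need_img <- which(msite$status %in% c("mapped", "ambiguous"))
  for (i in need_img) {
    lf <- lift_interval(main, msite$chrom[i], msite$start[i], msite$end[i],
                        min_match = 0.1)
    stopifnot(lf$status == "mapped")
    msite$img_chrom[i] <- lf$chrom
    msite$img_start[i] <- lf$start
    msite$img_end[i] <- lf$end
  }

  ## 6. human sites ----------------------------------------------------------
  hs <- list()
  add_h <- function(factor, chrom, start, end, class, source_unit) {
    hs[[length(hs) + 1L]] <<- data.frame(
      factor = factor, chrom = chrom, start = start, end = end,
      class = class, source_unit = source_unit, stringsAsFactors = FALSE)
  }
  for (i in which(!is.na(msite$fate) & msite$fate == "retained" &
                  msite$status == "mapped")) {
    w <- msite$img_end[i] - msite$img_start[i]
    sh <- floor(0.3 * w)
    add_h(msite$factor[i], msite$img_chrom[i], msite$img_start[i] + sh,
          msite$img_end[i] + sh, "partner", msite$unit_id[i])
  }
  to_units <- unique(msite$unit_id[!is.na(msite$fate) &
                                   msite$fate == "turnover"])
  for (u in to_units) {
    mem <- msite[msite$unit_id == u & msite$status == "mapped", ,
                 drop = FALSE]
    d0 <- sample(2000:7000, 1)
    for (j in seq_len(nrow(mem))) {
      d <- d0 + (j - 1L) * 800
      hw <- sample(cfg$site_widths, 1)
      mid <- floor((mem$img_start[j] + mem$img_end[j]) / 2)
      add_h(mem$factor[j], mem$img_chrom[j], mid + d - floor(hw / 2),
            mid + d - floor(hw / 2) + hw, "turnover_specific", u)
    }
  }
  for (i in which(grepl("^extra", units$type))) {
    lf <- lift_interval(main, units$chrom[i], units$pos[i], units$end[i],
                        min_match = 0.1)
    stopifnot(lf$status == "mapped")
    add_h(sub("^extra_", "", units$type[i]), lf$chrom, lf$start, lf$end,
          "extra", units$unit_id[i])
  }
  hsite <- do.call(rbind, hs)
  hsite <- hsite[order(hsite$chrom, hsite$start, hsite$factor), ,
                 drop = FALSE]
  hsite$site_id <- paste0("h_", hsite$factor, "_",
                          stats::ave(seq_len(nrow(hsite)), hsite$factor,
                                     FUN = seq_along))
  hsite$tag_count <- rep(cfg$human_site_strength, nrow(hsite))

  ## 7. genes ----------------------------------------------------------------
  genes <- .plant_genes(cfg, units, msite, unalign, main, genome_mouse)

  ## 8. write everything -----------------------------------------------------
  for (tf in c("CEBPA", "PPARG")) {
    m <- msite[msite$factor == tf, , drop = FALSE]
    write_sites(binding_sites(m$chrom, m$start, m$end, m$site_id, tf,
                              "mouse", m$tag_count),
                paths$mouse_sites[[tf]])
    h <- hsite[hsite$factor == tf, , drop = FALSE]
    write_sites(binding_sites(h$chrom, h$start, h$end, h$site_id, tf,
                              "human", h$tag_count),
                paths$human_sites[[tf]])
  }
  write_chain_tsv(fwd, paths$chains_fwd)
  write_chain_tsv(rev, paths$chains_rev)
  write_genome(genome_mouse, paths$genome_mouse)
  write_genome(genome_human, paths$genome_human)
  write_genes(genes$mouse, paths$genes_mouse)
  write_genes(genes$human, paths$genes_human)

  for (tf in c("CEBPA", "PPARG")) {
    m <- msite[msite$factor == tf, , drop = FALSE]
    mtrack <- simulate_tags(
      data.frame(chrom = m$chrom, start = m$start, end = m$end),
      cfg$lambda_bg, genome_mouse, strengths = m$tag_count)
    write_tag_track(mtrack, paths$tags_mouse[[tf]])
    h <- hsite[hsite$factor == tf, , drop = FALSE]
    htrack <- simulate_tags(
      data.frame(chrom = h$chrom, start = h$start, end = h$end),
      cfg$lambda_bg, genome_human, strengths = h$tag_count)
    write_tag_track(htrack, paths$tags_human[[tf]])
  }

  ## 9. sequences and alignments ---------------------------------------------
  msite$motif_cebpa <- NA
  msite$motif_pparg <- NA
  msite$identity_target <- NA_real_
  if (write_sequences) {
    seqres <- .plant_sequences(cfg, msite, paths)
    msite <- seqres$msite
  } else {
    writeLines(character(0), paths$regions)
    writeLines(character(0), paths$alignments)
  }

  truth <- list(
    sites = msite[, c("site_id", "unit_id", "factor", "chrom", "start",
                      "end", "tag_count", "cobound", "status", "fate",
                      "img_chrom", "img_start", "img_end", "motif_cebpa",
                      "motif_pparg", "identity_target")],
    human_sites = hsite[, c("site_id", "factor", "chrom", "start", "end",
                            "class", "source_unit")],
    genes = genes$truth,
    gene_tally = genes$tally)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  list(truth = truth)
}

# Gene placement: clusters allocated exactly; a planted fraction of TSSs
# sits in unalignable sequence ("unlifted"), another lifts cleanly but has
# no human counterpart ("no_ortholog"); cluster-3/4 genes optionally land
# near retained sites (the retention association).
.plant_genes <- function(cfg, units, msite, unalign, main, genome_mouse) {
  n <- cfg$n_genes
  cl <- rep(names(cfg$cluster_fracs), alloc_counts(n, cfg$cluster_fracs))
  cl <- sample(cl)
  gene_fate <- rep("lifted", n)
  n_unl <- round(cfg$frac_gene_unlifted * n)
  if (nrow(unalign) == 0L) n_unl <- 0L
  n_noo <- round(cfg$frac_gene_no_ortholog * n)
  marks <- sample.int(n, n_unl + n_noo)
  gene_fate[marks[seq_len(n_unl)]] <- "unlifted"
  gene_fate[marks[n_unl + seq_len(n_noo)]] <- "no_ortholog"

  placed <- stats::setNames(vector("list", nrow(genome_mouse)),
                            genome_mouse$chrom)
  ok_spaced <- function(ch, p, space) {
    !length(placed[[ch]]) || min(abs(placed[[ch]] - p)) >= space
  }
  flank <- 50
  liftable <- function(ch, p) {
    lf <- lift_interval(main, ch, p - flank, p + flank, 0.1)
    identical(lf$status, "mapped") && lf$covered_frac == 1
  }
  margin <- 30000
  chrom_len_of <- stats::setNames(genome_mouse$length, genome_mouse$chrom)
  ret_units <- units[!is.na(units$fate) & units$fate == "retained", ,
                     drop = FALSE]
  chrom <- character(n)
  tss <- numeric(n)
  boosted <- logical(n)
  for (i in seq_len(n)) {
    if (gene_fate[i] == "unlifted") {
      for (try in 1:500) {
        k <- sample.int(nrow(unalign), 1)
        lo <- unalign$start[k] + 60
        hi <- unalign$end[k] - 60
        if (hi <= lo) next
        p <- lo + floor(stats::runif(1) * (hi - lo))
        if (ok_spaced(unalign$chrom[k], p, 2000)) {
          chrom[i] <- unalign$chrom[k]; tss[i] <- p
          break
        }
      }
      if (chrom[i] == "") stop("could not place unlifted gene TSS")
    } else {
      strict <- gene_fate[i] == "no_ortholog"
      boost <- cfg$cluster_boost > 0 && cl[i] %in% c("3", "4") &&
        gene_fate[i] == "lifted" && nrow(ret_units) > 0 &&
        stats::runif(1) < cfg$cluster_boost
      boosted[i] <- boost
      done <- FALSE
      for (try in 1:500) {
        if (boost) {
          k <- sample.int(nrow(ret_units), 1)
          p <- floor((ret_units$pos[k] + ret_units$end[k]) / 2) +
            sample(-50000:50000, 1)
          ch <- ret_units$chrom[k]
        } else {
          ci <- sample.int(nrow(genome_mouse), 1,
                           prob = genome_mouse$length)
          ch <- genome_mouse$chrom[ci]
          p <- margin + floor(stats::runif(1) *
                              (genome_mouse$length[ci] - 2 * margin))
        }
        if (p < margin || p > chrom_len_of[[ch]] - margin) next
        space_need <- if (strict) cfg$gene_min_space else
          if (try <= 250) cfg$gene_min_space else 0
        if (!ok_spaced(ch, p, max(space_need, 1))) next
        if (!liftable(ch, p)) next
        chrom[i] <- ch; tss[i] <- p; done <- TRUE
        break
      }
      if (!done) stop("could not place gene TSS (infeasible sim_config)")
    }
    placed[[chrom[i]]] <- c(placed[[chrom[i]]], tss[i])
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  mouse <- data.frame(gene_id = paste0("g", seq_len(n)), chrom = chrom,
                      tss = tss, strand = strand, cluster = cl,
                      stringsAsFactors = FALSE)
  take <- gene_fate == "lifted"
  hm <- mouse[take, , drop = FALSE]
  h_tss <- numeric(nrow(hm))
  for (j in seq_len(nrow(hm))) {
    lf <- lift_interval(main, hm$chrom[j], hm$tss[j], hm$tss[j] + 1, 0.1)
    h_tss[j] <- lf$start + sample(-1000:1000, 1)
  }
  human <- data.frame(gene_id = paste0("h_", hm$gene_id), chrom = hm$chrom,
                      tss = h_tss, strand = hm$strand, cluster = hm$cluster,
                      stringsAsFactors = FALSE)
  list(mouse = mouse, human = human,
       truth = data.frame(gene_id = mouse$gene_id, cluster = cl,
                          gene_fate = gene_fate, boosted = boosted,
                          stringsAsFactors = FALSE),
       tally = c(lifted = sum(take), unlifted = sum(gene_fate == "unlifted"),
                 no_ortholog = sum(gene_fate == "no_ortholog")))
}

# Region sequences with planted consensus motifs, and mouse counterparts
# mutated to the per-fate identity target. Sequences are redrawn until the
# consensus flags equal exactly what was planted (chance hits removed).
.plant_sequences <- function(cfg, msite, paths) {
  pwms <- default_pwms(analysis_config())
  cons <- lapply(pwms, pwm_consensus)
  bases <- c("A", "C", "G", "T")
  idx <- which(msite$status == "mapped")
  region_lines <- character(0)
  aln_lines <- character(0)
  for (i in idx) {
    fate <- msite$fate[i]
    own <- msite$factor[i]
    other <- setdiff(c("CEBPA", "PPARG"), own)
    p_own <- cfg$motif_prob[[fate]]
    plant_own <- stats::runif(1) < p_own
    plant_other <- stats::runif(1) < cfg$cross_motif_prob
    plant <- c(CEBPA = FALSE, PPARG = FALSE)
    plant[own] <- plant_own
    plant[other] <- plant_other
    ok <- FALSE
    for (try in 1:80) {
      s <- paste(sample(bases, cfg$region_len, replace = TRUE),
                 collapse = "")
      prot <- data.frame(start = integer(0), end = integer(0))
      pos_used <- integer(0)
      bad <- FALSE
      for (tf in c("CEBPA", "PPARG")[plant]) {
        word <- cons[[tf]]
        L <- nchar(word)
        for (ptry in 1:20) {
          p0 <- sample.int(cfg$region_len - L + 1L, 1)
          if (!length(pos_used) ||
              min(abs(pos_used - p0)) > max(nchar(unlist(cons)))) {
            substr(s, p0, p0 + L - 1L) <- word
            prot <- rbind(prot, data.frame(start = p0, end = p0 + L - 1L))
            pos_used <- c(pos_used, p0)
            break
          }
          if (ptry == 20) bad <- TRUE
        }
      }
      if (bad) next
      flags <- vapply(pwms, function(w) has_consensus(s, w)$flag,
                      logical(1))
      if (identical(unname(flags), unname(plant[names(pwms)]))) {
        mseq <- mutate_to_identity(s, cfg$identity_target[[fate]],
                                   protect = prot)
        region_lines <- c(region_lines, paste0(">", msite$site_id[i]), s)
        aln_lines <- c(aln_lines,
                       paste0(">", msite$site_id[i], "|mouse"), mseq,
                       paste0(">", msite$site_id[i], "|human"), s)
        msite$motif_cebpa[i] <- unname(plant[["CEBPA"]])
        msite$motif_pparg[i] <- unname(plant[["PPARG"]])
        msite$identity_target[i] <- cfg$identity_target[[fate]]
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not realise planted motif pattern for region ",
                  msite$site_id[i])
  }
  writeLines(region_lines, paths$regions)
  writeLines(aln_lines, paths$alignments)
  list(msite = msite)
}
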