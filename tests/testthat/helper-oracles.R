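# Brute-force oracles, deliberately independent of the package internals:
# plain all-pairs loops and direct enumeration, used to cross-check the
# interval, retention, motif and statistics machinery.

oracle_overlap1 <- function(ac, as, ae, bc, bs, be) {
  if (ac != bc) return(0)
  max(0, min(ae, be) - max(as, bs))
}

# per-site best overlap (nt) of `a` sites against `b` sites, all pairs
oracle_best_overlap <- function(a, b) {
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- 0
    for (j in seq_len(nrow(b))) {
      best <- max(best, oracle_overlap1(a$chrom[i], a$start[i], a$end[i],
                                        b$chrom[j], b$start[j], b$end[j]))
    }
    out[i] <- best
  }
  out
}

# co-binding labels by all-pairs search
oracle_cobind <- function(cebpa, pparg, cfg, mode) {
  bc <- oracle_best_overlap(cebpa, pparg)
  bp <- oracle_best_overlap(pparg, cebpa)
  if (mode == "mouse") {
    list(cebpa = bc / (cebpa$end - cebpa$start) >= cfg$cobind_frac_cebpa,
         pparg = bp / (pparg$end - pparg$start) >= cfg$cobind_frac_pparg)
  } else {
    list(cebpa = bc >= cfg$human_cobind_min_nt,
         pparg = bp >= cfg$human_cobind_min_nt)
  }
}

# binary retention by all-pairs search (strict > threshold, either way)
oracle_retention <- function(spans, human, frac) {
  out <- logical(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    wi <- spans$end[i] - spans$start[i]
    for (j in seq_len(nrow(human))) {
      ol <- oracle_overlap1(spans$chrom[i], spans$start[i], spans$end[i],
                            human$chrom[j], human$start[j], human$end[j])
      wj <- human$end[j] - human$start[j]
      if (ol > frac * wi || ol > frac * wj) { out[i] <- TRUE; break }
    }
  }
  out
}

# two-sided Fisher p by direct hypergeometric enumeration (log-binomials)
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)
  p <- exp(lp)
  obs <- p[a == tab[1, 1]]
  sum(p[p <= obs * (1 + 1e-7)])
}

# all two-sided Fisher p values for one margin set, by enumeration
oracle_fisher_margin <- function(r1, r2, c1) {
  a <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)
  p <- exp(lp)
  vapply(seq_along(a), function(i) sum(p[p <= p[i] * (1 + 1e-7)]),
         numeric(1))
}

# PWM scan by explicit window/strand enumeration
oracle_scan <- function(seq, pwm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) {
    ch <- rev(strsplit(s, "")[[1L]])
    paste(ifelse(ch %in% names(comp), comp[ch], ch), collapse = "")
  }
  score_at <- function(s, k) {
    tot <- 0
    for (j in seq_len(pwm$length)) {
      b <- substr(s, k + j - 1L, k + j - 1L)
      if (!b %in% c("A", "C", "G", "T")) return(-Inf)
      tot <- tot + pwm$logodds[b, j]
    }
    tot
  }
  best <- -Inf
  for (s in c(toupper(seq), rc(toupper(seq)))) {
    W <- nchar(s) - pwm$length + 1L
    if (W < 1L) next
    for (k in seq_len(W)) best <- max(best, score_at(s, k))
  }
  is.finite(best) && best >= pwm$threshold
}

# random site set on a small genome (overlaps allowed)
random_sites_df <- function(n, tf, species = "mouse", chroms = c("chr1", "chr2"),
                            len = 100000) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n) * (len - 600))
  w <- sample(50:500, n, replace = TRUE)
  binding_sites(chrom, start, start + w,
                site_id = paste0(tf, "_", species, "_", seq_len(n)),
                tf = tf, species = species)
}

# single identity chain covering [0, len) on each chromosome
identity_chains <- function(chroms = c("chr1", "chr2"), len = 1e6) {
  data.frame(chain_id = paste0("id_", chroms), src_chrom = chroms,
             src_start = 0, src_end = len, tgt_chrom = chroms,
             tgt_start = 0, tgt_end = len, tgt_strand = "+",
             stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
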