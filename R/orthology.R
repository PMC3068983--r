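#' Invert alignment chains
#'
#' Swaps the source and target sides of every block, turning a
#' source-to-target chain set into the corresponding target-to-source set.
#' Reverse-strand blocks keep their strand: the per-base relation of a `-`
#' block is an involution, so the same orientation flag applies both ways.
#'
#' @param chains Chain block data frame.
#' @return Inverted chain block data frame, sorted by source coordinates.
#' @export
invert_chains <- function(chains) {
  validate_chains(chains)
  inv <- data.frame(chain_id = chains$chain_id,
                    src_chrom = chains$tgt_chrom,
                    src_start = chains$tgt_start,
                    src_end = chains$tgt_end,
                    tgt_chrom = chains$src_chrom,
                    tgt_start = chains$src_start,
                    tgt_end = chains$src_end,
                    tgt_strand = chains$tgt_strand,
                    stringsAsFactors = FALSE)
  inv[order(inv$src_chrom, inv$src_start), , drop = FALSE]
}

# Map a single source base through a block.
.map_base <- function(pos, blk) {
  if (blk$tgt_strand == "+") blk$tgt_start + (pos - blk$src_start)
  else blk$tgt_end - 1 - (pos - blk$src_start)
}

#' Lift an interval through alignment chains
#'
#' A lift succeeds when exactly one chain covers at least one base of the
#' interval and the covered fraction reaches `min_match`. The lifted span
#' runs from the target image of the first covered base to that of the
#' last covered base (half-open), so insertions or deletions between blocks
#' stretch or shrink the span. Failures are reported as statuses, not
#' errors:
#' \describe{
#'   \item{`unaligned`}{no chain covers any base}
#'   \item{`ambiguous`}{two or more distinct chains each cover >= 1 base}
#'   \item{`below_min_match`}{the single covering chain covers less than
#'     `min_match` of the interval}
#'   \item{`mapped`}{success; target span returned}
#' }
#'
#' @param chains Chain block data frame (see [read_chain_tsv()]).
#' @param chrom,start,end The interval to lift (0-based half-open).
#' @param min_match Minimum covered base fraction in `(0, 1]`.
#' @return A list: `status`, and for mapped lifts `chrom`, `start`, `end`
#'   of the target span plus `covered_frac`.
#' @export
lift_interval <- function(chains, chrom, start, end, min_match = 0.1) {
  stopifnot(min_match > 0, min_match <= 1, start < end)
  sel <- chains$src_chrom == chrom & chains$src_start < end &
    chains$src_end > start
  blocks <- chains[sel, , drop = FALSE]
  if (nrow(blocks) == 0L) return(list(status = "unaligned"))
  ids <- unique(blocks$chain_id)
  if (length(ids) >= 2L) return(list(status = "ambiguous"))
  ov_start <- pmax(blocks$src_start, start)
  ov_end <- pmin(blocks$src_end, end)
  covered <- sum(ov_end - ov_start)
  frac <- covered / (end - start)
  if (frac < min_match) {
    return(list(status = "below_min_match", covered_frac = frac))
  }
  blocks <- blocks[order(blocks$src_start), , drop = FALSE]
  first <- blocks[1L, ]
  last <- blocks[nrow(blocks), ]
  b1 <- max(start, first$src_start)
  b2 <- min(end, last$src_end) - 1
  i1 <- .map_base(b1, first)
  i2 <- .map_base(b2, last)
  list(status = "mapped", chrom = first$tgt_chrom,
       start = min(i1, i2), end = max(i1, i2) + 1, covered_frac = frac)
}

#' Reciprocally map one binding site across genomes
#'
#' Lifts the site forward, then lifts the resulting span back with the
#' reverse chains. The mapping is accepted only if the back lift is itself
#' uniquely mapped and its span overlaps at least
#' `cfg$back_overlap_frac` (default 90%) of the original site; otherwise
#' the status is `failed_reciprocal` (or the forward failure status).
#'
#' @param fwd Source-to-target chain blocks.
#' @param rev Target-to-source chain blocks (e.g. [invert_chains()] of an
#'   independent chain set, or a chain set computed in the other
#'   direction).
#' @param site One-row site data frame.
#' @param cfg An [analysis_config()].
#' @return A list: source site fields, `status` in
#'   `mapped`/`unaligned`/`ambiguous`/`below_min_match`/`failed_reciprocal`,
#'   and for mapped sites `h_chrom`, `h_start`, `h_end`,
#'   `back_overlap_frac`.
#' @export
reciprocal_map <- function(fwd, rev, site, cfg = analysis_config()) {
  stopifnot(nrow(site) == 1L)
  f <- lift_interval(fwd, site$chrom, site$start, site$end, cfg$min_match)
  res <- list(site_id = site$site_id, status = f$status,
              h_chrom = NA_character_, h_start = NA_real_, h_end = NA_real_,
              back_overlap_frac = NA_real_)
  if (f$status != "mapped") return(res)
  b <- lift_interval(rev, f$chrom, f$start, f$end, cfg$min_match)
  if (b$status != "mapped") {
    res$status <- "failed_reciprocal"
    return(res)
  }
  back_ol <- overlap_length(
    data.frame(chrom = b$chrom, start = b$start, end = b$end),
    site[, c("chrom", "start", "end")])
  frac <- back_ol / (site$end - site$start)
  if (frac < cfg$back_overlap_frac) {
    res$status <- "failed_reciprocal"
    res$back_overlap_frac <- frac
    return(res)
  }
  res$status <- "mapped"
  res$h_chrom <- f$chrom
  res$h_start <- f$start
  res$h_end <- f$end
  res$back_overlap_frac <- frac
  res
}

#' Reciprocally map a whole site set
#'
#' Applies [reciprocal_map()] to every site and returns one table of
#' mapped-site records. Mapping is deterministic.
#'
#' @param sites Site data frame.
#' @param fwd,rev Chain block data frames (forward and reverse direction).
#' @param cfg An [analysis_config()].
#' @return The `sites` data frame with added columns `status`, `h_chrom`,
#'   `h_start`, `h_end`, `back_overlap_frac`.
#' @export
map_sites <- function(sites, fwd, rev, cfg = analysis_config()) {
  validate_sites(sites)
  validate_chains(fwd)
  validate_chains(rev)
  n <- nrow(sites)
  status <- character(n)
  h_chrom <- rep(NA_character_, n)
  h_start <- rep(NA_real_, n)
  h_end <- rep(NA_real_, n)
  bof <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- reciprocal_map(fwd, rev, sites[i, , drop = FALSE], cfg)
    status[i] <- r$status
    h_chrom[i] <- r$h_chrom
    h_start[i] <- r$h_start
    h_end[i] <- r$h_end
    bof[i] <- r$back_overlap_frac
  }
  out <- sites
  out$status <- status
  out$h_chrom <- h_chrom
  out$h_start <- h_start
  out$h_end <- h_end
  out$back_overlap_frac <- bof
  out
}

#' Fraction of sites mapped, as a percentage
#'
#' The reporting convention for mapping success: uniquely, reciprocally
#' mapped sites over all detected sites, as a percentage rounded to one
#' decimal.
#'
#' @param n_detected Number of detected (input) sites.
#' @param n_mapped Number of uniquely reciprocally mapped sites.
#' @return Percentage, one decimal.
#' @examples
#' mapped_percentage(3481, 2176)  # 62.5
#' @export
mapped_percentage <- function(n_detected, n_mapped) {
  stopifnot(n_detected > 0, n_mapped >= 0, n_mapped <= n_detected)
  round(100 * n_mapped / n_detected, 1)
}
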