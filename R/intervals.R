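#' Genomic intervals
#'
#' All coordinates in this package are 0-based half-open (BED convention):
#' an interval `[start, end)` covers `end - start` nucleotides, `start` is
#' included and `end` is not. Intervals, binding sites, lifted spans and tag
#' windows all share this convention.
#'
#' @param chrom Chromosome name(s).
#' @param start 0-based inclusive start(s).
#' @param end Exclusive end(s); must satisfy `0 <= start < end`.
#' @return A data frame with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_interval("chr1", 100, 400)
#' @export
genomic_interval <- function(chrom, start, end) {
  iv <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv, what = "interval") {
  stopifnot(is.data.frame(iv),
            all(c("chrom", "start", "end") %in% names(iv)))
  if (nrow(iv) == 0L) return(invisible(iv))
  bad <- which(iv$start < 0 | iv$start >= iv$end)
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: start=%s end=%s (need 0 <= start < end)",
                 what, bad[1L], format(iv$start[bad[1L]], scientific = FALSE),
                 format(iv$end[bad[1L]], scientific = FALSE)))
  }
  invisible(iv)
}

#' Interval width in nucleotides
#' @param iv Interval data frame (`chrom`, `start`, `end`).
#' @return Numeric vector `end - start`.
#' @export
interval_width <- function(iv) iv$end - iv$start

#' Overlap length between two intervals
#'
#' Vectorised over rows; the two data frames are recycled to equal length.
#' Intervals on different chromosomes never overlap, and because intervals
#' are half-open, touching intervals (`a$end == b$start`) do not overlap.
#'
#' @param a,b Interval data frames (`chrom`, `start`, `end`).
#' @return Non-negative integer overlap in nt per row pair.
#' @examples
#' overlap_length(genomic_interval("chr1", 100, 200),
#'                genomic_interval("chr1", 150, 250))  # 50
#' @export
overlap_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (n == 0L) return(numeric(0))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  raw <- pmin(a$end[idx_a], b$end[idx_b]) - pmax(a$start[idx_a], b$start[idx_b])
  ifelse(a$chrom[idx_a] == b$chrom[idx_b], pmax(0, raw), 0)
}

#' Interval midpoint
#'
#' `floor((start + end) / 2)`; odd widths round down, so the midpoint is a
#' genuine base inside the interval.
#'
#' @param iv Interval data frame.
#' @return Numeric vector of midpoints.
#' @examples
#' midpoint(genomic_interval("chr1", 100, 201))  # 150
#' @export
midpoint <- function(iv) floor((iv$start + iv$end) / 2)

# All overlapping row pairs between two interval data frames, with overlap
# lengths. Backed by IRanges::findOverlaps per chromosome (half-open
# coordinates are shifted to 1-based closed internally).
overlap_hits <- function(a, b) {
  empty <- data.frame(a_idx = integer(0), b_idx = integer(0),
                      olap = numeric(0))
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  out <- vector("list", 0L)
  common <- intersect(unique(a$chrom), unique(b$chrom))
  for (ch in common) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    ra <- IRanges::IRanges(start = a$start[ai] + 1L, end = a$end[ai])
    rb <- IRanges::IRanges(start = b$start[bi] + 1L, end = b$end[bi])
    fo <- IRanges::findOverlaps(ra, rb)
    if (length(fo) == 0L) next
    qh <- S4Vectors::queryHits(fo)
    sh <- S4Vectors::subjectHits(fo)
    w <- IRanges::width(IRanges::pintersect(ra[qh], rb[sh]))
    out[[length(out) + 1L]] <-
      data.frame(a_idx = ai[qh], b_idx = bi[sh], olap = as.numeric(w))
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

validate_sites <- function(sites) {
  stopifnot(is.data.frame(sites))
  need <- c("site_id", "chrom", "start", "end", "factor", "species",
            "tag_count")
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    stop("site table lacks column(s): ", paste(miss, collapse = ", "))
  }
  validate_intervals(sites, "site")
  if (anyDuplicated(sites$site_id)) {
    stop("duplicated site_id in site set: ",
         sites$site_id[anyDuplicated(sites$site_id)][1L])
  }
  if (any(sites$tag_count < 0)) stop("tag_count must be >= 0")
  invisible(sites)
}

#' Construct a binding-site table
#'
#' @param chrom,start,end Site coordinates (0-based half-open).
#' @param site_id Unique identifiers; generated when `NULL`.
#' @param tf Factor name, `"CEBPA"` or `"PPARG"` (recycled).
#' @param species `"mouse"` or `"human"` (recycled).
#' @param tag_count Non-negative ChIP tag counts per site (recycled;
#'   default 0).
#' @return A site data frame with columns `site_id`, `chrom`, `start`,
#'   `end`, `factor`, `species`, `tag_count`.
#' @export
binding_sites <- function(chrom, start, end, site_id = NULL, tf = "CEBPA",
                          species = "mouse", tag_count = 0L) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (is.null(site_id)) {
    site_id <- if (n) paste0(rep_len(tf, n), "_", rep_len(species, n), "_",
                             seq_len(n)) else character(0)
  }
  sites <- data.frame(site_id = as.character(site_id),
                      chrom = as.character(chrom),
                      start = as.numeric(start),
                      end = as.numeric(end),
                      factor = rep_len(as.character(tf), n),
                      species = rep_len(as.character(species), n),
                      tag_count = rep_len(as.numeric(tag_count), n),
                      stringsAsFactors = FALSE)
  validate_sites(sites)
  sites
}
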