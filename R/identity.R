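#' Sequence identity of a pairwise alignment
#'
#' The identity score of two gapped, equal-length alignment rows:
#' number of columns with identical non-gap characters
#' (case-insensitive), divided by the *shorter* ungapped sequence length —
#' `#identity / min(length1, length2)`. Gap characters are `-` and `.`.
#'
#' @param aln1,aln2 Gapped sequences of equal aligned length.
#' @return Identity fraction in `[0, 1]` (it can exceed the matching
#'   fraction of the longer sequence by construction of the denominator).
#' @examples
#' identity_score("ACGT", "ACGA")        # 0.75
#' identity_score("ACGT--AC", "ACGTGGAC")  # 1.0
#' @export
identity_score <- function(aln1, aln2) {
  if (nchar(aln1) != nchar(aln2)) {
    stop("alignment rows must have equal length")
  }
  a <- strsplit(toupper(aln1), "")[[1L]]
  b <- strsplit(toupper(aln2), "")[[1L]]
  gap <- c("-", ".")
  len1 <- sum(!a %in% gap)
  len2 <- sum(!b %in% gap)
  if (len1 == 0L || len2 == 0L) stop("degenerate alignment: empty sequence")
  ident <- sum(a == b & !a %in% gap)
  ident / min(len1, len2)
}

#' Read pairwise alignments from a 2-row-per-pair aligned FASTA
#'
#' Consecutive record pairs are alignment rows; the pair id is the first
#' record's id up to an optional `|` suffix.
#'
#' @param path FASTA path.
#' @return Data frame `pair_id`, `seq1`, `seq2`.
#' @export
read_aligned_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) %% 2L != 0L) {
    stop(path, ": odd number of records; expected 2-row pairs")
  }
  i1 <- seq(1L, length(recs), by = 2L)
  ids <- sub("\\|.*$", "", sub("\\s.*$", "", names(recs)[i1]))
  out <- data.frame(pair_id = ids,
                    seq1 = as.character(recs[i1]),
                    seq2 = as.character(recs[i1 + 1L]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read pairwise alignment blocks from a MAF file
#'
#' Minimal MAF reader for pairwise blocks: each `a` line starts a block
#' whose first two `s` lines are taken as the aligned pair. The pair id is
#' the first `s` record's source name (sequence up to the first `.`
#' stripped of coordinates).
#'
#' @param path MAF path.
#' @return Data frame `pair_id`, `seq1`, `seq2`.
#' @export
read_maf_pairs <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- character(0)
  cur_id <- NA_character_
  flush <- function() {
    if (length(cur) >= 2L) {
      out[[length(out) + 1L]] <<- data.frame(
        pair_id = cur_id, seq1 = cur[1L], seq2 = cur[2L],
        stringsAsFactors = FALSE)
    }
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      flush()
      cur <- character(0)
      cur_id <- NA_character_
    } else if (startsWith(ln, "s")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1L]]
      if (length(f) < 7L) stop(path, ": malformed s line: ", ln)
      if (is.na(cur_id)) cur_id <- f[2L]
      cur <- c(cur, f[7L])
    }
  }
  flush()
  if (!length(out)) {
    return(data.frame(pair_id = character(0), seq1 = character(0),
                      seq2 = character(0)))
  }
  do.call(rbind, out)
}

#' Write pairwise alignments as 2-row aligned FASTA
#'
#' @param pairs Data frame `pair_id`, `seq1`, `seq2`.
#' @param path Output path.
#' @param labels Length-2 suffixes appended to the pair id per row
#'   (default `c("mouse", "human")`).
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(pairs, path,
                                labels = c("mouse", "human")) {
  lines <- character(0)
  if (nrow(pairs)) {
    lines <- as.vector(rbind(paste0(">", pairs$pair_id, "|", labels[1L]),
                             pairs$seq1,
                             paste0(">", pairs$pair_id, "|", labels[2L]),
                             pairs$seq2))
  }
  writeLines(lines, path)
  invisible(path)
}
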