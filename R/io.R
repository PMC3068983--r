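#' Read binding sites from a BED file
#'
#' Accepts 3-5 column BED: `chrom start end [name] [tag_count]`. Track,
#' browser and `#` comment lines are skipped. A missing name column yields
#' generated site ids; a missing fifth column yields `tag_count = 0`.
#' Coordinates are kept 0-based half-open as in the file.
#'
#' @param path BED file path.
#' @param tf Factor label attached to every site (`"CEBPA"`/`"PPARG"`).
#' @param species Species label (`"mouse"`/`"human"`).
#' @return A site data frame (see [binding_sites()]).
#' @export
read_sites <- function(path, tf, species) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) &
    !grepl("^(track|browser|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(binding_sites(character(0), numeric(0), numeric(0), tf = tf,
                         species = species))
  }
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("%s line %d: fewer than 3 BED columns", path,
                 lineno[which(nf < 3L)[1L]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("%s line %d: malformed coordinates '%s'", path,
                 lineno[bad[1L]], lines[bad[1L]]))
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
  if (anyNA(name)) {
    auto <- paste0(tf, "_", species, "_", seq_along(chrom))
    name[is.na(name)] <- auto[is.na(name)]
  }
  tags <- rep(0, length(chrom))
  has5 <- nf >= 5L
  if (any(has5)) {
    v <- suppressWarnings(as.numeric(vapply(fields, function(f)
      if (length(f) >= 5L) f[[5L]] else "0", "")))
    badt <- which(has5 & (is.na(v) | v < 0))
    if (length(badt)) {
      stop(sprintf("%s line %d: malformed tag count", path, lineno[badt[1L]]))
    }
    tags[has5] <- v[has5]
  }
  binding_sites(chrom, start, end, site_id = name, tf = tf,
                species = species, tag_count = tags)
}

#' Write binding sites as 5-column BED
#'
#' @param sites Site data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  validate_sites(sites)
  lines <- sprintf("%s\t%s\t%s\t%s\t%s", sites$chrom,
                   format(sites$start, scientific = FALSE, trim = TRUE),
                   format(sites$end, scientific = FALSE, trim = TRUE),
                   sites$site_id,
                   format(sites$tag_count, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Build a tag track from positions
#'
#' A tag track stores one genomic position per mapped ChIP tag (its 5'
#' position), per chromosome, sorted. No fragment extension or strand
#' shifting is applied.
#'
#' @param chrom Chromosome per tag.
#' @param pos 0-based position per tag.
#' @return Named list of sorted numeric position vectors, class
#'   `"tag_track"`.
#' @export
tag_track <- function(chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  tr <- lapply(split(as.numeric(pos), as.character(chrom)), sort)
  structure(tr, class = "tag_track")
}

#' Read a tag track from a BED file of tag positions
#'
#' Each data line contributes one tag at its start coordinate.
#'
#' @param path BED path.
#' @return A `"tag_track"` object.
#' @export
read_tag_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines)) return(structure(list(), class = "tag_track"))
  fields <- strsplit(lines, "[\t ]+")
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(pos)) stop(path, ": malformed tag position")
  tag_track(chrom, pos)
}

#' Write a tag track as BED (1-nt intervals)
#' @param track A `"tag_track"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_track <- function(track, path) {
  chunks <- lapply(names(track), function(ch) {
    p <- format(track[[ch]], scientific = FALSE, trim = TRUE)
    sprintf("%s\t%s\t%s", ch, p,
            format(track[[ch]] + 1, scientific = FALSE, trim = TRUE))
  })
  writeLines(unlist(chunks, use.names = FALSE), path)
  invisible(path)
}

#' Read a gene/TSS table
#'
#' Tab-separated with header `gene_id chrom tss strand cluster`; `cluster`
#' is `1`-`4` for differentially expressed genes or `none` for constitutive
#' genes.
#'
#' @param path TSV path.
#' @return Data frame of gene records.
#' @export
read_genes <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric",
                                        "character", "character"))
  need <- c("gene_id", "chrom", "tss", "strand", "cluster")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop(path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(g$cluster), c("1", "2", "3", "4", "none"))
  if (length(bad)) stop(path, ": unknown cluster label '", bad[1L], "'")
  if (!all(g$strand %in% c("+", "-"))) stop(path, ": strand must be + or -")
  g
}

#' Write a gene/TSS table
#' @param genes Gene data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  write_tsv(genes[, c("gene_id", "chrom", "tss", "strand", "cluster")], path)
  invisible(path)
}

#' Read a chromosome-length table
#'
#' Tab-separated `chrom length`, with header.
#'
#' @param path TSV path.
#' @return Data frame with columns `chrom`, `length`.
#' @export
read_genome <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length") %in% names(g)))
  g$chrom <- as.character(g$chrom)
  g$length <- as.numeric(g$length)
  g
}

#' Write a chromosome-length table
#' @param genome Data frame `chrom`, `length`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  write_tsv(genome[, c("chrom", "length")], path)
  invisible(path)
}

# Deterministic TSV writer: plain decimal numbers, "\n" line endings.
write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]])) {
      df2[[j]] <- format(df2[[j]], scientific = FALSE, trim = TRUE,
                         drop0trailing = TRUE)
    }
  }
  lines <- c(paste(names(df2), collapse = "\t"),
             if (nrow(df2)) do.call(paste,
                                    c(unname(as.list(df2)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

validate_chains <- function(chains) {
  need <- c("chain_id", "src_chrom", "src_start", "src_end", "tgt_chrom",
            "tgt_start", "tgt_end", "tgt_strand")
  miss <- setdiff(need, names(chains))
  if (length(miss)) stop("chain table lacks column(s): ",
                         paste(miss, collapse = ", "))
  w_src <- chains$src_end - chains$src_start
  w_tgt <- chains$tgt_end - chains$tgt_start
  if (any(w_src != w_tgt)) stop("chain block with unequal src/tgt widths")
  if (any(w_src <= 0)) stop("chain block with non-positive width")
  if (!all(chains$tgt_strand %in% c("+", "-"))) {
    stop("tgt_strand must be '+' or '-'")
  }
  invisible(chains)
}

#' Read alignment chains from a block TSV
#'
#' Simplified chain representation: one aligned block per line, columns
#' `src_chrom src_start src_end tgt_chrom tgt_start tgt_end chain_id`
#' and optional `tgt_strand` (default `+`), with header. Blocks of a chain
#' must be equal-width in both coordinate systems; target coordinates are
#' always forward-strand.
#'
#' @param path TSV path.
#' @return Chain block data frame.
#' @export
read_chain_tsv <- function(path) {
  ch <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"tgt_strand" %in% names(ch)) ch$tgt_strand <- "+"
  ch$chain_id <- as.character(ch$chain_id)
  validate_chains(ch)
  ch
}

#' Write alignment chains as a block TSV
#' @param chains Chain block data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_tsv <- function(chains, path) {
  validate_chains(chains)
  write_tsv(chains[, c("src_chrom", "src_start", "src_end", "tgt_chrom",
                       "tgt_start", "tgt_end", "chain_id", "tgt_strand")],
            path)
  invisible(path)
}

#' Read a UCSC chain file
#'
#' Parses the standard UCSC chain format (`chain score tName tSize tStrand
#' tStart tEnd qName qSize qStrand qStart qEnd id` headers followed by
#' `size dt dq` block lines). The `t` (target-genome-of-the-file) side is
#' the lift *source* and the `q` side the lift *destination*, matching how
#' liftover chain files are named and used. Negative-strand `q` coordinates
#' are converted to forward-strand coordinates; the per-base orientation is
#' kept in `tgt_strand`.
#'
#' @param path Chain file path.
#' @return Chain block data frame as in [read_chain_tsv()].
#' @export
read_chain_file <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) { i <- i + 1L; next }
    hdr <- strsplit(ln, "[ \t]+")[[1L]]
    if (hdr[1L] != "chain" || length(hdr) < 12L) {
      stop(path, ": expected chain header at line ", i)
    }
    src_chrom <- hdr[3L]
    src_strand <- hdr[5L]
    if (src_strand != "+") stop(path, ": source strand must be '+'")
    t_cur <- as.numeric(hdr[6L])
    tgt_chrom <- hdr[8L]
    q_size <- as.numeric(hdr[9L])
    q_strand <- hdr[10L]
    q_cur <- as.numeric(hdr[11L])
    chain_id <- if (length(hdr) >= 13L) hdr[13L] else paste0("chain", i)
    i <- i + 1L
    repeat {
      if (i > n) stop(path, ": truncated chain block list")
      bl <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
      if (length(bl) == 0L || bl[1L] == "") { i <- i + 1L; break }
      size <- as.numeric(bl[1L])
      if (q_strand == "+") {
        tgt_start <- q_cur
        tgt_end <- q_cur + size
      } else {
        # reverse-strand query coordinates -> forward coordinates
        tgt_start <- q_size - (q_cur + size)
        tgt_end <- q_size - q_cur
      }
      out[[length(out) + 1L]] <- data.frame(
        chain_id = chain_id, src_chrom = src_chrom, src_start = t_cur,
        src_end = t_cur + size, tgt_chrom = tgt_chrom,
        tgt_start = tgt_start, tgt_end = tgt_end,
        tgt_strand = if (q_strand == "+") "+" else "-",
        stringsAsFactors = FALSE)
      if (length(bl) >= 3L) {
        t_cur <- t_cur + size + as.numeric(bl[2L])
        q_cur <- q_cur + size + as.numeric(bl[3L])
        i <- i + 1L
      } else {
        i <- i + 1L
        # last block of this chain; skip trailing blank line if present
        if (i <= n && trimws(lines[i]) == "") i <- i + 1L
        break
      }
    }
  }
  if (!length(out)) stop(path, ": no chains found")
  ch <- do.call(rbind, out)
  validate_chains(ch)
  ch
}
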