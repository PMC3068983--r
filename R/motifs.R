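#' Read a position frequency matrix in JASPAR PFM format
#'
#' Accepts the common JASPAR text layouts: a `>id name` header followed by
#' either four bracketed rows (`A [ 4 19 0 ... ]`) or four bare
#' whitespace-separated count rows in A, C, G, T order.
#'
#' @param path PFM file path.
#' @return A list with `model_id`, `name` and `counts` (4 x L numeric
#'   matrix, rows A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  model_id <- "PFM"
  name <- ""
  if (startsWith(lines[1L], ">")) {
    hdr <- strsplit(sub("^>", "", lines[1L]), "[ \t]+")[[1L]]
    model_id <- hdr[1L]
    if (length(hdr) > 1L) name <- paste(hdr[-1L], collapse = " ")
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stop(path, ": expected 4 count rows")
  rows <- lapply(lines[1:4], function(ln) {
    ln <- sub("^[ACGTacgt]\\s*", "", ln)
    ln <- gsub("\\[|\\]", " ", ln)
    as.numeric(strsplit(trimws(ln), "[ \t]+")[[1L]])
  })
  L <- unique(lengths(rows))
  if (length(L) != 1L) stop(path, ": count rows of unequal length")
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  list(model_id = model_id, name = name, counts = counts)
}

#' Build a log-odds PWM model from a count matrix
#'
#' Column counts are turned into frequencies with a Laplace pseudo-count
#' toward the uniform background (`(count + 0.25) / (colsum + 1)`), then
#' into log2 odds against that uniform background. The consensus-site
#' threshold is `min_score + frac * (max_score - min_score)` with
#' `frac = cfg$pwm_threshold_frac` (default 0.80 of the scoring range).
#'
#' @param counts 4 x L non-negative matrix (rows A, C, G, T), no zero
#'   columns.
#' @param cfg An [analysis_config()].
#' @param model_id Identifier carried along (default `"PWM"`).
#' @return A list of class `"pwm_model"`: `model_id`, `counts`, `logodds`,
#'   `length`, `min_score`, `max_score`, `threshold`.
#' @export
build_pwm <- function(counts, cfg = analysis_config(), model_id = "PWM") {
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (any(counts < 0)) stop("negative counts in PFM")
  cs <- colSums(counts)
  if (any(cs == 0)) stop("zero-sum column in PFM")
  freq <- sweep(counts + 0.25, 2, cs + 1, "/")
  lo <- log2(freq / 0.25)
  rownames(lo) <- c("A", "C", "G", "T")
  min_score <- sum(apply(lo, 2, min))
  max_score <- sum(apply(lo, 2, max))
  structure(list(model_id = model_id, counts = counts, logodds = lo,
                 length = ncol(lo), min_score = min_score,
                 max_score = max_score,
                 threshold = min_score +
                   cfg$pwm_threshold_frac * (max_score - min_score)),
            class = "pwm_model")
}

#' Highest-scoring word of a PWM
#' @param pwm A `"pwm_model"`.
#' @return Character consensus string (argmax base per column).
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$logodds)[apply(pwm$logodds, 2, which.max)],
        collapse = "")
}

# DNA string -> integer codes A=1 C=2 G=3 T=4, NA otherwise.
.dna_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1L]], c("A", "C", "G", "T"))
}

# Scores of all windows of `codes`; windows with non-ACGT bases -> -Inf.
.score_windows <- function(codes, lo) {
  L <- ncol(lo)
  W <- length(codes) - L + 1L
  if (W < 1L) return(numeric(0))
  sc <- numeric(W)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + W - 1L)]
    sc <- sc + lo[cbind(cj, j)]
  }
  sc[is.na(sc)] <- -Inf
  sc
}

#' Scan a sequence for a consensus site
#'
#' Slides the PWM over every window of the sequence on both the forward
#' and the reverse-complement strand; the consensus flag is set when any
#' window scores at or above the model threshold. Windows containing
#' non-ACGT characters are skipped. Sequences shorter than the model give
#' `flag = FALSE` with a warning.
#'
#' @param seq DNA string.
#' @param pwm A `"pwm_model"` from [build_pwm()].
#' @return A list: `flag`, `score` (best window score), `position`
#'   (1-based start of the best window on the forward sequence) and
#'   `strand` (`"+"`/`"-"`).
#' @export
has_consensus <- function(seq, pwm) {
  n <- nchar(seq)
  if (n < pwm$length) {
    warning("sequence shorter than PWM (", n, " < ", pwm$length, " nt)")
    return(list(flag = FALSE, score = -Inf, position = NA_integer_,
                strand = NA_character_))
  }
  codes <- .dna_codes(seq)
  fwd <- .score_windows(codes, pwm$logodds)
  rc <- rev(5L - codes)  # complement then reverse; NA stays NA
  rev_sc <- .score_windows(rc, pwm$logodds)
  bf <- which.max(fwd)
  br <- which.max(rev_sc)
  if (fwd[bf] >= rev_sc[br]) {
    best <- fwd[bf]; pos <- bf; strand <- "+"
  } else {
    best <- rev_sc[br]
    pos <- n - (br + pwm$length - 1L) + 1L  # map back to forward coords
    strand <- "-"
  }
  list(flag = is.finite(best) && best >= pwm$threshold, score = best,
       position = as.integer(pos), strand = strand)
}

#' Bundled synthetic PWMs
#'
#' Loads the two position weight matrices shipped with the package. These
#' are *synthetic*, consensus-shaped stand-ins (a DR1-type direct repeat
#' for PPARG, a palindrome-like C/EBP element for CEBPA) built for testing
#' and simulation — they are not database matrices. Any JASPAR-format PFM
#' can be substituted via [read_jaspar_pfm()] + [build_pwm()].
#'
#' @param cfg An [analysis_config()] (sets the threshold fraction).
#' @return Named list of `"pwm_model"` objects: `CEBPA`, `PPARG`.
#' @export
default_pwms <- function(cfg = analysis_config()) {
  load1 <- function(file) {
    p <- read_jaspar_pfm(system.file("extdata", file, package = "tfretain",
                                     mustWork = TRUE))
    build_pwm(p$counts, cfg, model_id = p$model_id)
  }
  list(CEBPA = load1("synthetic_CEBPA.pfm"),
       PPARG = load1("synthetic_PPARG.pfm"))
}

#' Threshold-sweep diagnostic for consensus scanning
#'
#' For each threshold fraction, reports the fraction of bound-region and of
#' random-region sequences carrying a consensus hit and their difference —
#' the separation diagnostic used to justify a threshold choice. The
#' selection itself is left to the analyst.
#'
#' @param bound_seqs,random_seqs Character vectors of DNA sequences.
#' @param counts 4 x L PFM count matrix.
#' @param fracs Threshold fractions to sweep.
#' @param cfg An [analysis_config()].
#' @return Data frame `threshold_frac`, `hit_frac_bound`,
#'   `hit_frac_random`, `separation`.
#' @export
threshold_sweep <- function(bound_seqs, random_seqs, counts,
                            fracs = seq(0.6, 0.95, by = 0.05),
                            cfg = analysis_config()) {
  do.call(rbind, lapply(fracs, function(f) {
    cfg2 <- cfg
    cfg2$pwm_threshold_frac <- f
    pwm <- build_pwm(counts, cfg2)
    hb <- mean(vapply(bound_seqs,
                      function(s) has_consensus(s, pwm)$flag, logical(1)))
    hr <- mean(vapply(random_seqs,
                      function(s) has_consensus(s, pwm)$flag, logical(1)))
    data.frame(threshold_frac = f, hit_frac_bound = hb,
               hit_frac_random = hr, separation = hb - hr)
  }))
}
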