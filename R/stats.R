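#' Two-sided Fisher exact test for a 2x2 table
#'
#' Probability-ordering two-sided p: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (within a small relative
#' tolerance). A table with a zero margin carries no information; it
#' returns `p = 1` with a warning.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in 2x2 table; p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midranks for ties. For small samples
#' (`length(x) + length(y) <= 12`) the two-sided p is exact, by
#' enumeration of all rank assignments (ties handled through midranks);
#' for larger samples the normal approximation with tie-corrected variance
#' and continuity correction is used. Degenerate inputs (zero rank-sum
#' variance, e.g. all values equal) return `p = 1`.
#'
#' @param x,y Non-empty numeric samples.
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))
  if (stats::var(r) == 0) return(1)
  W <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (n <= 12L) {
    combs <- utils::combn(n, nx)
    Ws <- colSums(matrix(r[combs], nrow = nx))
    return(mean(abs(Ws - mu) >= abs(W - mu) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- W - mu
  z <- z - sign(z) * 0.5  # continuity correction
  p <- 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
  min(1, p)
}

#' Retention cross-tabulation with a Fisher contrast
#'
#' Counts retained / lost / turnover fates per group and attaches the
#' two-sided Fisher exact p for the 2x2 contrast
#' `[retained, not retained] x [groups A, groups B]`. Outputs are invariant
#' under permutation of the input rows.
#'
#' @param fates Fate table ([classify_fates()] rows with non-`NA` `fate`,
#'   or any data frame with a `fate` column).
#' @param groups Group label per row of `fates`.
#' @param comparison List with elements `a` and `b`: the group labels
#'   forming the two sides of the contrast. `NULL` skips the test.
#' @return A list of class `"crosstab_result"`: `table` (per-group counts
#'   `n`, `retained`, `lost`, `turnover` and fractions), `contingency`
#'   (the 2x2 matrix) and `fisher_p`.
#' @export
crosstab_retention <- function(fates, groups, comparison = NULL) {
  stopifnot("fate" %in% names(fates), length(groups) == nrow(fates))
  if (any(is.na(fates$fate))) stop("fates contain NA; keep mapped sites only")
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  cnt <- function(g, f) sum(groups == g & fates$fate == f)
  tab <- data.frame(
    group = lv,
    n = vapply(lv, function(g) sum(groups == g), numeric(1)),
    retained = vapply(lv, cnt, numeric(1), f = "retained"),
    lost = vapply(lv, cnt, numeric(1), f = "lost"),
    turnover = vapply(lv, cnt, numeric(1), f = "turnover"),
    stringsAsFactors = FALSE)
  tab$frac_retained <- ifelse(tab$n > 0, tab$retained / tab$n, NA_real_)
  tab$frac_turnover <- ifelse(tab$n > 0, tab$turnover / tab$n, NA_real_)
  rownames(tab) <- NULL
  res <- list(table = tab, contingency = NULL, fisher_p = NA_real_)
  if (!is.null(comparison)) {
    ina <- groups %in% comparison$a
    inb <- groups %in% comparison$b
    if (!any(ina) || !any(inb)) stop("empty comparison group")
    ret <- fates$fate == "retained"
    m <- matrix(c(sum(ina & ret), sum(ina & !ret),
                  sum(inb & ret), sum(inb & !ret)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("retained", "not_retained")))
    res$contingency <- m
    res$fisher_p <- if (any(rowSums(m) == 0) || any(colSums(m) == 0)) 1 else
      fisher_exact_2x2(m)
  }
  class(res) <- "crosstab_result"
  res
}

#' Violin-style summaries per group
#'
#' Median and 25th/75th percentiles (linear interpolation between order
#' statistics) and group size per group — the numeric content of a violin
#' or box plot — with an optional Wilcoxon rank-sum contrast between two
#' group sets.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @param contrast Optional list with `a` and `b` group-label sets; the
#'   two-sided [wilcoxon_rank_sum()] p of `values[a]` vs `values[b]` is
#'   attached.
#' @return Data frame `group`, `n`, `q25`, `median`, `q75`; when a
#'   contrast is given, attribute `wilcoxon_p` holds the p-value.
#' @export
violin_summary <- function(values, groups, contrast = NULL) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  out <- do.call(rbind, lapply(lv, function(g) {
    v <- values[groups == g]
    if (!length(v)) stop("empty group: ", g)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), q25 = q[1L], median = q[2L],
               q75 = q[3L], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(contrast)) {
    attr(out, "wilcoxon_p") <- wilcoxon_rank_sum(
      values[groups %in% contrast$a], values[groups %in% contrast$b])
  }
  out
}
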