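mapped_row <- function(chrom, start, end, tf = "CEBPA", id = "m1",
                       h_chrom = chrom, h_start = start, h_end = end) {
  s <- binding_sites(chrom, start, end, id, tf, "mouse")
  s$status <- "mapped"
  s$h_chrom <- h_chrom
  s$h_start <- h_start
  s$h_end <- h_end
  s$back_overlap_frac <- 1
  s
}

test_that("binary retention uses a strict >10% either-way overlap", {
  cfg <- analysis_config()
  m <- mapped_row("chr1", 1000, 1200)
  # 50 nt = 25% of the 200-nt span
  h1 <- binding_sites("chr1", 1150, 1500, "h1", "CEBPA", "human")
  expect_true(binary_retention(m, h1, cfg)$retained)
  # 15 nt = 7.5% of the span but 15% of the 100-nt human site: "vice versa"
  h2 <- binding_sites("chr1", 1185, 1285, "h2", "CEBPA", "human")
  expect_true(binary_retention(m, h2, cfg)$retained)
  # exactly 10.0% of both widths: NOT retained (strict >)
  h3 <- binding_sites("chr1", 1180, 1380, "h3", "CEBPA", "human")
  expect_false(binary_retention(m, h3, cfg)$retained)
  # unmapped input is a caller error
  bad <- m
  bad$status <- "unaligned"
  expect_error(binary_retention(bad, h1, cfg), "mapped")
})

test_that("binary retention matches the all-pairs oracle", {
  set.seed(29)
  cfg <- analysis_config()
  for (rep in 1:10) {
    n <- sample(20:150, 1)
    spans <- random_sites_df(n, "CEBPA", "mouse")
    m <- spans
    m$status <- "mapped"
    m$h_chrom <- spans$chrom
    m$h_start <- spans$start
    m$h_end <- spans$end
    hum <- random_sites_df(sample(20:150, 1), "CEBPA", "human")
    got <- binary_retention(m, hum, cfg)$retained
    expect_identical(got, oracle_retention(
      data.frame(chrom = m$h_chrom, start = m$h_start, end = m$h_end),
      hum, cfg$retention_frac))
  }
})

test_that("turnover distance is midpoint-to-midpoint, inclusive at 10 kb", {
  cfg <- analysis_config()
  m <- mapped_row("chr1", 49900, 50100)  # lifted midpoint 50,000
  hs <- function(mid) binding_sites("chr1", mid - 100, mid + 100, "h",
                                    "CEBPA", "human")
  expect_true(detect_turnover(m, hs(58000), cfg))
  expect_false(detect_turnover(m, hs(61000), cfg))
  expect_true(detect_turnover(m, hs(60000), cfg))   # exactly 10 kb
  expect_false(detect_turnover(m, binding_sites("chr2", 49900, 50100, "h",
                                                "CEBPA", "human"), cfg))
})

test_that("human-specific sites fail the 10% overlap against all lifts", {
  cfg <- analysis_config()
  m <- mapped_row("chr1", 1000, 1200)
  hum <- binding_sites("chr1", c(1100, 5000), c(1300, 5200),
                       c("h1", "h2"), "CEBPA", "human")
  expect_identical(human_specific_sites(hum, m, cfg), c(FALSE, TRUE))
})

test_that("fates partition mapped sites and respect retained_as", {
  cfg <- analysis_config()
  m <- rbind(mapped_row("chr1", 1000, 1200, id = "a"),
             mapped_row("chr1", 50000, 50200, id = "b"),
             mapped_row("chr1", 200000, 200200, id = "c"))
  m$status[3] <- "unaligned"
  hum <- rbind(
    binding_sites("chr1", 1100, 1400, "h1", "PPARG", "human"),  # retains a
    binding_sites("chr1", 56000, 56200, "h2", "CEBPA", "human")) # near b
  f <- classify_fates(m, hum, cfg)
  expect_equal(f$fate, c("retained", "turnover", NA))
  expect_equal(f$retained_as, c("PPARG", "", ""))
  mapped <- f[f$status == "mapped", ]
  expect_setequal(mapped$fate, c("retained", "turnover"))
  expect_true(all((f$retained_as != "") == (!is.na(f$fate) &
                                            f$fate == "retained")))
})

test_that("window width is the 75th percentile of site widths, rounded", {
  s <- binding_sites("chr1", c(0, 1000, 2000, 3000) ,
                     c(100, 1200, 2300, 3400))
  expect_equal(window_width_75th(s), 325)
  const <- binding_sites("chr1", (0:4) * 1000, (0:4) * 1000 + 300)
  expect_equal(window_width_75th(const), 300)
  expect_error(window_width_75th(const[0, ]), "non-empty")
})

test_that("tag windows are half-open with the odd base on the right", {
  tr <- tag_track(rep("chr1", 3), c(10, 50, 90))
  expect_equal(count_tags_in_window(tr, "chr1", 50, 80), 2)  # [10, 90)
  expect_equal(count_tags_in_window(tr, "chr1", 50, 81), 3)  # [10, 91)
  expect_equal(count_tags_in_window(tr, "chr2", 50, 80), 0)
  expect_equal(count_tags_in_window(structure(list(), class = "tag_track"),
                                    "chr1", 50, 80), 0)
})

test_that("enrichment log2fc follows the pseudo-counted ratio", {
  cfg <- analysis_config()
  m <- mapped_row("chr1", 460, 540)  # span midpoint 500
  tr <- tag_track(rep("chr1", 31), seq(480, 520, length.out = 31))
  expect_equal(enrichment_log2fc(m, tr, data.frame(chrom = "chr1",
                                                   length = 10000),
                                 width = 100, cfg, expected = 3), 3)
  empty <- structure(list(), class = "tag_track")
  expect_equal(enrichment_log2fc(m, empty, data.frame(chrom = "chr1",
                                                      length = 10000),
                                 width = 100, cfg, expected = 1), -1)
})

test_that("adding tags inside the window never decreases log2fc", {
  cfg <- analysis_config()
  m <- mapped_row("chr1", 1000, 1300)
  genome <- data.frame(chrom = "chr1", length = 50000)
  prev <- -Inf
  for (k in c(0, 1, 5, 20, 60)) {
    tr <- tag_track(rep("chr1", k + 1), c(1, rep(1150, k)))
    v <- enrichment_log2fc(m, tr, genome, 300, cfg, expected = 2.5)
    expect_gte(v, prev)
    prev <- v
  }
})

test_that("random windows always fit their chromosome", {
  set.seed(31)
  genome <- data.frame(chrom = c("chrA", "chrB"), length = c(2000, 5000))
  w <- sample_random_windows(genome, 900, 500)
  lo <- w$center - floor(900 / 2)
  len <- genome$length[match(w$chrom, genome$chrom)]
  expect_true(all(lo >= 0 & lo + 900 <= len))
  expect_error(sample_random_windows(data.frame(chrom = "c", length = 10),
                                     900, 5), "exceeds")
})

test_that("quartile bins are near-equal, larger first, stable under ties", {
  expect_equal(quartile_bins(1:8), rep(1:4, each = 2))
  expect_equal(quartile_bins(8:1), rep(4:1, each = 2))
  expect_equal(table(quartile_bins(1:6)), table(rep(c(1, 2, 3, 4),
                                                    c(2, 2, 1, 1))),
               ignore_attr = TRUE)
  expect_equal(quartile_bins(rep(5, 6)), c(1, 1, 2, 2, 3, 4))
  expect_error(quartile_bins(1:3), "at least")
})
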