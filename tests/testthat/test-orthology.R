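two_block_chain <- function() {
  data.frame(chain_id = "c1",
             src_chrom = "chr1", src_start = c(0, 150), src_end = c(100, 250),
             tgt_chrom = "chr1", tgt_start = c(0, 300), tgt_end = c(100, 400),
             tgt_strand = "+", stringsAsFactors = FALSE)
}

test_that("lift_interval maps through identity chains unchanged", {
  ch <- identity_chains()
  lf <- lift_interval(ch, "chr1", 100, 400)
  expect_equal(lf[c("status", "chrom", "start", "end")],
               list(status = "mapped", chrom = "chr1", start = 100,
                    end = 400))
  expect_equal(lf$covered_frac, 1)
})

test_that("lift_interval spans first-to-last covered base across blocks", {
  lf <- lift_interval(two_block_chain(), "chr1", 50, 200, 0.1)
  # covered 100 of 150 bases; base 50 -> 50, base 199 -> 349
  expect_equal(lf$status, "mapped")
  expect_equal(c(lf$start, lf$end), c(50, 350))
  expect_equal(lf$covered_frac, 100 / 150)
})

test_that("lift failures are statuses: unaligned, ambiguous, below_min_match", {
  ch <- two_block_chain()
  expect_equal(lift_interval(ch, "chr1", 105, 145)$status, "unaligned")
  expect_equal(lift_interval(ch, "chr9", 0, 50)$status, "unaligned")

  dup <- ch
  dup$chain_id <- "c2"
  dup$tgt_start <- dup$tgt_start + 5000
  dup$tgt_end <- dup$tgt_end + 5000
  expect_equal(lift_interval(rbind(ch, dup), "chr1", 50, 200)$status,
               "ambiguous")

  # only 5 of 100 bases covered: below the 0.1 minimum match
  one_block <- ch[1, , drop = FALSE]
  lf <- lift_interval(one_block, "chr1", 95, 195, 0.1)
  expect_equal(lf$status, "below_min_match")
  expect_equal(lf$covered_frac, 0.05)
})

test_that("reverse-strand blocks map with reversed per-base orientation", {
  ch <- data.frame(chain_id = "m", src_chrom = "chr1", src_start = 0,
                   src_end = 100, tgt_chrom = "chrQ", tgt_start = 0,
                   tgt_end = 100, tgt_strand = "-", stringsAsFactors = FALSE)
  lf <- lift_interval(ch, "chr1", 10, 20)
  # base 10 -> 89, base 19 -> 80: span [80, 90)
  expect_equal(c(lf$start, lf$end), c(80, 90))
})

test_that("UCSC chain format parses blocks and strands correctly", {
  f <- withr::local_tempfile(fileext = ".chain")
  writeLines(c("chain 1000 chrS 1000 + 100 200 chrQ 500 + 20 120 1",
               "60\t10\t10",
               "30",
               "",
               "chain 900 chrS 1000 + 300 360 chrQ 500 - 50 110 2",
               "60"), f)
  ch <- read_chain_file(f)
  expect_equal(nrow(ch), 3L)
  b <- ch[ch$chain_id == "1", ]
  expect_equal(b$src_start, c(100, 170))
  expect_equal(b$src_end, c(160, 200))
  expect_equal(b$tgt_start, c(20, 90))
  expect_equal(b$tgt_end, c(80, 120))
  # negative strand: q [50,110) on reverse strand = forward [390, 450)
  m <- ch[ch$chain_id == "2", ]
  expect_equal(c(m$tgt_start, m$tgt_end), c(390, 450))
  expect_equal(m$tgt_strand, "-")
  # per-base orientation: src base 300 maps to forward base 449
  lf <- lift_interval(m, "chrS", 300, 301)
  expect_equal(c(lf$start, lf$end), c(449, 450))
})

test_that("chain TSV round-trips and invert_chains is an involution", {
  ch <- two_block_chain()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_chain_tsv(ch, f)
  ch2 <- read_chain_tsv(f)
  expect_equal(ch2[order(ch2$src_start), ]$src_start, ch$src_start)
  inv2 <- invert_chains(invert_chains(ch))
  expect_equal(inv2[order(inv2$src_start),
                    c("src_start", "src_end", "tgt_start", "tgt_end")],
               ch[, c("src_start", "src_end", "tgt_start", "tgt_end")],
               ignore_attr = TRUE)
})

test_that("reciprocal mapping enforces uniqueness and 90% back-overlap", {
  cfg <- analysis_config()
  idch <- identity_chains()
  site <- binding_sites("chr1", 5000, 5300, "s1", "CEBPA")
  r <- reciprocal_map(idch, invert_chains(idch), site, cfg)
  expect_equal(r$status, "mapped")
  expect_equal(r$back_overlap_frac, 1.0)
  expect_equal(c(r$h_start, r$h_end), c(5000, 5300))

  # reverse chains shift the back-image so only 20% of the site is covered
  fwd <- identity_chains("chr1", 1e6)
  rev_shift <- data.frame(chain_id = "r", src_chrom = "chr1", src_start = 0,
                          src_end = 1e6, tgt_chrom = "chr1",
                          tgt_start = 240, tgt_end = 1e6 + 240,
                          tgt_strand = "+", stringsAsFactors = FALSE)
  r2 <- reciprocal_map(fwd, rev_shift, site, cfg)
  expect_equal(r2$status, "failed_reciprocal")
  expect_equal(r2$back_overlap_frac, 60 / 300)

  # forward failure propagates as its own status
  nochain <- identity_chains("chr9", 1e6)
  r3 <- reciprocal_map(nochain, invert_chains(nochain), site, cfg)
  expect_equal(r3$status, "unaligned")
  expect_true(is.na(r3$h_start))
})

test_that("map_sites is deterministic and identity chains map everything", {
  set.seed(23)
  cfg <- analysis_config()
  sites <- random_sites_df(60, "CEBPA", len = 900000)
  ch <- identity_chains()
  m1 <- map_sites(sites, ch, invert_chains(ch), cfg)
  m2 <- map_sites(sites, ch, invert_chains(ch), cfg)
  expect_identical(m1, m2)
  expect_true(all(m1$status == "mapped"))
  expect_true(all(m1$back_overlap_frac == 1))
  expect_equal(mapped_percentage(nrow(m1), sum(m1$status == "mapped")), 100)
})

test_that("mapped percentage follows the reporting convention", {
  expect_identical(mapped_percentage(3481, 2176), 62.5)
  expect_identical(mapped_percentage(8688, 4899), 56.4)
})
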