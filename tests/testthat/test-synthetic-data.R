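small_cfg <- function(seed, ...) {
  sim_config(seed = seed, n_sites = 200, n_human_extra = 30, n_genes = 60,
             chrom_len = 1.5e6, ...)
}

test_that("the same seed reproduces a byte-identical fixture bundle", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_fixture(small_cfg(101), d1)
  generate_fixture(small_cfg(101), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("planted lift statuses are recovered exactly by the mapper", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(small_cfg(103, frac_unalignable = 0.3,
                                   frac_ambiguous = 0.05),
                         d, write_sequences = FALSE)
  cfg <- analysis_config()
  fwd <- read_chain_tsv(fx$paths$chains_fwd)
  rev <- read_chain_tsv(fx$paths$chains_rev)
  for (tf in c("CEBPA", "PPARG")) {
    sites <- read_sites(fx$paths$mouse_sites[[tf]], tf, "mouse")
    m <- map_sites(sites, fwd, rev, cfg)
    truth <- fx$truth$sites[fx$truth$sites$factor == tf, ]
    truth <- truth[match(m$site_id, truth$site_id), ]
    expect_identical(m$status, truth$status)
    expect_equal(sum(m$status == "unaligned"), round(0.3 * 200))
    # mapped spans equal the true images
    ok <- m$status == "mapped"
    expect_equal(m$h_start[ok], truth$img_start[ok])
    expect_equal(m$h_end[ok], truth$img_end[ok])
  }
})

test_that("the construction guarantees hold for every planted fate", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(small_cfg(107), d, write_sequences = FALSE)
  tr <- fx$truth$sites
  hum <- fx$truth$human_sites
  mapped <- tr[!is.na(tr$fate), ]
  for (i in seq_len(nrow(mapped))) {
    span <- genomic_interval(mapped$img_chrom[i], mapped$img_start[i],
                             mapped$img_end[i])
    hh <- genomic_interval(hum$chrom, hum$start, hum$end)
    ol <- overlap_length(span[rep(1, nrow(hum)), ], hh)
    w_span <- interval_width(span)
    best <- if (nrow(hum)) max(ol / w_span) else 0
    if (mapped$fate[i] == "retained") {
      expect_gt(best, 0.10)  # a human partner overlaps >10% of the image
    } else {
      expect_equal(max(ol), 0)  # no overlapping human site at all
      d_mid <- abs(midpoint(hh) - midpoint(span))
      d_mid[hum$chrom != mapped$img_chrom[i]] <- Inf
      if (mapped$fate[i] == "turnover") {
        expect_true(any(d_mid >= 2000 - 200 & d_mid <= 8000 + 200))
      } else {
        expect_true(all(d_mid > 20000))  # lost: nothing within 20 kb
      }
    }
  }
})

test_that("simulate_tags is Poisson in total and concentrated on sites", {
  empty <- simulate_tags(binding_sites(character(0), numeric(0),
                                       numeric(0)), 0,
                         data.frame(chrom = "chr1", length = 1e6))
  expect_length(unlist(empty), 0)
  set.seed(109)
  genome <- data.frame(chrom = "chr1", length = 1e6)
  totals <- replicate(60, {
    tr <- simulate_tags(binding_sites(character(0), numeric(0),
                                      numeric(0)), 0.001, genome)
    length(tr$chr1)
  })
  # total ~ Poisson(1000): the mean of 60 draws sits within ~4 SE
  expect_lt(abs(mean(totals) - 1000), 4 * sqrt(1000 / 60))
  site <- binding_sites("chr1", 5000, 5300, "s", "CEBPA", tag_count = 32)
  counts <- replicate(60, {
    tr <- simulate_tags(site, 0, genome)
    count_tags_in_window(tr, "chr1", 5150, 520)
  })
  expect_lt(abs(mean(counts) - 32), 4 * sqrt(32 / 60))
})

test_that("planted gene fates are tallied exactly by the ortholog mapper", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(small_cfg(113), d, write_sequences = FALSE)
  cfg <- analysis_config()
  res <- lift_tss_orthologs(read_genes(fx$paths$genes_mouse),
                            read_chain_tsv(fx$paths$chains_fwd),
                            read_genes(fx$paths$genes_human), cfg)
  gt <- table(fx$truth$genes$gene_fate)
  expect_equal(res$tally[["unlifted"]], as.integer(gt[["unlifted"]]))
  expect_equal(res$tally[["no_nearby_gene"]],
               as.integer(gt[["no_ortholog"]]))
  expect_equal(sum(res$tally), nrow(fx$truth$genes))
})

test_that("planted motif flags and identities are recovered from files", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(small_cfg(127), d)
  tr <- fx$truth$sites[fx$truth$sites$status == "mapped", ]
  pwms <- default_pwms()
  seqs <- Biostrings::readDNAStringSet(fx$paths$regions)
  ids <- sub("\\s.*$", "", names(seqs))
  expect_setequal(ids, tr$site_id)
  sq <- as.character(seqs)[match(tr$site_id, ids)]
  got_c <- vapply(sq, function(s) has_consensus(s, pwms$CEBPA)$flag,
                  logical(1), USE.NAMES = FALSE)
  got_p <- vapply(sq, function(s) has_consensus(s, pwms$PPARG)$flag,
                  logical(1), USE.NAMES = FALSE)
  expect_identical(got_c, tr$motif_cebpa)
  expect_identical(got_p, tr$motif_pparg)

  aln <- read_aligned_fasta(fx$paths$alignments)
  aln <- aln[match(tr$site_id, aln$pair_id), ]
  ident <- vapply(seq_len(nrow(aln)), function(i)
    identity_score(aln$seq1[i], aln$seq2[i]), numeric(1))
  expect_equal(ident, tr$identity_target, tolerance = 0.002)
})

test_that("infeasible configurations fail loudly", {
  expect_error(generate_fixture(sim_config(seed = 1, n_chroms = 1,
                                           chrom_len = 2e5,
                                           n_sites = 500, n_genes = 10),
                                withr::local_tempdir(),
                                write_sequences = FALSE),
               "infeasible|place")
})
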