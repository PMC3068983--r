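genes_df <- function(tss, cluster, chrom = "chr1", strand = "+") {
  data.frame(gene_id = paste0("g", seq_along(tss)), chrom = chrom,
             tss = tss, strand = rep_len(strand, length(tss)),
             cluster = as.character(cluster), stringsAsFactors = FALSE)
}

test_that("cluster labels prefer the closest clustered gene", {
  cfg <- analysis_config()
  site <- binding_sites("chr1", 499900, 500100, "s", "CEBPA")  # mid 500,000
  # unclustered TSS at 10 kb, cluster-2 TSS at 60 kb: the clustered one wins
  g <- genes_df(c(510000, 560000), c("none", "2"))
  expect_equal(assign_cluster(site, g, cfg), 2L)
  # only an unclustered gene within range: constitutive label 5
  expect_equal(assign_cluster(site, genes_df(540000, "none"), cfg), 5L)
  # nearest TSS at 150 kb: distal label 6
  expect_equal(assign_cluster(site, genes_df(650000, "3"), cfg), 6L)
  # the alternative rule labels by the closest gene regardless of cluster
  expect_equal(assign_cluster(site, g, cfg, rule = "nearest_gene"), 5L)
})

test_that("every site gets exactly one label; shrinking the window never
          rescues a distal site", {
  set.seed(37)
  cfg <- analysis_config()
  sites <- random_sites_df(80, "PPARG", len = 2e6)
  g <- genes_df(sort(sample(0:2e6, 25)), sample(c(1:4, "none"), 25, TRUE))
  lab <- assign_cluster(sites, g, cfg)
  expect_true(all(lab %in% 1:6))
  expect_length(lab, nrow(sites))
  lab_small <- assign_cluster(sites, g, analysis_config(cluster_window = 2e4))
  expect_true(all(lab_small[lab == 6L] == 6L))
})

test_that("TSS ortholog mapping pairs within 5 kb and tallies discards", {
  cfg <- analysis_config()
  ch <- identity_chains("chr1", 1e6)
  mouse <- genes_df(c(10000, 200000, 400000), c("1", "2", "none"))
  human <- genes_df(c(13000, 206000), c("1", "2"))
  # gene 1: lifted TSS 10,000 -> nearest human TSS 13,000 (3 kb): paired
  # gene 2: nearest human TSS at 6 kb: discarded
  # gene 3: TSS in unalignable sequence (no chain there): unlifted
  ch_gap <- ch
  ch_gap$src_end <- 350000
  ch_gap$tgt_end <- 350000
  res <- lift_tss_orthologs(mouse, ch_gap, human, cfg)
  expect_equal(res$tally, c(paired = 1L, unlifted = 1L,
                            no_nearby_gene = 1L))
  expect_equal(res$pairs$gene_id, "g1")
  expect_equal(res$pairs$ortholog_id, "g1")
  expect_equal(res$pairs$distance, 3000)
  expect_equal(res$pairs$cluster, "1")
  expect_equal(sum(res$tally), nrow(mouse))
})

test_that("TSS profiles bin site midpoints, oriented by strand", {
  cfg <- analysis_config()
  g <- genes_df(500000, "4")
  sites <- binding_sites("chr1", c(404900, 504900), c(405100, 505100),
                         tf = "PPARG")
  pr <- tss_site_profile(g, sites, cfg)
  expect_equal(nrow(pr), 20L)
  expect_equal(pr$mean_sites[pr$bin_start == -100000], 1)  # tss - 95 kb
  expect_equal(pr$mean_sites[pr$bin_start == 0], 1)        # tss + 5 kb
  expect_equal(sum(pr$mean_sites), 2)

  # on the minus strand the same site lands in the mirrored bin
  gm <- genes_df(500000, "4", strand = "-")
  prm <- tss_site_profile(gm, sites[2, ], cfg)
  expect_equal(prm$mean_sites[prm$bin_start == -10000], 1)

  g2 <- genes_df(c(500000, 800000), "4")
  sites2 <- binding_sites("chr1", c(504900, 804900), c(505100, 805100),
                          tf = "PPARG")
  pr2 <- tss_site_profile(g2, sites2, cfg)
  expect_equal(pr2$mean_sites[pr2$bin_start == 0], 1)  # mean of 1 and 1
  expect_error(tss_site_profile(g[0, ], sites, cfg), "non-empty")
})

test_that("gained-site counts use a 50 kb window and normalise per cluster", {
  cfg <- analysis_config()
  g <- genes_df(c(500000, 900000), c("4", "4"))
  hs <- binding_sites("chr1", c(509900, 559900), c(510100, 560100),
                      tf = "PPARG", species = "human")
  res <- gained_sites_per_gene(g, hs, cfg)
  expect_equal(res$per_gene$n_sites, c(1L, 0L))  # 10 kb in, 60 kb out
  expect_equal(sum(res$histogram$fraction[res$histogram$cluster == "4"]), 1)
  set.seed(41)
  g2 <- genes_df(sample(1e5:9e5, 30), sample(c(1:4, "none"), 30, TRUE))
  res2 <- gained_sites_per_gene(g2, random_sites_df(50, "PPARG", "human",
                                                    len = 1e6), cfg)
  agg <- tapply(res2$histogram$fraction, res2$histogram$cluster, sum)
  expect_true(all(abs(agg - 1) < 1e-12))
})
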