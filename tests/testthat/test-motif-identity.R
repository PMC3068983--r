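# two-column toy model: columns (A=8) and (C=4, G=4)
toy_pwm <- function(cfg = analysis_config()) {
  counts <- matrix(c(8, 0, 0, 0,
                     0, 4, 4, 0), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  build_pwm(counts, cfg)
}

test_that("JASPAR PFM reader handles bracketed and bare layouts", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MX0001 toy",
               "A [ 8 0 ]", "C [ 0 4 ]", "G [ 0 4 ]", "T [ 0 0 ]"), f)
  p <- read_jaspar_pfm(f)
  expect_equal(p$model_id, "MX0001")
  expect_equal(unname(p$counts["A", 1]), 8)
  writeLines(c("8 0", "0 4", "0 4", "0 0"), f)
  p2 <- read_jaspar_pfm(f)
  expect_equal(p2$counts, p$counts)
})

test_that("PWM log-odds follow the uniform-background pseudo-count rule", {
  pwm <- toy_pwm()
  expect_equal(unname(pwm$logodds["A", 1]), log2((8.25 / 9) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(pwm$logodds["C", 1]), log2((0.25 / 9) / 0.25),
               tolerance = 1e-12)
  expect_equal(pwm$max_score, log2((8.25 / 9) / 0.25) +
                 log2((4.25 / 9) / 0.25), tolerance = 1e-9)
  expect_equal(pwm$min_score, 2 * log2((0.25 / 9) / 0.25),
               tolerance = 1e-9)
  expect_equal(pwm$threshold,
               pwm$min_score + 0.8 * (pwm$max_score - pwm$min_score))
  expect_equal(round(pwm$max_score, 3), 2.792)
  expect_equal(round(pwm$min_score, 3), -6.34)
  expect_equal(round(pwm$threshold, 3), 0.966)

  uni <- build_pwm(matrix(2, 4, 3, dimnames = list(c("A", "C", "G", "T"),
                                                   NULL)))
  expect_true(all(abs(uni$logodds) < 1e-12))
  bad <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0), 4)
  expect_error(build_pwm(bad), "zero")
})

test_that("consensus scanning covers both strands and skips bad windows", {
  pwm <- toy_pwm()
  hit <- has_consensus("TTACTT", pwm)     # window "AC" scores ~2.792
  expect_true(hit$flag)
  expect_equal(hit$score, pwm$max_score, tolerance = 1e-9)
  expect_false(has_consensus("GGGGGG", pwm)$flag)
  # reverse complement of the best word: "GT" revcomp -> "AC"
  rev_hit <- has_consensus("GGGTGG", pwm)
  expect_true(rev_hit$flag)
  expect_equal(rev_hit$strand, "-")
  # non-ACGT characters invalidate the windows containing them
  expect_false(has_consensus("ANCN", pwm)$flag)
  expect_warning(short <- has_consensus("A", pwm), "shorter")
  expect_false(short$flag)
})

test_that("scanning agrees with window/strand enumeration on random input", {
  set.seed(43)
  pwms <- default_pwms()
  for (i in 1:60) {
    s <- random_dna(sample(15:120, 1))
    pwm <- pwms[[sample(2, 1)]]
    expect_identical(has_consensus(s, pwm)$flag, oracle_scan(s, pwm))
  }
})

test_that("reverse-complementing the sequence never changes the flag", {
  set.seed(47)
  pwm <- default_pwms()$CEBPA
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  for (i in 1:40) {
    s <- random_dna(60)
    expect_identical(has_consensus(s, pwm)$flag,
                     has_consensus(rc(s), pwm)$flag)
  }
  # a planted consensus is found on either strand
  planted <- paste0(random_dna(20), pwm_consensus(pwm), random_dna(20))
  expect_true(has_consensus(planted, pwm)$flag)
  expect_true(has_consensus(rc(planted), pwm)$flag)
})

test_that("identity is matches over the shorter ungapped length", {
  expect_equal(identity_score("ACGT", "ACGA"), 0.75)
  expect_equal(identity_score("ACGT--AC", "ACGTGGAC"), 1.0)
  expect_equal(identity_score("acgt", "ACGT"), 1.0)  # case-insensitive
  set.seed(53)
  for (i in 1:20) {
    s <- random_dna(80)
    expect_equal(identity_score(s, s), 1.0)
  }
  expect_error(identity_score("ACG", "AC"), "equal length")
  expect_error(identity_score("---", "ACG"), "degenerate")
})

test_that("aligned FASTA and MAF pair readers agree on the same alignment", {
  pairs <- data.frame(pair_id = c("r1", "r2"),
                      seq1 = c("ACGT--AC", "TTTT"),
                      seq2 = c("ACGTGGAC", "TTTA"), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fa")
  write_aligned_fasta(pairs, f)
  back <- read_aligned_fasta(f)
  expect_equal(back, pairs)

  maf <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "a score=10",
               "s r1 0 6 + 100 ACGT--AC",
               "s hg.r1 0 8 + 200 ACGTGGAC", "",
               "a score=5",
               "s r2 0 4 + 100 TTTT",
               "s hg.r2 0 4 + 200 TTTA"), maf)
  mp <- read_maf_pairs(maf)
  expect_equal(mp$pair_id, c("r1", "r2"))
  expect_equal(mp$seq1, pairs$seq1)
  expect_equal(mp$seq2, pairs$seq2)
})

test_that("mutate_to_identity hits the target and honours protection", {
  set.seed(59)
  s <- random_dna(500)
  expect_identical(mutate_to_identity(s, 1.0), s)
  m <- mutate_to_identity(s, 0.8)
  expect_equal(identity_score(m, s), 0.8, tolerance = 0.002)
  prot <- data.frame(start = 101, end = 120)
  m2 <- mutate_to_identity(s, 0.7, protect = prot)
  expect_identical(substr(m2, 101, 120), substr(s, 101, 120))
  expect_error(mutate_to_identity(s, 0.01,
                                  protect = data.frame(start = 1,
                                                       end = 490)),
               "unreachable")
})

test_that("threshold sweep reports separation between bound and random", {
  set.seed(61)
  pwm_counts <- read_jaspar_pfm(system.file("extdata",
                                            "synthetic_CEBPA.pfm",
                                            package = "tfretain"))$counts
  word <- pwm_consensus(build_pwm(pwm_counts))
  bound <- replicate(15, paste0(random_dna(40), word, random_dna(40)))
  rand <- replicate(15, random_dna(92))
  sw <- threshold_sweep(bound, rand, pwm_counts, fracs = c(0.7, 0.8))
  expect_equal(sw$hit_frac_bound, c(1, 1))
  expect_true(all(sw$separation >= 0.8))
})
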