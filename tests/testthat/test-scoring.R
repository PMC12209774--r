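cfg <- hijack_config()

# independent beta-binomial oracle, plain log-gamma arithmetic
bb_lpmf <- function(k, n, mean, conc) {
  a <- mean * conc; b <- (1 - mean) * conc
  (lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)) +
    (lgamma(k + a) + lgamma(n - k + b) - lgamma(n + a + b)) +
    (lgamma(a + b) - lgamma(a) - lgamma(b))
}
llr_oracle <- function(ref, alt, conc = 10, clamp = 20) {
  n <- ref + alt
  mono <- log(0.5 * exp(bb_lpmf(ref, n, 0.98, conc)) +
                0.5 * exp(bb_lpmf(ref, n, 0.02, conc)))
  min(max(mono - bb_lpmf(ref, n, 0.5, conc), -clamp), clamp)
}

test_that("overexpression score branches meet at t = 2 and anchor at t = 0", {
  ref <- list(mu = 0, sigma = 0.7)
  # pick expression so that t is exactly 2, then exactly 0
  e_t2 <- exp(2 * (0.7 + cfg$sigma_floor)) - 0.5
  s <- overexpression_score(e_t2, ref, cfg)
  expect_equal(s$t, 2)
  expect_equal(s$score, 0)
  e_t0 <- exp(0) - 0.5
  s0 <- overexpression_score(e_t0, ref, cfg)
  expect_equal(s0$t, 0)
  expect_equal(s0$score, -2 * log(3))
  # continuity probes around the branch point
  eps <- 1e-9
  lo <- overexpression_score(e_t2 - eps, ref, cfg)$score
  hi <- overexpression_score(e_t2 + eps, ref, cfg)$score
  expect_lt(abs(hi - lo), 1e-6)
})

test_that("degenerate all-zero reference gives the hand-derived score", {
  # all reference TPM 0: mu = ln 0.5, sigma = 0; candidate at 10 TPM
  ref <- reference_distribution(rep(0, 8))
  expect_equal(ref$mu, log(0.5))
  expect_equal(ref$sigma, 0)
  s <- overexpression_score(10, ref, cfg)
  t_expected <- (log(10.5) - log(0.5)) / 0.3
  expect_equal(s$t, t_expected)
  expect_equal(s$score, log(t_expected - 1))
})

test_that("overexpression score increases strictly with candidate expression", {
  ref <- list(mu = 1.1, sigma = 0.4)
  e <- sort(c(0, 10^seq(-2, 3, length.out = 40)))
  sc <- overexpression_score(e, ref, cfg)$score
  expect_true(all(diff(sc) > 0))
})

test_that("doubling CN and TPM together leaves the overexpression score unchanged", {
  set.seed(11)
  ref <- reference_distribution(rlnorm(20, 1, 0.5))
  for (tpm in c(0.5, 4, 120)) {
    s1 <- overexpression_score(copy_number_correct(tpm, 2), ref, cfg)$score
    s2 <- overexpression_score(copy_number_correct(2 * tpm, 4), ref, cfg)$score
    expect_equal(s1, s2, tolerance = 1e-12)
  }
})

test_that("snp_llr is ref/alt-symmetric and matches the pmf oracle", {
  grid <- expand.grid(a = c(0, 1, 3, 7, 15, 40), b = c(0, 2, 8, 15, 40))
  grid <- grid[grid$a + grid$b >= 1, ]
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]
    expect_equal(snp_llr(a, b, cfg), snp_llr(b, a, cfg), tolerance = 1e-12)
    expect_equal(snp_llr(a, b, cfg), llr_oracle(a, b), tolerance = 1e-9)
  }
  expect_gt(snp_llr(20, 0, cfg), 0)   # fully monoallelic
  expect_lt(snp_llr(10, 10, cfg), 0)  # balanced
})

test_that("snp_llr saturates at the clamp for extreme monoallelic depth", {
  expect_equal(snp_llr(5000, 0, cfg), cfg$llr_clamp)
  expect_gt(snp_llr(200, 0, cfg), snp_llr(30, 0, cfg))  # grows with depth
})

test_that("ASE score averages with damping and obeys the gating rules", {
  auto <- tibble::tibble(is_sex_chrom = FALSE, is_imprinted = FALSE)
  snps <- tibble::tibble(ref_count = c(28, 1), alt_count = c(2, 25))
  llr <- snp_llr(snps$ref_count, snps$alt_count, cfg)
  got <- ase_score(snps, gene_cn = 2, auto, cfg)
  expect_equal(got$s_ase, sum(llr) / 4)  # n + 2 damping with n = 2
  expect_equal(got$n_snps, 2L)

  expect_equal(ase_score(NULL, 2, auto, cfg)$s_ase, 0)
  expect_equal(ase_score(snps[0, ], 2, auto, cfg)$s_ase, 0)
  # copy-number gating: below 2 or above 4
  expect_equal(ase_score(snps, 1.9, auto, cfg)$s_ase, 0)
  expect_equal(ase_score(snps, 4.1, auto, cfg)$s_ase, 0)
  expect_false(ase_score(snps, 4, auto, cfg)$s_ase == 0)
  # sex chromosome and imprinting gating
  x <- tibble::tibble(is_sex_chrom = TRUE, is_imprinted = FALSE)
  expect_identical(ase_score(snps, 2, x, cfg)$s_ase, 0)
  imp <- tibble::tibble(is_sex_chrom = FALSE, is_imprinted = TRUE)
  expect_identical(ase_score(snps, 2, imp, cfg)$s_ase, 0)
})

test_that("enhancer score is rank-weighted, order-invariant and bounded", {
  expect_equal(enhancer_score(numeric(0)), 0)
  expect_equal(enhancer_score(c(3, 2, 1)), 3 / 1 + 2 / 2 + 1 / 3)
  expect_equal(enhancer_score(c(1, 3, 2)), enhancer_score(c(3, 2, 1)))
  set.seed(5)
  for (rep in 1:10) {
    e <- runif(sample(1:8, 1), 0, 10)
    expect_lte(enhancer_score(e), sum(e))
    expect_gte(enhancer_score(c(e, runif(1, 0, 10))), enhancer_score(e))
  }
})

test_that("combined score is the documented weighted sum", {
  expect_equal(combine_sample_score(1, 1, 1, 0, cfg), 7)
  expect_equal(combine_sample_score(1, 1, 1, 1, cfg), 6)
  expect_equal(combine_sample_score(0, 0, 0, 0, cfg), 0)
  expect_equal(deletion_indicator(1, cfg), 1L)
  expect_equal(deletion_indicator(1.4, cfg), 1L)
  expect_equal(deletion_indicator(2, cfg), 0L)
})

test_that("gene aggregation is 5*sum/(n+4) over candidate samples", {
  expect_equal(aggregate_gene_score(7), 7)
  expect_equal(aggregate_gene_score(c(7, 3)), 50 / 6)
  expect_equal(aggregate_gene_score(c(7, -7)), 0)
  expect_error(aggregate_gene_score(numeric(0)), ">= 1")
  # strictly increasing in any single component
  expect_gt(aggregate_gene_score(c(7.5, 3)), aggregate_gene_score(c(7, 3)))
})

# --- hijacked-enhancer traversal on a constructed two-TAD locus -------------
# gene TAD [1.0, 2.0) Mb on chr1; donor TADs [1.0, 2.0) and [2.0, 3.0) Mb on
# chr5 with enhancers E1 (1.5 Mb, 5.0) and E2 (2.5 Mb, 2.0)
toy_locus <- function() {
  list(
    gene = tibble::tibble(gene_id = "G", chrom = "1",
                          start = 1400000, end = 1420000),
    tads = tibble::tibble(chrom = c("1", "5", "5"),
                          start = c(1e6, 1e6, 2e6), end = c(2e6, 2e6, 3e6)),
    enh = tibble::tibble(chrom = c("5", "5", "1"),
                         start = c(1500000, 2500000, 1600000),
                         end = c(1502000, 2502000, 1602000),
                         enrichment = c(5, 2, 9))
  )
}

test_that("a gene-retaining junction collects partner enhancers up to the TAD boundary", {
  loc <- toy_locus()
  nb <- build_neighborhood(loc$gene, loc$tads, cfg)
  # gene-side end keeps left flank (gene upstream of it); partner end at
  # chr5:1.8 Mb keeps its left flank, reaching E1 but bounded before E2
  bk <- bkend("S1", "1", 1500000, "left", "5", 1800000, "left", "deletion")
  got <- hijacked_enhancers(loc$gene, nb, bk, loc$enh, loc$tads, cfg)
  expect_equal(nrow(got), 1L)
  expect_equal(got$enrichment, 5)

  # flipping the partner orientation reaches only the next TAD: E2
  bk2 <- bkend("S1", "1", 1500000, "left", "5", 2200000, "right")
  got2 <- hijacked_enhancers(loc$gene, nb, bk2, loc$enh, loc$tads, cfg)
  expect_equal(got2$enrichment, 2)
})

test_that("junctions that do not retain the gene contribute no enhancers", {
  loc <- toy_locus()
  nb <- build_neighborhood(loc$gene, loc$tads, cfg)
  # right flank retained at chr1:1.5 Mb excludes the gene body (gene < pos)
  bk <- bkend("S1", "1", 1500000, "right", "5", 1800000, "left")
  expect_equal(nrow(hijacked_enhancers(loc$gene, nb, bk, loc$enh,
                                       loc$tads, cfg)), 0L)
})

test_that("intra-TAD junctions are excluded as self-hijack", {
  loc <- toy_locus()
  nb <- build_neighborhood(loc$gene, loc$tads, cfg)
  # both ends inside the gene's own search region; E3 at chr1:1.6 Mb is not
  # collected even though it sits on a retained flank
  bk <- bkend("S1", "1", 1450000, "left", "1", 1700000, "right")
  expect_equal(nrow(hijacked_enhancers(loc$gene, nb, bk, loc$enh,
                                       loc$tads, cfg)), 0L)
  expect_equal(nrow(hijacked_enhancers(loc$gene, nb, bk[0, ], loc$enh,
                                       loc$tads, cfg)), 0L)
})

test_that("unknown orientations take the union and duplicates collapse", {
  loc <- toy_locus()
  nb <- build_neighborhood(loc$gene, loc$tads, cfg)
  # unknown sides: both partner orientations tried; E1 leftwards, rightwards
  # the traversal stops at the 2 Mb boundary before any enhancer
  bk <- bkend("S1", "1", 1500000, NA, "5", 1800000, NA)
  got <- hijacked_enhancers(loc$gene, nb, bk, loc$enh, loc$tads, cfg)
  expect_equal(got$enrichment, 5)
  # two breakends reaching the same enhancer count it once
  bk2 <- dplyr::bind_rows(
    bkend("S1", "1", 1500000, "left", "5", 1800000, "left"),
    bkend("S1", "1", 1520000, "left", "5", 1900000, "left"))
  got2 <- hijacked_enhancers(loc$gene, nb, bk2, loc$enh, loc$tads, cfg)
  expect_equal(got2$enrichment, 5)
})
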