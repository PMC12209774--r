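test_that("the simulator is deterministic given its seed", {
  s1 <- simulate_cohort(simulation_spec(n_genes = 50, n_samples = 12,
                                        n_hijack_events = 2, rng_seed = 9))
  s2 <- simulate_cohort(simulation_spec(n_genes = 50, n_samples = 12,
                                        n_hijack_events = 2, rng_seed = 9))
  expect_identical(s1$cohort$expression, s2$cohort$expression)
  expect_identical(s1$cohort$breakends, s2$cohort$breakends)
  expect_identical(s1$cohort$allelic, s2$cohort$allelic)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(simulation_spec(n_genes = 50, n_samples = 12,
                                        n_hijack_events = 2, rng_seed = 10))
  expect_false(identical(s1$cohort$expression, s3$cohort$expression))
})

test_that("injected events exist exactly as promised by the spec", {
  sim <- simulate_cohort(simulation_spec(rng_seed = 2))  # 5 events, 200 x 30
  truth <- sim$truth[sim$truth$class == "hijack", ]
  expect_equal(nrow(truth), 5L)
  expect_equal(anyDuplicated(truth$gene_id), 0L)
  genes <- sim$cohort$genes
  tads <- sim$cohort$tads
  bks <- sim$cohort$breakends
  for (i in seq_len(nrow(truth))) {
    g <- genes[genes$gene_id == truth$gene_id[i], ]
    tad <- tads[tads$chrom == g$chrom & tads$start <= g$start &
                  tads$end >= g$end, ]
    smp <- bks[bks$sample == truth$sample[i], ]
    in_tad <- (smp$chrom_a == g$chrom & smp$pos_a - 1 >= tad$start &
                 smp$pos_a - 1 < tad$end) |
      (smp$chrom_b == g$chrom & smp$pos_b - 1 >= tad$start &
         smp$pos_b - 1 < tad$end)
    expect_true(any(in_tad))
    # the hijacked gene is silent elsewhere and strongly expressed here
    tpm <- sim$cohort$expression[
      sim$cohort$expression$gene_id == g$gene_id, -1]
    expect_gte(as.numeric(tpm[[truth$sample[i]]]), 100)
    expect_lt(max(as.numeric(tpm[setdiff(names(tpm), truth$sample[i])])), 0.5)
  }
})

test_that("hijack genes are candidates exactly in their injected samples", {
  sim <- simulate_cohort(simulation_spec(rng_seed = 4))
  truth <- sim$truth[sim$truth$class == "hijack", ]
  samples <- names(sim$cohort$expression)[-1]
  for (i in seq_len(nrow(truth))) {
    g <- sim$cohort$genes[sim$cohort$genes$gene_id == truth$gene_id[i], ]
    nb <- build_neighborhood(g, sim$cohort$tads, sim$cohort$config)
    part <- partition_samples(nb, sim$cohort$breakends, samples)
    expect_equal(part$candidate_samples, truth$sample[i])
  }
})

test_that("a zero-event spec yields a null cohort with empty truth", {
  sim <- simulate_cohort(simulation_spec(n_genes = 60, n_samples = 12,
                                         n_hijack_events = 0,
                                         n_amplification_decoys = 0,
                                         n_breakpoint_decoys = 0,
                                         rng_seed = 3))
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nrow(sim$cohort$breakends), 0L)
})

test_that("amplification decoys cancel out under copy-number correction", {
  sim <- simulate_cohort(simulation_spec(n_genes = 80, n_samples = 15,
                                         n_hijack_events = 0,
                                         n_amplification_decoys = 6,
                                         n_breakpoint_decoys = 0,
                                         rng_seed = 6))
  amp <- sim$truth[sim$truth$class == "amplification", ]
  expect_equal(nrow(amp), 6L)
  for (i in seq_len(nrow(amp))) {
    g <- sim$cohort$genes[sim$cohort$genes$gene_id == amp$gene_id[i], ]
    cn <- gene_copy_number(g, amp$sample[i], sim$cohort$cna)
    expect_equal(cn, 6)
    tpm <- sim$cohort$expression[sim$cohort$expression$gene_id == g$gene_id, -1]
    corrected <- copy_number_correct(as.numeric(tpm[[amp$sample[i]]]), cn)
    others <- as.numeric(tpm[setdiff(names(tpm), amp$sample[i])])
    # corrected expression sits inside the reference range: t pulled to 0
    ref <- reference_distribution(others)
    t_val <- overexpression_score(corrected, ref, sim$cohort$config)$t
    expect_lt(abs(t_val), 2)
  }
})

test_that("simulator output satisfies the input-model invariants", {
  sim <- simulate_cohort(simulation_spec(n_genes = 60, n_samples = 14,
                                         n_hijack_events = 2,
                                         n_amplification_decoys = 2,
                                         n_breakpoint_decoys = 3,
                                         rng_seed = 12))
  co <- sim$cohort
  expect_true(all(as.matrix(co$expression[-1]) >= 0))
  expect_equal(anyDuplicated(co$expression$gene_id), 0L)
  expect_true(all(co$breakends$pos_a >= 1 & co$breakends$pos_b >= 1))
  expect_true(all(co$breakends$side_a %in% c("left", "right")))
  expect_true(all(co$allelic$ref_count + co$allelic$alt_count >= 1))
  expect_equal(anyDuplicated(co$allelic[c("sample", "chrom", "pos")]), 0L)
  expect_true(all(co$cna$copy_number >= 0))
  # re-validation through the constructors raises no error
  expect_silent(hijackr:::validate_cna(co$cna))
  expect_silent(hijackr:::validate_breakends(co$breakends))
  # truth classes are disjoint
  expect_equal(anyDuplicated(sim$truth[c("gene_id", "sample")]), 0L)
})

test_that("an infeasible spec is rejected", {
  expect_error(simulation_spec(n_genes = 20, frac_silent = 0.1,
                               n_hijack_events = 5), "infeasible")
})
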