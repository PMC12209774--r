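test_that("fusion annotation records the partner, role and sample", {
  genes_tbl <- tibble::tibble(
    gene_id = c("G3", "G7"),
    candidate_samples = list("S1", "S2"))
  fusions <- tibble::tibble(sample = c("S1", "S9"),
                            gene5 = c("G5", "G7"), gene3 = c("G3", "G1"))
  ann <- annotate_fusions(genes_tbl, fusions)
  expect_equal(ann$fusion[1], "3' partner of G5 in S1")
  # fusion exists only in a non-candidate sample
  expect_equal(ann$fusion[2], "no fusion detected")
  # no fusion list at all
  expect_equal(annotate_fusions(genes_tbl, NULL)$fusion,
               rep("no fusion detected", 2))
  # 5' role
  f2 <- tibble::tibble(sample = "S2", gene5 = "G7", gene3 = "G9")
  expect_equal(annotate_fusions(genes_tbl, f2)$fusion[2],
               "5' partner of G9 in S2")
})

test_that("result tables are ranked, deterministic and carry a manifest", {
  sim <- simulate_cohort(simulation_spec(n_genes = 60, n_samples = 15,
                                         n_hijack_events = 2,
                                         n_breakpoint_decoys = 4,
                                         rng_seed = 31))
  res <- hijack_detect(sim$cohort)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_results(res, d1)
  write_results(res, d2)
  tab <- readr::read_tsv(file.path(d1, "results.tsv"), show_col_types = FALSE)
  expect_false(is.unsorted(tab$fdr))
  expect_true(all(c("gene_id", "name", "chrom", "score", "n_candidates",
                    "p_value", "fdr", "candidate_samples", "fusion",
                    "significant") %in% names(tab)))
  expect_identical(readLines(file.path(d1, "results.tsv")),
                   readLines(file.path(d2, "results.tsv")))
  expect_identical(readLines(file.path(d1, "manifest.yaml")),
                   readLines(file.path(d2, "manifest.yaml")))
  man <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  expect_equal(man$seed, sim$cohort$config$rng_seed)
  expect_equal(man$counts$genes_tested, nrow(res$genes))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$n_genes_tested, nrow(res$genes))
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(ggplot2::autoplot(res, type = "pvalues"), "ggplot")
})

test_that("the CLI runs end to end on simulator output and validates flags", {
  sim <- simulate_cohort(simulation_spec(n_genes = 50, n_samples = 12,
                                         n_hijack_events = 1,
                                         n_breakpoint_decoys = 3,
                                         rng_seed = 13))
  indir <- withr::local_tempdir()
  outdir <- file.path(withr::local_tempdir(), "out")
  paths <- write_cohort(sim$cohort, indir)
  status <- suppressMessages(cli_run(c(
    "--expression", paths$expression, "--breakends", paths$breakends,
    "--genes", paths$genes, "--cna", paths$cna, "--allelic", paths$allelic,
    "--tads", paths$tads, "--enhancers", paths$enhancers,
    "--out", outdir, "--seed", "77", "--log-level", "ERROR")))
  expect_equal(status, 0L)
  tab <- readr::read_tsv(file.path(outdir, "results.tsv"),
                         show_col_types = FALSE)
  expect_gt(nrow(tab), 0)
  expect_equal(tab$gene_id[1],
               sim$truth$gene_id[sim$truth$class == "hijack"])
  man <- yaml::read_yaml(file.path(outdir, "manifest.yaml"))
  expect_equal(man$seed, 77L)
  expect_true(!is.null(man$inputs$expression$md5))

  # missing required flag: usage error, nonzero status
  expect_equal(suppressMessages(cli_run(c("--breakends", paths$breakends,
                                          "--genes", paths$genes))), 2L)
  # unknown subcommand
  expect_equal(suppressMessages(cli_main("frobnicate")), 2L)
})

test_that("the simulate subcommand writes consumable inputs and truth", {
  dir <- file.path(withr::local_tempdir(), "sim")
  spec_file <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_genes = 40, n_samples = 12, n_hijack_events = 1,
                        n_breakpoint_decoys = 2, rng_seed = 19), spec_file)
  status <- suppressMessages(cli_simulate(c("--spec", spec_file,
                                            "--out", dir)))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(dir, "expression.tsv")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  expect_equal(sum(truth$class == "hijack"), 1L)
})

test_that("an empty result set writes header-only tables with a warning", {
  co <- toy_cohort()  # no breakends at all -> nothing tested
  expect_warning(res <- hijack_detect(co), "no genes")
  dir <- withr::local_tempdir()
  expect_warning(write_results(res, dir), "empty result")
  tab <- readr::read_tsv(file.path(dir, "results.tsv"), show_col_types = FALSE)
  expect_equal(nrow(tab), 0L)
})
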