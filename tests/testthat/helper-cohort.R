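# Shared fixtures: quiet logging, tiny hand-built cohorts and file writers.

options(hijackr.log_level = "ERROR")

# a minimal 12-sample cohort with one gene-per-TAD toy geometry
toy_cohort <- function(breakends = NULL, enhancers = NULL, allelic = NULL,
                       cna = NULL, fusions = NULL,
                       config = hijack_config(niter = 5, rng_seed = 42)) {
  samples <- sprintf("S%02d", 1:12)
  genes <- tibble::tibble(
    gene_id = c("GA", "GB", "GX"),
    name = c("GeneA", "GeneB", "GeneX"),
    chrom = c("1", "2", "X"),
    start = c(1200000, 1200000, 1200000),
    end = c(1220000, 1220000, 1220000),
    is_sex_chrom = c(FALSE, FALSE, TRUE),
    is_imprinted = FALSE
  )
  tads <- tibble::tibble(chrom = c("1", "1", "2", "2", "X"),
                         start = c(1e6, 2e6, 1e6, 2e6, 1e6),
                         end = c(2e6, 3e6, 2e6, 3e6, 2e6))
  set.seed(99)
  tpm <- matrix(round(runif(3 * 12, 2, 6), 3), nrow = 3,
                dimnames = list(genes$gene_id, samples))
  expression <- dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id),
                                 tibble::as_tibble(tpm))
  if (is.null(breakends)) {
    breakends <- tibble::tibble(
      sample = character(0), chrom_a = character(0), pos_a = integer(0),
      side_a = character(0), chrom_b = character(0), pos_b = integer(0),
      side_b = character(0), sv_class = character(0))
  }
  cohort_bundle(expression = expression, breakends = breakends,
                genes = genes, cna = cna, allelic = allelic, tads = tads,
                enhancers = enhancers, fusions = fusions, config = config)
}

bkend <- function(sample, chrom_a, pos_a, side_a, chrom_b, pos_b, side_b,
                  sv_class = NA_character_) {
  tibble::tibble(sample = sample, chrom_a = as.character(chrom_a),
                 pos_a = as.integer(pos_a), side_a = side_a,
                 chrom_b = as.character(chrom_b), pos_b = as.integer(pos_b),
                 side_b = side_b, sv_class = sv_class)
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
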