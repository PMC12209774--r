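#' Assemble a cohort bundle
#'
#' Gathers every per-cohort input into one validated object. Sample IDs in
#' breakends, copy-number segments, allelic counts and fusions must all appear
#' in the expression matrix header; cohorts with fewer than 10 samples run but
#' draw a prominent warning, since the reference distributions become noisy.
#'
#' @param expression Expression tibble (`gene_id` + one TPM column per sample),
#'   as from [read_expression()].
#' @param breakends Breakend tibble, as from [read_breakends()].
#' @param genes Gene annotation tibble, as from [read_gene_annotation()].
#' @param cna Optional copy-number segment tibble ([read_cna()]).
#' @param allelic Optional allelic-count tibble ([read_allelic_counts()]).
#' @param tads Optional TAD tibble ([read_tads()]).
#' @param enhancers Optional scored-enhancer tibble ([read_enhancers()]).
#' @param fusions Optional fusion-call tibble ([read_fusions()]).
#' @param imprinted Optional character vector of imprinted gene IDs; flags are
#'   set on `genes`.
#' @param config A [hijack_config()].
#'
#' @return A list of class `hijack_cohort`.
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_spec(n_genes = 40, n_samples = 12,
#'                                        n_hijack_events = 1, rng_seed = 7))
#' cohort <- sim$cohort
#' cohort
cohort_bundle <- function(expression, breakends, genes,
                          cna = NULL, allelic = NULL, tads = NULL,
                          enhancers = NULL, fusions = NULL,
                          imprinted = character(),
                          config = hijack_config()) {
  expression <- validate_expression(expression)
  breakends <- validate_breakends(breakends)
  genes <- validate_genes(genes, imprinted = unique(c(
    imprinted, genes$gene_id[isTRUE_vec(genes$is_imprinted)])))
  samples <- names(expression)[-1]

  check_sample_ids <- function(tbl, what) {
    if (is.null(tbl)) return(invisible(NULL))
    bad <- setdiff(unique(tbl$sample), samples)
    if (length(bad) > 0) {
      stopf("%s: sample ID(s) absent from expression matrix: %s",
            what, paste(bad, collapse = ", "))
    }
  }
  check_sample_ids(breakends, "breakends")
  check_sample_ids(cna, "cna")
  check_sample_ids(allelic, "allelic counts")
  check_sample_ids(fusions, "fusions")

  if (length(samples) < 10) {
    warn(sprintf(paste0(
      "cohort has only %d samples; the detector runs but is designed for ",
      ">= 10 samples and works best with large cohorts"), length(samples)))
  }

  structure(list(
    expression = expression,
    breakends = breakends,
    genes = genes,
    cna = if (is.null(cna)) NULL else validate_cna(cna),
    allelic = if (is.null(allelic)) NULL else validate_allelic(allelic),
    tads = tads,
    enhancers = enhancers,
    fusions = fusions,
    config = config
  ), class = "hijack_cohort")
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

cohort_samples <- function(cohort) names(cohort$expression)[-1]

# genes x samples TPM matrix
expression_matrix <- function(cohort) {
  m <- as.matrix(cohort$expression[-1])
  rownames(m) <- cohort$expression$gene_id
  m
}

#' @export
print.hijack_cohort <- function(x, ...) {
  cat("<hijack_cohort>\n")
  cat(sprintf("  samples:    %d\n", length(cohort_samples(x))))
  cat(sprintf("  genes:      %d annotated, %d in expression matrix\n",
              nrow(x$genes), nrow(x$expression)))
  cat(sprintf("  breakends:  %d pairs\n", nrow(x$breakends)))
  cat(sprintf("  cna:        %s\n",
              if (is.null(x$cna)) "absent" else paste(nrow(x$cna), "segments")))
  cat(sprintf("  allelic:    %s\n",
              if (is.null(x$allelic)) "absent" else paste(nrow(x$allelic), "SNP rows")))
  cat(sprintf("  tads:       %s\n",
              if (is.null(x$tads)) "absent" else paste(nrow(x$tads), "domains")))
  cat(sprintf("  enhancers:  %s\n",
              if (is.null(x$enhancers)) "absent" else paste(nrow(x$enhancers), "scored")))
  cat(sprintf("  fusions:    %s\n",
              if (is.null(x$fusions)) "absent" else paste(nrow(x$fusions), "calls")))
  invisible(x)
}

#' Read a cohort bundle from files
#'
#' Convenience wrapper combining the individual readers and
#' [cohort_bundle()].
#'
#' @param expression,breakends,genes Required file paths.
#' @param cna,allelic,tads,enhancers,fusions,imprinted Optional file paths.
#' @param config A [hijack_config()].
#' @return A `hijack_cohort`.
#' @export
read_cohort <- function(expression, breakends, genes,
                        cna = NULL, allelic = NULL, tads = NULL,
                        enhancers = NULL, fusions = NULL, imprinted = NULL,
                        config = hijack_config()) {
  cohort_bundle(
    expression = read_expression(expression),
    breakends = read_breakends(breakends),
    genes = read_gene_annotation(genes),
    cna = if (!is.null(cna)) read_cna(cna),
    allelic = if (!is.null(allelic)) read_allelic_counts(allelic),
    tads = if (!is.null(tads)) read_tads(tads),
    enhancers = if (!is.null(enhancers)) read_enhancers(enhancers),
    fusions = if (!is.null(fusions)) read_fusions(fusions),
    imprinted = if (!is.null(imprinted)) read_imprinted(imprinted) else character(),
    config = config
  )
}
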