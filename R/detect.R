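# End-to-end detector: filter -> partition -> score -> null -> FDR -> annotate.

# Precompute everything the observed scoring and the null resampling share:
# corrected log-expression, copy-number / ASE / deletion matrices (genes x
# samples), per-gene neighborhoods and sample partitions.
prepare_analysis <- function(cohort) {
  config <- cohort$config
  samples <- cohort_samples(cohort)
  tpm <- expression_matrix(cohort)

  expressed <- filter_expressed_genes(cohort$expression,
                                      config$min_tpm_expressed)
  genes <- cohort$genes[match(expressed, cohort$genes$gene_id), , drop = FALSE]
  unannotated <- expressed[is.na(genes$gene_id)]
  if (length(unannotated) > 0) {
    hj_log("WARNING", sprintf(
      "%d expressed gene(s) missing from the annotation were skipped",
      length(unannotated)))
    genes <- genes[!is.na(genes$gene_id), , drop = FALSE]
  }
  if (nrow(genes) == 0) stopf("no expressed, annotated genes to test")

  cn <- gene_cn_matrix(genes, samples, cohort$cna)
  ecorr <- copy_number_correct(tpm[genes$gene_id, samples, drop = FALSE], cn)
  ecorr_log <- log(0.5 + ecorr)
  del <- matrix(deletion_indicator(cn, config), nrow = nrow(cn),
                dimnames = dimnames(cn))
  if (is.null(cohort$cna)) del[] <- 0L

  # ASE score matrix: sum(llr)/(n+2) per (gene, sample), gated afterwards
  ase <- matrix(0, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$gene_id, samples))
  nsnp <- matrix(0L, nrow = nrow(genes), ncol = length(samples),
                 dimnames = list(genes$gene_id, samples))
  if (!is.null(cohort$allelic) && nrow(cohort$allelic) > 0) {
    al <- cohort$allelic |>
      filter(.data$gene_id %in% genes$gene_id) |>
      mutate(llr = snp_llr(.data$ref_count, .data$alt_count, config)) |>
      group_by(.data$gene_id, .data$sample) |>
      summarise(s = sum(.data$llr) / (n() + 2), n = n(), .groups = "drop")
    idx <- cbind(match(al$gene_id, genes$gene_id), match(al$sample, samples))
    ase[idx] <- al$s
    nsnp[idx] <- al$n
    gate <- cn < config$ase_cn_low | cn > config$ase_cn_high |
      genes$is_sex_chrom | genes$is_imprinted
    ase[gate] <- 0
  }

  neighborhoods <- lapply(seq_len(nrow(genes)), function(i) {
    build_neighborhood(genes[i, ], cohort$tads, config)
  })
  partitions <- lapply(neighborhoods, partition_samples,
                       breakends = cohort$breakends, samples = samples)

  list(cohort = cohort, config = config, samples = samples, genes = genes,
       n_expressed = length(expressed), cn = cn, ecorr = ecorr,
       ecorr_log = ecorr_log, del = del, ase = ase, nsnp = nsnp,
       neighborhoods = neighborhoods, partitions = partitions)
}

# Observed per-(gene, sample) scores for one eligible gene
score_gene_observed <- function(prep, gi) {
  config <- prep$config
  gene <- prep$genes[gi, ]
  part <- prep$partitions[[gi]]
  cands <- part$candidate_samples
  refs <- part$reference_samples
  el <- prep$ecorr_log[gi, ]
  ref <- list(mu = mean(el[refs]), sigma = sd_pop(el[refs]),
              n_ref = length(refs))

  rows <- lapply(cands, function(s) {
    t <- (el[s] - ref$mu) / (ref$sigma + config$sigma_floor)
    s_ovx <- if (t > 2) log(t - 1) else -2 * log(3 - t)
    hij <- hijacked_enhancers(
      gene, prep$neighborhoods[[gi]],
      prep$cohort$breakends[prep$cohort$breakends$sample == s, , drop = FALSE],
      prep$cohort$enhancers, prep$cohort$tads, config)
    s_enh <- enhancer_score(hij)
    tibble(
      gene_id = gene$gene_id, sample = s,
      s_overexpression = unname(s_ovx), t_value = unname(t),
      s_ase = prep$ase[gi, s], n_snps = prep$nsnp[gi, s],
      s_enhancer = s_enh, n_enhancers = nrow(hij),
      deleted = prep$del[gi, s],
      combined = combine_sample_score(unname(s_ovx), prep$ase[gi, s],
                                      s_enh, prep$del[gi, s], config)
    )
  })
  details <- bind_rows(rows)
  list(details = details,
       score = aggregate_gene_score(details$combined),
       n_candidates = length(cands), mu = ref$mu, sigma = ref$sigma)
}

#' Detect putative enhancer-hijacking events in a cohort
#'
#' Runs the full detector: expressed-gene filtering, candidate/reference
#' sample partition per gene, per-sample component scoring (overexpression,
#' allele-specific expression, hijacked enhancers, deletion penalty),
#' gene-level aggregation, empirical null resampling, empirical p-values and
#' Benjamini-Hochberg adjustment, and fusion annotation.
#'
#' @param cohort A [cohort_bundle()].
#' @param fdr_threshold Reporting threshold for the `significant` flag
#'   (default 0.2). Affects only that flag, never the scores.
#' @return A `hijack_result`: a list with `genes` (ranked tibble of tested
#'   genes), `sample_scores` (per-(gene, sample) component detail),
#'   `null_scores`, `config` and run metadata. Supports [tidy()], [glance()],
#'   [ggplot2::autoplot()] and [write_results()].
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_spec(n_genes = 60, n_samples = 15,
#'                                        n_hijack_events = 1,
#'                                        n_breakpoint_decoys = 4,
#'                                        rng_seed = 11))
#' res <- hijack_detect(sim$cohort)
#' res$genes
hijack_detect <- function(cohort, fdr_threshold = 0.2) {
  stopifnot(inherits(cohort, "hijack_cohort"))
  config <- cohort$config
  prep <- prepare_analysis(cohort)

  eligible <- vapply(prep$partitions, eligible_for_scoring,
                     logical(1), config = config)
  tested <- which(eligible)
  hj_log("INFO", sprintf(
    "%d genes annotated, %d expressed, %d tested (>=1 candidate, >=%d references)",
    nrow(cohort$genes), prep$n_expressed, length(tested),
    config$min_reference_samples))

  scored <- lapply(tested, function(gi) score_gene_observed(prep, gi))
  null <- build_null(prep, config)

  if (length(tested) > 0) {
    observed <- vapply(scored, `[[`, numeric(1), "score")
    p <- empirical_pvalues(observed, null$scores)
    fdr <- bh_correct(p)
    genes_tbl <- tibble(
      gene_id = prep$genes$gene_id[tested],
      name = prep$genes$name[tested],
      chrom = prep$genes$chrom[tested],
      score = observed,
      n_candidates = vapply(scored, `[[`, numeric(1), "n_candidates"),
      p_value = p,
      fdr = fdr,
      candidate_samples = lapply(prep$partitions[tested],
                                 `[[`, "candidate_samples")
    )
  } else {
    warn("no genes were eligible for testing; returning an empty result")
    genes_tbl <- tibble(
      gene_id = character(0), name = character(0), chrom = character(0),
      score = numeric(0), n_candidates = numeric(0), p_value = numeric(0),
      fdr = numeric(0), candidate_samples = list()
    )
  }
  genes_tbl <- annotate_fusions(genes_tbl, cohort$fusions)
  genes_tbl$significant <- genes_tbl$fdr < fdr_threshold
  genes_tbl <- genes_tbl |>
    arrange(.data$fdr, desc(.data$score), .data$gene_id)

  details <- bind_rows(lapply(scored, `[[`, "details"))
  if (nrow(details) == 0) {
    details <- tibble(
      gene_id = character(0), sample = character(0),
      s_overexpression = numeric(0), t_value = numeric(0),
      s_ase = numeric(0), n_snps = integer(0), s_enhancer = numeric(0),
      n_enhancers = integer(0), deleted = integer(0), combined = numeric(0))
  }
  details <- details |> arrange(.data$gene_id, .data$sample)

  structure(list(
    genes = genes_tbl,
    sample_scores = details,
    null_scores = null$scores,
    config = config,
    fdr_threshold = fdr_threshold,
    n_samples = length(prep$samples),
    n_genes_total = nrow(cohort$genes),
    n_genes_expressed = prep$n_expressed,
    n_genes_tested = length(tested)
  ), class = "hijack_result")
}

#' Annotate results with fusion-transcript status
#'
#' For each tested gene, scans the fusion calls of its candidate samples. A
#' matching fusion (the gene as either partner) is recorded with the partner
#' gene and the gene's 5'/3' role; the 3'-partner case marks likely
#' promoter-swap activation, a mechanism distinct from enhancer hijacking.
#' Genes without any matching call are flagged `"no fusion detected"`.
#'
#' @param genes_tbl Result gene tibble with `gene_id` and a
#'   `candidate_samples` list-column.
#' @param fusions Fusion-call tibble or `NULL`.
#' @return `genes_tbl` with a `fusion` annotation column added.
#' @export
annotate_fusions <- function(genes_tbl, fusions = NULL) {
  ann <- rep("no fusion detected", nrow(genes_tbl))
  if (!is.null(fusions) && nrow(fusions) > 0 && nrow(genes_tbl) > 0) {
    for (i in seq_len(nrow(genes_tbl))) {
      g <- genes_tbl$gene_id[i]
      cands <- genes_tbl$candidate_samples[[i]]
      hit <- fusions[fusions$sample %in% cands &
                       (fusions$gene5 == g | fusions$gene3 == g), ,
                     drop = FALSE]
      if (nrow(hit) > 0) {
        ann[i] <- paste(ifelse(
          hit$gene3 == g,
          sprintf("3' partner of %s in %s", hit$gene5, hit$sample),
          sprintf("5' partner of %s in %s", hit$gene3, hit$sample)
        ), collapse = "; ")
      }
    }
  }
  genes_tbl$fusion <- ann
  genes_tbl
}

#' @export
print.hijack_result <- function(x, ...) {
  cat("<hijack_result>\n")
  cat(sprintf("  samples: %d, genes tested: %d of %d expressed\n",
              x$n_samples, x$n_genes_tested, x$n_genes_expressed))
  cat(sprintf("  null scores: %d (niter = %d)\n",
              length(x$null_scores), x$config$niter))
  cat(sprintf("  significant at FDR < %.2g: %d\n",
              x$fdr_threshold, sum(x$genes$significant)))
  if (nrow(x$genes) > 0) {
    print(utils::head(select(x$genes, "gene_id", "name", "score",
                             "n_candidates", "p_value", "fdr"), 10))
  }
  invisible(x)
}

#' Tidy a detection result
#'
#' @param x A `hijack_result`.
#' @param ... Unused.
#' @return The ranked gene tibble, with candidate samples flattened to a
#'   comma-separated string.
#' @method tidy hijack_result
#' @export
tidy.hijack_result <- function(x, ...) {
  out <- x$genes
  out$candidate_samples <- vapply(out$candidate_samples, paste,
                                  character(1), collapse = ",")
  out
}

#' @method glance hijack_result
#' @export
#' @rdname tidy.hijack_result
glance.hijack_result <- function(x, ...) {
  tibble(
    n_samples = x$n_samples,
    n_genes_expressed = x$n_genes_expressed,
    n_genes_tested = x$n_genes_tested,
    n_null_scores = length(x$null_scores),
    fdr_threshold = x$fdr_threshold,
    n_significant = sum(x$genes$significant)
  )
}

#' Plot a detection result
#'
#' `type = "scores"` shows ranked gene scores coloured by significance;
#' `type = "pvalues"` the empirical p-value histogram of tested genes;
#' `type = "null"` the null score distribution with observed scores overlaid.
#'
#' @param object A `hijack_result`.
#' @param type One of `"scores"`, `"pvalues"`, `"null"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 ggplot aes geom_point geom_histogram geom_rug labs
#' @method autoplot hijack_result
#' @export
autoplot.hijack_result <- function(object, type = c("scores", "pvalues", "null"),
                                   ...) {
  type <- match.arg(type)
  genes <- object$genes
  if (type == "scores") {
    df <- mutate(genes, rank = row_number(desc(.data$score)))
    ggplot(df, aes(x = .data$rank, y = .data$score,
                   colour = .data$significant)) +
      geom_point() +
      labs(x = "gene rank", y = "aggregated gene score",
           colour = sprintf("FDR < %.2g", object$fdr_threshold))
  } else if (type == "pvalues") {
    ggplot(genes, aes(x = .data$p_value)) +
      geom_histogram(breaks = seq(0, 1, by = 0.05),
                     fill = "grey70", colour = "grey30") +
      labs(x = "empirical p-value", y = "genes")
  } else {
    ggplot(tibble(score = object$null_scores), aes(x = .data$score)) +
      geom_histogram(bins = 60, fill = "grey70", colour = "grey30") +
      geom_rug(data = genes, aes(x = .data$score), colour = "red") +
      labs(x = "aggregated score", y = "null draws")
  }
}
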