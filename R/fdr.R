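# Empirical null, empirical p-values, Benjamini-Hochberg step-up.

# Derive a per-iteration seed from the master seed (kept < 2^31)
iter_seed <- function(master_seed, iter) {
  as.integer((as.numeric(master_seed) + 7919 * iter) %% 2147483647)
}

#' Build the empirical null score distribution
#'
#' For every null-eligible gene (at least `min_reference_samples + 3`
#' reference samples) and each of `niter` iterations, 1, 2 or 3 randomly
#' chosen reference samples are promoted to pseudo-candidates and scored with
#' the full stack: overexpression against the remaining references, their
#' observed ASE score, an enhancer score of 0 (they carry no breakpoint near
#' the gene, hence no hijacked enhancers) and their observed deletion status.
#' The aggregated pseudo-gene scores form a pooled null of length
#' `niter * n_genes`.
#'
#' @param prep Internal analysis state from `prepare_analysis()` (see
#'   [hijack_detect()], which drives this).
#' @param config A [hijack_config()]; `rng_seed` seeds the resampling,
#'   per-iteration generators are derived deterministically from it.
#' @return A list with `scores`, `niter`, `master_seed` and `n_genes_null`.
#' @keywords internal
build_null <- function(prep, config) {
  eligible <- which(vapply(prep$partitions, function(p) {
    length(p$reference_samples) >= config$min_reference_samples + 3
  }, logical(1)))
  if (length(eligible) == 0) stopf("no genes eligible for null resampling")

  el <- prep$ecorr_log
  scores <- numeric(config$niter * length(eligible))
  pos <- 0L
  for (iter in seq_len(config$niter)) {
    set.seed(iter_seed(config$rng_seed, iter))
    for (gi in eligible) {
      refs <- prep$partitions[[gi]]$reference_samples
      k <- sample.int(3, 1)
      pseudo <- sample(refs, k)
      rem <- setdiff(refs, pseudo)
      mu <- mean(el[gi, rem])
      sigma <- sd_pop(el[gi, rem])
      t <- (el[gi, pseudo] - mu) / (sigma + config$sigma_floor)
      s_ovx <- -2 * log(3 - pmin(t, 2))
      up <- t > 2
      s_ovx[up] <- log(t[up] - 1)
      s <- combine_sample_score(s_ovx, prep$ase[gi, pseudo], 0,
                                prep$del[gi, pseudo], config)
      pos <- pos + 1L
      scores[pos] <- aggregate_gene_score(s)
    }
  }
  list(scores = scores, niter = config$niter,
       master_seed = config$rng_seed, n_genes_null = length(eligible))
}

#' Empirical p-values against a null score set
#'
#' Add-one tail probability \eqn{p = (1 + \#\{null \ge obs\}) / (1 + N)};
#' ties count into the numerator and p is always strictly positive.
#'
#' @param observed Numeric vector of observed gene scores.
#' @param null_scores Numeric vector of null scores (non-empty).
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' empirical_pvalues(5, runif(99))  # 0.01: above every null score
empirical_pvalues <- function(observed, null_scores) {
  if (length(null_scores) == 0) stopf("null score set is empty")
  n <- length(null_scores)
  vapply(observed, function(o) (1 + sum(null_scores >= o)) / (1 + n),
         numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: with p sorted ascending, \eqn{q_{(i)} = \min_{j \ge i}
#' p_{(j)} m / j}, capped at 1 and mapped back to the input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted values (FDR), same order as `p`.
#' @export
#' @examples
#' bh_correct(c(0.01, 0.02, 0.03))
bh_correct <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
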