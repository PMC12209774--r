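# Per-(gene, sample) score components and their combination. Logarithms are
# natural throughout; any other base would only rescale scores jointly with
# the weights.

#' Reference expression distribution for a gene
#'
#' Mean and population standard deviation (divisor n) of
#' \eqn{\ln(0.5 + E)} over the reference samples, where `E` is the
#' copy-number-corrected TPM.
#'
#' @param e_corrected_ref Corrected TPM values of the reference samples.
#' @return A list with `mu`, `sigma` and `n_ref`.
#' @export
reference_distribution <- function(e_corrected_ref) {
  x <- log(0.5 + e_corrected_ref)
  list(mu = mean(x), sigma = sd_pop(x), n_ref = length(x))
}

#' Overexpression score
#'
#' Measures how far a candidate sample's expression lies above the reference
#' distribution: \eqn{t = (\ln(0.5+E) - \mu) / (\sigma + floor)}, then
#' \eqn{S = \ln(t-1)} when \eqn{t > 2} and \eqn{S = -2\ln(3-t)} otherwise.
#' Both branches meet at 0 for \eqn{t = 2}; the damping keeps extreme outliers
#' from dominating the combined score. Strictly increasing in `e_corrected`.
#'
#' @param e_corrected Copy-number-corrected TPM of the candidate sample
#'   (vectorized).
#' @param ref Output of [reference_distribution()].
#' @param config A [hijack_config()].
#' @return A list with `score` and `t`, each as long as `e_corrected`.
#' @export
#' @examples
#' ref <- reference_distribution(rep(0, 10))
#' overexpression_score(10, ref)
overexpression_score <- function(e_corrected, ref, config = hijack_config()) {
  e <- log(0.5 + e_corrected)
  t <- (e - ref$mu) / (ref$sigma + config$sigma_floor)
  score <- -2 * log(3 - pmin(t, 2))
  up <- t > 2
  score[up] <- log(t[up] - 1)
  list(score = score, t = t)
}

#' Per-SNP log-likelihood ratio of monoallelic vs biallelic expression
#'
#' Monoallelic model: equal mixture of two beta-binomials with means at the
#' configured `mono_means` (default 2% and 98%, allowing leaky expression of
#' the silent allele). Biallelic model: one beta-binomial centred on 50%. All
#' three share the concentration `bb_concentration`
#' (\eqn{\alpha = p s, \beta = (1-p) s}). The ratio is symmetric in
#' (ref, alt) and clamped to `±llr_clamp`.
#'
#' @param ref_count,alt_count Non-negative integer read counts (vectorized);
#'   totals must be >= 1.
#' @param config A [hijack_config()].
#' @return Numeric vector of clamped log-likelihood ratios.
#' @export
#' @examples
#' snp_llr(20, 0)   # strongly monoallelic: positive
#' snp_llr(10, 10)  # balanced: negative
snp_llr <- function(ref_count, alt_count, config = hijack_config()) {
  n <- ref_count + alt_count
  if (any(n < 1)) stopf("snp_llr requires ref_count + alt_count >= 1")
  k <- ref_count
  s <- config$bb_concentration
  mono <- logsumexp2(
    log(0.5) + dbetabinom_log(k, n, config$mono_means[1], s),
    log(0.5) + dbetabinom_log(k, n, config$mono_means[2], s)
  )
  bi <- dbetabinom_log(k, n, config$bi_mean, s)
  pmin(pmax(mono - bi, -config$llr_clamp), config$llr_clamp)
}

#' Allele-specific expression score for one (gene, sample)
#'
#' Averages the per-SNP log-likelihood ratios with damping,
#' \eqn{S_{ase} = \sum_i llr_i / (n + 2)}, so that several concordant SNPs
#' score higher than one. The score is forced to 0 where allelic balance is
#' uninformative: gene copy number below `ase_cn_low` or above `ase_cn_high`,
#' sex-chromosome genes, imprinted genes, or no SNP data.
#'
#' @param snps Tibble with `ref_count`/`alt_count` for the SNPs of this gene
#'   in this sample (may be empty or `NULL`).
#' @param gene_cn Copy number of the gene in this sample.
#' @param gene One-row gene tibble with `is_sex_chrom`, `is_imprinted`.
#' @param config A [hijack_config()].
#' @return A list with `s_ase` and `n_snps`.
#' @export
ase_score <- function(snps, gene_cn, gene, config = hijack_config()) {
  gated <- gene_cn < config$ase_cn_low || gene_cn > config$ase_cn_high ||
    isTRUE(gene$is_sex_chrom) || isTRUE(gene$is_imprinted)
  if (gated || is.null(snps) || nrow(snps) == 0) {
    return(list(s_ase = 0, n_snps = 0L))
  }
  llr <- snp_llr(snps$ref_count, snps$alt_count, config)
  list(s_ase = sum(llr) / (length(llr) + 2), n_snps = length(llr))
}

# TAD boundary coordinates on one chromosome, sorted
tad_boundaries <- function(tads, chrom) {
  if (is.null(tads) || nrow(tads) == 0) return(numeric(0))
  on <- tads$chrom == chrom
  sort(unique(c(tads$start[on], tads$end[on])))
}

#' Enhancers brought into a gene's TAD by a sample's rearrangements
#'
#' Each breakend pair is considered independently. A pair contributes when
#' one end (A) lies inside the gene's search region and its retained side
#' carries the gene body — so the derivative allele keeps the gene — while
#' the partner end (B) lies elsewhere. The enhancers collected are those on
#' the retained side of B, from its position up to the nearest TAD boundary
#' in that direction (a proxy for the derivative TAD), capped at
#' `fallback_window_bp` when no boundary exists. Ends with unknown
#' orientation are tried both ways and the union kept (conservative toward
#' sensitivity). Enhancers already inside the gene's own search regions are
#' excluded (no self-hijack), and each enhancer is counted once across
#' breakends. Complex nested rearrangements can hide enhancers from this
#' per-breakpoint view.
#'
#' @param gene One-row gene tibble.
#' @param neighborhood Output of [build_neighborhood()] for this gene.
#' @param sample_breakends Breakend tibble restricted to one sample.
#' @param enhancers Scored-enhancer tibble or `NULL`.
#' @param tads TAD tibble or `NULL`.
#' @param config A [hijack_config()].
#' @return Tibble of hijacked enhancers (`chrom, start, end, enrichment`).
#' @export
hijacked_enhancers <- function(gene, neighborhood, sample_breakends,
                               enhancers, tads, config = hijack_config()) {
  empty <- tibble(chrom = character(0), start = numeric(0),
                  end = numeric(0), enrichment = numeric(0))
  if (is.null(enhancers) || nrow(enhancers) == 0 ||
      is.null(sample_breakends) || nrow(sample_breakends) == 0) {
    return(empty)
  }
  regions <- neighborhood$search_regions
  found <- empty

  collect_side <- function(chrom_b, pos_b, side_b) {
    bounds <- tad_boundaries(tads, chrom_b)
    if (side_b == "left") {
      lower <- bounds[bounds <= pos_b - 1]
      lo <- if (length(lower) > 0) max(lower) else pos_b - 1 - config$fallback_window_bp
      win <- c(max(0, lo), pos_b)
    } else {
      upper <- bounds[bounds >= pos_b]
      hi <- if (length(upper) > 0) min(upper) else pos_b - 1 + config$fallback_window_bp
      win <- c(pos_b - 1, hi)
    }
    hit <- enhancers$chrom == chrom_b &
      enhancers$start < win[2] & enhancers$end > win[1]
    enhancers[hit, , drop = FALSE]
  }

  gene_on_retained <- function(pos_a, side_a) {
    (side_a == "left" && gene$end <= pos_a) ||
      (side_a == "right" && gene$start >= pos_a - 1)
  }

  for (i in seq_len(nrow(sample_breakends))) {
    bk <- sample_breakends[i, ]
    ends <- list(
      list(chrom = bk$chrom_a, pos = bk$pos_a, side = bk$side_a),
      list(chrom = bk$chrom_b, pos = bk$pos_b, side = bk$side_b)
    )
    for (which_a in 1:2) {
      a <- ends[[which_a]]
      b <- ends[[3 - which_a]]
      a_in <- pos_in_regions(a$chrom, a$pos, regions)
      b_in <- pos_in_regions(b$chrom, b$pos, regions)
      if (!a_in || b_in) next
      sides_a <- if (is.na(a$side)) c("left", "right") else a$side
      if (!any(vapply(sides_a, function(sa) gene_on_retained(a$pos, sa),
                      logical(1)))) next
      sides_b <- if (is.na(b$side)) c("left", "right") else b$side
      for (sb in sides_b) {
        found <- bind_rows(found, collect_side(b$chrom, b$pos, sb))
      }
    }
  }
  if (nrow(found) == 0) return(empty)
  # no self-hijack: drop enhancers inside the gene's own search regions
  own <- rep(FALSE, nrow(found))
  for (r in seq_len(nrow(regions))) {
    own <- own | (found$chrom == regions$chrom[r] &
                    found$start < regions$end[r] &
                    found$end > regions$start[r])
  }
  found <- found[!own, , drop = FALSE]
  distinct(found, .data$chrom, .data$start, .data$end, .keep_all = TRUE)
}

#' Rank-weighted enhancer score
#'
#' With enrichments sorted descending as \eqn{E_0 \ge E_1 \ge \dots}, the
#' score is \eqn{\sum_i E_i / (i + 1)}: every hijacked enhancer contributes,
#' but the strongest dominate. Empty input scores 0 (also the behaviour when
#' no enhancer data are supplied).
#'
#' @param hijacked Tibble of hijacked enhancers (needs `enrichment`), or a
#'   bare numeric vector of enrichments.
#' @return A single score.
#' @export
#' @examples
#' enhancer_score(c(3, 2, 1))  # 3/1 + 2/2 + 1/3
enhancer_score <- function(hijacked) {
  e <- if (is.numeric(hijacked)) hijacked else hijacked$enrichment
  if (length(e) == 0) return(0)
  e <- sort(e, decreasing = TRUE)
  sum(e / seq_along(e))
}

#' Deletion indicator
#'
#' 1 when the gene is deleted in the sample (copy number below
#' `deletion_cn_threshold`), else 0. Rearrangements that truly hijack an
#' enhancer should not delete the activated gene, so deletions are penalized.
#'
#' @param gene_cn Copy number of the gene in this sample (2 when no CNA data).
#' @param config A [hijack_config()].
#' @return 0 or 1, vectorized.
#' @export
deletion_indicator <- function(gene_cn, config = hijack_config()) {
  as.integer(gene_cn < config$deletion_cn_threshold)
}

#' Combine score components for one (gene, sample)
#'
#' Weighted sum
#' \eqn{S = \omega_{ovx} S_{ovx} + \omega_{ase} S_{ase} +
#'   \omega_{enh} S_{enh} - \omega_{del} 1_{del}}.
#'
#' @param s_overexpression,s_ase,s_enhancer Component scores.
#' @param deleted Deletion indicator (0/1).
#' @param config A [hijack_config()].
#' @return The combined score (vectorized over the components).
#' @export
#' @examples
#' combine_sample_score(1, 1, 1, 0)  # 4 + 2 + 1 = 7
combine_sample_score <- function(s_overexpression, s_ase, s_enhancer, deleted,
                                 config = hijack_config()) {
  config$w_overexpression * s_overexpression +
    config$w_ase * s_ase +
    config$w_enhancer * s_enhancer -
    config$w_deletion * deleted
}

#' Aggregate per-sample scores into a gene score
#'
#' \eqn{S_{gene} = 5 \sum_i S_i / (n + 4)} over the gene's `n` candidate
#' samples. A single sample passes through unchanged; recurrently activated
#' genes gain weight. All candidates contribute, including negative scores.
#'
#' @param sample_scores Numeric vector of combined per-sample scores.
#' @return The aggregated gene score.
#' @export
#' @examples
#' aggregate_gene_score(7)        # 7
#' aggregate_gene_score(c(7, 3))  # 50/6
aggregate_gene_score <- function(sample_scores) {
  n <- length(sample_scores)
  if (n == 0) stopf("aggregate_gene_score requires >= 1 sample score")
  5 * sum(sample_scores) / (n + 4)
}
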