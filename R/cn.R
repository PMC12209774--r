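# Copy-number lookup/correction, expressed-gene filtering and enhancer-list
# merging.

#' Copy number of a gene in one sample
#'
#' Returns the copy number of the segment with the largest overlap with the
#' gene body, or 2 (diploid) when no segment overlaps or no CNA data are
#' provided. Ties go to the first segment in file order.
#'
#' @param gene One-row gene tibble (or list) with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param sample_id Sample identifier.
#' @param cna Copy-number segment tibble, or `NULL`.
#' @return A single copy number.
#' @export
gene_copy_number <- function(gene, sample_id, cna) {
  if (is.null(cna) || nrow(cna) == 0) return(2)
  seg <- cna[cna$sample == sample_id & cna$chrom == gene$chrom, , drop = FALSE]
  if (nrow(seg) == 0) return(2)
  ov <- pmax(0, pmin(gene$end, seg$end) - pmax(gene$start, seg$start))
  if (all(ov <= 0)) return(2)
  seg$copy_number[which.max(ov)]
}

# genes x samples copy-number matrix (default 2 everywhere)
gene_cn_matrix <- function(genes, samples, cna) {
  m <- matrix(2, nrow = nrow(genes), ncol = length(samples),
              dimnames = list(genes$gene_id, samples))
  if (is.null(cna) || nrow(cna) == 0) return(m)
  for (s in intersect(unique(cna$sample), samples)) {
    seg <- cna[cna$sample == s, , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      on_chr <- seg$chrom == g$chrom
      if (!any(on_chr)) next
      sc <- seg[on_chr, , drop = FALSE]
      ov <- pmax(0, pmin(g$end, sc$end) - pmax(g$start, sc$start))
      if (any(ov > 0)) m[i, s] <- sc$copy_number[which.max(ov)]
    }
  }
  m
}

#' Correct a TPM value for copy number
#'
#' Multiplies the expression by `2 / max(cn, 1)`; the floor at 1 guards the
#' homozygous-deletion case where the raw formula `2/CN` is undefined.
#'
#' @param tpm Non-negative expression value(s) in TPM.
#' @param cn Copy number(s).
#' @return Corrected expression, vectorized.
#' @export
#' @examples
#' copy_number_correct(40, 4)  # 20
#' copy_number_correct(40, 0)  # 80, denominator floored at 1
copy_number_correct <- function(tpm, cn) {
  tpm * 2 / pmax(cn, 1)
}

#' Filter genes by expression
#'
#' Keeps genes whose TPM exceeds `threshold` (strictly) in at least one
#' sample, preserving input order.
#'
#' @param expression Expression tibble (`gene_id` + sample columns).
#' @param threshold Expression threshold in TPM (default 1).
#' @return Character vector of retained gene IDs.
#' @export
filter_expressed_genes <- function(expression, threshold = 1) {
  m <- as.matrix(expression[-1])
  keep <- apply(m, 1, max) > threshold
  expression$gene_id[keep]
}

#' Merge enhancer rankings across datasets
#'
#' Combines scored-enhancer lists from several ChIP-seq datasets into one.
#' Enhancers are matched across lists by at least 50% reciprocal overlap and
#' the merged enrichment is the arithmetic mean of the matched scores, with
#' datasets lacking the enhancer contributing 0. This tames the
#' dataset-to-dataset variability of single-experiment enhancer rankings.
#'
#' @param lists A list of scored-enhancer tibbles (`chrom, start, end,
#'   enrichment`), one per dataset.
#' @return One merged scored-enhancer tibble.
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "7", start = 100, end = 200, enrichment = 4)
#' b <- tibble::tibble(chrom = "7", start = 110, end = 210, enrichment = 6)
#' merge_enhancer_rankings(list(a, b))  # one enhancer, enrichment 5
merge_enhancer_rankings <- function(lists) {
  if (length(lists) == 0) stopf("merge_enhancer_rankings needs >= 1 list")
  n <- length(lists)
  merged <- as_tibble(lists[[1]])[c("chrom", "start", "end")]
  total <- as_tibble(lists[[1]])$enrichment
  for (k in seq_along(lists)[-1]) {
    cur <- as_tibble(lists[[k]])
    for (j in seq_len(nrow(cur))) {
      cand <- which(merged$chrom == cur$chrom[j])
      hit <- NA_integer_
      if (length(cand) > 0) {
        ov <- pmax(0, pmin(merged$end[cand], cur$end[j]) -
                      pmax(merged$start[cand], cur$start[j]))
        recip <- ov >= 0.5 * (merged$end[cand] - merged$start[cand]) &
                 ov >= 0.5 * (cur$end[j] - cur$start[j])
        if (any(recip)) hit <- cand[recip][which.max(ov[recip])]
      }
      if (is.na(hit)) {
        merged <- bind_rows(merged, cur[j, c("chrom", "start", "end")])
        total <- c(total, cur$enrichment[j])
      } else {
        total[hit] <- total[hit] + cur$enrichment[j]
      }
    }
  }
  merged$enrichment <- total / n
  merged
}
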