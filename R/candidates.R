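# Candidate/reference sample partition: a sample is a candidate for a gene
# when any of its breakend ends falls inside the gene's extended TAD(s), or
# inside a gene-centred fallback window when no TAD list is supplied.

#' Build a gene's breakpoint search neighborhood
#'
#' When at least one TAD overlaps the gene body, the search regions are those
#' TADs extended by `tad_extension_bp` on each side (clipped at 0); otherwise
#' a single window of the gene body extended by `fallback_window_bp` is used.
#'
#' @param gene One-row gene tibble with `gene_id, chrom, start, end`.
#' @param tads TAD tibble (`chrom, start, end`) or `NULL`.
#' @param config A [hijack_config()].
#' @return A list with `gene_id`, `search_regions` (tibble of
#'   `chrom, start, end`) and `used_fallback`.
#' @export
build_neighborhood <- function(gene, tads, config = hijack_config()) {
  regions <- NULL
  used_fallback <- TRUE
  if (!is.null(tads) && nrow(tads) > 0) {
    hit <- tads$chrom == gene$chrom &
      tads$start < gene$end & tads$end > gene$start
    if (any(hit)) {
      regions <- tibble(
        chrom = tads$chrom[hit],
        start = pmax(0, tads$start[hit] - config$tad_extension_bp),
        end = tads$end[hit] + config$tad_extension_bp
      )
      used_fallback <- FALSE
    }
  }
  if (is.null(regions)) {
    regions <- tibble(
      chrom = gene$chrom,
      start = pmax(0, gene$start - config$fallback_window_bp),
      end = gene$end + config$fallback_window_bp
    )
  }
  list(gene_id = gene$gene_id, search_regions = regions,
       used_fallback = used_fallback)
}

# 1-based positions vs 0-based half-open regions on one chromosome set
pos_in_regions <- function(chrom, pos, regions) {
  inside <- rep(FALSE, length(pos))
  for (r in seq_len(nrow(regions))) {
    inside <- inside | (chrom == regions$chrom[r] &
                          pos - 1 >= regions$start[r] &
                          pos - 1 < regions$end[r])
  }
  inside
}

# Long table of breakend ends: one row per junction side
breakend_ends <- function(breakends) {
  bind_rows(
    tibble(sample = breakends$sample, chrom = breakends$chrom_a,
           pos = breakends$pos_a),
    tibble(sample = breakends$sample, chrom = breakends$chrom_b,
           pos = breakends$pos_b)
  )
}

#' Partition cohort samples into candidates and references for a gene
#'
#' A sample is a candidate when at least one end of any of its breakend pairs
#' (each end tested independently) falls inside a search region; all other
#' samples are references.
#'
#' @param neighborhood Output of [build_neighborhood()].
#' @param breakends Breakend tibble.
#' @param samples Character vector of all cohort sample IDs.
#' @return A list with `gene_id`, `candidate_samples` and `reference_samples`.
#' @export
partition_samples <- function(neighborhood, breakends, samples) {
  cand <- character(0)
  if (nrow(breakends) > 0) {
    ends <- breakend_ends(breakends)
    inside <- pos_in_regions(ends$chrom, ends$pos, neighborhood$search_regions)
    cand <- unique(ends$sample[inside])
  }
  list(gene_id = neighborhood$gene_id,
       candidate_samples = sort(cand),
       reference_samples = sort(setdiff(samples, cand)))
}

#' Is a gene eligible for scoring?
#'
#' Requires at least one candidate sample and at least
#' `min_reference_samples` references; genes failing either are skipped (the
#' reference mean/SD would be undefined or unstable).
#'
#' @param partition Output of [partition_samples()].
#' @param config A [hijack_config()].
#' @return Logical flag.
#' @export
eligible_for_scoring <- function(partition, config = hijack_config()) {
  n_cand <- length(partition$candidate_samples)
  n_ref <- length(partition$reference_samples)
  if (n_cand < 1) {
    hj_log("DEBUG", sprintf("gene %s skipped: no candidate samples",
                            partition$gene_id))
    return(FALSE)
  }
  if (n_ref < config$min_reference_samples) {
    hj_log("DEBUG", sprintf(
      "gene %s skipped: %d reference samples (< %d required)",
      partition$gene_id, n_ref, config$min_reference_samples))
    return(FALSE)
  }
  TRUE
}
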