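# Result tables and the run manifest.

format_num <- function(x) {
  # fixed formatting so result files are byte-stable across runs
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

#' Write ranked result tables and a run manifest
#'
#' Emits three files into `dir`: `results.tsv` (one row per tested gene,
#' sorted by FDR, then descending score, then gene_id), `sample_scores.tsv`
#' (per-(gene, candidate sample) component detail) and `manifest.yaml`
#' (configuration echo, input checksums, counts, seed and package version —
#' enough to reproduce the run). Output is deterministic: identical inputs
#' and seed give byte-identical files.
#'
#' @param result A `hijack_result` from [hijack_detect()].
#' @param dir Output directory (created if missing).
#' @param inputs Optional named list of input file paths; checksummed into
#'   the manifest.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir, inputs = NULL) {
  stopifnot(inherits(result, "hijack_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  genes <- tidy(result)
  genes$score <- format_num(genes$score)
  genes$p_value <- format_num(genes$p_value)
  genes$fdr <- format_num(genes$fdr)
  readr::write_tsv(genes, file.path(dir, "results.tsv"), progress = FALSE)
  if (nrow(genes) == 0) {
    warn("empty result set: header-only tables written")
  }

  det <- result$sample_scores
  for (col in c("s_overexpression", "t_value", "s_ase", "s_enhancer",
                "combined")) {
    det[[col]] <- format_num(det[[col]])
  }
  readr::write_tsv(det, file.path(dir, "sample_scores.tsv"), progress = FALSE)

  yaml::write_yaml(run_manifest(result, inputs),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

run_manifest <- function(result, inputs = NULL) {
  checksums <- NULL
  if (!is.null(inputs)) {
    inputs <- inputs[!vapply(inputs, is.null, logical(1))]
    checksums <- lapply(inputs, function(p) {
      list(path = as.character(p),
           md5 = unname(tools::md5sum(as.character(p))))
    })
  }
  list(
    tool = "hijackr",
    version = as.character(utils::packageVersion("hijackr")),
    seed = result$config$rng_seed,
    config = lapply(unclass(result$config), function(v)
      if (length(v) > 1) as.list(v) else v),
    inputs = checksums,
    counts = list(
      samples = result$n_samples,
      genes_total = result$n_genes_total,
      genes_expressed = result$n_genes_expressed,
      genes_tested = result$n_genes_tested,
      null_scores = length(result$null_scores)
    ),
    fdr_threshold = result$fdr_threshold
  )
}
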