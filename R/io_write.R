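# Writers emitting exactly the dialects the readers consume, so that a
# simulated cohort can be round-tripped through files and the CLI.

#' Write cohort input tables
#'
#' Each writer emits the file dialect its matching reader consumes, so
#' `read_*(write_*(x))` round-trips at record level.
#'
#' @param x The table to write (as returned by the matching reader).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name cohort_writers
NULL

#' @rdname cohort_writers
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_breakends <- function(x, path) {
  out <- tibble(
    sample = x$sample,
    chrom1 = x$chrom_a, pos1 = x$pos_a, side1 = side_to_token(x$side_a),
    chrom2 = x$chrom_b, pos2 = x$pos_b, side2 = side_to_token(x$side_b),
    sv_class = x$sv_class
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_cna <- function(x, path) {
  readr::write_tsv(x[c("sample", "chrom", "start", "end", "copy_number")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_allelic_counts <- function(x, path) {
  readr::write_tsv(
    x[c("sample", "gene_id", "chrom", "pos", "ref_count", "alt_count")],
    path, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_tads <- function(x, path) {
  readr::write_tsv(x[c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_enhancers <- function(x, path) {
  readr::write_tsv(x[c("chrom", "start", "end", "enrichment")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_fusions <- function(x, path) {
  readr::write_tsv(x[c("sample", "gene5", "gene3")], path, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_gene_annotation <- function(x, path) {
  readr::write_tsv(x[c("gene_id", "name", "chrom", "start", "end")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname cohort_writers
#' @export
write_imprinted <- function(x, path) {
  readr::write_lines(x, path)
  invisible(path)
}
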