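# Readers for the per-cohort tabular inputs. Coordinate dialects: BED-style
# intervals (TADs, enhancers, CNA segments, gene bodies) are 0-based half-open;
# point positions (breakends, SNPs) are 1-based. Conversion to normalized
# chromosome names happens here, once; downstream code never sees "chr".

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stopf("%s: missing column(s) %s", what, paste(missing, collapse = ", "))
  }
}

#' Read a TPM expression matrix
#'
#' Expects a TSV whose header row holds sample IDs, whose first column is
#' `gene_id`, and whose body is non-negative TPM values.
#'
#' @param path Path to the TSV file.
#' @return A tibble with a `gene_id` column followed by one numeric column per
#'   sample.
#' @export
read_expression <- function(path) {
  df <- read_tsv_quiet(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), name_repair = "minimal")
  names(df)[1] <- "gene_id"
  validate_expression(df)
}

validate_expression <- function(df) {
  if (ncol(df) < 2) stopf("expression table needs at least one sample column")
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) {
    stopf("duplicate sample IDs in expression header: %s",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  df <- as_tibble(df)
  if (anyDuplicated(df$gene_id)) {
    stopf("duplicate gene IDs in expression table: %s",
          paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  body <- as.matrix(df[-1])
  if (!is.numeric(body) || anyNA(body)) {
    stopf("expression body must be numeric with no missing values")
  }
  if (any(body < 0)) stopf("negative expression values are not allowed")
  df
}

# sides: "+" = left flank retained (coordinates <= pos survive on the
# derivative), "-" = right flank retained, "." = unknown orientation.
parse_side <- function(tok, what) {
  tok <- as.character(tok)
  tok[tok == "−"] <- "-"  # unicode minus
  out <- rep(NA_character_, length(tok))
  out[tok == "+"] <- "left"
  out[tok == "-"] <- "right"
  bad <- !(tok %in% c("+", "-", "."))
  if (any(bad)) {
    stopf("%s: unknown side token(s): %s", what,
          paste(unique(tok[bad]), collapse = ", "))
  }
  out
}

side_to_token <- function(side) {
  out <- rep(".", length(side))
  out[!is.na(side) & side == "left"] <- "+"
  out[!is.na(side) & side == "right"] <- "-"
  out
}

#' Read structural-variant breakends
#'
#' Expects a BEDPE-like TSV with columns `sample, chrom1, pos1, side1, chrom2,
#' pos2, side2` and an optional `sv_class`. Positions are 1-based. Side tokens:
#' `+` means the left flank (coordinates \eqn{\le} pos) is retained on the
#' derivative allele, `-` the right flank, `.` unknown. Intrachromosomal pairs
#' are normalized so `pos_a <= pos_b`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample, chrom_a, pos_a, side_a, chrom_b,
#'   pos_b, side_b, sv_class`.
#' @export
read_breakends <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("sample", "chrom1", "pos1", "side1",
                        "chrom2", "pos2", "side2"), "breakends")
  out <- tibble(
    sample = as.character(df$sample),
    chrom_a = normalize_chrom(df$chrom1),
    pos_a = as.integer(df$pos1),
    side_a = parse_side(df$side1, "breakends"),
    chrom_b = normalize_chrom(df$chrom2),
    pos_b = as.integer(df$pos2),
    side_b = parse_side(df$side2, "breakends"),
    sv_class = if ("sv_class" %in% names(df)) as.character(df$sv_class)
               else NA_character_
  )
  validate_breakends(out)
}

validate_breakends <- function(df) {
  df <- as_tibble(df)
  if (any(df$pos_a < 1 | df$pos_b < 1)) {
    stopf("breakend positions must be >= 1 (1-based)")
  }
  # order intrachromosomal ends ascending, swapping the retained sides with them
  swap <- df$chrom_a == df$chrom_b & df$pos_a > df$pos_b
  if (any(swap)) {
    tmp <- df[swap, c("chrom_a", "pos_a", "side_a")]
    df[swap, c("chrom_a", "pos_a", "side_a")] <-
      df[swap, c("chrom_b", "pos_b", "side_b")]
    df[swap, c("chrom_b", "pos_b", "side_b")] <- tmp
  }
  df
}

#' Read copy-number segments
#'
#' Expects a TSV with columns `sample, chrom, start, end, copy_number`;
#' `start`/`end` are 0-based half-open. Overlapping segments within one sample
#' are rejected.
#'
#' @param path Path to the TSV file.
#' @return A tibble of segments.
#' @export
read_cna <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("sample", "chrom", "start", "end", "copy_number"), "cna")
  out <- tibble(
    sample = as.character(df$sample),
    chrom = normalize_chrom(df$chrom),
    start = as.numeric(df$start),
    end = as.numeric(df$end),
    copy_number = as.numeric(df$copy_number)
  )
  validate_cna(out)
}

validate_cna <- function(df) {
  df <- as_tibble(df)
  if (any(df$copy_number < 0)) stopf("copy numbers must be >= 0")
  if (any(df$end <= df$start)) stopf("CNA segments must satisfy end > start")
  overlaps <- df |>
    arrange(.data$sample, .data$chrom, .data$start) |>
    group_by(.data$sample, .data$chrom) |>
    filter(n() > 1, .data$start < lag(.data$end, default = -Inf)) |>
    ungroup()
  if (nrow(overlaps) > 0) {
    stopf("overlapping CNA segments within sample(s): %s",
          paste(unique(overlaps$sample), collapse = ", "))
  }
  df
}

#' Read heterozygous-SNP allelic read counts
#'
#' Expects a TSV with columns `sample, gene_id, chrom, pos, ref_count,
#' alt_count` (`pos` 1-based). Rows with zero total coverage are dropped with
#' a warning; duplicate rows for one (sample, position) are collapsed by
#' summing counts, with a warning.
#'
#' @param path Path to the TSV file.
#' @return A tibble of per-SNP counts.
#' @export
read_allelic_counts <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("sample", "gene_id", "chrom", "pos",
                        "ref_count", "alt_count"), "allelic counts")
  out <- tibble(
    sample = as.character(df$sample),
    gene_id = as.character(df$gene_id),
    chrom = normalize_chrom(df$chrom),
    pos = as.integer(df$pos),
    ref_count = as.integer(df$ref_count),
    alt_count = as.integer(df$alt_count)
  )
  validate_allelic(out)
}

validate_allelic <- function(df) {
  df <- as_tibble(df)
  if (any(df$ref_count < 0 | df$alt_count < 0)) {
    stopf("allelic counts must be non-negative")
  }
  if (any(df$pos < 1)) stopf("SNP positions must be >= 1 (1-based)")
  zero <- df$ref_count + df$alt_count == 0
  if (any(zero)) {
    warn(sprintf("dropping %d SNP row(s) with zero total coverage", sum(zero)))
    df <- df[!zero, , drop = FALSE]
  }
  key <- paste(df$sample, df$chrom, df$pos)
  if (anyDuplicated(key)) {
    warn("collapsing duplicate SNP rows (same sample/position) by summing counts")
    df <- df |>
      group_by(.data$sample, .data$gene_id, .data$chrom, .data$pos) |>
      summarise(ref_count = sum(.data$ref_count),
                alt_count = sum(.data$alt_count), .groups = "drop")
  }
  df
}

#' Read TADs from a BED3 file
#'
#' @param path Path to a headerless BED3 file (0-based half-open).
#' @return A tibble with columns `chrom, start, end`.
#' @export
read_tads <- function(path) {
  df <- read_tsv_quiet(path, col_names = c("chrom", "start", "end"),
                       col_types = "cdd")
  out <- tibble(chrom = normalize_chrom(df$chrom),
                start = as.numeric(df$start), end = as.numeric(df$end))
  if (any(out$end <= out$start)) stopf("TADs must satisfy end > start")
  out
}

#' Read scored enhancers from a BED4 file
#'
#' Column 4 holds the enhancer-mark enrichment (e.g. an averaged ROSE score).
#'
#' @param path Path to a headerless BED4 file (0-based half-open).
#' @return A tibble with columns `chrom, start, end, enrichment`.
#' @export
read_enhancers <- function(path) {
  df <- read_tsv_quiet(path, col_names = c("chrom", "start", "end", "enrichment"),
                       col_types = "cddd")
  out <- tibble(chrom = normalize_chrom(df$chrom),
                start = as.numeric(df$start), end = as.numeric(df$end),
                enrichment = as.numeric(df$enrichment))
  if (any(out$end <= out$start)) stopf("enhancers must satisfy end > start")
  if (any(out$enrichment < 0)) stopf("enhancer enrichment must be >= 0")
  out
}

#' Read fusion-transcript calls
#'
#' @param path Path to a TSV with columns `sample, gene5, gene3` (5' and 3'
#'   fusion partners).
#' @return A tibble of fusion calls.
#' @export
read_fusions <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("sample", "gene5", "gene3"), "fusions")
  out <- tibble(sample = as.character(df$sample),
                gene5 = as.character(df$gene5),
                gene3 = as.character(df$gene3))
  if (any(out$gene5 == out$gene3)) stopf("fusion partners must differ")
  out
}

#' Read a gene annotation table
#'
#' Expects a TSV with columns `gene_id, name, chrom, start, end`
#' (`start`/`end` 0-based half-open gene body).
#'
#' @param path Path to the TSV file.
#' @param imprinted Optional character vector of imprinted gene IDs; sets the
#'   `is_imprinted` flag.
#' @return A tibble with columns `gene_id, name, chrom, start, end,
#'   is_sex_chrom, is_imprinted`.
#' @export
read_gene_annotation <- function(path, imprinted = character()) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("gene_id", "name", "chrom", "start", "end"),
                  "gene annotation")
  out <- tibble(
    gene_id = as.character(df$gene_id),
    name = as.character(df$name),
    chrom = normalize_chrom(df$chrom),
    start = as.numeric(df$start),
    end = as.numeric(df$end)
  )
  validate_genes(out, imprinted)
}

validate_genes <- function(df, imprinted = character()) {
  df <- as_tibble(df)
  if (anyDuplicated(df$gene_id)) {
    stopf("duplicate gene_id in annotation: %s",
          paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (any(df$end <= df$start)) stopf("gene bodies must satisfy end > start")
  df$is_sex_chrom <- df$chrom %in% c("X", "Y")
  df$is_imprinted <- df$gene_id %in% imprinted
  df
}

#' Read an imprinted-gene list
#'
#' @param path Path to a text file with one gene_id per line.
#' @return Character vector of gene IDs.
#' @export
read_imprinted <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}
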