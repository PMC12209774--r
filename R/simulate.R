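# Synthetic-cohort simulator with injected ground truth. The generator
# emulates the statistical structure the detector assumes: hijacking-prone
# genes that are silent in almost every sample, strong monoallelic
# overexpression co-located with a gene-retaining breakend that reaches a
# strong donor enhancer, amplification decoys whose overexpression vanishes
# after copy-number correction, and breakpoint decoys with no expression
# change. One gene per TAD, and all simulated features keep a 100 kb margin
# from TAD boundaries, so the 80 kb TAD extension cannot create accidental
# cross-TAD candidates: injected genes are candidates exactly in the injected
# samples.

#' Simulation parameters
#'
#' @param n_samples Cohort size (default 30).
#' @param n_genes Number of genes, one per TAD (default 200).
#' @param n_chromosomes Chromosomes the TADs are tiled over (default 4).
#' @param tad_size_mean Mean TAD width in bp; widths are drawn uniformly in
#'   ±20% of it (default 1e6, a typical mammalian TAD scale).
#' @param frac_silent Fraction of genes with (near-)zero baseline expression
#'   (default 0.3); hijack events are injected into these.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline TPM of expressed
#'   genes (defaults 2.5 and 1); baselines are floored at 1.5 TPM so every
#'   non-silent gene passes the expressed-gene filter.
#' @param noise_sdlog Log-normal multiplicative per-sample expression noise
#'   (default 0.3).
#' @param silent_tpm_max Silent genes draw per-sample TPM uniformly from
#'   `[0, silent_tpm_max]` (default 0.3, below the 1 TPM filter).
#' @param n_hijack_events Injected enhancer-hijacking events (default 5).
#' @param hijack_tpm_range TPM of the hijacked gene in the event sample
#'   (default `c(100, 200)`).
#' @param snps_per_gene Candidate heterozygous SNP sites per expressed gene
#'   (default 2).
#' @param het_site_prob Probability that a candidate site is heterozygous
#'   (hence usable for ASE) in a given sample (default 0.3, so about half of
#'   gene-sample pairs have no usable site, as typical of RNA-seq ASE data).
#'   Injected hijack events always carry all their sites.
#' @param allelic_depth RNA-seq read depth per SNP (default 30).
#' @param mono_fraction Major-allele fraction at hijacked genes (default
#'   0.97: strongly monoallelic with slight leakage, deliberately not sitting
#'   on the 0.98 model mean).
#' @param n_amplification_decoys Amplified-gene decoys (default 5).
#' @param amp_cn Copy number of the amplified segment (default 6).
#' @param amp_fold Expression fold-change of amplification decoys (default 3,
#'   proportional to CN 6 / diploid after allowing for saturation).
#' @param n_breakpoint_decoys Breakpoint-only decoy loci with unchanged
#'   expression (default 10). Each locus recurs in 1-3 samples (uniform),
#'   mirroring the recurrently rearranged regions real cohorts show.
#' @param enhancers_per_tad Mean background enhancers per TAD, Poisson
#'   (default 0.5).
#' @param enhancer_enrichment_meanlog,enhancer_enrichment_sdlog Log-normal
#'   background enhancer enrichments (defaults 0.5 and 0.6), giving the
#'   unequal values the rank-weighted enhancer score needs.
#' @param hijack_enhancer_min Minimum enrichment of the donor enhancer of an
#'   injected event (default 5); drawn uniformly in `[min, 2 min]`.
#' @param rng_seed Seed for the generator (default 1).
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_samples = 30,
                            n_genes = 200,
                            n_chromosomes = 4,
                            tad_size_mean = 1e6,
                            frac_silent = 0.3,
                            baseline_meanlog = 2.5,
                            baseline_sdlog = 1,
                            noise_sdlog = 0.3,
                            silent_tpm_max = 0.3,
                            n_hijack_events = 5,
                            hijack_tpm_range = c(100, 200),
                            snps_per_gene = 2,
                            het_site_prob = 0.3,
                            allelic_depth = 30,
                            mono_fraction = 0.97,
                            n_amplification_decoys = 5,
                            amp_cn = 6,
                            amp_fold = 3,
                            n_breakpoint_decoys = 10,
                            enhancers_per_tad = 0.5,
                            enhancer_enrichment_meanlog = 0.5,
                            enhancer_enrichment_sdlog = 0.6,
                            hijack_enhancer_min = 5,
                            rng_seed = 1) {
  spec <- as.list(environment())
  counts <- c(spec$n_samples, spec$n_genes, spec$n_hijack_events,
              spec$n_amplification_decoys, spec$n_breakpoint_decoys,
              spec$snps_per_gene, spec$allelic_depth)
  if (any(counts < 0)) stopf("simulation counts must be >= 0")
  if (spec$n_hijack_events > floor(spec$frac_silent * spec$n_genes)) {
    stopf("infeasible spec: %d hijack events but only %d silent genes",
          spec$n_hijack_events, floor(spec$frac_silent * spec$n_genes))
  }
  if (spec$frac_silent < 0 || spec$frac_silent > 1) {
    stopf("frac_silent must lie in [0, 1]")
  }
  structure(spec, class = "simulation_spec")
}

#' Read a simulation spec from a YAML file
#'
#' Keys mirror the arguments of [simulation_spec()].
#'
#' @param path Path to a YAML file.
#' @return A `simulation_spec`.
#' @export
read_simulation_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_spec))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stopf("unknown spec keys: %s", paste(bad, collapse = ", "))
  do.call(simulation_spec, vals)
}

# margin kept between any simulated feature and a TAD edge; must exceed the
# detector's TAD extension so events never leak into neighbouring TADs
.sim_margin <- 1e5

# sample() that never falls into the 1:n trap for length-1 vectors
sample_vec <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Simulate a cohort with known ground truth
#'
#' Tiles a genome into TADs (one gene per TAD plus gene-free donor TADs),
#' draws baseline expression, then injects hijack events, amplification
#' decoys and breakpoint decoys as described in [simulation_spec()].
#'
#' @param spec A [simulation_spec()].
#' @param config A [hijack_config()] stored in the returned cohort.
#' @return A list with `cohort` (a [cohort_bundle()]) and `truth` (a tibble
#'   of `gene_id, sample, class` with classes `hijack`, `amplification`,
#'   `breakpoint`).
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_spec(n_genes = 50, n_samples = 12,
#'                                        n_hijack_events = 2, rng_seed = 3))
#' sim$truth
simulate_cohort <- function(spec, config = hijack_config(rng_seed = spec$rng_seed)) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$rng_seed)
  m <- .sim_margin

  n_donor <- max(10, 2 * spec$n_hijack_events)
  n_tads <- spec$n_genes + n_donor
  widths <- runif(n_tads, 0.8 * spec$tad_size_mean, 1.2 * spec$tad_size_mean)
  chrom_of <- rep_len(as.character(seq_len(spec$n_chromosomes)), n_tads)
  tad_start <- numeric(n_tads)
  offset <- stats::setNames(rep(0, spec$n_chromosomes),
                            as.character(seq_len(spec$n_chromosomes)))
  for (i in seq_len(n_tads)) {
    tad_start[i] <- offset[chrom_of[i]]
    offset[chrom_of[i]] <- offset[chrom_of[i]] + widths[i]
  }
  tads <- tibble(chrom = chrom_of, start = tad_start,
                 end = tad_start + widths)
  gene_tad <- seq_len(spec$n_genes)           # TAD index hosting each gene
  donor_tads <- spec$n_genes + seq_len(n_donor)

  # genes: 20 kb bodies well inside their TAD, room to the right for the
  # gene-retaining breakend
  gene_len <- 2e4
  gstart <- floor(runif(spec$n_genes, tads$start[gene_tad] + 1.5 * m,
                        tads$end[gene_tad] - 2.5 * m - gene_len))
  genes <- tibble(
    gene_id = sprintf("G%04d", seq_len(spec$n_genes)),
    name = sprintf("GENE%04d", seq_len(spec$n_genes)),
    chrom = tads$chrom[gene_tad],
    start = gstart, end = gstart + gene_len,
    is_sex_chrom = FALSE, is_imprinted = FALSE
  )

  samples <- sprintf("S%03d", seq_len(spec$n_samples))

  # baseline expression
  n_silent <- floor(spec$frac_silent * spec$n_genes)
  silent <- sort(sample.int(spec$n_genes, n_silent))
  baseline <- pmax(1.5, stats::rlnorm(spec$n_genes, spec$baseline_meanlog,
                                      spec$baseline_sdlog))
  baseline[silent] <- 0
  tpm <- matrix(0, spec$n_genes, spec$n_samples,
                dimnames = list(genes$gene_id, samples))
  for (j in seq_len(spec$n_samples)) {
    tpm[, j] <- baseline * stats::rlnorm(spec$n_genes, 0, spec$noise_sdlog)
  }
  tpm[silent, ] <- matrix(runif(n_silent * spec$n_samples, 0,
                                spec$silent_tpm_max),
                          n_silent, spec$n_samples)

  # background enhancers: Poisson per TAD, log-normal enrichment
  n_enh <- stats::rpois(n_tads, spec$enhancers_per_tad)
  enh_tad <- rep(seq_len(n_tads), n_enh)
  enhancers <- tibble(
    chrom = tads$chrom[enh_tad],
    start = floor(runif(length(enh_tad), tads$start[enh_tad] + m,
                        tads$end[enh_tad] - m - 2e3)),
    enrichment = stats::rlnorm(length(enh_tad),
                               spec$enhancer_enrichment_meanlog,
                               spec$enhancer_enrichment_sdlog)
  )
  enhancers$end <- enhancers$start + 2e3

  # heterozygous-SNP positions per expressed gene; counts drawn per sample
  expressed_idx <- setdiff(seq_len(spec$n_genes), silent)
  allelic <- NULL
  if (spec$snps_per_gene > 0 && length(expressed_idx) > 0) {
    snp_pos <- lapply(expressed_idx, function(i) {
      genes$start[i] + sort(sample.int(gene_len, spec$snps_per_gene))
    })
    al <- tidyr::expand_grid(ei = seq_along(expressed_idx),
                             k = seq_len(spec$snps_per_gene),
                             sample = samples)
    al <- al[runif(nrow(al)) < spec$het_site_prob, , drop = FALSE]
    gi <- expressed_idx[al$ei]
    al$gene_id <- genes$gene_id[gi]
    al$chrom <- genes$chrom[gi]
    al$pos <- as.integer(mapply(function(e, k) snp_pos[[e]][k], al$ei, al$k))
    tot <- spec$allelic_depth
    al$ref_count <- stats::rbinom(nrow(al), tot, 0.5)
    al$alt_count <- tot - al$ref_count
    allelic <- al[c("sample", "gene_id", "chrom", "pos",
                    "ref_count", "alt_count")]
  }

  breakends <- tibble(sample = character(0), chrom_a = character(0),
                      pos_a = integer(0), side_a = character(0),
                      chrom_b = character(0), pos_b = integer(0),
                      side_b = character(0), sv_class = character(0))
  cna <- NULL
  truth <- tibble(gene_id = character(0), sample = character(0),
                  class = character(0))

  # --- injected hijack events -----------------------------------------------
  if (spec$n_hijack_events > 0) {
    hijack_genes <- sample_vec(silent, spec$n_hijack_events)
    hijack_samples <- sample_vec(samples, spec$n_hijack_events, replace = TRUE)
    donors <- sample_vec(donor_tads, spec$n_hijack_events)
    for (e in seq_len(spec$n_hijack_events)) {
      gi <- hijack_genes[e]; s <- hijack_samples[e]; d <- donors[e]
      tpm[gi, s] <- runif(1, spec$hijack_tpm_range[1], spec$hijack_tpm_range[2])
      # donor enhancer, strong, inside the donor TAD
      e_start <- floor(runif(1, tads$start[d] + m, tads$end[d] - m - 5e4))
      enhancers <- bind_rows(enhancers, tibble(
        chrom = tads$chrom[d], start = e_start, end = e_start + 5e3,
        enrichment = runif(1, spec$hijack_enhancer_min,
                           2 * spec$hijack_enhancer_min)))
      # junction: gene-side end keeps the gene (left flank retained), donor
      # end keeps the enhancer on its left flank
      pos_a <- as.integer(genes$end[gi] + floor(runif(1, 1e4, 5e4)))
      pos_b <- as.integer(e_start + 5e3 + floor(runif(1, 5e3, 2e4)))
      breakends <- bind_rows(breakends, tibble(
        sample = s, chrom_a = genes$chrom[gi], pos_a = pos_a, side_a = "left",
        chrom_b = tads$chrom[d], pos_b = pos_b, side_b = "left",
        sv_class = "translocation"))
      # monoallelic allelic counts at the activated gene
      if (spec$snps_per_gene > 0) {
        pos <- genes$start[gi] + sort(sample.int(gene_len, spec$snps_per_gene))
        major <- stats::rbinom(spec$snps_per_gene, spec$allelic_depth,
                               spec$mono_fraction)
        ref_major <- runif(spec$snps_per_gene) < 0.5
        allelic <- bind_rows(allelic, tibble(
          sample = s, gene_id = genes$gene_id[gi], chrom = genes$chrom[gi],
          pos = as.integer(pos),
          ref_count = ifelse(ref_major, major, spec$allelic_depth - major),
          alt_count = ifelse(ref_major, spec$allelic_depth - major, major)))
      }
      truth <- bind_rows(truth, tibble(gene_id = genes$gene_id[gi],
                                       sample = s, class = "hijack"))
    }
  } else {
    hijack_genes <- integer(0)
  }

  # --- amplification decoys -------------------------------------------------
  free_genes <- setdiff(seq_len(spec$n_genes), hijack_genes)
  if (spec$n_amplification_decoys > 0) {
    amp_genes <- sample_vec(intersect(free_genes, expressed_idx),
                            spec$n_amplification_decoys)
    amp_samples <- sample_vec(samples, spec$n_amplification_decoys,
                              replace = TRUE)
    for (e in seq_len(spec$n_amplification_decoys)) {
      gi <- amp_genes[e]; s <- amp_samples[e]; td <- gene_tad[gi]
      tpm[gi, s] <- tpm[gi, s] * spec$amp_fold
      seg_start <- tads$start[td] + m
      seg_end <- tads$end[td] - m
      cna <- bind_rows(cna, tibble(sample = s, chrom = tads$chrom[td],
                                   start = seg_start, end = seg_end,
                                   copy_number = spec$amp_cn))
      truth <- bind_rows(truth, tibble(gene_id = genes$gene_id[gi],
                                       sample = s, class = "amplification"))
    }
    free_genes <- setdiff(free_genes, amp_genes)
  }

  # --- breakpoint decoys: recurrent loci, expression unchanged --------------
  if (spec$n_breakpoint_decoys > 0) {
    if (spec$n_breakpoint_decoys > length(free_genes)) {
      stopf("infeasible spec: not enough genes left for breakpoint decoys")
    }
    decoy_genes <- sample_vec(free_genes, spec$n_breakpoint_decoys)
    for (gi in decoy_genes) {
      td <- gene_tad[gi]
      n_rec <- sample.int(3, 1)
      for (s in sample_vec(samples, n_rec)) {
        p <- sort(floor(runif(2, tads$start[td] + m, tads$end[td] - m)))
        breakends <- bind_rows(breakends, tibble(
          sample = s, chrom_a = tads$chrom[td], pos_a = as.integer(p[1]),
          side_a = sample(c("left", "right"), 1),
          chrom_b = tads$chrom[td], pos_b = as.integer(p[2]),
          side_b = sample(c("left", "right"), 1), sv_class = "inversion"))
        truth <- bind_rows(truth, tibble(gene_id = genes$gene_id[gi],
                                         sample = s, class = "breakpoint"))
      }
    }
  }

  expression <- bind_cols(tibble(gene_id = genes$gene_id),
                          as_tibble(round(tpm, 4)))
  cohort <- cohort_bundle(
    expression = expression,
    breakends = breakends,
    genes = genes,
    cna = cna,
    allelic = allelic,
    tads = tads,
    enhancers = enhancers[c("chrom", "start", "end", "enrichment")],
    config = config
  )
  list(cohort = cohort, truth = truth)
}

#' Write a cohort to input files
#'
#' Writes every table of the cohort in the dialects the readers (and the CLI)
#' consume; optional tables that are absent are not written.
#'
#' @param cohort A `hijack_cohort`.
#' @param dir Output directory (created if missing).
#' @return Named list of the file paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hijack_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    expression = write_expression(cohort$expression,
                                  file.path(dir, "expression.tsv")),
    breakends = write_breakends(cohort$breakends,
                                file.path(dir, "breakends.tsv")),
    genes = write_gene_annotation(cohort$genes, file.path(dir, "genes.tsv"))
  )
  if (!is.null(cohort$cna)) {
    paths$cna <- write_cna(cohort$cna, file.path(dir, "cna.tsv"))
  }
  if (!is.null(cohort$allelic)) {
    paths$allelic <- write_allelic_counts(cohort$allelic,
                                          file.path(dir, "allelic.tsv"))
  }
  if (!is.null(cohort$tads)) {
    paths$tads <- write_tads(cohort$tads, file.path(dir, "tads.bed"))
  }
  if (!is.null(cohort$enhancers)) {
    paths$enhancers <- write_enhancers(cohort$enhancers,
                                       file.path(dir, "enhancers.bed"))
  }
  if (!is.null(cohort$fusions)) {
    paths$fusions <- write_fusions(cohort$fusions,
                                   file.path(dir, "fusions.tsv"))
  }
  imprinted <- cohort$genes$gene_id[cohort$genes$is_imprinted]
  if (length(imprinted) > 0) {
    paths$imprinted <- write_imprinted(imprinted,
                                       file.path(dir, "imprinted.txt"))
  }
  invisible(paths)
}
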