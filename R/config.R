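#' Analysis configuration
#'
#' Bundles every tunable parameter of the detector. The component weights
#' follow the published defaults of the combined score
#' \eqn{S = \omega_{ovx} S_{ovx} + \omega_{ase} S_{ase} + \omega_{enh} S_{enh}
#' - \omega_{del} 1_{del}}.
#'
#' @param w_overexpression Weight of the overexpression score (default 4).
#' @param w_ase Weight of the allele-specific expression score (default 2).
#' @param w_enhancer Weight of the hijacked-enhancer score (default 1).
#' @param w_deletion Weight of the deletion penalty (default 1).
#' @param niter Number of null resampling iterations (default 50).
#' @param tad_extension_bp Extension added to each side of a TAD when testing
#'   breakpoint membership, in bp (default 80000). Guards against imprecise
#'   TAD boundary calls.
#' @param fallback_window_bp Half-width of the gene-centred search window used
#'   when no TAD list is supplied, and the cap on enhancer traversal when no
#'   TAD boundary bounds it (default 1.5e6).
#' @param min_tpm_expressed A gene is considered expressed when its TPM exceeds
#'   this value (strictly) in at least one sample (default 1).
#' @param sigma_floor Additive floor on the reference standard deviation in
#'   \eqn{t = (E - \mu)/(\sigma + \mathrm{floor})} (default 0.3); prevents
#'   runaway t when all reference samples agree.
#' @param ase_cn_low,ase_cn_high ASE gating bounds: the ASE score is forced to
#'   0 when the gene copy number is below `ase_cn_low` (default 2) or above
#'   `ase_cn_high` (default 4), where allelic balance is uninformative.
#' @param bb_concentration Concentration \eqn{s} of the beta-binomial allelic
#'   model (\eqn{\alpha = ps}, \eqn{\beta = (1-p)s}; default 10).
#' @param mono_means Means of the two monoallelic mixture components
#'   (default `c(0.02, 0.98)`); must be symmetric about 0.5.
#' @param bi_mean Mean of the biallelic component (default 0.5).
#' @param llr_clamp Per-SNP log-likelihood ratios are clamped to
#'   `[-llr_clamp, llr_clamp]` (default 20) so a single ultra-deep SNP cannot
#'   dominate a gene's score.
#' @param deletion_cn_threshold A gene counts as deleted in a sample when its
#'   copy number falls below this value (default 1.5).
#' @param min_reference_samples Minimum number of reference samples required
#'   to score a gene (default 5); fewer make \eqn{\mu}/\eqn{\sigma} unstable.
#' @param rng_seed Master seed for the null resampling (default 1).
#'
#' @return A list of class `hijack_config`.
#' @export
#' @examples
#' cfg <- hijack_config(niter = 20)
#' cfg$w_overexpression
hijack_config <- function(w_overexpression = 4,
                          w_ase = 2,
                          w_enhancer = 1,
                          w_deletion = 1,
                          niter = 50,
                          tad_extension_bp = 80000,
                          fallback_window_bp = 1500000,
                          min_tpm_expressed = 1,
                          sigma_floor = 0.3,
                          ase_cn_low = 2,
                          ase_cn_high = 4,
                          bb_concentration = 10,
                          mono_means = c(0.02, 0.98),
                          bi_mean = 0.5,
                          llr_clamp = 20,
                          deletion_cn_threshold = 1.5,
                          min_reference_samples = 5,
                          rng_seed = 1) {
  cfg <- list(
    w_overexpression = w_overexpression, w_ase = w_ase,
    w_enhancer = w_enhancer, w_deletion = w_deletion,
    niter = as.integer(niter),
    tad_extension_bp = tad_extension_bp,
    fallback_window_bp = fallback_window_bp,
    min_tpm_expressed = min_tpm_expressed,
    sigma_floor = sigma_floor,
    ase_cn_low = ase_cn_low, ase_cn_high = ase_cn_high,
    bb_concentration = bb_concentration,
    mono_means = sort(mono_means), bi_mean = bi_mean,
    llr_clamp = llr_clamp,
    deletion_cn_threshold = deletion_cn_threshold,
    min_reference_samples = as.integer(min_reference_samples),
    rng_seed = as.integer(rng_seed)
  )
  validate_hijack_config(cfg)
  structure(cfg, class = "hijack_config")
}

validate_hijack_config <- function(cfg) {
  w <- c(cfg$w_overexpression, cfg$w_ase, cfg$w_enhancer, cfg$w_deletion)
  if (any(w < 0)) stopf("all component weights must be >= 0")
  if (cfg$niter < 1) stopf("niter must be >= 1")
  if (cfg$tad_extension_bp < 0 || cfg$fallback_window_bp <= 0) {
    stopf("search windows must be positive")
  }
  if (length(cfg$mono_means) != 2 ||
      abs(sum(cfg$mono_means) - 1) > 1e-8) {
    stopf("mono_means must be two values symmetric about 0.5")
  }
  if (cfg$bb_concentration <= 0) stopf("bb_concentration must be > 0")
  if (cfg$llr_clamp <= 0) stopf("llr_clamp must be > 0")
  if (cfg$min_reference_samples < 1) stopf("min_reference_samples must be >= 1")
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' Keys mirror the arguments of [hijack_config()]; missing keys keep their
#' defaults, unknown keys raise an error.
#'
#' @param path Path to a YAML file.
#' @return A `hijack_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(hijack_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(hijack_config, vals)
}

#' @export
print.hijack_config <- function(x, ...) {
  cat("<hijack_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
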