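# Internal helpers: chromosome-name normalization, logging, beta-binomial pmf.

#' @importFrom rlang .data abort warn inform %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Log levels, lowest = most verbose
.log_levels <- c(DEBUG = 10L, INFO = 20L, WARNING = 30L, ERROR = 40L)

hj_log_threshold <- function() {
  lvl <- getOption("hijackr.log_level", "INFO")
  .log_levels[[match.arg(toupper(lvl), names(.log_levels))]]
}

hj_log <- function(level, ...) {
  if (.log_levels[[level]] >= hj_log_threshold()) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix (any case) and upper-cases the sex and
#' mitochondrial chromosomes so that mixed-reference inputs (`"chr7"` vs `"7"`,
#' `"chrx"` vs `"X"`) compare equal everywhere downstream.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_chrom(c("chr7", "7", "chrX", "mt"))
normalize_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  low <- tolower(x)
  x[low == "x"] <- "X"
  x[low == "y"] <- "Y"
  x[low %in% c("mt", "m")] <- "MT"
  if (any(!nzchar(x))) abort("empty chromosome name after normalization")
  x
}

# Beta-binomial log-pmf, mean/concentration parameterization:
# alpha = mean * conc, beta = (1 - mean) * conc. Vectorized over k, n.
dbetabinom_log <- function(k, n, mean, conc) {
  a <- mean * conc
  b <- (1 - mean) * conc
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

# log(exp(a) + exp(b)) without overflow, vectorized
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

# Population standard deviation (divisor n, not n - 1)
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

stopf <- function(...) abort(sprintf(...))
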