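#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows bind_cols n row_number across case_when distinct pull
#'   rename if_else first
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rbinom rbeta rnorm runif median sd ks.test chisq.test
#'   setNames
NULL

#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention used for the printed
#' missingness percentages and percentile tables), unlike [base::round()]'s
#' banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.345, 2.5, 4.165), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# normalise chromosome labels: strip "chr" prefix, uppercase X/Y/MT
norm_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  toupper(x)
}

is_sex_chrom <- function(chrom) norm_chrom(chrom) %in% c("X", "Y")

# key used for positional joins
site_key <- function(chrom, pos) paste(norm_chrom(chrom), pos, sep = ":")

valid_allele <- function(a) {
  !is.na(a) & grepl("^[ACGT]+$", a)
}

`%not_in%` <- function(x, y) !x %in% y

# Run code with a seed when one is given, otherwise use the ambient RNG state.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
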