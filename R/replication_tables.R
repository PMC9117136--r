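# Published validation data shipped with the package.

#' Published replication 2x2 tables
#'
#' High-risk-PRS-by-disease contingency tables from a large biobank
#' replication of six disease scores (breast, colorectal and prostate
#' cancer, atrial fibrillation, coronary artery disease, type 2 diabetes),
#' overall and stratified by reported race. Each row carries the cell
#' counts (a = high-risk cases, b = high-risk controls, c = other cases,
#' d = other controls) and the odds ratio and 95\% CI as printed in the
#' source publication, at its printed precision. The Asian colorectal
#' cancer stratum is degenerate (zero high-risk cases), printed as OR 0
#' with an undefined interval.
#'
#' These tables are the fixed input for verifying that
#' \code{\link{odds_ratio_ci}} (Woolf interval) reproduces the published
#' intervals.
#'
#' @return data.frame with columns \code{disease}, \code{stratum},
#'   \code{a}, \code{b}, \code{c}, \code{d}, \code{or_printed},
#'   \code{ci_lo_printed}, \code{ci_hi_printed}.
#' @export
replication_tables <- function() {
  path <- system.file("extdata", "replication_2x2_tables.tsv",
                      package = "prsassay", mustWork = TRUE)
  tab <- .read_tsv(path)
  tab$or_printed <- as.character(tab$or_printed)
  tab$ci_lo_printed <- as.character(tab$ci_lo_printed)
  tab$ci_hi_printed <- as.character(tab$ci_hi_printed)
  tab
}

# Round half up at the number of decimals a printed value displays, then
# format at that precision; used to compare computed statistics with their
# printed renderings.
.printed_decimals <- function(x) {
  dot <- regexpr(".", x, fixed = TRUE)
  ifelse(dot < 0, 0L, nchar(x) - dot)
}

#' Format a number the way a printed table would
#'
#' Half-up rounding at the same number of decimals as the printed string,
#' so computed values can be compared with published renderings exactly.
#'
#' @param value numeric value.
#' @param printed the printed string whose precision to match.
#' @return character rendering of \code{value} at that precision.
#' @export
format_like_printed <- function(value, printed) {
  digits <- .printed_decimals(printed)
  scaled <- value * 10^digits
  rounded <- floor(scaled + 0.5) / 10^digits  # half-up, as tables print
  formatC(rounded, format = "f", digits = digits)
}
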