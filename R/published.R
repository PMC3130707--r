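#' Published score / p-value reference pairs
#'
#' The 163 (integer score, p-value) pairs printed in the large-scale
#' microRNAome target-network survey this package models: 156 from its
#' large-network table (52 miRNAs x pathway/disease/pathological event) and
#' 7 from its results text. They pin the reporting transform: in all but a
#' handful of typographically inconsistent rows,
#' `round_half_up(score_transform(p))` reproduces the printed score.
#' P-values are kept as the printed strings so tests can reason about the
#' printed precision.
#'
#' @return data frame with columns `mirna`, `category`, `network`, `score`
#'   (integer as printed), `p_value` (character as printed), `source`
#'   (`"table1"` or `"results_text"`).
#' @export
published_scores <- function() {
  path <- system.file("extdata", "published_scores.tsv", package = "mirnet",
                      mustWork = TRUE)
  df <- utils::read.delim(path, colClasses = "character")
  df$score <- as.integer(df$score)
  df
}

#' Published cohort attrition counts
#'
#' Stage counts of the published microRNAome survey: 1,223 miRNAs examined,
#' 532 with any predicted target, 273 with reliable (score >= 20) targets,
#' 232 with an extractable molecular network.
#'
#' @return data frame with columns `stage`, `n`.
#' @export
published_attrition <- function() {
  path <- system.file("extdata", "published_attrition.tsv",
                      package = "mirnet", mustWork = TRUE)
  utils::read.delim(path)
}

#' Interval of p-values compatible with a printed value
#'
#' A p-value printed with a fixed number of significant digits (e.g.
#' `"2.69E-179"`) stands for any true value in its rounding interval. Used
#' to decide whether a printed (score, p) pair is internally consistent: the
#' pair is feasible iff some p in the interval maps to the printed score.
#'
#' @param p_printed character vector of p-values in `mE+x` notation.
#' @return data frame with columns `lower`, `upper` (half-open interval).
#' @export
printed_p_interval <- function(p_printed) {
  mant_str <- sub("[eE].*$", "", p_printed)
  expo <- as.numeric(sub("^.*[eE]", "", p_printed))
  mant <- as.numeric(mant_str)
  n_digits <- nchar(gsub("[^0-9]", "", mant_str))
  half_ulp <- 0.5 * 10^-(n_digits - 1)
  data.frame(lower = (mant - half_ulp) * 10^expo,
             upper = (mant + half_ulp) * 10^expo)
}
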