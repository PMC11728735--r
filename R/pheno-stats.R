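#' Phenotype distribution summary for BSA suitability
#'
#' Descriptive statistics of a trait vector: max, min, mean, sample SD,
#' skewness and excess kurtosis by the adjusted Fisher-Pearson sample
#' formulas, and a suitability flag. A trait distribution is considered
#' suitable for bulk-segregant QTL mapping when both |skewness| and
#' |kurtosis| are below 1, i.e. it approximates a normal distribution.
#'
#' @param values Numeric trait measurements (length >= 4, not constant).
#' @param year Optional label for the replicate/year.
#' @param type Kurtosis/skewness flavor: `"adjusted"` (Fisher-Pearson
#'   sample statistics, the default) or `"moment"` (raw moment ratios,
#'   excess kurtosis).
#' @return One-row data frame: `year`, `n`, `max`, `min`, `mean`, `sd`,
#'   `kurtosis`, `skewness`, `suitable`.
#' @examples
#' pheno_summary(rnorm(85, 8, 2), year = "2020")
#' @export
pheno_summary <- function(values, year = NA_character_,
                          type = c("adjusted", "moment")) {
  type <- match.arg(type)
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing trait values")
  if (length(values) < 4L)
    stop("at least 4 values are needed (kurtosis undefined below n = 4)")
  if (max(values) == min(values))
    stop("constant trait vector: skewness and kurtosis undefined")
  e_type <- if (type == "adjusted") 2L else 1L
  sk <- e1071::skewness(values, type = e_type)
  ku <- e1071::kurtosis(values, type = e_type)
  data.frame(year = year, n = length(values),
             max = max(values), min = min(values),
             mean = mean(values), sd = stats::sd(values),
             kurtosis = ku, skewness = sk,
             suitable = abs(sk) < 1 && abs(ku) < 1,
             stringsAsFactors = FALSE)
}

#' Per-year phenotype summary table
#'
#' Applies [pheno_summary()] to each year of a long-format phenotype table.
#'
#' @param phenotypes Data frame with columns `id`, `year`, `trait`
#'   (see [read_phenotypes()]).
#' @param ... Passed to [pheno_summary()].
#' @return Data frame with one summary row per year.
#' @export
pheno_table <- function(phenotypes, ...) {
  stopifnot(all(c("year", "trait") %in% names(phenotypes)))
  years <- unique(phenotypes$year)
  do.call(rbind, lapply(years, function(y)
    pheno_summary(phenotypes$trait[phenotypes$year == y], year = y, ...)))
}
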