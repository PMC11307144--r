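#' Pearson chi-square test of independence on a contingency table
#'
#' Expected counts come from the table margins; df = (r-1)(c-1); the
#' two-sided p-value is the chi-square upper tail. With `continuity = TRUE`
#' and a 2x2 table, |O - E| is reduced by 0.5 before squaring (Yates).
#' Continuity correction is only defined for 2x2 tables.
#'
#' The convention pair used by [makeTable1()] — Yates correction for 2x2
#' tables, none for larger ones — is reverse-engineered from the printed
#' descriptive statistics it reproduces; the test functions of the source
#' analyses are not named anywhere.
#'
#' @param table matrix of non-negative integer counts, >= 2 rows (groups)
#'   and >= 2 columns (category levels).
#' @param continuity apply the Yates continuity correction (2x2 only).
#' @return list with `statistic`, `df`, `p.value` and `expected`.
#' @export
chisqIndependence <- function(table, continuity = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  if (continuity && !(nrow(table) == 2 && ncol(table) == 2))
    stop("continuity correction applies only to 2 x 2 tables")
  res <- suppressWarnings(stats::chisq.test(table, correct = continuity))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value, expected = res$expected)
}

#' Two-sample t-test from group summary statistics
#'
#' Works from per-group n, mean and SD only, so Table-1-style rows can be
#' tested without raw data. With `equalVariance = TRUE` the pooled-variance
#' statistic with df = n1 + n2 - 2 is used; otherwise the Welch statistic
#' with Satterthwaite df.
#'
#' Degenerate input conventions: both SDs zero with equal means gives
#' p = 1; both SDs zero with different means gives p = 0 with a warning.
#'
#' @param mean1,sd1,n1 first group summary (n >= 2, sd >= 0).
#' @param mean2,sd2,n2 second group summary.
#' @param equalVariance pooled (TRUE) or Welch (FALSE) statistic.
#' @return list with `t`, `df` and `p.value` (two-sided).
#' @export
tTestFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2,
                             equalVariance = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p.value = 1))
    warning("both SDs zero with different means; p = 0 by convention")
    return(list(t = Inf, df = n1 + n2 - 2, p.value = 0))
  }
  if (equalVariance) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se1 <- sd1^2 / n1; se2 <- sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se1 + se2)
    df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  }
  list(t = t, df = df, p.value = 2 * stats::pt(-abs(t), df))
}

#' Table-1-style descriptive comparison of responders and nonresponders
#'
#' Summarizes continuous variables as mean (SD) with a pooled two-sample
#' t-test and categorical variables as n (%) with a chi-square test (Yates
#' continuity correction for 2x2 tables, none otherwise). Indeterminate
#' samples are excluded. Percentages are reported to one decimal place.
#'
#' @param metadata data.frame with a `response` factor (see
#'   [labelResponse()]) and the variables to summarize.
#' @param continuous character vector of continuous variable names present
#'   in `metadata`.
#' @param categorical character vector of categorical variable names.
#' @return data.frame with one row per variable level: columns `variable`,
#'   `level`, `nonresponder`, `responder`, `p.value` (p on the first row
#'   of each variable only).
#' @export
makeTable1 <- function(metadata,
                       continuous = intersect(c("age", "os_months"),
                                              names(metadata)),
                       categorical = intersect(c("sex", "ici_class"),
                                               names(metadata))) {
  if (!"response" %in% names(metadata))
    stop("metadata lacks a 'response' column; run labelResponse() first")
  md <- metadata[metadata$response %in% c("nonresponder", "responder"), ,
                 drop = FALSE]
  md$response <- factor(as.character(md$response),
                        levels = c("nonresponder", "responder"))
  counts <- table(md$response)
  if (length(counts) < 2 || any(counts < 2))
    stop("each response group needs at least 2 samples")
  rows <- list()
  rows[[1]] <- data.frame(variable = "n", level = "",
                          nonresponder = as.character(counts["nonresponder"]),
                          responder = as.character(counts["responder"]),
                          p.value = NA_real_, stringsAsFactors = FALSE)
  for (v in continuous) {
    s <- lapply(split(md[[v]], md$response), function(x)
      c(n = length(x), mean = mean(x), sd = stats::sd(x)))
    tt <- tTestFromSummary(s$nonresponder["mean"], s$nonresponder["sd"],
                           s$nonresponder["n"],
                           s$responder["mean"], s$responder["sd"],
                           s$responder["n"], equalVariance = TRUE)
    fmt <- function(g) sprintf("%.2f (%.2f)", g["mean"], g["sd"])
    rows[[length(rows) + 1]] <- data.frame(
      variable = paste0(v, " [mean (SD)]"), level = "",
      nonresponder = fmt(s$nonresponder), responder = fmt(s$responder),
      p.value = tt$p.value, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    tab <- table(md$response, md[[v]])
    if (ncol(tab) < 2) {
      warning("variable '", v, "' has a single level; p = NA")
      p <- NA_real_
    } else {
      p <- chisqIndependence(tab,
                             continuity = ncol(tab) == 2)$p.value
    }
    for (k in seq_len(ncol(tab))) {
      pct <- sweep(tab, 1, rowSums(tab), "/") * 100
      rows[[length(rows) + 1]] <- data.frame(
        variable = if (k == 1) paste0(v, " [n (%)]") else "",
        level = colnames(tab)[k],
        nonresponder = sprintf("%d (%.1f)", tab["nonresponder", k],
                               pct["nonresponder", k]),
        responder = sprintf("%d (%.1f)", tab["responder", k],
                            pct["responder", k]),
        p.value = if (k == 1) p else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
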