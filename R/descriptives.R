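#' Descriptive city and group summaries
#'
#' Analogues of the survey's published descriptive tables: per-city sample
#' sizes, smoker prevalence and severity shares, and per-covariate-level
#' summaries with bivariate screening tests (chi-square on smoker status,
#' rank-sum / rank ANOVA on the counts).  A smoker is a respondent with
#' `y > 0` at interview.  The tests are reporting conveniences and never
#' gate the modeling stages.
#'
#' @name descriptives
NULL

#' @describeIn descriptives Per-city table: n, percent smokers, percent
#'   light/moderate/heavy (of all respondents in the city), mean and SD of
#'   the daily count; final row `Total` pools all cities.
#' @param data data frame with `y` and `city_id`.
#' @export
city_summary <- function(data) {
  stopifnot(nrow(data) > 0)
  one <- function(y) {
    sev <- severity(y)
    data.frame(n = length(y),
               pct_smoker = 100 * mean(y > 0),
               pct_light = 100 * mean(sev == "light"),
               pct_moderate = 100 * mean(sev == "moderate"),
               pct_heavy = 100 * mean(sev == "heavy"),
               mean = mean(y), sd = if (length(y) > 1) sd(y) else NA_real_)
  }
  parts <- lapply(split(data$y, data$city_id), one)
  out <- cbind(city = names(parts), do.call(rbind, parts))
  out <- rbind(out, cbind(city = "Total", one(data$y)))
  rownames(out) <- NULL
  out
}

#' @describeIn descriptives Per-covariate-level table: n (%), mean (SD) of
#'   the count, smoker / non-smoker split, chi-square p for smoker status
#'   by level, and Mann--Whitney (2 levels) or Kruskal--Wallis (>2) p for
#'   the counts.  Levels with zero observations are dropped with a warning.
#' @param covariates covariate columns to summarize (default: the coded
#'   survey covariates present in `data`).
#' @export
group_summary <- function(data,
                          covariates = intersect(names(dscs_coding()),
                                                 names(data))) {
  stopifnot(nrow(data) > 0)
  y <- data$y
  smoker <- factor(y > 0, levels = c(FALSE, TRUE),
                   labels = c("non_smoker", "smoker"))
  rows <- list()
  for (v in covariates) {
    f <- factor(as.character(data[[v]]),
                levels = if (v %in% names(dscs_coding()))
                  dscs_coding(v)[[1]] else unique(data[[v]]))
    empty <- levels(f)[tabulate(f, length(levels(f))) == 0L]
    if (length(empty)) {
      warning("dropping empty level(s) of '", v, "': ",
              paste(empty, collapse = ", "), call. = FALSE)
      f <- droplevels(f)
    }
    # Pearson chi-square without Yates continuity correction (the survey's
    # published 2x2 p-values follow the uncorrected statistic)
    p_chi <- tryCatch(
      suppressWarnings(chisq.test(table(smoker, f),
                                  correct = FALSE)$p.value),
      error = function(e) NA_real_)
    p_rank <- if (nlevels(f) == 2L)
      suppressWarnings(wilcox.test(y ~ f)$p.value)
    else tryCatch(kruskal.test(y ~ f)$p.value, error = function(e) NA_real_)
    for (lev in levels(f)) {
      sel <- f == lev
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev, n = sum(sel),
        pct = 100 * mean(sel),
        mean = mean(y[sel]), sd = if (sum(sel) > 1) sd(y[sel]) else NA,
        non_smoker = sum(sel & smoker == "non_smoker"),
        smoker = sum(sel & smoker == "smoker"),
        p_chisq = p_chi, p_rank = p_rank)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @describeIn descriptives Overdispersion screen: sample variance of the
#'   count divided by its sample mean.  All-zero data have no defined
#'   ratio and return `NA` with a warning.
#' @export
variance_mean_ratio <- function(data) {
  y <- if (is.data.frame(data)) data$y else data
  stopifnot(length(y) > 0)
  if (all(y == 0)) {
    warning("all counts are zero; variance/mean ratio undefined",
            call. = FALSE)
    return(NA_real_)
  }
  var(y) / mean(y)
}
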