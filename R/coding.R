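#' Covariate coding of the DSCS analysis
#'
#' All covariates are categorical and enter the model with treatment
#' (reference-level) coding.  Reference categories follow the survey
#' analysis: age <=20, female, underweight, married, illiterate,
#' unemployed/student, rural, and "No" for every binary history/habit.
#' With all twelve covariates this yields 23 dummy columns plus an
#' intercept, i.e. 24 fixed effects per model part.
#'
#' @param covariates character vector of covariate names to include;
#'   defaults to all twelve.
#' @return Named list mapping covariate name to its ordered level vector
#'   (reference level first).
#' @export
dscs_coding <- function(covariates = NULL) {
  lv <- lapply(dscs_covariate_counts(), names)
  if (!is.null(covariates)) {
    bad <- setdiff(covariates, names(lv))
    if (length(bad))
      stop("unknown covariates: ", paste(bad, collapse = ", "),
           call. = FALSE)
    lv <- lv[covariates]
  }
  lv
}

#' Build a treatment-coded design matrix
#'
#' @param data data frame holding the covariate columns as characters or
#'   factors.
#' @param coding output of [dscs_coding()] (possibly a subset); an empty
#'   list yields an intercept-only design.
#' @return Numeric matrix, intercept first, one dummy column per
#'   non-reference level named `<covariate><level>`.
#' @export
build_design <- function(data, coding) {
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (v in names(coding)) {
    if (!v %in% names(data))
      stop("data lacks covariate column '", v, "'", call. = FALSE)
    f <- factor(as.character(data[[v]]), levels = coding[[v]])
    if (anyNA(f))
      stop("covariate '", v, "' has values outside its coding", call. = FALSE)
    for (lev in coding[[v]][-1])
      X <- cbind(X, `colnames<-`(matrix(as.numeric(f == lev), n, 1),
                                 paste0(v, lev)))
  }
  X
}

#' Model specification for a two-level count fit
#'
#' @param family count family: `"poisson"`, `"negbin"` or `"cmp"`.
#' @param zero_inflated logical; add the structural-zero mixture part?
#' @param count_covariates,zero_covariates covariate names for each part
#'   (defaults: all twelve survey covariates; the zero part exists only for
#'   zero-inflated models).
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("poisson", "negbin", "cmp"),
                       zero_inflated = FALSE,
                       count_covariates = names(dscs_coding()),
                       zero_covariates = count_covariates) {
  family <- match.arg(family)
  structure(list(family = family, zero_inflated = isTRUE(zero_inflated),
                 count_covariates = count_covariates,
                 zero_covariates = if (isTRUE(zero_inflated))
                   zero_covariates else character(0)),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  paste0("TL-", if (x$zero_inflated) "ZI" else "",
         switch(x$family, poisson = "P", negbin = "NB", cmp = "CMP"))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(format(x), "two-level model:", x$family,
      if (x$zero_inflated) "(zero-inflated)" else "", "\n")
  invisible(x)
}
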