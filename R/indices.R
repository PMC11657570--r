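#' Goodness-of-fit indices, model ranking and effect tables
#'
#' The comparison machinery behind the model-selection and effect-reporting
#' stages: deviance `D = -2 LL`, `AIC = -2 LL + 2 P`,
#' `BIC = -2 LL + P log(n)` with `n` the number of observations (not
#' clusters), mean squared error of the fitted means, per-index rankings,
#' and odds-ratio / rate-ratio tables (`OR = exp(alpha_k)`,
#' `RR = exp(beta_k)`, reference rows exactly 1).
#'
#' @name model_selection
NULL

#' @describeIn model_selection Index identities from a log-likelihood,
#'   parameter count and sample size alone.
#' @param LL log-likelihood; @param P parameter count; @param n sample size.
#' @export
index_from_ll <- function(LL, P, n) {
  list(D = -2 * LL, AIC = -2 * LL + 2 * P, BIC = -2 * LL + P * log(n))
}

#' @describeIn model_selection Full index row for a fitted model.  MSE uses
#'   conditional fitted means at the per-cluster empirical-Bayes modes by
#'   default; `mse_type = "marginal"` plugs in `w = u = 0` instead.
#' @param fit a [fit_model()] result.
#' @param mse_type `"conditional"` (empirical-Bayes modes) or `"marginal"`.
#' @export
fit_indices <- function(fit, mse_type = c("conditional", "marginal")) {
  stopifnot(inherits(fit, "tl_fit"))
  mse_type <- match.arg(mse_type)
  prep <- fit$prep; spec <- fit$spec
  idx <- index_from_ll(fit$loglik, fit$n_params, fit$n)
  yhat <- numeric(fit$n)
  for (k in seq_along(prep$cluster)) {
    rows <- prep$cluster[[k]]
    wk <- if (mse_type == "conditional") fit$eb_modes[k, "w"] else 0
    uk <- if (mse_type == "conditional") fit$eb_modes[k, "u"] else 0
    if (is.na(wk)) wk <- 0
    if (is.na(uk)) uk <- 0
    eta <- drop(prep$Xc[rows, , drop = FALSE] %*% fit$beta) + uk
    phi <- if (spec$zero_inflated)
      stats::plogis(drop(prep$Xz[rows, , drop = FALSE] %*% fit$alpha) + wk)
    else 0
    yhat[rows] <- fitted_mean(phi, eta, spec$family, fit$dispersion)
  }
  mse <- mean((prep$y - yhat)^2)
  data.frame(model = format(fit$spec), P = fit$n_params, LL = fit$loglik,
             D = idx$D, AIC = idx$AIC, BIC = idx$BIC, MSE = mse,
             dispersion = if (is.null(fit$dispersion)) NA_real_
             else fit$dispersion,
             n = fit$n, converged = fit$converged)
}

#' @describeIn model_selection Rank fitted models per index and pick an
#'   overall winner by AIC with BIC tiebreak.  All rows must describe fits
#'   on the same data (`n` must agree).  Disagreements between the
#'   index-wise winners are flagged in the `notes` attribute.
#' @param indices data frame of [fit_indices()] rows.
#' @export
rank_models <- function(indices) {
  stopifnot(is.data.frame(indices), nrow(indices) >= 1)
  if (length(unique(indices$n)) != 1L)
    stop("models were fitted on different datasets (n differs)",
         call. = FALSE)
  rk <- data.frame(model = indices$model,
                   rank_LL = rank(-indices$LL, ties.method = "min"),
                   rank_D = rank(indices$D, ties.method = "min"),
                   rank_AIC = rank(indices$AIC, ties.method = "min"),
                   rank_BIC = rank(indices$BIC, ties.method = "min"),
                   rank_MSE = rank(indices$MSE, ties.method = "min"))
  ord <- order(indices$AIC, indices$BIC)
  winner <- indices$model[ord[1]]
  tie <- sum(indices$AIC == min(indices$AIC)) > 1L
  perindex <- vapply(c("rank_LL", "rank_D", "rank_AIC", "rank_BIC",
                       "rank_MSE"),
                     function(cn) rk$model[which.min(rk[[cn]])],
                     character(1))
  notes <- character(0)
  if (tie) notes <- c(notes, "AIC tie broken by BIC")
  if (length(unique(perindex)) > 1L)
    notes <- c(notes, paste0("index disagreement: ",
      paste(names(perindex), perindex, sep = "=", collapse = ", ")))
  structure(list(ranking = rk[order(rk$rank_AIC), ], winner = winner,
                 notes = notes, indices = indices[ord, ]),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  print(x$ranking, row.names = FALSE)
  cat("winner (AIC, BIC tiebreak):", x$winner, "\n")
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}

#' @describeIn model_selection Two-part effect table: per covariate level
#'   the zero-part and count-part estimates with SEs and significance
#'   tiers, `OR = exp(zero estimate)`, `RR = exp(count estimate)`;
#'   reference rows carry OR = RR = 1 exactly.
#' @param se optional precomputed [standard_errors()] output.
#' @export
effect_table <- function(fit, se = NULL) {
  stopifnot(inherits(fit, "tl_fit"))
  if (!fit$spec$zero_inflated)
    stop("effect_table needs a zero-inflated (two-part) fit", call. = FALSE)
  if (is.null(se)) se <- standard_errors(fit)
  covs <- union(fit$spec$zero_covariates, fit$spec$count_covariates)
  coding <- dscs_coding(covs)
  rows <- list()
  pick <- function(part, nm) {
    i <- match(paste0(part, ".", nm), se$parameter)
    if (is.na(i)) list(est = NA_real_, se = NA_real_, sig = "")
    else list(est = se$estimate[i], se = se$se[i], sig = se$sig[i])
  }
  for (v in names(coding)) {
    for (lev in coding[[v]]) {
      ref <- lev == coding[[v]][1]
      nm <- paste0(v, lev)
      zz <- if (ref) NULL else pick("zero", nm)
      cc <- if (ref) NULL else pick("count", nm)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev, reference = ref,
        zero_est = if (ref) NA_real_ else zz$est,
        zero_se = if (ref) NA_real_ else zz$se,
        zero_sig = if (ref) "" else zz$sig,
        count_est = if (ref) NA_real_ else cc$est,
        count_se = if (ref) NA_real_ else cc$se,
        count_sig = if (ref) "" else cc$sig,
        OR = if (ref) 1 else exp(zz$est),
        RR = if (ref) 1 else exp(cc$est))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("effect_table", "data.frame")
  out
}

#' @describeIn model_selection Percent-change phrasing for a rate ratio
#'   below one: `100 * (1 - RR)` percent lower.
#' @param rr rate ratio(s).
#' @export
pct_lower <- function(rr) 100 * (1 - rr)
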