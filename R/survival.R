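#' Elastic-net penalized Cox variable selection
#'
#' Fits a penalized Cox partial likelihood over a regularisation path with
#' equal ridge and lasso penalty weights (mixing 0.5) on standardized
#' covariates, chooses the penalty by cross-validated deviance minimum, and
#' returns the variables with a nonzero coefficient there. A factor counts
#' as selected if any of its contrasts is nonzero.
#'
#' @param covars Data frame of candidate covariates (numeric or factor; >= 2
#'   columns, none constant).
#' @param times,events Survival times and 0/1 event indicators (>= 10
#'   events).
#' @param alpha Elastic-net mixing (0 = ridge, 1 = lasso).
#' @param cv_folds Number of cross-validation folds.
#' @param seed Optional integer seed (fold assignment).
#' @param lambda Optional fixed penalty, bypassing cross-validation (0 gives
#'   the unpenalized limit, i.e. every variable selected; a very large value
#'   selects none).
#' @return Character vector of selected variable names; attributes `lambda`
#'   and `coef` carry the chosen penalty and coefficients.
#' @export
elastic_net_select <- function(covars, times, events, alpha = 0.5,
                               cv_folds = 5L, seed = NULL, lambda = NULL) {
  if (ncol(covars) < 2L) stop("need >= 2 candidate covariates")
  if (sum(events) < 10L) stop("need >= 10 events for variable selection")
  const <- vapply(covars, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(covars)[const], collapse = ", "))
  mm <- stats::model.matrix(~ ., data = covars)[, -1, drop = FALSE]
  assign_map <- attr(stats::model.matrix(~ ., data = covars), "assign")[-1]
  y <- survival::Surv(times, events)
  if (is.null(lambda)) {
    cf <- with_seed(seed, {
      foldid <- sample(rep_len(seq_len(cv_folds), nrow(mm)))
      cv <- glmnet::cv.glmnet(mm, y, family = "cox", alpha = alpha,
                              foldid = foldid, standardize = TRUE)
      list(coef = as.vector(coef(cv, s = "lambda.min")),
           lambda = cv$lambda.min)
    })
  } else {
    fit <- glmnet::glmnet(mm, y, family = "cox", alpha = alpha,
                          standardize = TRUE)
    cf <- list(coef = as.vector(coef(fit, s = lambda, exact = TRUE, x = mm,
                                     y = y, alpha = alpha,
                                     standardize = TRUE)),
               lambda = lambda)
  }
  nz <- which(abs(cf$coef) > 0)
  selected <- unique(names(covars)[assign_map[nz]])
  structure(selected, lambda = cf$lambda,
            coef = setNames(cf$coef, colnames(mm)))
}

#' Multivariable Cox proportional-hazards fit
#'
#' Maximum partial likelihood with Wald confidence intervals and p-values.
#' Ordinal ECOG performance status should be supplied as a factor so levels
#' are expanded against reference level 0.
#'
#' @param covars Data frame of covariates (no constant columns).
#' @param times,events Survival times and 0/1 event indicators; the number
#'   of events must be at least the number of model columns.
#' @param conf_level Confidence level for the hazard-ratio intervals.
#' @return An object of class `cox_result`: `table` (term, coef, HR, CI,
#'   p-value), `loglik`, `n`, `n_events`, and the underlying `coxph` fit.
#' @export
fit_cox <- function(covars, times, events, conf_level = 0.95) {
  const <- vapply(covars, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(covars)[const], collapse = ", "))
  df <- cbind(data.frame(.time = times, .event = events), covars)
  nterms <- ncol(stats::model.matrix(~ ., data = covars)) - 1L
  if (sum(events) < nterms)
    stop("fewer events (", sum(events), ") than model terms (", nterms, ")")
  warns <- character()
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = df),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  if (any(!is.finite(beta)) || any(grepl("converge|infinite", warns)))
    stop("Cox fit did not converge (possible separation): ",
         paste(unique(warns), collapse = "; "))
  se <- sqrt(diag(fit$var))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(term = names(beta), coef = unname(beta),
                    hr = exp(unname(beta)),
                    lower = exp(unname(beta) - z * se),
                    upper = exp(unname(beta) + z * se),
                    p = 2 * pnorm(-abs(unname(beta) / se)))
  structure(list(table = tab, loglik = fit$loglik[2], n = fit$n,
                 n_events = fit$nevent, fit = fit,
                 warnings = unique(warns)),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_result> n = %d, events = %d, log partial likelihood %.2f\n",
              x$n, x$n_events, x$loglik))
  tab <- x$table
  tab$hr_ci <- sprintf("%.*f (%.*f-%.*f)", digits, tab$hr, digits, tab$lower,
                       digits, tab$upper)
  print(tab[, c("term", "hr_ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Octile-based dose-threshold estimation
#'
#' Splits the cohort into octiles of planned region dose (rank-based, so
#' pre-merge subset sizes differ by at most one; reported boundaries are the
#' linearly interpolated k/8 quantiles), merges the lowest `merge_lowest`
#' octiles to equalise the spanned dose range, refits the multivariable Cox
#' model with the regional delta-dose term in every subset, and estimates
#' the dose threshold as the lower dose bound of the lowest-dose subset in
#' which delta-dose is significant.
#'
#' @param planned_region Per-patient mean planned dose in the region, Gy.
#' @param delta_region Per-patient mean delta-dose in the region, Gy.
#' @param covars Data frame of adjustment covariates (may have 0 columns).
#' @param times,events Survival data.
#' @param merge_lowest Number of lowest octiles merged into one subset.
#' @param alpha Significance level for the delta-dose term.
#' @param min_n,min_events Minimum subset size / events; smaller subsets are
#'   fitted but flagged and excluded from the threshold estimate.
#' @return An object of class `octile_analysis`: `boundaries` (9 Gy values),
#'   `subsets` (per-subset data frame with the delta-dose HR, CI, p, flag),
#'   `threshold_estimate` (Gy, or NA if no subset qualifies).
#' @export
octile_analysis <- function(planned_region, delta_region, covars, times,
                            events, merge_lowest = 3L, alpha = 0.05,
                            min_n = 30L, min_events = 10L) {
  n <- length(planned_region)
  stopifnot(length(delta_region) == n, length(times) == n,
            length(events) == n)
  if (n < 8L) stop("octile analysis needs at least 8 patients")
  boundaries <- unname(quantile(planned_region, probs = 0:8 / 8, type = 7))
  oct <- ceiling(rank(planned_region, ties.method = "first") * 8 / n)
  group <- pmax(oct - merge_lowest + 1L, 1L)
  gids <- sort(unique(group))
  subsets <- do.call(rbind, lapply(gids, function(g) {
    sel <- group == g
    octs <- unique(oct[sel])
    lo <- boundaries[min(octs)]
    hi <- boundaries[max(octs) + 1L]
    row <- data.frame(octiles = paste(range(octs), collapse = "-"),
                      dose_lo = lo, dose_hi = hi, n = sum(sel),
                      n_events = sum(events[sel]), hr = NA_real_,
                      lower = NA_real_, upper = NA_real_, p = NA_real_,
                      flagged = FALSE, note = "")
    sub_cov <- data.frame(delta_region = delta_region[sel])
    if (!is.null(covars) && ncol(covars) > 0L)
      sub_cov <- cbind(sub_cov, droplevels(covars[sel, , drop = FALSE]))
    sub_cov <- sub_cov[, vapply(sub_cov, function(v) length(unique(v)) > 1L,
                                logical(1)), drop = FALSE]
    fit <- tryCatch(fit_cox(sub_cov, times[sel], events[sel]),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      row$flagged <- TRUE
      row$note <- conditionMessage(fit)
    } else {
      dd <- fit$table[fit$table$term == "delta_region", ]
      if (nrow(dd) == 1L) {
        row$hr <- dd$hr; row$lower <- dd$lower
        row$upper <- dd$upper; row$p <- dd$p
      }
      if (row$n < min_n || row$n_events < min_events) {
        row$flagged <- TRUE
        row$note <- "subset below minimum size for a stable model"
      }
    }
    row
  }))
  eligible <- !subsets$flagged & is.finite(subsets$p) & subsets$p < alpha
  threshold <- if (any(eligible)) min(subsets$dose_lo[eligible]) else NA_real_
  structure(list(boundaries = boundaries, subsets = subsets,
                 merge_lowest = as.integer(merge_lowest), alpha = alpha,
                 threshold_estimate = threshold,
                 octile_assignment = oct),
            class = "octile_analysis")
}

#' @export
print.octile_analysis <- function(x, ...) {
  cat(sprintf("<octile_analysis> boundaries (Gy): %s\n",
              paste(sprintf("%.1f", x$boundaries), collapse = ", ")))
  print(x$subsets[, c("octiles", "dose_lo", "dose_hi", "n", "n_events",
                      "hr", "p", "flagged")], row.names = FALSE, digits = 3)
  cat(sprintf("  threshold estimate: %s Gy\n",
              ifelse(is.na(x$threshold_estimate), "none",
                     sprintf("%.2f", x$threshold_estimate))))
  invisible(x)
}

#' Kaplan-Meier validation of a dose cut-point
#'
#' Splits patients at a planned region-dose cut-point, compares survival by
#' the log-rank test, and reports the univariable proportional-hazards
#' hazard ratio for the below-cut-point group versus the above group
#' (values < 1 mean lower region dose confers better survival). An optional
#' covariate-adjusted hazard ratio is reported alongside, since unadjusted
#' curves and adjusted effects answer slightly different questions.
#'
#' @param planned_region Per-patient mean planned region dose, Gy.
#' @param cutpoint Dose cut-point, Gy; both sides must be nonempty.
#' @param times,events Survival data.
#' @param covars Optional data frame of adjustment covariates.
#' @return An object of class `km_validation`: group sizes, `hr`/`lower`/
#'   `upper` (below vs above), `logrank_p`, optional `hr_adjusted`, and the
#'   `survfit` object for plotting.
#' @export
km_validation <- function(planned_region, cutpoint, times, events,
                          covars = NULL) {
  below <- planned_region < cutpoint
  if (!any(below) || all(below))
    stop("cut-point ", cutpoint, " Gy leaves an empty group (cohort range ",
         sprintf("%.2f-%.2f", min(planned_region), max(planned_region)), " Gy)")
  grp <- factor(ifelse(below, "below", "above"), levels = c("above", "below"))
  df <- data.frame(.time = times, .event = events, group = grp)
  sf <- survival::survfit(survival::Surv(.time, .event) ~ group, data = df)
  sd <- survival::survdiff(survival::Surv(.time, .event) ~ group, data = df)
  logrank_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  cx <- fit_cox(data.frame(group = grp), times, events)
  out <- list(cutpoint = cutpoint, n_below = sum(below),
              n_above = sum(!below),
              hr = cx$table$hr[1], lower = cx$table$lower[1],
              upper = cx$table$upper[1], hr_p = cx$table$p[1],
              logrank_p = logrank_p, survfit = sf)
  if (!is.null(covars) && ncol(covars) > 0L) {
    cx_adj <- fit_cox(cbind(data.frame(group = grp), covars), times, events)
    gi <- grep("^group", cx_adj$table$term)[1]
    out$hr_adjusted <- cx_adj$table$hr[gi]
    out$hr_adjusted_p <- cx_adj$table$p[gi]
  }
  structure(out, class = "km_validation")
}

#' @export
print.km_validation <- function(x, ...) {
  cat(sprintf("<km_validation> cut-point %.2f Gy: %d below vs %d above\n",
              x$cutpoint, x$n_below, x$n_above))
  cat(sprintf("  HR(below vs above) = %.3f (%.3f-%.3f), log-rank p = %.2g\n",
              x$hr, x$lower, x$upper, x$logrank_p))
  if (!is.null(x$hr_adjusted))
    cat(sprintf("  covariate-adjusted HR = %.3f (p = %.2g)\n",
                x$hr_adjusted, x$hr_adjusted_p))
  invisible(x)
}
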