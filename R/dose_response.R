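# Four-parameter logistic dose-response fitting, AUC and sensitivity.
#
# Doses are handled internally in nM regardless of input unit. The model
# is v(d) = bottom + (top - bottom) / (1 + (d / IC50)^hill); IC50 is the
# concentration at the curve midpoint. AUC is computed from raw mean
# viabilities over log10(dose), scaled so a flat nonresponder scores 1.

dose_to_nM <- function(doses, dose_unit = c("uM", "nM")) {
  dose_unit <- match.arg(dose_unit)
  if (dose_unit == "uM") doses * 1000 else doses
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit over grid-initialized starts (log-spaced IC50 across
#' and beyond the tested range), using bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM]). Zero-dose wells are excluded from the fit; they
#' only serve as the 100%-viability control. The fit is flagged censored
#' when the fitted IC50 exceeds the maximum tested dose or the curve
#' never reaches its midpoint within range (no dynamic range); censored
#' IC50 is reported at the maximum dose.
#'
#' @param doses Dose vector (replicate rows allowed), first may be 0.
#' @param viability Viability fractions (same length as `doses`).
#' @param dose_unit `"uM"` (default) or `"nM"`.
#' @return A `fit_result` list: ic50_nM, log10_ic50_nM, hill, top, bottom,
#'   censored, converged, rss.
#' @export
fit_four_pl <- function(doses, viability, dose_unit = c("uM", "nM")) {
  d <- dose_to_nM(doses, dose_unit)
  keep <- d > 0 & is.finite(viability)
  d <- d[keep]
  v <- viability[keep]
  if (length(unique(d)) < 5)
    stop("need >= 5 distinct nonzero doses to fit", call. = FALSE)
  if (any(v < 0)) stop("viability must be >= 0", call. = FALSE)
  max_d <- max(d)
  lg_range <- range(log10(d))
  starts <- seq(lg_range[1] - 1, lg_range[2] + 1, length.out = 8)
  # viability is a fraction of control: the lower asymptote cannot be
  # negative, and letting it go negative trades off against IC50 when
  # the curve does not bottom out within the tested range
  lower <- c(top = 0.5, bottom = 0, hill = 0.2,
             lg = lg_range[1] - 3)
  upper <- c(top = 1.5, bottom = 0.7, hill = 5, lg = lg_range[2] + 3)
  dat <- data.frame(d = d, v = v)
  best <- NULL
  for (s in starts) for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + (d / 10^lg)^hill),
        data = dat,
        start = list(top = 1, bottom = 0, hill = h0, lg = s),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(ic50_nM = NA_real_, log10_ic50_nM = NA_real_,
                          hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, censored = TRUE,
                          converged = FALSE, rss = NA_real_),
                     class = "fit_result"))
  }
  cf <- stats::coef(best$fit)
  ic50 <- 10^cf[["lg"]]
  # right-censored when the fitted IC50 lies beyond the tested range or
  # the data never demonstrate a half-maximal drop within it
  v_top_dose <- mean(v[d == max_d])
  censored <- ic50 > max_d || (cf[["top"]] - cf[["bottom"]]) < 0.2 ||
    v_top_dose > 0.5
  if (censored) ic50 <- max_d
  structure(list(ic50_nM = ic50, log10_ic50_nM = log10(ic50),
                 hill = cf[["hill"]], top = cf[["top"]],
                 bottom = cf[["bottom"]], censored = censored,
                 converged = TRUE, rss = best$rss),
            class = "fit_result")
}

#' Area under the viability-log(dose) curve
#'
#' Trapezoidal integral of the mean replicate viability over log10(dose)
#' across the nonzero doses, divided by the log-dose span so a flat
#' nonresponder (viability 1 everywhere) scores exactly 1. Optionally
#' normalized to a reference assay sharing the same dose grid.
#'
#' @param doses Dose vector (replicate rows allowed); zeros are excluded
#'   from the integral.
#' @param viability Viability fractions matching `doses`.
#' @param reference Optional list with `doses` and `viability` of the
#'   reference cell line (same nonzero dose grid), or a precomputed
#'   reference `auc_raw` scalar.
#' @param dose_unit `"uM"` (default) or `"nM"`.
#' @return List with `auc_raw` and (when a reference is given)
#'   `auc_normalized`.
#' @export
compute_auc <- function(doses, viability, reference = NULL,
                        dose_unit = c("uM", "nM")) {
  d <- dose_to_nM(doses, dose_unit)
  keep <- d > 0 & is.finite(viability)
  d <- d[keep]
  v <- viability[keep]
  mu <- tapply(v, d, mean)
  x <- log10(sort(unique(d)))
  y <- as.numeric(mu[order(as.numeric(names(mu)))])
  if (length(x) < 2) stop("need >= 2 nonzero doses", call. = FALSE)
  span <- x[length(x)] - x[1]
  auc_raw <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) /
    span
  out <- list(auc_raw = auc_raw)
  if (!is.null(reference)) {
    ref_auc <- if (is.numeric(reference) && length(reference) == 1) {
      reference
    } else {
      rd <- dose_to_nM(reference$doses, dose_unit)
      rnz <- sort(unique(rd[rd > 0]))
      if (!isTRUE(all.equal(rnz, sort(unique(d)))))
        stop("reference dose grid does not match assay dose grid",
             call. = FALSE)
      compute_auc(reference$doses, reference$viability,
                  dose_unit = dose_unit)$auc_raw
    }
    out$auc_normalized <- auc_raw / ref_auc
  }
  out
}

#' Classify a fitted curve as sensitive or resistant
#'
#' Sensitive when the fitted IC50 is strictly below the threshold
#' (default 2 uM); censored fits are resistant.
#'
#' @param fit A `fit_result` from [fit_four_pl()].
#' @param threshold_uM Sensitivity threshold in uM (default 2).
#' @return `"sensitive"` or `"resistant"`.
#' @export
classify_sensitivity <- function(fit, threshold_uM = 2) {
  if (isTRUE(fit$censored)) return("resistant")
  if (!isTRUE(fit$converged) || !is.finite(fit$ic50_nM))
    stop("cannot classify a non-converged, non-censored fit",
         call. = FALSE)
  if (fit$ic50_nM < threshold_uM * 1000) "sensitive" else "resistant"
}

#' Fold change in sensitivity between two IC50s
#'
#' Ratio of the two IC50s in common units. When the numerator IC50 is
#' censored (a lower bound on the true value) the ratio is itself a lower
#' bound on the true fold difference and flagged as such; a censored
#' denominator flags an upper bound.
#'
#' @param ic50_a,ic50_b Positive concentrations in the same unit.
#' @param censored_a,censored_b Censoring flags for each IC50.
#' @return List with `ratio`, `lower_bound`, `upper_bound`.
#' @export
fold_sensitivity <- function(ic50_a, ic50_b, censored_a = FALSE,
                             censored_b = FALSE) {
  if (!is.finite(ic50_a) || !is.finite(ic50_b) || ic50_a <= 0 ||
      ic50_b <= 0)
    stop("IC50 values must be positive and finite", call. = FALSE)
  list(ratio = ic50_a / ic50_b, lower_bound = isTRUE(censored_a),
       upper_bound = isTRUE(censored_b))
}

#' Fit, summarize and classify every assay in a long dose-response table
#'
#' @param dose_long Long-format data.frame (cell_line, drug, dose_uM,
#'   replicate, viability).
#' @param reference Cell line used to normalize AUC; `NULL` uses the
#'   assay with the largest raw AUC.
#' @param threshold_uM Sensitivity threshold in uM.
#' @return data.frame with one row per (cell_line, drug): fit parameters,
#'   censoring, AUCs and sensitivity label.
#' @export
summarize_dose_response <- function(dose_long, reference = NULL,
                                    threshold_uM = 2) {
  keys <- unique(dose_long[, c("cell_line", "drug")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- dose_long[dose_long$cell_line == keys$cell_line[i] &
                     dose_long$drug == keys$drug[i], ]
    fit <- fit_four_pl(d$dose_uM, d$viability)
    auc <- compute_auc(d$dose_uM, d$viability)
    data.frame(cell_line = keys$cell_line[i], drug = keys$drug[i],
               ic50_nM = fit$ic50_nM, log10_ic50_nM = fit$log10_ic50_nM,
               hill = fit$hill, top = fit$top, bottom = fit$bottom,
               censored = fit$censored, converged = fit$converged,
               auc_raw = auc$auc_raw,
               label = classify_sensitivity(fit, threshold_uM),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ref_auc <- if (is.null(reference)) max(out$auc_raw)
             else out$auc_raw[out$cell_line == reference][1]
  if (!is.finite(ref_auc))
    stop("reference cell line not found: ", reference, call. = FALSE)
  out$auc_normalized <- out$auc_raw / ref_auc
  rownames(out) <- NULL
  out
}
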