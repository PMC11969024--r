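#' Drop supra-peak doses showing receptor desensitization
#'
#' In agonist (EC) dose-response data, responses that fall below the peak at
#' doses above it indicate receptor desensitization and are excluded before
#' curve fitting. Let `d*` be the dose with maximal mean response: every dose
#' greater than `d*` whose mean response is below that peak mean is dropped.
#' The peak itself, all lower doses, and supra-peak doses that match the peak
#' (a plateau) are always retained, so monotone data pass unchanged.
#'
#' @param data Tibble with `dose` (molar, > 0) and `response` columns
#'   (replicates as repeated dose rows).
#' @return Filtered tibble; dropped doses in the `excluded_doses` attribute.
#' @export
exclude_desensitized <- function(data) {
  stopifnot(all(c("dose", "response") %in% names(data)), all(data$dose > 0))
  means <- summarise(group_by(as_tibble(data), .data$dose),
                     mean_response = mean(.data$response), .groups = "drop")
  peak_dose <- means$dose[which.max(means$mean_response)]
  peak_mean <- max(means$mean_response)
  drop <- means$dose[means$dose > peak_dose & means$mean_response < peak_mean]
  out <- filter(as_tibble(data), !.data$dose %in% drop)
  attr(out, "excluded_doses") <- drop
  out
}

ll3_curve <- function(x, b, c, d, e) c + (d - c) / (1 + exp(b * (log(x) - log(e))))

#' Fit a 3-parameter log-logistic dose-response model
#'
#' The model is `f(x) = c + (d - c) / (1 + exp(b (ln x - ln e)))` with slope
#' `b`, lower asymptote `c`, upper asymptote `d` and midpoint `e` (molar).
#' In agonist (`"EC"`) mode the maximal response is fixed at `d = 100` (so
#' responses must be on a percent scale; `response_scale = "counts"`
#' normalises to percent of the maximal observed mean response first). In
#' inhibition (`"IC"`) mode the bottom is fixed at `c = 0`. Three parameters
#' remain free in either mode.
#'
#' Fitting is least squares over raw replicates via a multi-start
#' Levenberg-Marquardt search (both slope signs, a log-spaced midpoint grid
#' over the dose range); the lowest-deviance converged start wins. EC-mode
#' data should first pass [exclude_desensitized()].
#'
#' @param data Tibble with `dose` (molar) and `response`.
#' @param mode `"EC"` (agonist) or `"IC"` (inhibitor).
#' @param response_scale `"percent"` (default) or `"counts"`.
#' @return An object of class `ll3_fit` with elements `coefficients`
#'   (b, c, d, e), `fixed` (logical mask), `mode`, `converged`, `sigma`,
#'   `df.residual`, `data`, `fitted`, `residuals`. Non-convergence yields
#'   `converged = FALSE` with `NA` coefficients (never a silent fallback).
#' @seealso [derive_ecf()], [to_potency()], [tidy.ll3_fit()]
#' @export
fit_ll3 <- function(data, mode = c("EC", "IC"),
                    response_scale = c("percent", "counts")) {
  mode <- match.arg(mode)
  response_scale <- match.arg(response_scale)
  data <- as_tibble(data)
  stopifnot(all(c("dose", "response") %in% names(data)), all(data$dose > 0))
  if (length(unique(data$dose)) < 3L) {
    abort("need at least 3 distinct doses to fit")
  }
  y <- data$response
  normalized <- FALSE
  if (mode == "EC" && response_scale == "counts") {
    means <- tapply(y, data$dose, mean)
    y <- 100 * y / max(means)
    normalized <- TRUE
    inform("responses normalised to percent of maximal observed mean response")
  }
  x <- data$dose
  lx <- log(x)

  e_grid <- exp(seq(min(lx), max(lx), length.out = 5L))
  b_grid <- c(-2, -1, -0.5, 0.5, 1, 2)
  best <- NULL
  msgs <- character()
  for (b0 in b_grid) {
    for (e0 in e_grid) {
      fit <- tryCatch({
        if (mode == "EC") {
          minpack.lm::nlsLM(
            y ~ c + (100 - c) / (1 + exp(b * (lx - loge))),
            start = list(b = b0, c = min(y), loge = log(e0)),
            control = minpack.lm::nls.lm.control(maxiter = 200,
                                                 ftol = 1e-12, ptol = 1e-12))
        } else {
          minpack.lm::nlsLM(
            y ~ d / (1 + exp(b * (lx - loge))),
            start = list(b = b0, d = max(y), loge = log(e0)),
            control = minpack.lm::nls.lm.control(maxiter = 200,
                                                 ftol = 1e-12, ptol = 1e-12))
        }
      }, error = function(e) conditionMessage(e))
      if (is.character(fit)) {
        msgs <- c(msgs, fit)
        next
      }
      dev <- sum(stats::resid(fit)^2)
      if (is.null(best) || dev < best$dev) best <- list(fit = fit, dev = dev)
    }
  }

  if (is.null(best)) {
    return(structure(
      list(coefficients = c(b = NA_real_, c = NA_real_,
                            d = NA_real_, e = NA_real_),
           fixed = c(b = FALSE, c = mode == "IC", d = mode == "EC",
                     e = FALSE),
           mode = mode, converged = FALSE, normalized = normalized,
           sigma = NA_real_, df.residual = NA_integer_,
           data = data, fitted = NULL, residuals = NULL,
           diagnostics = unique(msgs)),
      class = "ll3_fit"))
  }

  cf <- stats::coef(best$fit)
  coefficients <- if (mode == "EC") {
    c(b = unname(cf["b"]), c = unname(cf["c"]), d = 100,
      e = exp(unname(cf["loge"])))
  } else {
    c(b = unname(cf["b"]), c = 0, d = unname(cf["d"]),
      e = exp(unname(cf["loge"])))
  }
  df_res <- length(y) - 3L
  structure(
    list(coefficients = coefficients,
         fixed = c(b = FALSE, c = mode == "IC", d = mode == "EC", e = FALSE),
         mode = mode, converged = TRUE, normalized = normalized,
         sigma = sqrt(best$dev / max(df_res, 1L)),
         df.residual = df_res,
         data = mutate(data, .response_used = y),
         fitted = stats::fitted(best$fit),
         residuals = stats::resid(best$fit),
         diagnostics = character()),
    class = "ll3_fit")
}

#' @export
print.ll3_fit <- function(x, ...) {
  cat("3-parameter log-logistic fit (", x$mode, " mode",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  cf <- x$coefficients
  fx <- ifelse(x$fixed, " (fixed)", "")
  for (p in names(cf)) {
    cat(sprintf("  %s = %.6g%s\n", p, cf[[p]], fx[[p]]))
  }
  invisible(x)
}

#' @export
#' @rdname fit_ll3
#' @param object,x An `ll3_fit`.
#' @param ... Unused.
tidy.ll3_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         fixed = unname(x$fixed))
}

#' @export
#' @rdname fit_ll3
glance.ll3_fit <- function(x, ...) {
  tibble(converged = x$converged, sigma = x$sigma,
         df.residual = x$df.residual, mode = x$mode,
         nobs = nrow(x$data))
}

#' Dose achieving a given percent of the fitted response span
#'
#' Solves `f(x) = c + (f/100) (d - c)` on the fitted curve, giving e.g. the
#' EC80 used to set agonist concentrations for inhibition assays. Closed
#' form: `x = e ((100 - f) / f)^(1/b)`; `f = 50` returns the midpoint `e`
#' exactly.
#'
#' @param fit A converged [fit_ll3()] object.
#' @param f Percent of the response span, in (0, 100).
#' @return Dose in molar units.
#' @export
derive_ecf <- function(fit, f) {
  stopifnot(inherits(fit, "ll3_fit"))
  if (!fit$converged) abort("fit did not converge; no derived doses")
  if (!(f > 0 && f < 100)) abort("f must lie strictly between 0 and 100")
  cf <- fit$coefficients
  unname(cf["e"] * ((100 - f) / f)^(1 / cf["b"]))
}

#' Negative log10 of a molar concentration
#'
#' `p_molar(9.5e-6)` is `5.02` (2 dp): the pEC50/pEC80/pIC50 transform.
#'
#' @param x Molar concentration(s), > 0.
#' @return `-log10(x)`.
#' @export
p_molar <- function(x) {
  if (any(!is.finite(x) | x <= 0)) abort("molar values must be positive")
  -log10(x)
}

#' Potency summary of a fitted dose-response curve
#'
#' EC mode reports EC50 (the midpoint), EC80 and their negative-log
#' transforms; IC mode reports IC50 and pIC50.
#'
#' @param fit A converged [fit_ll3()] object, or a positive molar value
#'   (interpreted as a midpoint; only the 50%-level entries are filled).
#' @return One-row tibble `ec50`, `ec80`, `ic50`, `pec50`, `pec80`, `pic50`
#'   (`NA` where not applicable).
#' @export
to_potency <- function(fit) {
  if (is.numeric(fit)) {
    stopifnot(length(fit) == 1L)
    if (fit <= 0) abort("molar value must be positive")
    return(tibble(ec50 = NA_real_, ec80 = NA_real_, ic50 = fit,
                  pec50 = NA_real_, pec80 = NA_real_, pic50 = p_molar(fit)))
  }
  stopifnot(inherits(fit, "ll3_fit"))
  if (!fit$converged) abort("fit did not converge; no potency summary")
  e <- unname(fit$coefficients["e"])
  if (fit$mode == "EC") {
    ec80 <- derive_ecf(fit, 80)
    tibble(ec50 = e, ec80 = ec80, ic50 = NA_real_,
           pec50 = p_molar(e), pec80 = p_molar(ec80), pic50 = NA_real_)
  } else {
    tibble(ec50 = NA_real_, ec80 = NA_real_, ic50 = e,
           pec50 = NA_real_, pec80 = NA_real_, pic50 = p_molar(e))
  }
}

#' Design a disease chemokine pool from mean expression
#'
#' Molar fractions are proportional to the mean relative expression (TPM) of
#' each chemokine in the reference tissue, so the pool mimics the diseased
#' tissue's chemokine milieu. Which chemokines enter the pool is the caller's
#' choice; no expression filtering is applied beyond the mean.
#'
#' @param tpm Tibble with `chemokine` and `tpm` (mean TPM, >= 0; at least one
#'   positive).
#' @return Tibble `chemokine`, `tpm`, `fraction` (fractions sum to 1).
#' @export
design_pool <- function(tpm) {
  stopifnot(all(c("chemokine", "tpm") %in% names(tpm)), all(tpm$tpm >= 0))
  if (sum(tpm$tpm) == 0) abort("all-zero expression table")
  mutate(as_tibble(tpm), fraction = .data$tpm / sum(.data$tpm))
}
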