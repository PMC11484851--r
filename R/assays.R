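# Functional-assay models: normalized fold-change transformation of
# luminescence counts, 3-parameter concentration-response fitting (Hill
# slope fixed at 1; pEC50 and span = Top - Bottom as Emax), and one-site
# saturation binding with a linear nonspecific component
# (total = Bmax * L / (Kd + L) + ns * L).

#' Normalize luminescence counts to fold change over vehicle
#'
#' Each well's counts are first normalized to its own baseline (initial)
#' count; responses are then expressed as fold change over the mean
#' baseline-normalized vehicle signal.
#'
#' @param raw numeric vector of ligand-treated counts.
#' @param baseline matching vector (or scalar) of initial counts, > 0.
#' @param vehicle_raw,vehicle_baseline vehicle-treated counts and their
#'   initial counts.
#' @return numeric vector of normalized responses (vehicle mean = 1).
#' @export
normalize_luminescence <- function(raw, baseline, vehicle_raw,
                                   vehicle_baseline) {
  if (any(baseline <= 0) || any(vehicle_baseline <= 0))
    stop("baseline counts must be positive")
  if (!length(vehicle_raw)) stop("vehicle series must be non-empty")
  veh <- mean(vehicle_raw / vehicle_baseline)
  (raw / baseline) / veh
}

logistic3 <- function(log10c, pEC50, bottom, top, hill = 1) {
  bottom + (top - bottom) / (1 + 10^(hill * (-pEC50 - log10c)))
}

#' Fit a 3-parameter concentration-response curve
#'
#' Model: `y = bottom + (top - bottom) / (1 + 10^(log10(EC50) - log10(c)))`
#' with the Hill slope fixed at 1 (the 3 free parameters are pEC50, top and
#' bottom). Zero-concentration (vehicle) points are retained as
#' bottom-informative observations at a pseudo-concentration three log
#' units below the lowest nonzero dose. Bounded Levenberg-Marquardt least
#' squares with a 5-point multi-start over the concentration span.
#'
#' @param conc_M ligand concentrations, molar (zeros allowed).
#' @param response normalized responses.
#' @param hill fixed Hill slope (default 1).
#' @return a `dose_response_fit`: list with `pEC50`, `top`, `bottom`,
#'   `span` (= top - bottom, the Emax measure), `EC50_M`, `sse`,
#'   `converged`, `degenerate`, `extrapolated`, `n`.
#' @export
fit_dose_response <- function(conc_M, response, hill = 1) {
  if (length(conc_M) != length(response)) stop("length mismatch")
  if (any(conc_M < 0)) stop("concentrations must be >= 0")
  if (any(!is.finite(response))) stop("responses must be finite")
  nz <- conc_M > 0
  if (length(unique(conc_M[nz])) < 4L)
    stop("need at least 4 distinct nonzero concentrations")
  pseudo <- min(conc_M[nz]) / 1000
  x <- log10(ifelse(nz, conc_M, pseudo))
  y <- response
  sse_const <- sum((y - mean(y))^2)
  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    # a flat response carries no concentration information
    return(structure(list(pEC50 = NA_real_, top = mean(y), bottom = mean(y),
                          span = 0, EC50_M = NA_real_, sse = sse_const,
                          converged = TRUE, degenerate = TRUE,
                          extrapolated = NA, n = length(y),
                          diagnostics = "constant response"),
                     class = "dose_response_fit"))
  }
  xr <- range(log10(conc_M[nz]))
  starts <- seq(-xr[2], -xr[1], length.out = 5)
  lower <- c(pEC50 = -xr[2] - 3, bottom = -Inf, top = -Inf)
  upper <- c(pEC50 = -xr[1] + 3, bottom = Inf, top = Inf)
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ logistic3(x, pEC50, bottom, top, hill),
        start = list(pEC50 = s0, bottom = min(y), top = max(y)),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(structure(list(pEC50 = NA_real_, top = NA_real_, bottom = NA_real_,
                          span = NA_real_, EC50_M = NA_real_, sse = NA_real_,
                          converged = FALSE, degenerate = FALSE,
                          extrapolated = NA, n = length(y),
                          diagnostics = "no start converged"),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(best$fit)
  span <- unname(cf["top"] - cf["bottom"])
  ec50 <- 10^(-unname(cf["pEC50"]))
  degenerate <- abs(span) < 1e-6 * max(1, abs(unname(cf["top"]))) ||
    best$sse > sse_const * (1 - 1e-9)
  structure(list(pEC50 = unname(cf["pEC50"]), top = unname(cf["top"]),
                 bottom = unname(cf["bottom"]), span = span, EC50_M = ec50,
                 sse = best$sse, converged = TRUE, degenerate = degenerate,
                 extrapolated = ec50 < min(conc_M[nz]) || ec50 > max(conc_M),
                 n = length(y), diagnostics = ""),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) { cat("<dose_response_fit> not converged\n"); return(invisible(x)) }
  cat(sprintf("<dose_response_fit> pEC50 %.3f (EC50 %.3g M), span %.3g (top %.3g, bottom %.3g)%s\n",
              x$pEC50, x$EC50_M, x$span, x$top, x$bottom,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fit a one-site saturation-binding curve (total and nonspecific)
#'
#' Model: `total = Bmax * L / (Kd + L) + ns_slope * L`. When a separate
#' nonspecific series is supplied and `joint = FALSE`, it is subtracted
#' pointwise and a 2-parameter specific-binding fit is performed; the
#' default is the joint 3-parameter fit.
#'
#' @param L free ligand concentrations, molar (>= 5 distinct values).
#' @param total_bound bound counts.
#' @param nonspecific optional matching nonspecific counts.
#' @param joint fit ns_slope jointly (default TRUE).
#' @return a `saturation_fit`: list with `Kd_M`, `Bmax`, `ns_slope`,
#'   `sse`, `converged`.
#' @export
fit_saturation_binding <- function(L, total_bound, nonspecific = NULL,
                                   joint = TRUE) {
  if (length(unique(L)) < 5L) stop("need at least 5 distinct concentrations")
  if (!is.null(nonspecific) && !joint) {
    total_bound <- total_bound - nonspecific
    return(fit_specific_binding(L, total_bound))
  }
  # rescale concentrations to O(1) so Kd, Bmax and the nonspecific slope
  # are commensurate for the optimizer (picomolar designs otherwise span
  # ~25 orders of magnitude across parameters)
  sc <- max(L)
  l <- L / sc
  y <- total_bound
  kd0s <- stats::median(unique(l)) * c(0.3, 1, 3)
  best <- NULL
  for (kd0 in kd0s) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ Bmax * l / (Kd + l) + ns * l,
        start = list(Kd = kd0, Bmax = max(y), ns = 0),
        lower = c(Kd = 1e-12, Bmax = 0, ns = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    return(structure(list(Kd_M = NA_real_, Bmax = NA_real_,
                          ns_slope = NA_real_, sse = NA_real_,
                          converged = FALSE), class = "saturation_fit"))
  cf <- stats::coef(best$fit)
  structure(list(Kd_M = unname(cf["Kd"]) * sc, Bmax = unname(cf["Bmax"]),
                 ns_slope = unname(cf["ns"]) / sc, sse = best$sse,
                 converged = TRUE), class = "saturation_fit")
}

fit_specific_binding <- function(L, specific) {
  sc <- max(L)
  l <- L / sc
  y <- specific
  fit <- minpack.lm::nlsLM(
    y ~ Bmax * l / (Kd + l),
    start = list(Kd = stats::median(l), Bmax = max(y)),
    lower = c(Kd = 1e-12, Bmax = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(Kd_M = unname(cf["Kd"]) * sc, Bmax = unname(cf["Bmax"]),
                 ns_slope = 0, sse = sum(stats::residuals(fit)^2),
                 converged = TRUE), class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  if (!x$converged) { cat("<saturation_fit> not converged\n"); return(invisible(x)) }
  cat(sprintf("<saturation_fit> Kd %.3g M, Bmax %.4g, ns slope %.3g\n",
              x$Kd_M, x$Bmax, x$ns_slope))
  invisible(x)
}
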