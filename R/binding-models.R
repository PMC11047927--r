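# Quantitative binding computations: three-parameter logistic dose-response,
# normalised MFI, 1:1 Langmuir BLI kinetics, and sandwich epitope binning.

#' Three-parameter logistic response
#'
#' `response = bottom + (top - bottom) / (1 + ec50/dose)` - a Hill slope of
#' 1, the "three parameters" convention of common plate-fitting software.
#' At `dose == ec50` the response is the midpoint `(bottom + top) / 2`.
#'
#' @param dose Positive doses (same units as `ec50`).
#' @param bottom,top Lower/upper response asymptotes.
#' @param ec50 Half-maximal dose, must be positive.
#' @return Numeric responses.
#' @export
logistic3_eval <- function(dose, bottom, top, ec50) {
  if (any(ec50 <= 0)) stop("ec50 must be positive")
  if (any(dose <= 0)) stop("doses must be positive")
  bottom + (top - bottom) / (1 + ec50 / dose)
}

# profiled RSS: with ec50 fixed the model is linear in (bottom, top)
.logistic3_profile <- function(log_ec50, dose, y, hill = 1) {
  f <- 1 / (1 + (exp(log_ec50) / dose)^hill)
  fit <- stats::lm.fit(cbind(1, f), y)
  list(rss = sum(fit$residuals^2),
       bottom = unname(fit$coefficients[[1]]),
       top = unname(fit$coefficients[[1]] + fit$coefficients[[2]]),
       slope = unname(fit$coefficients[[2]]))
}

#' Fit the three-parameter logistic to a dose-response curve
#'
#' Least squares with the EC50 profiled on a log-dose grid spanning two
#' decades beyond the observed dose range (multi-start), then refined by
#' golden-section optimisation; bottom and top are solved linearly at each
#' EC50. Degenerate (flat or decreasing) curves are reported with
#' `converged = FALSE` rather than silently returned.
#'
#' @param dose,response Equal-length numeric vectors (replicates as repeated
#'   doses). At least 4 distinct doses are required.
#' @param hill Fixed Hill slope, default 1. (Setting another value gives the
#'   generalised fixed-slope variant; the slope is not estimated.)
#' @return Object of class `logistic3_fit`: list with `bottom`, `top`,
#'   `ec50`, `residual_sd`, `converged`, `n`.
#' @export
logistic3_fit <- function(dose, response, hill = 1) {
  stopifnot(length(dose) == length(response))
  keep <- is.finite(dose) & is.finite(response)
  dose <- dose[keep]; response <- response[keep]
  if (any(dose <= 0)) stop("doses must be positive")
  if (length(unique(dose)) < 4L)
    stop("at least 4 distinct doses are required")
  out <- list(bottom = mean(response), top = mean(response),
              ec50 = NA_real_, residual_sd = sd(response),
              converged = FALSE, n = length(dose))
  if (sd(response) < 1e-12 * (abs(mean(response)) + 1)) {
    class(out) <- "logistic3_fit"
    return(out)   # flat curve: degenerate, bottom == top
  }
  lo <- log(min(dose)) - 2 * log(10)
  hi <- log(max(dose)) + 2 * log(10)
  grid <- seq(lo, hi, length.out = 80L)
  rss <- vapply(grid, function(g)
    .logistic3_profile(g, dose, response, hill)$rss, numeric(1))
  i <- which.min(rss)
  bracket <- c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)])
  opt <- optimize(function(g)
    .logistic3_profile(g, dose, response, hill)$rss,
    interval = bracket, tol = 1e-10)
  prof <- .logistic3_profile(opt$minimum, dose, response, hill)
  out$ec50 <- exp(opt$minimum)
  out$bottom <- prof$bottom
  out$top <- prof$top
  out$residual_sd <- sqrt(prof$rss / max(1L, length(dose) - 3L))
  out$converged <- prof$slope > 0 &&
    out$ec50 > min(dose) / 1e4 && out$ec50 < max(dose) * 1e4
  if (prof$slope <= 0)
    warning("decreasing dose-response curve; fit flagged as not converged")
  class(out) <- "logistic3_fit"
  out
}

#' @export
print.logistic3_fit <- function(x, ...) {
  cat(sprintf(
    "logistic3_fit: bottom %.4g, top %.4g, ec50 %.4g (converged: %s)\n",
    x$bottom, x$top, x$ec50, x$converged))
  invisible(x)
}

#' Normalised mean fluorescence intensity
#'
#' `(mfi - mfi_negative) / (mfi_at_top_dose - mfi_negative)`: 0 at the
#' negative control, 1 at the top antibody dose.
#'
#' @param mfi Measured MFI (vectorised).
#' @param mfi_negative Negative-control MFI.
#' @param mfi_at_top_dose MFI at the highest dose.
#' @return Normalised values.
#' @export
normalize_mfi <- function(mfi, mfi_negative, mfi_at_top_dose) {
  denom <- mfi_at_top_dose - mfi_negative
  if (any(denom == 0)) stop("zero denominator: top-dose MFI equals negative")
  (mfi - mfi_negative) / denom
}

#' Simulate a noise-free 1:1 binding sensorgram
#'
#' Closed-form Langmuir kinetics: during association
#' `R(t) = Rmax * C / (C + KD) * (1 - exp(-(ka C + kd) t))`; during
#' dissociation `R(t) = R(t_assoc) * exp(-kd (t - t_assoc))`.
#'
#' @param ka Association rate constant, 1/(M s).
#' @param kd Dissociation rate constant, 1/s.
#' @param rmax Saturating response, nm.
#' @param conc Analyte concentration, M.
#' @param t_assoc Association time, s (default 300).
#' @param t_dissoc Dissociation time, s (default 600).
#' @param dt Time step, s.
#' @return `data.table` with columns `time_s`, `response_nm`,
#'   `concentration_M`, `phase`.
#' @export
simulate_sensorgram <- function(ka, kd, rmax, conc, t_assoc = 300,
                                t_dissoc = 600, dt = 1) {
  stopifnot(ka > 0, kd >= 0, rmax > 0, conc > 0, t_assoc > 0, t_dissoc > 0,
            dt > 0)
  t <- seq(0, t_assoc + t_dissoc, by = dt)
  kobs <- ka * conc + kd
  req <- rmax * conc / (conc + kd / ka)
  r_end <- req * (1 - exp(-kobs * t_assoc))
  resp <- ifelse(t <= t_assoc,
                 req * (1 - exp(-kobs * t)),
                 r_end * exp(-kd * (t - t_assoc)))
  data.table(time_s = t, response_nm = resp, concentration_M = conc,
             phase = ifelse(t <= t_assoc, "association", "dissociation"))
}

#' Subtract a reference trace from a sensorgram
#'
#' Plain point-wise difference of the response columns; time grids must
#' match.
#'
#' @param sgram,reference Sensorgram `data.table`s (see
#'   [simulate_sensorgram()]).
#' @return The sensorgram with the reference response subtracted.
#' @export
subtract_reference <- function(sgram, reference) {
  if (!isTRUE(all.equal(sgram$time_s, reference$time_s)))
    stop("reference time grid does not match")
  out <- copy_sensorgram(sgram)
  out$response_nm <- out$response_nm - reference$response_nm
  out
}

copy_sensorgram <- function(x) data.table::copy(as.data.table(x))

.kinetics_predict <- function(lpar, time_s, conc, t_assoc) {
  ka <- exp(lpar[[1]]); kd <- exp(lpar[[2]]); rmax <- exp(lpar[[3]])
  kobs <- ka * conc + kd
  req <- rmax * conc / (conc + kd / ka)
  r_end <- req * (1 - exp(-kobs * t_assoc))
  ifelse(time_s <= t_assoc,
         req * (1 - exp(-kobs * time_s)),
         r_end * exp(-kd * (time_s - t_assoc)))
}

#' Global 1:1 kinetic fit across analyte concentrations
#'
#' Fits a single (ka, kd, Rmax) triple to all sensorgrams simultaneously by
#' least squares over both phases, with multi-start initialisation in
#' log-parameter space. KD = kd/ka and half-life = ln(2)/kd are derived;
#' standard errors come from the local curvature (numerical Hessian of the
#' residual sum of squares) with the KD error obtained by the delta method.
#'
#' @param sensorgrams Either one long `data.table` with columns `time_s`,
#'   `response_nm`, `concentration_M`, or a list of per-concentration
#'   sensorgram tables; at least two distinct concentrations.
#' @param t_assoc End of the association phase, s (default 300).
#' @param reference Optional reference trace subtracted from every
#'   sensorgram before fitting (see [subtract_reference()]).
#' @return Object of class `kinetic_fit`: list with `ka`, `kd`, `rmax`,
#'   `KD`, `KD_se`, `half_life`, `residual_sd`, `rss`, `converged`, `n`,
#'   and `per_curve_rss`.
#' @export
fit_kinetics_global <- function(sensorgrams, t_assoc = 300,
                                reference = NULL) {
  if (is.data.frame(sensorgrams)) sensorgrams <- list(sensorgrams)
  if (!is.null(reference))
    sensorgrams <- lapply(sensorgrams, subtract_reference, reference)
  dat <- rbindlist(lapply(sensorgrams, function(x)
    as.data.table(x)[, list(time_s, response_nm, concentration_M)]))
  concs <- unique(dat$concentration_M)
  if (length(concs) < 2L)
    stop("global fit needs sensorgrams at >= 2 analyte concentrations")
  if (max(dat$response_nm) <= 0)
    stop("negative-going traces rejected: no positive response")
  rmax0 <- max(dat$response_nm)
  obj <- function(lpar)
    sum((dat$response_nm -
           .kinetics_predict(lpar, dat$time_s, dat$concentration_M,
                             t_assoc))^2)
  starts <- expand.grid(lka = log(10^c(3, 4, 5, 6)),
                        lkd = log(10^c(-4, -3, -2, -1)),
                        lrm = log(rmax0 * c(1.05, 2)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("kinetic fit did not converge from any start")
  # polish with Nelder-Mead from the best BFGS solution
  best <- optim(best$par, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
  lpar <- best$par
  ka <- exp(lpar[[1]]); kd <- exp(lpar[[2]]); rmax <- exp(lpar[[3]])
  n <- nrow(dat)
  rss <- best$value
  sigma2 <- rss / max(1L, n - 3L)
  KD <- kd / ka
  KD_se <- NA_real_
  H <- tryCatch(optimHess(lpar, obj), error = function(e) NULL)
  if (!is.null(H)) {
    cov <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      v <- cov[1, 1] + cov[2, 2] - 2 * cov[1, 2]   # var of log(kd) - log(ka)
      if (is.finite(v) && v >= 0) KD_se <- KD * sqrt(v)
    }
  }
  per_curve <- vapply(concs, function(cc) {
    sub <- dat[dat$concentration_M == cc, ]
    sum((sub$response_nm -
           .kinetics_predict(lpar, sub$time_s, cc, t_assoc))^2)
  }, numeric(1))
  structure(list(ka = ka, kd = kd, rmax = rmax, KD = KD, KD_se = KD_se,
                 half_life = log(2) / kd, rss = rss,
                 residual_sd = sqrt(sigma2),
                 converged = best$convergence == 0, n = n,
                 per_curve_rss = setNames(per_curve, signif(concs, 4))),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    paste0("kinetic_fit: ka %.3e 1/(Ms), kd %.3e 1/s, Rmax %.3g nm\n",
           "  KD %.4g nM (se %.3g nM), half-life %.4g s\n"),
    x$ka, x$kd, x$rmax, x$KD * 1e9, x$KD_se * 1e9, x$half_life))
  invisible(x)
}

#' Half-life of a binding complex
#'
#' `ln(2) / kd`, seconds.
#' @param kd Dissociation rate constant, 1/s.
#' @return Half-life in seconds.
#' @export
half_life <- function(kd) {
  stopifnot(all(kd > 0))
  log(2) / kd
}

#' Classify a sandwich epitope-binning shift
#'
#' The second antibody's extra response is compared with the shift it would
#' give on free antigen: at or above `bind_threshold_fraction` of the full
#' shift the two antibodies bind non-overlapping epitopes; at or below
#' `block_threshold_fraction` the epitopes overlap (blocked); in between the
#' overlap is partial.
#'
#' @param mab2_shift Observed MAb2 shift, nm. Negative values are treated as
#'   0 with a warning.
#' @param expected_full_shift MAb2 shift on free antigen, nm; must be
#'   positive.
#' @param bind_threshold_fraction,block_threshold_fraction Classification
#'   thresholds as fractions of the full shift (defaults 0.2 and 0.05).
#' @return List with `classification` (`"non_overlapping"`, `"overlapping"`
#'   or `"partial"`), `shift`, `fraction_of_full`, `thresholds`.
#' @export
bin_epitope <- function(mab2_shift, expected_full_shift,
                        bind_threshold_fraction = 0.2,
                        block_threshold_fraction = 0.05) {
  if (expected_full_shift <= 0)
    stop("expected_full_shift must be positive")
  if (mab2_shift < 0) {
    warning("negative shift treated as 0")
    mab2_shift <- 0
  }
  frac <- mab2_shift / expected_full_shift
  cls <- if (frac >= bind_threshold_fraction) "non_overlapping"
         else if (frac <= block_threshold_fraction) "overlapping"
         else "partial"
  list(classification = cls, shift = mab2_shift, fraction_of_full = frac,
       thresholds = c(bind = bind_threshold_fraction,
                      block = block_threshold_fraction))
}
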