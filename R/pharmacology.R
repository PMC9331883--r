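## Quantitative pharmacology around the target-deconvolution core:
## percent-growth / GI50 dose-response fitting, PAMPA effective
## permeability, coupled enzymatic assay kinetics, and docking free-energy
## to dissociation-constant conversion.

#' Percent growth of treated cells
#'
#' `% growth = 100 * (T - T0) / (C - T0)`, where `T` is the treated signal
#' at the readout time, `T0` the signal at time zero and `C` the vehicle
#' control at the readout time. Values below 0 (net cytotoxicity) and
#' above 100 are legitimate and preserved.
#'
#' @param treated treated signal `T`.
#' @param t0 time-zero signal `T0`.
#' @param control vehicle control signal `C` (must differ from `t0`).
#' @return percent growth (vectorised).
#' @export
percentGrowth <- function(treated, t0, control) {
  if (any(control == t0))
    stop("degenerate control: C equals T0, percent growth undefined",
         call. = FALSE)
  100 * (treated - t0) / (control - t0)
}

## decreasing 4PL on log10 concentration
fourPL <- function(logc, top, bottom, logMid, hill) {
  bottom + (top - bottom) / (1 + 10 ^ (hill * (logc - logMid)))
}

## concentration at which the fitted 4PL crosses `level` percent
crossing4PL <- function(top, bottom, logMid, hill, level = 50) {
  num <- (top - level) / (level - bottom)
  if (!is.finite(num) || num <= 0) return(NA_real_)
  10 ^ (logMid + log10(num) / hill)
}

#' Fit a four-parameter logistic growth-inhibition curve and read off GI50
#'
#' Least-squares 4PL fit of percent growth against log10 concentration
#' (top, bottom, midpoint, Hill slope), via Levenberg-Marquardt. The GI50
#' is the concentration at which the fitted curve crosses 50% growth;
#' `fit_ok` is `FALSE` when the curve does not cross 50% within the tested
#' concentration range (e.g. no inhibition). Confidence intervals come
#' from a seeded parametric bootstrap: responses are resimulated from the
#' fitted curve with Gaussian noise at the residual standard deviation and
#' refit.
#'
#' @param concentration dose values in uM (> 0; at least 4 distinct).
#' @param growth percent growth at each dose.
#' @param nboot bootstrap draws for the CI (default 500; 0 disables).
#' @param seed RNG seed for the bootstrap; required when `nboot > 0`.
#' @param level CI coverage (default 0.95).
#' @return list with `gi50` (uM), `hill`, `top`, `bottom`, `fit_ok`,
#'   `ci` (lo/hi uM, `NA` when `nboot = 0` or the fit failed) and the
#'   underlying `fit` object.
#' @seealso [gi50Interpolate()] for the model-free fallback.
#' @export
fitGI50 <- function(concentration, growth, nboot = 500L, seed = NULL,
                    level = 0.95) {
  if (any(concentration <= 0))
    stop("concentrations must be positive (log scale)", call. = FALSE)
  if (length(unique(concentration)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  if (nboot > 0 && is.null(seed))
    stop("seed is required when nboot > 0 (reproducible bootstrap)",
         call. = FALSE)
  logc <- log10(concentration)
  midGuess <- logc[which.min(abs(growth -
    (max(growth) + min(growth)) / 2))][1]
  ## deterministic multi-start ladder; the best (lowest-RSS) fit wins.
  ## starts are nudged off the data extremes, where the Jacobian of an
  ## exact-fit problem can degenerate
  starts <- list(
    list(top = max(growth) + 2, bottom = min(growth) - 2,
         logMid = midGuess, hill = 1),
    list(top = max(growth) + 2, bottom = min(growth) - 2,
         logMid = midGuess, hill = 0.5),
    list(top = max(growth) + 2, bottom = min(growth) - 2,
         logMid = midGuess, hill = 2),
    list(top = 100, bottom = 0, logMid = median(logc), hill = 1))
  fit <- NULL
  for (st in starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(growth ~ fourPL(logc, top, bottom, logMid, hill),
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || sum(resid(cand)^2) < sum(resid(fit)^2)))
      fit <- cand
  }
  failed <- list(gi50 = NA_real_, hill = NA_real_, top = NA_real_,
                 bottom = NA_real_, fit_ok = FALSE,
                 ci = c(lo = NA_real_, hi = NA_real_), fit = NULL)
  if (is.null(fit)) return(failed)
  cf <- coef(fit)
  gi50 <- crossing4PL(cf["top"], cf["bottom"], cf["logMid"], cf["hill"])
  fitOk <- is.finite(gi50) && gi50 >= min(concentration) &&
    gi50 <= max(concentration)
  ci <- c(lo = NA_real_, hi = NA_real_)
  if (fitOk && nboot > 0) {
    fitted0 <- fourPL(logc, cf["top"], cf["bottom"], cf["logMid"],
                      cf["hill"])
    sigma <- sqrt(sum(resid(fit)^2) / max(length(growth) - 4L, 1L))
    set.seed(seed)
    draws <- vapply(seq_len(nboot), function(i) {
      yb <- fitted0 + rnorm(length(fitted0), 0, sigma)
      fb <- tryCatch(
        minpack.lm::nlsLM(yb ~ fourPL(logc, top, bottom, logMid, hill),
                          start = as.list(cf),
                          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(fb)) return(NA_real_)
      cb <- coef(fb)
      crossing4PL(cb["top"], cb["bottom"], cb["logMid"], cb["hill"])
    }, numeric(1))
    draws <- draws[is.finite(draws)]
    if (length(draws) >= 10L)
      ci <- setNames(unname(quantile(draws, c((1 - level) / 2,
                                              1 - (1 - level) / 2))),
                     c("lo", "hi"))
  }
  list(gi50 = unname(gi50), hill = unname(cf["hill"]),
       top = unname(cf["top"]), bottom = unname(cf["bottom"]),
       fit_ok = fitOk, ci = ci, fit = fit)
}

#' Model-free GI50 by linear interpolation
#'
#' Interpolates percent growth linearly in log10 concentration between the
#' two doses bracketing 50%; a fallback when the 4PL fit is rejected.
#'
#' @inheritParams fitGI50
#' @return GI50 in uM, or `NA` when the data never cross 50%.
#' @export
gi50Interpolate <- function(concentration, growth) {
  ord <- order(concentration)
  conc <- concentration[ord]; g <- growth[ord]
  below <- which(g <= 50)
  if (!length(below) || all(g <= 50)) return(NA_real_)
  i <- below[1]
  if (i == 1L) return(NA_real_)
  x1 <- log10(conc[i - 1L]); x2 <- log10(conc[i])
  10 ^ (x1 + (50 - g[i - 1L]) * (x2 - x1) / (g[i] - g[i - 1L]))
}

#' PAMPA effective permeability from a single-time-point two-compartment
#' record
#'
#' The donor and acceptor wells equilibrate toward
#' `C_eq = C_D(0) * V_D / (V_D + V_A)`; the effective permeability is
#' `Pe = -ln(1 - C_A(t)/C_eq) * V_D*V_A / ((V_D + V_A) * A * t)` with `t`
#' in seconds, reported with `-log10 Pe` and the usual classification:
#' permeable below 6, intermediate in \[6, 6.5\], impermeable above 6.5.
#' The donor-side form (`from = "donor"`) converts a measured residual
#' donor concentration to its acceptor equivalent by mass balance before
#' applying the same expression.
#'
#' @param donorConc0 initial donor concentration (uM).
#' @param acceptorConcT acceptor concentration at time `t` (uM; used when
#'   `from = "acceptor"`).
#' @param donorConcT donor concentration at time `t` (uM; used when
#'   `from = "donor"`).
#' @param vDonor,vAcceptor donor/acceptor volumes in uL (defaults 150 and
#'   300, the usual sandwich geometry).
#' @param area membrane area in cm^2 (default 0.3).
#' @param timeHours incubation time in hours (default 24).
#' @param from which compartment was measured.
#' @return list with `pe` (cm/s), `neg_log_pe` and `label`.
#' @export
pampaPe <- function(donorConc0, acceptorConcT = NULL, donorConcT = NULL,
                    vDonor = 150, vAcceptor = 300, area = 0.3,
                    timeHours = 24, from = c("acceptor", "donor")) {
  from <- match.arg(from)
  if (timeHours <= 0) stop("time must be > 0", call. = FALSE)
  cEq <- donorConc0 * vDonor / (vDonor + vAcceptor)
  ca <- if (from == "acceptor") {
    if (is.null(acceptorConcT))
      stop("acceptorConcT required when from = 'acceptor'", call. = FALSE)
    acceptorConcT
  } else {
    if (is.null(donorConcT))
      stop("donorConcT required when from = 'donor'", call. = FALSE)
    (donorConc0 - donorConcT) * vDonor / vAcceptor
  }
  if (ca < 0) stop("negative acceptor concentration", call. = FALSE)
  if (ca >= cEq)
    stop(sprintf("acceptor concentration (%.4g uM) at or beyond equilibrium (%.4g uM)",
                 ca, cEq), call. = FALSE)
  if (ca == 0) {
    pe <- 0; nlp <- Inf
  } else {
    vd <- vDonor / 1000; va <- vAcceptor / 1000   # uL -> cm^3
    tSec <- timeHours * 3600
    pe <- -log(1 - ca / cEq) * vd * va / ((vd + va) * area * tSec)
    nlp <- -log10(pe)
  }
  label <- if (nlp < 6) "permeable" else if (nlp <= 6.5) "intermediate"
           else "impermeable"
  list(pe = pe, neg_log_pe = nlp, label = label)
}

#' Blank-corrected absorbance increment and initial rate of a coupled
#' kinetic assay
#'
#' For an NADPH-coupled glycogenolysis readout monitored at 340 nm:
#' `dAbs = [OD(t_read) - OD(0)] - [blank(t_read) - blank(0)]`, with linear
#' interpolation between sampled times, plus the initial rate as the
#' least-squares slope of the blank-corrected trace over an early window.
#'
#' @param time sampling times in minutes (increasing).
#' @param od sample absorbance at 340 nm.
#' @param blank blank absorbance (same time base).
#' @param tRead readout time in minutes (default 30; must lie within the
#'   sampled range).
#' @param rateWindow width in minutes of the initial-rate window
#'   (default 30).
#' @return list with `delta_abs` and `rate` (absorbance units per minute).
#' @export
activityDeltaAbs <- function(time, od, blank, tRead = 30,
                             rateWindow = 30) {
  if (length(time) != length(od) || length(time) != length(blank))
    stop("time, od and blank must have equal length", call. = FALSE)
  if (tRead < min(time) || tRead > max(time))
    stop(sprintf("t_read = %g outside sampled range [%g, %g]",
                 tRead, min(time), max(time)), call. = FALSE)
  odAt <- function(y, t) approx(time, y, xout = t)$y
  t0 <- min(time)
  deltaAbs <- (odAt(od, tRead) - odAt(od, t0)) -
    (odAt(blank, tRead) - odAt(blank, t0))
  corrected <- od - blank
  early <- time <= t0 + rateWindow
  rate <- if (sum(early) >= 2L)
    unname(coef(lm(corrected[early] ~ time[early]))[2L]) else NA_real_
  list(delta_abs = deltaAbs, rate = rate)
}

#' Predicted dissociation constant from a binding free energy
#'
#' `Kd = exp(dG / (R * T))` with R = 1.9872e-3 kcal/(mol K); a free energy
#' of 0 gives the 1 M reference state, and more negative free energies
#' give tighter (smaller) Kd.
#'
#' @param dG binding free energy in kcal/mol.
#' @param temperature temperature in K (default 298).
#' @return dissociation constant in molar units.
#' @seealso [dgFromKd()] for the inverse.
#' @examples
#' kdFromDg(-7.884) # ~1.65e-6 M
#' @export
kdFromDg <- function(dG, temperature = 298) {
  if (any(temperature <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  exp(dG / (1.9872e-3 * temperature))
}

#' @rdname kdFromDg
#' @param kd dissociation constant in molar units (> 0).
#' @export
dgFromKd <- function(kd, temperature = 298) {
  if (any(kd <= 0)) stop("kd must be > 0", call. = FALSE)
  if (any(temperature <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  1.9872e-3 * temperature * log(kd)
}
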