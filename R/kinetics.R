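## mtDNA turnover kinetics: exponential decay of labeled mtDNA (BrdU
## chase), decomposition of the apparent decay into degradation plus
## dilution by cell division, depletion/repopulation series under
## replication arrest, and qPCR quantification via the inflection point
## of a four-parameter Chapman curve.

#' Fit an exponential decay
#'
#' Fits `signal = N0 * exp(-k * t)`. The default estimator is log-linear
#' least squares (`lm(log(signal) ~ t)`), which is exact on noiseless
#' exponential data and matches the usual fit to normalized band
#' intensities; it requires strictly positive signals. For series with
#' zeros use `method = "nls"` (direct nonlinear least squares).
#'
#' @param timepoints strictly increasing times (hours by convention).
#' @param signals signal values, normalized so the 0-h value is 1 by the
#'   reader (positive for the log-linear method).
#' @param label series label.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return a [DecayFit-class]; `k = 0` and infinite half-life for a
#'   non-decaying series.
#' @examples
#' halfLife(fitExponential(c(0, 24), c(1, 0.25)))  # 12 h
#' @export
fitExponential <- function(timepoints, signals, label = "",
                           method = c("loglinear", "nls")) {
  method <- match.arg(method)
  if (length(timepoints) < 2L || length(signals) != length(timepoints))
    stop("need >= 2 (time, signal) pairs", call. = FALSE)
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing", call. = FALSE)
  if (method == "loglinear") {
    if (any(signals <= 0))
      stop("non-positive signal: use method = \"nls\" for series with zeros",
           call. = FALSE)
    fit <- stats::lm(log(signals) ~ timepoints)
    k <- -unname(stats::coef(fit)[2L])
    N0 <- exp(unname(stats::coef(fit)[1L]))
    rss <- sum(stats::residuals(fit)^2)
  } else {
    st <- list(N0 = max(signals),
               k = max(1e-6, log(2) / max(diff(range(timepoints)))))
    fit <- minpack.lm::nlsLM(signals ~ N0 * exp(-k * timepoints),
                             start = st,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    k <- unname(cf["k"]); N0 <- unname(cf["N0"])
    rss <- sum(stats::residuals(fit)^2)
  }
  new("DecayFit", k = k, N0 = N0,
      halfLife = if (k > 0) log(2) / k else Inf,
      rss = rss, label = label, n = length(timepoints), method = method)
}

#' Decompose an apparent decay into degradation and dilution
#'
#' Labeled mtDNA signal declines both by degradation and by dilution with
#' newly synthesized unlabeled genomes as cells divide. Given the
#' apparent rate `k` and the culture doubling time, the degradation rate
#' is `k_deg = k - ln(2)/doublingTime`. When `k_deg <= 0` the apparent
#' decay is fully explained by dilution and the result is flagged
#' dilution-dominated. `doublingTime = Inf` (no division) returns the
#' apparent half-life unchanged.
#'
#' @param fit a [DecayFit-class] (or a plain apparent rate via
#'   `fit = NULL, k = ...`).
#' @param doublingTime culture doubling time, hours (> 0; may be `Inf`).
#' @param k apparent decay rate per hour, used when `fit` is `NULL`.
#' @return `list(kDegradation, degradationHalfLife, dilutionDominated)`.
#' @examples
#' f <- fitExponential(c(0, 24), c(1, 0.25))        # apparent 12 h
#' decomposeDilution(f, doublingTime = 30)$degradationHalfLife  # 20 h
#' @export
decomposeDilution <- function(fit, doublingTime, k = NULL) {
  if (is.null(k)) {
    stopifnot(is(fit, "DecayFit"))
    k <- fit@k
  }
  if (doublingTime <= 0) stop("doublingTime must be positive", call. = FALSE)
  kDiv <- if (is.finite(doublingTime)) log(2) / doublingTime else 0
  kDeg <- k - kDiv
  dominated <- kDeg <= .Machine$double.eps^0.5 * max(k, kDiv, 1)
  list(kDegradation = max(kDeg, 0),
       degradationHalfLife = if (dominated) Inf else log(2) / kDeg,
       dilutionDominated = dominated)
}

.chapman <- function(x, y0, a, b, c) y0 + a * (1 - exp(-b * x))^c

#' Fit a four-parameter Chapman curve to a qPCR amplification trace
#'
#' Nonlinear least squares of `y = y0 + a * (1 - exp(-b*x))^c` over a
#' multi-start grid: `y0` from the minimum fluorescence, `a` from the
#' range, and a coarse grid over the rate `b` (0.05-1 per cycle) and
#' shape `c`; the best converged start by residual sum of squares wins.
#' The quantification cycle is the inflection point `Ct = ln(c)/b`,
#' defined for `c > 1`; fits at or near `c = 1` (a saturating exponential
#' with no interior inflection) are flagged and return `NA` for Ct.
#'
#' @param cycles increasing cycle numbers (>= 5 points).
#' @param fluorescence fluorescence readings.
#' @param bGrid,cGrid multi-start grids for `b` and `c`.
#' @return a [ChapmanFit-class].
#' @export
chapmanFit <- function(cycles, fluorescence,
                       bGrid = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.5, 0.75, 1),
                       cGrid = c(1.5, 3, 5, 10, 20, 50, 100)) {
  if (length(cycles) < 5L || length(fluorescence) != length(cycles))
    stop("need >= 5 (cycle, fluorescence) pairs", call. = FALSE)
  if (is.unsorted(cycles, strictly = TRUE))
    stop("cycles must be strictly increasing", call. = FALSE)
  y0s <- min(fluorescence)
  as0 <- max(diff(range(fluorescence)), .Machine$double.eps)
  best <- NULL
  for (b0 in bGrid) for (c0 in cGrid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fluorescence ~ .chapman(cycles, y0, a, b, c),
        start = list(y0 = y0s, a = as0, b = b0, c = c0),
        lower = c(y0 = -Inf, a = 1e-12, b = 1e-6, c = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best))
    stop("Chapman fit failed to converge from any start; check the trace",
         call. = FALSE)
  cf <- best$coef
  cBoundary <- cf[["c"]] <= 1.01
  new("ChapmanFit", y0 = cf[["y0"]], a = cf[["a"]], b = cf[["b"]],
      c = cf[["c"]],
      ct = if (cBoundary) NA_real_ else log(cf[["c"]]) / cf[["b"]],
      rss = best$rss, converged = TRUE, cBoundary = cBoundary)
}

#' mtDNA copies per cell from paired Ct values
#'
#' `copies = 2 * efficiency^(Ct_nuclear - Ct_mito)`: the factor 2 counts
#' the two alleles of the diploid single-copy nuclear reference locus,
#' and each cycle difference multiplies template by the amplification
#' efficiency (2 = perfect doubling, the default since no efficiency
#' correction is applied).
#'
#' @param ctMito,ctNuclear inflection-point Ct values (cycles).
#' @param efficiency amplification factor per cycle, in `(1, 2]`.
#' @return `list(deltaCt, copiesPerCell)`.
#' @examples
#' copyNumber(20, 20)$copiesPerCell        # 2 at equal Ct
#' copyNumber(15, 23.7)$copiesPerCell      # ~832
#' @export
copyNumber <- function(ctMito, ctNuclear, efficiency = 2) {
  if (efficiency <= 1 || efficiency > 2)
    stop("efficiency must lie in (1, 2]", call. = FALSE)
  deltaCt <- ctNuclear - ctMito
  list(deltaCt = deltaCt, copiesPerCell = 2 * efficiency^deltaCt)
}

#' Fit a depletion/repopulation time course
#'
#' For a copy-number series under replication arrest followed by release
#' (e.g. ddC treatment withdrawn at `switchTime`): an exponential decay
#' is fitted to the depletion phase (`t <= switchTime`), and recovery is
#' summarized as the time after the switch at which the signal first
#' returns to `recoveryFraction` of the pre-treatment baseline (the
#' first timepoint's signal). With no post-switch observations, recovery
#' is reported as not observed.
#'
#' @param timepoints strictly increasing times.
#' @param signals signal (e.g. relative copy number) per timepoint.
#' @param switchTime time at which the arrest is released.
#' @param recoveryFraction fraction of baseline counting as recovered
#'   (default 0.9).
#' @param label series label.
#' @return `list(decay = DecayFit, recoveryTime, recoveryObserved,
#'   baseline, switchTime)`; `recoveryTime` is `NA` when not observed.
#' @export
fitDepletionRepopulation <- function(timepoints, signals, switchTime,
                                     recoveryFraction = 0.9, label = "") {
  pre <- timepoints <= switchTime
  if (sum(pre) < 2L)
    stop("need >= 2 points in the depletion phase", call. = FALSE)
  decay <- fitExponential(timepoints[pre], signals[pre], label = label)
  baseline <- signals[1L]
  post <- which(timepoints > switchTime)
  rec <- post[signals[post] >= recoveryFraction * baseline]
  observed <- length(rec) > 0L
  list(decay = decay,
       recoveryTime = if (observed) timepoints[rec[1L]] - switchTime
                      else NA_real_,
       recoveryObserved = if (length(post)) observed else NA,
       baseline = baseline, switchTime = switchTime)
}
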