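# Circadian rhythmicity detection for bioluminescence reporter traces.
# A trace is preprocessed (first-day exclusion, moving-average detrending),
# fitted by ordinary least squares to a line and by multi-start nonlinear
# least squares to a plain sine (period, phase, amplitude, offset), and the
# two fits are compared with the small-sample corrected Akaike criterion
# (AICc). The two-model Akaike weight of the sine is read as the probability
# that a sine fits better than a line; a trace is called rhythmic when this
# weight reaches the threshold (default 0.95).

.as_ts <- function(ts) {
  if (is.data.frame(ts)) {
    stopifnot(all(c("time_h", "value") %in% names(ts)))
    ts <- list(t = ts$time_h, y = ts$value)
  }
  stopifnot(length(ts$t) == length(ts$y), !anyNA(ts$t), !anyNA(ts$y))
  if (any(diff(ts$t) <= 0))
    stop("time points must be strictly increasing", call. = FALSE)
  ts
}

#' Preprocess a reporter trace
#'
#' Removes samples recorded before \code{dropBeforeH} hours (plate-transfer
#' artifacts contaminate the first day) and detrends by subtracting a
#' centered local-linear fit of window \code{detrendWindowH} hours (windows
#' truncated at the edges; the local line, rather than a plain moving
#' average, removes linear drift exactly even at the series ends), which
#' takes out slow baseline drift and amplitude decay. The detrended series
#' has mean approximately zero.
#'
#' @param ts data.frame with \code{time_h, value} (or list with \code{t, y}).
#' @param dropBeforeH drop samples with \code{t < dropBeforeH} (default 24).
#' @param detrendWindowH moving-average window in hours (default 24);
#'   \code{0} disables detrending, \code{"linear"} subtracts an OLS line
#'   instead.
#' @return list with \code{t} and detrended \code{y}.
#' @export
preprocessSeries <- function(ts, dropBeforeH = 24, detrendWindowH = 24) {
  ts <- .as_ts(ts)
  keep <- ts$t >= dropBeforeH
  t <- ts$t[keep]; y <- ts$y[keep]
  if (length(t) < 12L)
    stop("fewer than 12 samples remain after first-day exclusion",
         call. = FALSE)
  if (identical(detrendWindowH, "linear")) {
    y <- as.numeric(residuals(lm(y ~ t)))
  } else if (is.numeric(detrendWindowH) && detrendWindowH > 0) {
    half <- detrendWindowH / 2
    trend <- vapply(seq_along(t), function(i) {
      w <- which(abs(t - t[i]) <= half)
      if (length(w) < 3L || var(t[w]) == 0) return(mean(y[w]))
      cf <- coef(lm.fit(cbind(1, t[w] - t[i]), y[w]))
      cf[1]                      # local line evaluated at t_i
    }, numeric(1))
    y <- y - trend
  }
  list(t = t, y = y)
}

#' Fit a line by ordinary least squares
#'
#' @param ts preprocessed series (list \code{t, y} or data.frame).
#' @return list of class \code{LineFit}: \code{slope, intercept, rss, n,
#'   k = 3} (slope, intercept, and residual variance count as parameters).
#' @export
fitLine <- function(ts) {
  ts <- .as_ts(ts)
  n <- length(ts$t)
  if (n < 4L) stop("need at least 4 points for a line fit", call. = FALSE)
  if (var(ts$t) == 0) stop("degenerate time axis", call. = FALSE)
  fit <- lm(y ~ t, data = list(t = ts$t, y = ts$y))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 rss = sum(residuals(fit)^2), n = n, k = 3L),
            class = "LineFit")
}

# harmonic linear regression at fixed period: y = c + b1 cos(wt) + b2 sin(wt)
.harmonic_fit <- function(t, y, T) {
  w <- 2 * pi / T
  X <- cbind(1, cos(w * t), sin(w * t))
  cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  rss <- sum((y - X %*% cf)^2)
  list(c = cf[1], b1 = cf[2], b2 = cf[3], T = T, rss = rss)
}

.sine_pred <- function(p, t) {
  w <- 2 * pi / p["T"]
  p["c"] + p["b1"] * cos(w * t) + p["b2"] * sin(w * t)
}

#' Fit a sine wave by multi-start nonlinear least squares
#'
#' Model: \code{y = c + A sin(2 pi (t - phi0) / T)}, parameterized internally
#' as \code{c + b1 cos(wt) + b2 sin(wt)} with \code{w = 2 pi / T} (linear in
#' all but \code{T}, which makes each refinement well conditioned). For each
#' trial period on a 1 h grid over \code{periodBounds}, the harmonic
#' coefficients are initialized by linear regression and all four parameters
#' are refined by Levenberg-Marquardt with the period constrained to the
#' bounds; the refinement with the smallest residual sum of squares wins.
#'
#' @param ts preprocessed series (list \code{t, y} or data.frame).
#' @param periodBounds numeric length-2, period search bounds in hours
#'   (default \code{c(16, 32)}, bracketing the organism's free-running
#'   period of roughly 20-22 h).
#' @return list of class \code{SineFit}: \code{period, phase} (time of first
#'   model peak in \code{[0, period)}), \code{amplitude} (>= 0),
#'   \code{offset, rss, n, k = 5, converged}.
#' @examples
#' t <- seq(24, 114, by = 1.5)
#' fitSine(list(t = t, y = 3 + 2 * sin(2 * pi * t / 22)))$period
#' @export
fitSine <- function(ts, periodBounds = c(16, 32)) {
  ts <- .as_ts(ts)
  t <- ts$t; y <- ts$y
  n <- length(t)
  if (n < 8L) stop("need at least 8 points for a sine fit", call. = FALSE)
  if (diff(range(t)) < 1.5 * periodBounds[1])
    warning("time span shorter than 1.5 periods; the fit may be unstable")

  best <- NULL
  for (T0 in seq(periodBounds[1], periodBounds[2], by = 1)) {
    init <- .harmonic_fit(t, y, T0)
    if (is.null(init)) next
    start <- c(T = init$T, c = init$c, b1 = init$b1, b2 = init$b2)
    ref <- tryCatch(
      minpack.lm::nls.lm(par = start,
        fn = function(p) y - .sine_pred(p, t),
        lower = c(periodBounds[1], -Inf, -Inf, -Inf),
        upper = c(periodBounds[2], Inf, Inf, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    cand <- if (!is.null(ref)) {
      list(par = ref$par, rss = sum(ref$fvec^2), converged = ref$info %in% 1:4)
    } else {
      list(par = start, rss = init$rss, converged = FALSE)
    }
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }
  if (is.null(best))
    return(structure(list(period = NA_real_, phase = NA_real_,
                          amplitude = NA_real_, offset = NA_real_,
                          rss = Inf, n = n, k = 5L, converged = FALSE),
                     class = "SineFit"))
  p <- best$par
  T <- unname(p["T"]); b1 <- unname(p["b1"]); b2 <- unname(p["b2"])
  A <- sqrt(b1^2 + b2^2)
  # c + b1 cos(wt) + b2 sin(wt) = c + A sin(wt + delta), delta = atan2(b1, b2);
  # the model peaks where wt + delta = pi/2 (mod 2 pi)
  delta <- atan2(b1, b2)
  phase <- ((pi / 2 - delta) / (2 * pi / T)) %% T
  structure(list(period = T, phase = phase, amplitude = A,
                 offset = unname(p["c"]), rss = best$rss, n = n, k = 5L,
                 converged = isTRUE(best$converged)),
            class = "SineFit")
}

.aicc <- function(rss, n, k) {
  rss <- max(rss, .Machine$double.xmin)   # guard log(0) for exact fits
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Sine-versus-line rhythmicity test
#'
#' Both models are fitted to the (preprocessed) trace and compared by AICc
#' (\code{n ln(rss/n) + 2k + 2k(k+1)/(n-k-1)}, counting the residual
#' variance as a parameter: line k = 3, sine k = 5). \code{pSineBetter} is
#' the two-model Akaike weight of the sine,
#' \code{exp(-dAICc_sine/2) / (exp(-dAICc_sine/2) + exp(-dAICc_line/2))},
#' and the trace is called rhythmic when the weight reaches
#' \code{threshold} and the sine fit converged.
#'
#' @param ts preprocessed series (list \code{t, y} or data.frame).
#' @param threshold Akaike-weight threshold for the rhythmic call
#'   (default 0.95).
#' @param periodBounds passed to [fitSine()].
#' @return list of class \code{RhythmCall}: \code{pSineBetter, rhythmic,
#'   line} ([fitLine()] result), \code{sine} ([fitSine()] result).
#' @export
rhythmTest <- function(ts, threshold = 0.95, periodBounds = c(16, 32)) {
  ts <- .as_ts(ts)
  lf <- fitLine(ts)
  sf <- fitSine(ts, periodBounds = periodBounds)
  aics <- c(line = .aicc(lf$rss, lf$n, lf$k),
            sine = .aicc(sf$rss, sf$n, sf$k))
  d <- aics - min(aics)
  w <- exp(-d / 2)
  pSine <- unname(w["sine"] / sum(w))
  structure(list(pSineBetter = pSine,
                 rhythmic = pSine >= threshold && isTRUE(sf$converged),
                 line = lf, sine = sf),
            class = "RhythmCall")
}

#' Summarize rhythm calls across replicates
#'
#' Period mean and standard deviation over rhythmic replicates, and the
#' circular mean phase computed on unit vectors with the mean period as the
#' full circle (so phases 21.9 and 0.1 at period 22 average to ~0, not 11).
#'
#' @param calls list of \code{RhythmCall} objects (one per replicate).
#' @return list: \code{meanPeriod, sdPeriod, meanPhase, nRhythmic,
#'   singleReplicate} (TRUE when only one replicate was rhythmic, in which
#'   case \code{sdPeriod} is 0).
#' @export
summarizeReplicates <- function(calls) {
  rhythmic <- Filter(function(cl) isTRUE(cl$rhythmic), calls)
  if (!length(rhythmic))
    stop("no rhythmic replicates to summarize", call. = FALSE)
  periods <- vapply(rhythmic, function(cl) cl$sine$period, numeric(1))
  phases <- vapply(rhythmic, function(cl) cl$sine$phase, numeric(1))
  mp <- mean(periods)
  ang <- 2 * pi * phases / mp
  meanPhase <- (atan2(mean(sin(ang)), mean(cos(ang))) %% (2 * pi)) * mp /
    (2 * pi)
  list(meanPeriod = mp,
       sdPeriod = if (length(periods) > 1L) sd(periods) else 0,
       meanPhase = meanPhase,
       nRhythmic = length(rhythmic),
       singleReplicate = length(rhythmic) == 1L)
}
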