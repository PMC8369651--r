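#' FRAP intensity trace
#'
#' Raw fluorescence-recovery-after-photobleaching series for one spot:
#' bleached-region, unbleached-control and extracellular-background
#' intensities on a common time axis, with the first `n_prebleach` frames
#' acquired before the bleach pulse.
#'
#' @param times time points in seconds, strictly increasing.
#' @param bleached,control,background intensity series of equal length.
#' @param n_prebleach number of pre-bleach frames (>= 1).
#' @return an object of class `FRAPTrace` (field `normalized` is filled by
#'   [normalize_trace()]).
#' @export
frap_trace <- function(times, bleached, control = rep(1, length(times)),
                       background = rep(0, length(times)), n_prebleach = 3) {
  len <- length(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(bleached) != len || length(control) != len ||
      length(background) != len)
    stop("all series must have the same length")
  if (n_prebleach < 1 || n_prebleach >= len)
    stop("n_prebleach must be in [1, length(times) - 1]")
  structure(list(times = as.numeric(times), bleached = as.numeric(bleached),
                 control = as.numeric(control),
                 background = as.numeric(background),
                 n_prebleach = as.integer(n_prebleach), normalized = NULL),
            class = "FRAPTrace")
}

#' Double-normalize a FRAP trace
#'
#' Subtracts the background from both channels, divides the bleached by the
#' control channel at each time point (cancelling acquisition
#' photobleaching and laser drift), and rescales so the pre-bleach mean is
#' 1, i.e. intensities become proportions of the original pre-bleach
#' signal.
#'
#' @param trace a [frap_trace()].
#' @return the trace with `normalized` filled in.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "FRAPTrace"))
  ctrl <- trace$control - trace$background
  if (any(ctrl <= 0)) stop("non-positive control intensity after background subtraction")
  ratio <- (trace$bleached - trace$background) / ctrl
  pre <- mean(ratio[seq_len(trace$n_prebleach)])
  if (pre <= 0) stop("non-positive pre-bleach mean")
  trace$normalized <- ratio / pre
  trace
}

#' Fit the exponential recovery model to a FRAP trace
#'
#' Fits `FRAP(t) = A * (1 - exp(-t / tau)) + y0` to the post-bleach points
#' of a normalized trace by bounded nonlinear least squares
#' ([minpack.lm::nlsLM()]), with time measured from the first post-bleach
#' frame so `y0` is the intensity immediately after bleaching and `A` the
#' amplitude of the mobile population (mobile fraction). The half-time of
#' recovery is `t_half = tau * log(2)`.
#'
#' Start values: `A0` = last minus first post-bleach intensity, `y00` =
#' first post-bleach intensity, `tau0` = first time the trace exceeds
#' `y00 + A0/2` (falling back to a third of the time span). Bounds:
#' `A` in \[0, 2\], `tau` in (0, 10 * span\], `y0` in \[0, 1.5\].
#'
#' @param trace a normalized [frap_trace()] with at least 5 post-bleach
#'   points.
#' @return list of class `FRAPFit`: `A`, `tau`, `y0`, `t_half`, `rms`
#'   (residual root-mean-square) and `flag` (`"ok"` or `"wide_tau"` when
#'   the amplitude is essentially zero and tau is unidentifiable).
#' @export
fit_frap <- function(trace) {
  stopifnot(inherits(trace, "FRAPTrace"))
  if (is.null(trace$normalized)) stop("run normalize_trace() first")
  post <- (trace$n_prebleach + 1L):length(trace$times)
  if (length(post) < 5L) stop("need at least 5 post-bleach points")
  t <- trace$times[post] - trace$times[post[1L]]
  y <- trace$normalized[post]
  span <- max(t)
  if (stats::sd(y) < 1e-8) {
    # flat trace: no recovery, amplitude zero, tau unidentifiable
    return(structure(list(A = 0, tau = NA_real_, y0 = mean(y),
                          t_half = NA_real_,
                          rms = sqrt(mean((y - mean(y))^2)),
                          flag = "wide_tau"),
                     class = "FRAPFit"))
  }
  y00 <- y[1L]
  A0 <- max(y[length(y)] - y[1L], 1e-3)
  above <- which(y > y00 + A0 / 2)
  tau0 <- if (length(above)) max(t[above[1L]], span / 100) else span / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-t / tau)) + y0,
                      start = list(A = A0, tau = tau0, y0 = max(y00, 0)),
                      lower = c(A = 0, tau = 1e-9, y0 = 0),
                      upper = c(A = 2, tau = 10 * span, y0 = 1.5),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("FRAP fit did not converge: ", conditionMessage(fit))
  cf <- stats::coef(fit)
  flag <- "ok"
  if (cf[["A"]] < 1e-4 || cf[["tau"]] >= 10 * span * (1 - 1e-6)) {
    flag <- "wide_tau"
    if (cf[["A"]] < 1e-4) cf[["A"]] <- 0
  }
  structure(list(A = unname(cf[["A"]]), tau = unname(cf[["tau"]]),
                 y0 = unname(cf[["y0"]]),
                 t_half = unname(cf[["tau"]]) * log(2),
                 rms = sqrt(mean(stats::resid(fit)^2)), flag = flag),
            class = "FRAPFit")
}

#' @export
print.FRAPFit <- function(x, ...) {
  cat(sprintf("FRAPFit: A = %.4f, tau = %.3f s, y0 = %.4f, t_half = %.3f s (%s)\n",
              x$A, x$tau, x$y0, x$t_half, x$flag))
  invisible(x)
}

#' Regress mobile fraction on AICAP
#'
#' Ordinary least squares of per-protein FRAP mobile fractions (amplitudes
#' A) on AICAP values, testing whether 1,6-HD-sensitive proteins are also
#' the more mobile ones.
#'
#' @param A numeric vector of mobile fractions.
#' @param aicap numeric vector of AICAP values, same proteins.
#' @return list with `slope`, `intercept`, `r` (Pearson), `p_value`
#'   (two-sided, for the slope), `n`.
#' @export
mobility_regression <- function(A, aicap) {
  ok <- !is.na(A) & !is.na(aicap)
  A <- A[ok]; aicap <- aicap[ok]
  if (length(A) < 3L) stop("need at least 3 proteins with both values")
  if (stats::sd(aicap) == 0) stop("constant predictor")
  if (stats::sd(A) == 0)
    return(list(slope = 0, intercept = A[1L], r = 0, p_value = 1,
                n = length(A)))
  fit <- stats::lm(A ~ aicap)
  s <- summary(fit)$coefficients
  list(slope = unname(s["aicap", "Estimate"]),
       intercept = unname(s["(Intercept)", "Estimate"]),
       r = stats::cor(A, aicap),
       p_value = unname(s["aicap", "Pr(>|t|)"]),
       n = length(A))
}
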