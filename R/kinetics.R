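# From per-frame masses to the reported quantities: normalized curves,
# NEBD- and onset-aligned ensembles with confidence bands, disassembly rates,
# percent rate reductions, and persistent-mass fractions.

#' Construct a PCM mass curve
#'
#' @param times_s Strictly increasing times, seconds post-NEBD.
#' @param raw_mass Integrated masses (counts x px), same length; frames where
#'   the centrosome was no longer detectable carry mass 0 (not `NA`).
#' @param centrosome Label: `"anterior"`, `"posterior"` or `"merged"`.
#' @param condition Condition label (e.g. a preset name).
#' @return An object of class `mass_curve`; `norm_mass` is `NULL` until
#'   [normalize_curve()] is applied.
#' @export
mass_curve <- function(times_s, raw_mass, centrosome = "anterior",
                       condition = "wild_type") {
  if (length(times_s) != length(raw_mass))
    stop("`times_s` and `raw_mass` must have the same length")
  if (any(diff(times_s) <= 0)) stop("`times_s` must be strictly increasing")
  if (any(raw_mass < 0)) stop("`raw_mass` must be >= 0")
  structure(
    list(times_s = as.numeric(times_s), raw_mass = as.numeric(raw_mass),
         norm_mass = NULL, centrosome = centrosome, condition = condition),
    class = "mass_curve"
  )
}

#' Build a mass curve from quantifier output
#'
#' @param fq A `frame_quant` tibble from [quantify_movie()] (or any data
#'   frame with `time_s` and `integrated_mass` columns).
#' @param centrosome,condition Labels, see [mass_curve()].
#' @return A `mass_curve`.
#' @export
as_mass_curve <- function(fq, centrosome = "anterior", condition = "wild_type") {
  stopifnot(is.data.frame(fq), all(c("time_s", "integrated_mass") %in% names(fq)))
  mass_curve(fq$time_s, fq$integrated_mass, centrosome, condition)
}

#' @export
print.mass_curve <- function(x, ...) {
  cat(sprintf("<mass_curve> %s / %s, %d frames, t = [%g, %g] s%s\n",
              x$condition, x$centrosome, length(x$times_s),
              min(x$times_s), max(x$times_s),
              if (is.null(x$norm_mass)) "" else ", normalized"))
  invisible(x)
}

#' @export
as.data.frame.mass_curve <- function(x, ...) {
  data.frame(time_s = x$times_s, raw_mass = x$raw_mass,
             norm_mass = x$norm_mass %||% rep(NA_real_, length(x$times_s)),
             centrosome = x$centrosome, condition = x$condition)
}

#' Normalize a mass curve to its maximum
#'
#' Divides the integrated mass of each frame by the highest integrated mass
#' of the stack, so the output maximum is exactly 1. Idempotent and invariant
#' to positive rescaling of the raw masses.
#'
#' @param curve A `mass_curve` with at least one positive raw value.
#' @return The curve with `norm_mass` filled in.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "mass_curve"))
  m <- max(curve$raw_mass)
  if (m <= 0) stop("all-zero curve: nothing to normalize")
  curve$norm_mass <- curve$raw_mass / m
  curve
}

.ensure_norm <- function(curve) {
  if (is.null(curve$norm_mass)) normalize_curve(curve) else curve
}

# centred moving average with truncated windows at the edges
.moving_average <- function(v, half_width) {
  n <- length(v)
  vapply(seq_len(n), function(i)
    mean(v[max(1, i - half_width):min(n, i + half_width)]), numeric(1))
}

#' Detect disassembly onset
#'
#' Onset is the anchor from which decay is measured: the anaphase mass peak.
#' The normalized curve is smoothed with a centred moving average of window
#' `2*smooth_window + 1` samples and the global maximum located (ties ->
#' earliest); the estimate is then refined to the raw-curve maximum within the
#' smoothing half-window around that point (again ties -> earliest). The
#' smoothing pass rejects single-frame noise spikes; the refinement removes
#' the early bias the moving average has on an asymmetric peak (slow rise,
#' fast decay).
#'
#' @param curve A `mass_curve` (normalized internally if needed) with at
#'   least `2*smooth_window + 3` samples.
#' @param smooth_window Half-width in samples; default 2 (5-sample window).
#' @return An object of class `onset_estimate`: `t_onset_s` (an element of
#'   `times_s`), `index`, `rule`, `smooth_window`.
#' @export
detect_onset <- function(curve, smooth_window = 2) {
  curve <- .ensure_norm(curve)
  n <- length(curve$times_s)
  if (n < 2 * smooth_window + 3)
    stop("need at least ", 2 * smooth_window + 3, " samples to detect onset")
  sm <- .moving_average(curve$norm_mass, smooth_window)
  i_s <- which.max(sm)  # first maximum on ties
  win <- max(1, i_s - smooth_window):min(n, i_s + smooth_window)
  i <- win[which.max(curve$norm_mass[win])]
  structure(
    list(t_onset_s = curve$times_s[i], index = i,
         rule = "smoothed_argmax_refined", smooth_window = smooth_window),
    class = "onset_estimate"
  )
}

#' Align curves at NEBD or at disassembly onset and pool them
#'
#' Shifts each curve's time axis so that the chosen anchor sits at t = 0
#' (NEBD-anchored curves are already expressed in seconds post-NEBD and are
#' not shifted), then computes the pointwise ensemble mean with a
#' normal-approximation confidence band, mean +- z * SE, at every time where
#' at least two curves contribute (the band is `NA` elsewhere).
#'
#' @param curves List of `mass_curve` objects (normalized internally).
#' @param anchor `"nebd"` or `"onset"`.
#' @param smooth_window Passed to [detect_onset()] for the onset anchor.
#' @param conf_level Confidence level of the band (default 0.95, i.e.
#'   mean +- 1.96 SE).
#' @return An object of class `aligned_curves`: `curves` (time-shifted,
#'   normalized), `ensemble` (tibble: `time_s`, `mean`, `ci_lo`, `ci_hi`,
#'   `n`), `anchor`.
#' @export
align_curves <- function(curves, anchor = c("nebd", "onset"),
                         smooth_window = 2, conf_level = 0.95) {
  anchor <- match.arg(anchor)
  if (!length(curves)) stop("need at least one curve")
  curves <- lapply(curves, .ensure_norm)
  if (anchor == "onset") {
    curves <- lapply(curves, function(cv) {
      on <- detect_onset(cv, smooth_window)
      cv$times_s <- cv$times_s - on$t_onset_s
      cv
    })
  }
  times <- unlist(lapply(curves, `[[`, "times_s"))
  vals <- unlist(lapply(curves, `[[`, "norm_mass"))
  key <- round(times, 9)
  z <- stats::qnorm((1 + conf_level) / 2)
  grid <- sort(unique(key))
  agg <- lapply(grid, function(tt) {
    v <- vals[key == tt]
    n <- length(v)
    mu <- mean(v)
    if (n >= 2) {
      se <- stats::sd(v) / sqrt(n)
      c(mu, mu - z * se, mu + z * se, n)
    } else c(mu, NA_real_, NA_real_, n)
  })
  agg <- do.call(rbind, agg)
  ensemble <- tibble::tibble(time_s = grid, mean = agg[, 1],
                             ci_lo = agg[, 2], ci_hi = agg[, 3],
                             n = as.integer(agg[, 4]))
  structure(list(curves = curves, ensemble = ensemble, anchor = anchor),
            class = "aligned_curves")
}

#' Estimate the disassembly rate
#'
#' Least-squares slope of normalized mass versus time over the decay window:
#' from the raw-curve maximum at/after the onset anchor down to the first
#' sample below `fit_fraction` (default one half) of the window's starting
#' value — i.e. peak to half-maximum. Starting at the raw peak rather than
#' the smoothed onset anchor keeps pre-peak rising samples out of the fit.
#' If the curve never falls below the fraction the window extends to the last
#' sample (a flat post-onset curve yields rate 0). The alternative
#' `method = "exponential"` fits `log(norm_mass)` over the same window and
#' reports the slope, i.e. minus the exponential decay constant in 1/s.
#'
#' @param curve A `mass_curve` (normalized internally).
#' @param onset Optional [detect_onset()] result; detected if missing.
#' @param fit_fraction Window ends when the curve first falls below this
#'   fraction of its value at the window start.
#' @param method `"linear"` (normalized mass per second) or `"exponential"`.
#' @return An object of class `rate_estimate`: `rate` (<= 0 during
#'   disassembly), `window` (start/end times), `n`, `r_squared`, `method`,
#'   `fit_fraction`.
#' @export
disassembly_rate <- function(curve, onset = NULL, fit_fraction = 0.5,
                             method = c("linear", "exponential")) {
  method <- match.arg(method)
  curve <- .ensure_norm(curve)
  onset <- onset %||% detect_onset(curve)
  stopifnot(inherits(onset, "onset_estimate"))
  nv <- curve$norm_mass; tt <- curve$times_s; n <- length(nv)
  i0 <- onset$index - 1L + which.max(nv[onset$index:n])
  v0 <- nv[i0]
  below <- which(seq_len(n) > i0 & nv < fit_fraction * v0)
  j <- if (length(below)) below[1] else n
  w <- i0:j
  if (length(w) < 3)
    stop(sprintf(paste0("too few samples for a rate fit: window [%g, %g] s ",
                        "holds %d sample(s), need >= 3"),
                 tt[i0], tt[j], length(w)))
  y <- if (method == "exponential") log(pmax(nv[w], 1e-12)) else nv[w]
  fit <- stats::lm(y ~ tt[w])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_
        else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(rate = unname(stats::coef(fit)[2]), window = c(tt[i0], tt[j]),
         n = length(w), r_squared = r2, method = method,
         fit_fraction = fit_fraction),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %s fit: %.4g per s over [%g, %g] s (n = %d, R2 = %s)\n",
              x$method, x$rate, x$window[1], x$window[2], x$n,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  invisible(x)
}

#' Percent reduction in disassembly speed
#'
#' `100 * (1 - |treated| / |reference|)`: 60 means the treated condition
#' disassembles at 40% of the reference speed.
#'
#' @param reference,treated [disassembly_rate()] results (or bare rates);
#'   both should use the same method. The reference rate must be nonzero.
#' @return Percent, a bare number.
#' @export
rate_reduction <- function(reference, treated) {
  r <- if (inherits(reference, "rate_estimate")) reference$rate else reference
  t <- if (inherits(treated, "rate_estimate")) treated$rate else treated
  if (r == 0) stop("reference rate is zero; reduction undefined")
  100 * (1 - abs(t) / abs(r))
}

#' Persistent-mass fraction
#'
#' The normalized mass remaining at the end of the movie — PCM carried into
#' the next cell cycle. Computed as the median of normalized mass over the
#' trailing `eval_window_s` seconds, which resists single-frame noise.
#'
#' @param curve A `mass_curve` (normalized internally).
#' @param eval_window_s Trailing window length, seconds (default 60).
#' @param onset Optional [detect_onset()] result; the curve must extend at
#'   least `eval_window_s` beyond onset.
#' @return Fraction in `[0, 1]`.
#' @export
persistence_fraction <- function(curve, eval_window_s = 60, onset = NULL) {
  curve <- .ensure_norm(curve)
  onset <- onset %||% detect_onset(curve)
  t_end <- max(curve$times_s)
  if (t_end - onset$t_onset_s < eval_window_s)
    stop("curve ends ", t_end - onset$t_onset_s, " s after onset; need at ",
         "least `eval_window_s` = ", eval_window_s, " s")
  sel <- curve$times_s > t_end - eval_window_s
  stats::median(curve$norm_mass[sel])
}
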