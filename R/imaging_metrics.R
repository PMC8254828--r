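# Deterministic calculators for imaging-derived statistics: FRAP
# normalization and one-phase association fitting, mobile fraction, spine
# morphological-index dynamics, puncta-size filtering.

#' Construct a FRAP trace
#'
#' A fluorescence-recovery-after-photobleaching recording: bleached-region
#' and unbleached-reference intensities over strictly increasing time
#' points, with at least 5 pre-bleach frames (the default acquisition is
#' one frame every 10 s for 200 s post-bleach).
#'
#' @param time_s time stamps in seconds (bleach at t = 0; pre-bleach frames
#'   have negative times).
#' @param bleached intensity of the bleached region (arbitrary units).
#' @param reference intensity of an unbleached reference region (> 0).
#' @param phase character, "pre" or "post" per frame.
#' @return data.frame of class `frap_trace`.
#' @export
frap_trace <- function(time_s, bleached, reference, phase) {
  stopifnot(length(time_s) == length(bleached),
            length(time_s) == length(reference),
            length(time_s) == length(phase))
  if (any(diff(time_s) <= 0)) stop_domain("times must be strictly increasing")
  if (!all(phase %in% c("pre", "post"))) {
    stop_domain("phase must be 'pre' or 'post'")
  }
  if (sum(phase == "pre") < 5L) {
    stop_domain("need at least 5 pre-bleach frames, got ", sum(phase == "pre"))
  }
  bad <- which(reference <= 0)
  if (length(bad)) {
    stop_domain("reference intensity must be positive; frame ", bad[1],
                " (t = ", time_s[bad[1]], " s) is not")
  }
  structure(data.frame(time_s = time_s, bleached = bleached,
                       reference = reference, phase = phase,
                       stringsAsFactors = FALSE),
            class = c("frap_trace", "data.frame"))
}

#' Read a FRAP trace from CSV
#'
#' Columns: `time_s`, `bleached`, `reference`, `phase` ("pre"/"post").
#'
#' @param path CSV file.
#' @return A [frap_trace()].
#' @export
read_frap_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  frap_trace(df$time_s, df$bleached, df$reference, df$phase)
}

#' Normalize a FRAP trace
#'
#' Three steps, in order: (1) divide the bleached-region intensity by the
#' reference-region intensity frame-wise, correcting acquisition
#' photobleaching; (2) divide by the mean of the 5 frames immediately
#' before the bleach, so the pre-bleach level is exactly 1; (3) subtract
#' the minimum of the whole series, so the series minimum is exactly 0.
#'
#' @param trace a [frap_trace()].
#' @return data.frame `time_s`, `phase`, `normalized`, with attributes
#'   `F_initial` (pre-bleach level after step 2, by construction 1),
#'   `F_0` (first post-bleach value after step 2), `F_end` (final value
#'   after step 2) and `offset` (the subtracted minimum) for
#'   mobile-fraction arithmetic.
#' @export
normalize_frap <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  ratio <- trace$bleached / trace$reference
  pre_idx <- which(trace$phase == "pre")
  last5 <- pre_idx[(length(pre_idx) - 4):length(pre_idx)]
  scaled <- ratio / mean(ratio[last5])
  offset <- min(scaled)
  post_idx <- which(trace$phase == "post")
  out <- data.frame(time_s = trace$time_s, phase = trace$phase,
                    normalized = scaled - offset, stringsAsFactors = FALSE)
  attr(out, "F_initial") <- mean(scaled[last5])  # == 1 by construction
  attr(out, "F_0") <- scaled[post_idx[1]]
  attr(out, "F_end") <- scaled[length(scaled)]
  attr(out, "offset") <- offset
  out
}

#' Fit a one-phase association recovery model
#'
#' Least-squares fit of \eqn{Y(t) = plateau (1 - e^{-rate\, t})} to a
#' normalized post-bleach recovery series (after [normalize_frap()] the
#' first post-bleach value is 0, matching Y(0) = 0).  Deterministic
#' initialization: plateau from the final value, rate from the first
#' half-recovery crossing; bounded Levenberg-Marquardt with 3 deterministic
#' restarts at scaled initial rates.  A series with no recovery signal
#' (non-positive or constant) returns a degenerate fit.
#'
#' @param times seconds since the bleach (first value typically 0).
#' @param values normalized recovery values (same length, >= 5 points).
#' @return list of class `frap_fit`: `plateau`, `rate`, `rms` (residual
#'   root-mean-square), `degenerate` (logical), `converged`.
#' @examples
#' t <- seq(0, 200, 10)
#' fit_one_phase(t, 0.7 * (1 - exp(-0.02 * t)))
#' @export
fit_one_phase <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (length(values) < 5L) stop_domain("need at least 5 post-bleach points")
  degenerate <- function(plateau, rate) {
    structure(list(plateau = plateau, rate = rate,
                   rms = stats::sd(values) * sqrt((length(values) - 1) / length(values)),
                   degenerate = TRUE, converged = FALSE),
              class = "frap_fit")
  }
  if (max(values) <= 0 || stats::sd(values) == 0) {
    return(degenerate(plateau = max(0, values[length(values)]), rate = NA_real_))
  }
  plateau0 <- values[length(values)]
  if (plateau0 <= 0) plateau0 <- max(values)
  cross <- which(values >= plateau0 / 2 & times > 0)
  rate0 <- if (length(cross)) log(2) / times[cross[1]] else 1 / max(times[times > 0])
  fits <- list()
  for (mult in c(1, 0.2, 5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ plateau * (1 - exp(-rate * t)),
        data = data.frame(t = times, y = values),
        start = list(plateau = plateau0, rate = rate0 * mult),
        lower = c(plateau = 0, rate = 1e-8),
        upper = c(plateau = 2, rate = 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fits[[length(fits) + 1L]] <- fit
    }
  }
  if (!length(fits)) return(degenerate(plateau = plateau0, rate = rate0))
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  co <- stats::coef(best)
  structure(list(plateau = unname(co["plateau"]), rate = unname(co["rate"]),
                 rms = sqrt(min(rss) / length(values)),
                 degenerate = FALSE, converged = TRUE),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit> plateau = ", signif(x$plateau, 4),
      ", rate = ", signif(x$rate, 4), " /s, rms = ", signif(x$rms, 3),
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' Mobile fraction from FRAP endpoints
#'
#' \eqn{100 (F_{end} - F_0) / (F_{initial} - F_0)}: the percentage of the
#' bleached fluorescence recovered by the end of the recording, where
#' F_initial is the pre-bleach level, F_0 the value immediately after the
#' bleach and F_end the final value.  Invariant under affine rescaling of
#' all three intensities.  Values above 110% (possible with noise) are
#' flagged with a warning.
#'
#' @param F_end final intensity.
#' @param F_initial pre-bleach intensity (must exceed `F_0`).
#' @param F_0 first post-bleach intensity.
#' @return Mobile fraction in percent.
#' @examples
#' mobile_fraction(0.6, 1.0, 0.2)  # 50
#' @export
mobile_fraction <- function(F_end, F_initial, F_0) {
  if (F_initial <= F_0) {
    stop_domain("F_initial must exceed F_0 (no bleach occurred): F_initial = ",
                F_initial, ", F_0 = ", F_0)
  }
  mf <- 100 * (F_end - F_0) / (F_initial - F_0)
  if (mf > 110) warning("mobile fraction ", round(mf, 1),
                        "% exceeds 110%; check the trace", call. = FALSE)
  mf
}

#' Full FRAP analysis of one trace
#'
#' Normalizes the trace, fits the one-phase association model to the
#' post-bleach series and reports the mobile fraction both ways the field
#' computes it: from the raw normalized endpoints (F_end vs F_initial,
#' bleach-corrected) and from the fitted plateau.
#'
#' @param trace a [frap_trace()].
#' @return list: `normalized` (from [normalize_frap()]), `fit`
#'   ([fit_one_phase()]), `mobile_fraction_endpoint`,
#'   `mobile_fraction_plateau` (percent).
#' @export
frap_analysis <- function(trace) {
  norm <- normalize_frap(trace)
  post <- norm$phase == "post"
  t_post <- norm$time_s[post] - norm$time_s[post][1]
  fit <- fit_one_phase(t_post, norm$normalized[post])
  f_init <- attr(norm, "F_initial"); f0 <- attr(norm, "F_0")
  f_end <- attr(norm, "F_end")
  mf_end <- mobile_fraction(f_end, f_init, f0)
  # plateau variant: recovery plateaus at offset + plateau on the step-2
  # scale (the fit is performed after the minimum subtraction)
  mf_plateau <- mobile_fraction(attr(norm, "offset") + fit$plateau, f_init, f0)
  list(normalized = norm, fit = fit,
       mobile_fraction_endpoint = mf_end,
       mobile_fraction_plateau = mf_plateau)
}

#' Morphological index of a closed contour
#'
#' \eqn{M.I. = P^2 / (4 \pi A)} for perimeter P and area A: 1 for a circle
#' (isoperimetric equality) and larger for more complex shapes; an index of
#' spine head shape complexity.
#'
#' @param perimeter,area positive numerics (vectorized), in µm and µm².
#' @return Numeric vector of morphological indices.
#' @examples
#' morphological_index(2 * pi, pi)  # circle of radius 1 -> 1
#' morphological_index(4, 1)       # unit square -> 4/pi
#' @export
morphological_index <- function(perimeter, area) {
  if (any(perimeter <= 0) || any(area <= 0)) {
    stop_domain("perimeter and area must be positive")
  }
  perimeter^2 / (4 * pi * area)
}

#' Frame-to-frame dynamics of a morphometric series
#'
#' Quantifies remodeling of a per-frame measurement (spine head perimeter,
#' area, or morphological index) as the mean relative absolute successive
#' change, \eqn{mean_i |x_{i+1} - x_i| / x_i} (default).  Alternatives:
#' `"sd"` (standard deviation of the series) and `"cv"` (coefficient of
#' variation).  A constant series scores 0 under all methods.
#'
#' @param x positive numeric series (>= 2 frames).
#' @param method "rel_change" (default), "sd" or "cv".
#' @return The dynamics score (unit-free for "rel_change" and "cv").
#' @examples
#' series_dynamics(c(4, 5, 4))  # (0.25 + 0.2)/2
#' @export
series_dynamics <- function(x, method = c("rel_change", "sd", "cv")) {
  method <- match.arg(method)
  if (length(x) < 2L) stop_domain("need at least 2 frames")
  if (any(x <= 0)) stop_domain("series values must be positive")
  switch(method,
         rel_change = mean(abs(diff(x)) / x[-length(x)]),
         sd = stats::sd(x),
         cv = stats::sd(x) / mean(x))
}

#' Dynamics of a spine ROI time series
#'
#' Convenience wrapper over [series_dynamics()] for an ROI table
#' (`frame_min`, `perimeter_um`, `area_um2`); the `"mi"` metric first
#' computes the per-frame morphological index.
#'
#' @param series data.frame with columns `frame_min`, `perimeter_um`,
#'   `area_um2`.
#' @param metric "perimeter", "area" or "mi".
#' @param method passed to [series_dynamics()].
#' @return The dynamics score.
#' @export
spine_dynamics <- function(series, metric = c("perimeter", "area", "mi"),
                           method = "rel_change") {
  metric <- match.arg(metric)
  stopifnot(all(c("perimeter_um", "area_um2") %in% names(series)))
  x <- switch(metric,
              perimeter = series$perimeter_um,
              area = series$area_um2,
              mi = morphological_index(series$perimeter_um, series$area_um2))
  series_dynamics(x, method = method)
}

#' Filter puncta by minimum area and summarize
#'
#' Excludes puncta strictly smaller than `min_area` (default 0.006 µm²;
#' the boundary value is retained) and summarizes counts per compartment,
#' puncta density per 10 µm of dendrite when a dendrite length is given,
#' and the spine-versus-dendrite count ratio.
#'
#' @param puncta data.frame with columns `area` (µm², > 0) and
#'   `compartment` ("spine"/"dendrite").
#' @param min_area exclusion threshold in µm² (> 0).
#' @param dendrite_length_um optional dendrite length for densities.
#' @return list: `puncta` (retained rows), `summary` (list with `n_input`,
#'   `n_kept`, `n_excluded`, `counts` per compartment, `density_per_10um`,
#'   `spine_dendrite_ratio`).
#' @export
filter_puncta <- function(puncta, min_area = 0.006, dendrite_length_um = NULL) {
  stopifnot(is.data.frame(puncta), min_area > 0)
  if (nrow(puncta)) {
    stopifnot(all(c("area", "compartment") %in% names(puncta)))
    if (any(puncta$area <= 0)) stop_domain("puncta areas must be positive")
    if (!all(puncta$compartment %in% c("spine", "dendrite"))) {
      stop_domain("compartment must be 'spine' or 'dendrite'")
    }
  }
  kept <- puncta[puncta$area >= min_area, , drop = FALSE]
  counts <- c(spine = sum(kept$compartment == "spine"),
              dendrite = sum(kept$compartment == "dendrite"))
  density <- if (!is.null(dendrite_length_um)) {
    10 * counts / dendrite_length_um
  } else NULL
  ratio <- if (counts[["dendrite"]] > 0) {
    counts[["spine"]] / counts[["dendrite"]]
  } else NA_real_
  list(puncta = kept,
       summary = list(n_input = nrow(puncta), n_kept = nrow(kept),
                      n_excluded = nrow(puncta) - nrow(kept),
                      counts = counts, density_per_10um = density,
                      spine_dendrite_ratio = ratio))
}
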