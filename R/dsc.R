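#' Construct a thermogram
#'
#' Wraps an excess-heat-capacity trace (x = temperature in degrees Celsius,
#' y = excess heat capacity in kJ mol^-1 K^-1) together with the scan rate
#' and, for mixtures, the solute mole fraction.
#'
#' @param curve An [xy_curve] with strictly increasing temperature.
#' @param scan_rate Heating rate in degrees C per hour (> 0). Default 60.
#' @param composition Solute mole fraction in \[0, 1).
#' @return An object of class `thermogram`.
#' @export
thermogram <- function(curve, scan_rate = 60, composition = 0) {
  stopifnot(inherits(curve, "xy_curve"))
  if (any(diff(curve$x) <= 0)) {
    stop("temperature must be strictly increasing", call. = FALSE)
  }
  if (scan_rate <= 0) stop("scan_rate must be > 0", call. = FALSE)
  if (composition < 0 || composition >= 1) {
    stop("composition must be in [0, 1)", call. = FALSE)
  }
  structure(list(curve = curve, scan_rate = scan_rate,
                 composition = composition,
                 baseline_corrected = isTRUE(curve$meta$baseline_corrected)),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %d points, T in [%.2f, %.2f] C, %.0f C/h, x_solute = %.3g%s\n",
              length(x$curve$x), min(x$curve$x), max(x$curve$x), x$scan_rate,
              x$composition,
              if (x$baseline_corrected) ", baseline corrected" else ""))
  invisible(x)
}

#' Subtract a linear baseline through two peak-free windows
#'
#' A straight line through the (temperature, heat-capacity) means of the
#' pre-transitional and post-transitional windows is subtracted, so the
#' corrected trace averages zero inside both windows. The operation is
#' idempotent to floating point precision. It is an error for either window
#' to overlap a detectable transition peak.
#'
#' @param thermo A [thermogram].
#' @param pre_window,post_window Length-2 temperature intervals (degrees C)
#'   inside the scan range, below and above the transitions.
#' @return The baseline-corrected [thermogram].
#' @export
subtract_baseline <- function(thermo, pre_window, post_window) {
  stopifnot(inherits(thermo, "thermogram"))
  x <- thermo$curve$x; y <- thermo$curve$y
  win_idx <- function(w, name) {
    w <- sort(as.numeric(w))
    if (w[1] < min(x) - 1e-9 || w[2] > max(x) + 1e-9) {
      stop(name, " window extends beyond the data range", call. = FALSE)
    }
    idx <- which(x >= w[1] & x <= w[2])
    if (length(idx) < 2L) stop(name, " window contains fewer than 2 points", call. = FALSE)
    idx
  }
  i_pre <- win_idx(pre_window, "pre")
  i_post <- win_idx(post_window, "post")
  x1 <- mean(x[i_pre]); y1 <- mean(y[i_pre])
  x2 <- mean(x[i_post]); y2 <- mean(y[i_post])
  if (abs(x2 - x1) < 1e-12) stop("baseline windows coincide", call. = FALSE)

  # a peak under either window defeats the construction: each window must be
  # linear to within a small fraction of the full signal excursion
  thr <- 0.02 * diff(range(y)) + 1e-8
  for (idx in list(i_pre, i_post)) {
    lf <- stats::lm.fit(cbind(1, x[idx]), y[idx])
    if (max(abs(lf$residuals)) > thr) {
      stop("baseline window overlaps a peak: window is not linear",
           call. = FALSE)
    }
  }
  slope <- (y2 - y1) / (x2 - x1)
  corrected <- y - (y1 + slope * (x - x1))
  out <- thermo
  out$curve <- xy_curve(x, corrected, thermo$curve$y_err,
                        meta = utils::modifyList(thermo$curve$meta,
                                                 list(baseline_corrected = TRUE)))
  out$baseline_corrected <- TRUE
  out
}

# Topographic prominence of a local maximum at index i.
peak_prominence <- function(y, i) {
  left <- if (i > 1L) {
    higher <- which(y[seq_len(i - 1L)] > y[i])
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(y[lo:i])
  } else y[i]
  right <- if (i < length(y)) {
    higher <- which(y[(i + 1L):length(y)] > y[i]) + i
    hi <- if (length(higher)) min(higher) - 1L else length(y)
    min(y[i:hi])
  } else y[i]
  y[i] - max(left, right)
}

#' Detect transition peaks in a baseline-corrected thermogram
#'
#' Local maxima with topographic prominence at least `min_prominence` are
#' reported; each peak's region extends on both sides to where the signal
#' first falls below 1 percent of the peak height. Overlapping regions are
#' merged and flagged.
#'
#' @param thermo Baseline-corrected [thermogram].
#' @param min_prominence Minimum peak prominence (same units as y).
#' @return List of regions, each a list with `i_start`, `i_end`, `i_peak`
#'   (indices), `T_peak` (degrees C), `overlapping` flag. Empty list when no
#'   peak qualifies.
#' @export
detect_transitions <- function(thermo, min_prominence = 0.5) {
  stopifnot(inherits(thermo, "thermogram"))
  y <- thermo$curve$y; x <- thermo$curve$x
  n <- length(y)
  if (n < 3L) return(list())
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  is_max <- is_max[vapply(is_max, function(i) peak_prominence(y, i),
                          numeric(1)) >= min_prominence]
  if (!length(is_max)) return(list())
  regions <- lapply(is_max, function(i) {
    thr <- 0.01 * y[i]
    lo <- i; while (lo > 1L && y[lo - 1L] >= thr) lo <- lo - 1L
    hi <- i; while (hi < n && y[hi + 1L] >= thr) hi <- hi + 1L
    list(i_start = lo, i_end = hi, i_peak = i, T_peak = x[i],
         overlapping = FALSE)
  })
  # merge overlapping regions (shared indices) in temperature order
  merged <- list(regions[[1L]])
  for (r in regions[-1L]) {
    last <- merged[[length(merged)]]
    if (r$i_start <= last$i_end) {
      last$i_end <- max(last$i_end, r$i_end)
      if (y[r$i_peak] > y[last$i_peak]) {
        last$i_peak <- r$i_peak; last$T_peak <- r$T_peak
      }
      last$overlapping <- TRUE
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- r
    }
  }
  merged
}

# Smoothed derivative dy/dx on a uniform grid (Savitzky-Golay when the
# window fits, plain central differences otherwise).
smoothed_derivative <- function(x, y, sg_window = 9L) {
  dx <- mean(diff(x))
  n <- length(y)
  sg_window <- min(sg_window, if (n %% 2L == 0L) n - 1L else n)
  if (sg_window %% 2L == 0L) sg_window <- sg_window - 1L
  if (sg_window >= 5L && n >= sg_window) {
    signal::sgolayfilt(y, p = 3, n = sg_window, m = 1) / dx
  } else {
    c(diff(y)[1L], (y[-(1:2)] - y[1:(n - 2L)]) / 2, diff(y)[n - 1L]) / dx
  }
}

#' Tangent-method onset and completion temperatures
#'
#' The tangent to the leading edge of the endotherm at its steepest point
#' (maximum of a Savitzky-Golay smoothed derivative) is intersected with the
#' zero baseline to give the onset temperature; the completion temperature is
#' the mirrored construction on the trailing edge. For a Gaussian peak of
#' center c and standard deviation s on a flat baseline both constructions
#' have the closed form c -/+ 2 s.
#'
#' @param thermo Baseline-corrected [thermogram].
#' @param region One region from [detect_transitions()].
#' @param sg_window Savitzky-Golay window length (odd, points). Default 9.
#' @return Named numeric `c(T_onset, T_completion)` in degrees C.
#' @export
onset_completion <- function(thermo, region, sg_window = 9L) {
  stopifnot(inherits(thermo, "thermogram"))
  idx <- region$i_start:region$i_end
  x <- thermo$curve$x[idx]; y <- thermo$curve$y[idx]
  ipk <- region$i_peak - region$i_start + 1L
  if (ipk <= 1L || ipk >= length(idx)) {
    stop("region is monotone: no interior maximum to take tangents from",
         call. = FALSE)
  }
  dydx <- smoothed_derivative(x, y, sg_window)
  i_lead <- which.max(dydx[seq_len(ipk)])
  i_trail <- ipk - 1L + which.min(dydx[ipk:length(idx)])
  tangent_zero <- function(i) {
    if (abs(dydx[i]) < 1e-12) stop("degenerate tangent: zero slope", call. = FALSE)
    x[i] - y[i] / dydx[i]
  }
  c(T_onset = tangent_zero(i_lead), T_completion = tangent_zero(i_trail))
}

#' Transition enthalpy by trapezoidal integration
#'
#' Integrates the baseline-corrected excess heat capacity over the region.
#' With y in kJ mol^-1 K^-1 and x in degrees C the area is the molar
#' transition enthalpy in kJ/mol. A detection region (delimited at 1 percent
#' of the peak height) is first padded outward along the monotonically
#' decaying tails down to 0.1 percent of the peak height, so the truncation
#' error for a Gaussian-like endotherm is below 0.1 percent of its area.
#' Explicit `c(lo, hi)` temperature intervals are integrated as given.
#'
#' @param thermo Baseline-corrected [thermogram].
#' @param region One region from [detect_transitions()], or a length-2
#'   temperature interval.
#' @return Enthalpy (kJ/mol).
#' @export
enthalpy <- function(thermo, region) {
  stopifnot(inherits(thermo, "thermogram"))
  x <- thermo$curve$x; y <- thermo$curve$y
  if (is.numeric(region) && length(region) == 2L) {
    region <- sort(region)
    if (region[1] < min(x) - 1e-9 || region[2] > max(x) + 1e-9) {
      stop("integration region extends beyond the data", call. = FALSE)
    }
    idx <- which(x >= region[1] & x <= region[2])
  } else {
    lo <- region$i_start; hi <- region$i_end
    thr <- 0.001 * y[region$i_peak]
    while (lo > 1L && y[lo - 1L] <= y[lo] && y[lo - 1L] >= thr) lo <- lo - 1L
    while (hi < length(y) && y[hi + 1L] <= y[hi] && y[hi + 1L] >= thr) hi <- hi + 1L
    idx <- lo:hi
  }
  if (length(idx) < 2L) stop("integration region too narrow", call. = FALSE)
  pracma::trapz(x[idx], y[idx])
}

#' Full thermogram characterization
#'
#' Convenience wrapper: baseline correction (when windows are given),
#' transition detection, tangent onset/completion and enthalpy per region,
#' with labels assigned by enthalpy rank: the most energetic peak is the
#' `main` transition, any smaller peak at lower temperature is the
#' `pretransition`, everything else is `extra`.
#'
#' @param thermo A [thermogram].
#' @param pre_window,post_window Optional baseline windows (degrees C).
#' @param min_prominence Passed to [detect_transitions()].
#' @param sg_window Passed to [onset_completion()].
#' @return Data frame with columns `label`, `T_onset`, `T_peak`,
#'   `T_completion`, `delta_H`, `overlapping`.
#' @export
analyze_thermogram <- function(thermo, pre_window = NULL, post_window = NULL,
                               min_prominence = 0.5, sg_window = 9L) {
  if (!is.null(pre_window) && !is.null(post_window)) {
    thermo <- subtract_baseline(thermo, pre_window, post_window)
  }
  regions <- detect_transitions(thermo, min_prominence)
  if (!length(regions)) {
    return(data.frame(label = character(0), T_onset = numeric(0),
                      T_peak = numeric(0), T_completion = numeric(0),
                      delta_H = numeric(0), overlapping = logical(0)))
  }
  rows <- lapply(regions, function(r) {
    oc <- onset_completion(thermo, r, sg_window)
    data.frame(T_onset = oc[["T_onset"]], T_peak = r$T_peak,
               T_completion = oc[["T_completion"]],
               delta_H = enthalpy(thermo, r), overlapping = r$overlapping)
  })
  out <- do.call(rbind, rows)
  main <- which.max(out$delta_H)
  out$label <- "extra"
  out$label[main] <- "main"
  out$label[out$T_peak < out$T_peak[main] & seq_len(nrow(out)) != main] <- "pretransition"
  out[, c("label", "T_onset", "T_peak", "T_completion", "delta_H", "overlapping")]
}

#' Assemble a partial phase diagram from per-composition transitions
#'
#' Onset temperatures of the main transition trace the solidus boundary and
#' completion temperatures the fluidus; the fluidus minus solidus gap is the
#' gel/fluid coexistence width at each composition.
#'
#' @param transitions Data frame with columns `mole_fraction`, `onset`,
#'   `completion` (degrees C), one row per composition.
#' @return An object of class `phase_diagram`: `points` (sorted by mole
#'   fraction, with `coexistence_width`), plus immiscibility `flags` filled
#'   by [detect_immiscibility()] when called through [annotate_miscibility()].
#' @export
build_phase_diagram <- function(transitions) {
  stopifnot(is.data.frame(transitions),
            all(c("mole_fraction", "onset", "completion") %in% names(transitions)))
  if (anyDuplicated(transitions$mole_fraction)) {
    stop("compositions must be distinct", call. = FALSE)
  }
  bad <- transitions$onset > transitions$completion
  if (any(bad)) {
    stop(sprintf("onset exceeds completion at mole fraction %g",
                 transitions$mole_fraction[which(bad)[1L]]), call. = FALSE)
  }
  pts <- transitions[order(transitions$mole_fraction),
                     c("mole_fraction", "onset", "completion")]
  names(pts) <- c("mole_fraction", "solidus", "fluidus")
  pts$coexistence_width <- pts$fluidus - pts$solidus
  rownames(pts) <- NULL
  structure(list(points = pts, flags = NULL), class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %d compositions\n", nrow(x$points)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Flag immiscibility plateaus on a phase boundary
#'
#' A compound that does not mix with the phospholipid leaves the transition
#' temperature unchanged as its concentration grows, so a flat run on the
#' solidus or fluidus signals immiscibility in that phase. Maximal runs of at
#' least 3 consecutive boundary points whose temperature spread is at most
#' `T_tolerance` are flagged `immiscible`; the remaining segments are
#' `mixing`.
#'
#' @param boundary Data frame (or two-column matrix) with columns `x` (mole
#'   fraction) and `T` (degrees C), or a `phase_diagram` plus `which`.
#' @param T_tolerance Temperature spread (degrees C) below which a run counts
#'   as constant. Default 0.3, the order of peak-position reproducibility.
#' @return Data frame of segments: `i_start`, `i_end` (point indices into the
#'   sorted boundary), `x_start`, `x_end`, `flag`.
#' @export
detect_immiscibility <- function(boundary, T_tolerance = 0.3) {
  boundary <- as.data.frame(boundary)
  names(boundary)[1:2] <- c("x", "T")
  if (nrow(boundary) < 3L) stop("need at least 3 boundary points", call. = FALSE)
  boundary <- boundary[order(boundary$x), ]
  n <- nrow(boundary)
  Tv <- boundary$T
  # maximal windows with spread <= tolerance, length >= 3
  runs <- list()
  i <- 1L
  while (i <= n - 2L) {
    j <- i
    while (j < n && diff(range(Tv[i:(j + 1L)])) <= T_tolerance) j <- j + 1L
    if (j - i + 1L >= 3L) {
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  seg <- function(i1, i2, flag) data.frame(i_start = i1, i_end = i2,
                                           x_start = boundary$x[i1],
                                           x_end = boundary$x[i2],
                                           flag = flag,
                                           stringsAsFactors = FALSE)
  out <- list()
  pos <- 1L
  for (r in runs) {
    if (r[1] > pos) out[[length(out) + 1L]] <- seg(pos, r[1] - 1L, "mixing")
    out[[length(out) + 1L]] <- seg(r[1], r[2], "immiscible")
    pos <- r[2] + 1L
  }
  if (pos <= n) out[[length(out) + 1L]] <- seg(pos, n, "mixing")
  do.call(rbind, out)
}

#' Annotate a phase diagram with miscibility flags
#'
#' Runs [detect_immiscibility()] on both the solidus and the fluidus.
#'
#' @param pd A `phase_diagram`.
#' @param T_tolerance Passed to [detect_immiscibility()].
#' @return The `phase_diagram` with `flags` set: a list with `solidus` and
#'   `fluidus` segment data frames.
#' @export
annotate_miscibility <- function(pd, T_tolerance = 0.3) {
  stopifnot(inherits(pd, "phase_diagram"))
  pd$flags <- list(
    solidus = detect_immiscibility(pd$points[, c("mole_fraction", "solidus")],
                                   T_tolerance),
    fluidus = detect_immiscibility(pd$points[, c("mole_fraction", "fluidus")],
                                   T_tolerance))
  pd
}
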