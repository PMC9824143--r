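#' Sub-resolution position of a band maximum
#'
#' Finds the discrete maximum of the spectrum inside the window and refines
#' it by the vertex of a quadratic fit through the five points around it,
#' giving a sub-grid estimate of the band maximum wavenumber. The estimate is
#' invariant under uniform intensity scaling and constant offsets.
#'
#' @param spectrum [xy_curve] with x = wavenumber (cm^-1).
#' @param window Length-2 wavenumber interval, default the ester carbonyl
#'   region `c(1670, 1780)`.
#' @return Wavenumber of the maximum (cm^-1). Warns (`"truncated band"`) and
#'   returns the edge wavenumber when the maximum sits on a window edge.
#' @export
band_maximum <- function(spectrum, window = c(1670, 1780)) {
  stopifnot(inherits(spectrum, "xy_curve"))
  s <- crop_curve(spectrum, window)
  i <- which.max(s$y)
  n <- length(s$x)
  if (i <= 2L || i >= n - 1L) {
    warning("truncated band: maximum at the window edge")
    return(s$x[i])
  }
  idx <- (i - 2L):(i + 2L)
  fit <- stats::lm.fit(cbind(1, s$x[idx], s$x[idx]^2), s$y[idx])
  a <- fit$coefficients[3L]; b <- fit$coefficients[2L]
  if (!is.finite(a) || a >= 0) return(s$x[i])
  vx <- -b / (2 * a)
  # keep the refinement inside the stencil
  min(max(vx, s$x[i - 2L]), s$x[i + 2L])
}

#' Decompose the ester carbonyl band into two components
#'
#' The carbonyl stretching band of a hydrated phospholipid is a superposition
#' of a non-hydrogen-bonded component near 1742 cm^-1 and a hydrogen-bonded
#' component near 1728 cm^-1; the relative area of the low-wavenumber
#' component, `f_hbond`, tracks the hydrogen-bonded subpopulation. The fit is
#' a two-Gaussian least squares with component centers bounded to +/- 6
#' cm^-1 of the initial guesses.
#'
#' @param spectrum Baseline-flattened [xy_curve] over the carbonyl window.
#' @param init_centers Initial component centers, default `c(1742, 1728)`.
#' @param center_bound Half-width of the center bound (cm^-1), default 6.
#' @param seed Seed for fit restarts.
#' @return An object of class `carbonyl_fit`: `center_high`, `center_low`,
#'   `width_high`, `width_low` (Gaussian sd, cm^-1), `area_high`, `area_low`,
#'   and `f_hbond` = area_low / (area_low + area_high).
#' @export
decompose_carbonyl <- function(spectrum, init_centers = c(1742, 1728),
                               center_bound = 6, seed = 1) {
  stopifnot(inherits(spectrum, "xy_curve"), length(init_centers) == 2L)
  x <- spectrum$x; y <- spectrum$y
  c_hi <- max(init_centers); c_lo <- min(init_centers)
  total <- max(pracma::trapz(x, pmax(y, 0)), 1e-12)
  p0 <- c(c1 = c_hi, w1 = 8, a1 = total / 2,
          c2 = c_lo, w2 = 8, a2 = total / 2)
  lo <- c(c_hi - center_bound, 1, 0, c_lo - center_bound, 1, 0)
  hi <- c(c_hi + center_bound, 30, Inf, c_lo + center_bound, 30, Inf)
  model <- function(p) {
    p[["a1"]] * stats::dnorm(x, p[["c1"]], p[["w1"]]) +
      p[["a2"]] * stats::dnorm(x, p[["c2"]], p[["w2"]])
  }
  resid_fn <- function(p) y - model(p)
  starts <- with_seed(seed, lapply(1:3, function(k) {
    if (k == 1L) p0 else {
      s <- p0 * exp(stats::rnorm(length(p0), 0, 0.05))
      pmin(pmax(s, lo), hi)
    }
  }))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(minpack.lm::nls.lm(par = s, lower = lo, upper = hi,
                                       fn = resid_fn,
                                       control = minpack.lm::nls.lm.control(maxiter = 200)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best) || !(best$info %in% 1:4)) {
    stop("carbonyl decomposition did not converge", call. = FALSE)
  }
  p <- best$par
  comp <- data.frame(center = c(p[["c1"]], p[["c2"]]),
                     width = c(p[["w1"]], p[["w2"]]),
                     area = c(p[["a1"]], p[["a2"]]))
  comp <- comp[order(comp$center), ]  # low first, reordered if swapped
  f_hbond <- comp$area[1] / max(sum(comp$area), 1e-300)
  structure(list(center_low = comp$center[1], center_high = comp$center[2],
                 width_low = comp$width[1], width_high = comp$width[2],
                 area_low = comp$area[1], area_high = comp$area[2],
                 f_hbond = f_hbond, residual = best$deviance,
                 fitted = model(best$par), x = x, observed = y),
            class = "carbonyl_fit")
}

#' @export
print.carbonyl_fit <- function(x, ...) {
  cat(sprintf("<carbonyl_fit> components %.1f / %.1f cm^-1, f_hbond = %.3f\n",
              x$center_low, x$center_high, x$f_hbond))
  invisible(x)
}

#' Track the carbonyl band maximum across temperature
#'
#' Computes [band_maximum()] for each spectrum of a temperature series and
#' fits a descending logistic sigmoid nu(T) = nu_gel - drop / (1 +
#' exp(-(T - T_m)/s)) to the maxima; the midpoint T_m estimates the phase
#' transition temperature seen by the interfacial carbonyls. When the sigmoid
#' does not beat a constant model by the corrected Akaike criterion, the
#' series is deemed non-sigmoidal and the midpoint reported as `NA`.
#'
#' @param spectra List of [xy_curve] spectra.
#' @param temperatures Numeric, degrees C, one per spectrum; taken from each
#'   spectrum's `meta$temperature` when omitted.
#' @param window Passed to [band_maximum()].
#' @return List with `curve` (an [xy_curve] of band maximum vs temperature),
#'   `midpoint` (degrees C or `NA`), `amplitude` (wavenumber drop, cm^-1).
#' @export
maximum_vs_temperature <- function(spectra, temperatures = NULL,
                                   window = c(1670, 1780)) {
  stopifnot(is.list(spectra), length(spectra) >= 5L)
  if (is.null(temperatures)) {
    temperatures <- vapply(spectra, function(s) {
      t <- s$meta$temperature
      if (is.null(t)) NA_real_ else as.numeric(t)
    }, numeric(1))
  }
  if (anyNA(temperatures)) {
    stop("temperatures missing: supply them or set meta$temperature",
         call. = FALSE)
  }
  nu <- vapply(spectra, band_maximum, numeric(1), window = window)
  ord <- order(temperatures)
  Tv <- temperatures[ord]; nu <- nu[ord]
  n <- length(Tv)

  rss_const <- sum((nu - mean(nu))^2)
  # the sigmoid width is bounded below by a fraction of the sampling step:
  # narrower widths make the midpoint unidentifiable between two samples
  s_lo <- max(0.25 * stats::median(diff(Tv)), 1e-3)
  lo <- c(-Inf, 0, min(Tv), s_lo)
  hi <- c(Inf, Inf, max(Tv), diff(range(Tv)))
  resid_fn <- function(p) {
    nu - (p[["nu_gel"]] - p[["drop"]] * stats::plogis((Tv - p[["T_m"]]) / p[["s"]]))
  }
  fit <- NULL
  for (tm0 in unique(c(Tv[which.min(abs(nu - mean(range(nu))))],
                       Tv[-c(1, n)]))) {
    p0 <- c(nu_gel = max(nu), drop = max(diff(range(nu)), 1e-6),
            T_m = tm0, s = max(diff(range(Tv)) / 10, s_lo))
    cand <- tryCatch(minpack.lm::nls.lm(par = p0, lower = lo, upper = hi,
                                        fn = resid_fn,
                                        control = minpack.lm::nls.lm.control(maxiter = 200)),
                     error = function(e) NULL)
    if (!is.null(cand) && cand$info %in% 1:4 &&
        (is.null(fit) || cand$deviance < fit$deviance)) {
      fit <- cand
    }
  }
  aicc <- function(rss, k) n * log(max(rss, 1e-300) / n) + 2 * k +
    if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
  midpoint <- NA_real_; amplitude <- NA_real_
  if (!is.null(fit) && fit$info %in% 1:4 &&
      aicc(fit$deviance, 4L) < aicc(rss_const, 1L)) {
    midpoint <- fit$par[["T_m"]]
    amplitude <- fit$par[["drop"]]
  }
  list(curve = xy_curve(Tv, nu, meta = list(x_unit = "degC")),
       midpoint = midpoint, amplitude = amplitude)
}
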