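# Michaelis-Menten uptake kinetics: forward depletion model (Lambert-W closed
# form) and bounded nonlinear least-squares fits to depletion series and to
# rate-vs-concentration data.

#' Lambert W of an exponential argument
#'
#' Evaluates `W(exp(a))` on the principal branch, i.e. the unique `w > 0`
#' with `w + log(w) = a`. Working from the log of the argument keeps the
#' evaluation stable when `exp(a)` would overflow (substrate far above the
#' half-saturation constant) or underflow (deep depletion). Solved by Newton
#' iteration on `u + e^u = a` with `u = log(w)`; the iteration is globally
#' convergent because the map is smooth, convex, and increasing.
#'
#' @param a Numeric vector of log-arguments (may be any finite value; `-Inf`
#'   returns 0).
#' @return `W(exp(a))`, same length as `a`.
#' @export
lambert_w_exp <- function(a) {
  vapply(a, function(ai) {
    if (is.na(ai)) return(NA_real_)
    if (ai == -Inf) return(0)
    if (!is.finite(ai)) abort("lambert_w_exp: non-finite argument")
    if (ai < -36) return(exp(ai)) # w = e^a(1 - e^a + ...): correction < eps
    u <- if (ai > 1) log(ai) else ai - exp(min(ai, 1))
    for (i in seq_len(100)) {
      eu <- exp(u)
      d <- (eu + u - ai) / (eu + 1)
      u <- u - d
      if (abs(d) < 1e-15) break
    }
    exp(u)
  }, numeric(1))
}

#' Michaelis-Menten uptake rate
#'
#' Specific uptake rate at external concentration `C`:
#' `Imax * (C - Cmin) / (Km + (C - Cmin))` for `C > Cmin`, else 0. `Cmin` is
#' an optional concentration floor at which net uptake ceases.
#'
#' @param conc_uM External concentration (µM), vectorized.
#' @param imax Maximum specific uptake rate (µmol cm⁻¹ h⁻¹).
#' @param km Half-saturation constant (µM), positive.
#' @param cmin Concentration floor (µM), default 0.
#' @return Specific uptake rate (µmol cm⁻¹ h⁻¹).
#' @export
mm_rate <- function(conc_uM, imax, km, cmin = 0) {
  stopifnot(imax >= 0, km > 0, cmin >= 0)
  s <- pmax(conc_uM - cmin, 0)
  imax * s / (km + s)
}

#' Closed-form concentration of a Michaelis-Menten depletion
#'
#' In a closed chamber of volume `V` containing a root system of length `L`
#' taking nutrient up at the Michaelis-Menten specific rate, the concentration
#' obeys `dC/dt = -(Imax * L / V) * (C - Cmin) / (Km + (C - Cmin))`. The
#' integrated trajectory satisfies
#' `Km * log((C0 - Cmin)/(C - Cmin)) + (C0 - C) = (Imax * L / V) * t` and has
#' the closed form `C(t) = Cmin + Km * W(exp(a))` with
#' `a = log((C0 - Cmin)/Km) + (C0 - Cmin - k t)/Km`, evaluated in the log
#' domain so extreme `C0/Km` regimes stay finite.
#'
#' @param t_h Time since the start (h), vectorized.
#' @param c0_uM Initial concentration (µM), must exceed `cmin`.
#' @param imax,km,cmin Kinetic parameters as in [mm_rate()].
#' @param root_length_cm Root length `L` (cm).
#' @param volume_ml Chamber volume `V` (mL).
#' @return Concentration (µM) at each `t_h`, bounded below by `cmin`.
#' @examples
#' # half-depletion time for C0=1000, Km=100, k=200 uM/h:
#' mm_depletion_conc((100 * log(2) + 500) / 200, 1000,
#'   imax = 0.1, km = 100, root_length_cm = 500, volume_ml = 250
#' ) # 500
#' @export
mm_depletion_conc <- function(t_h, c0_uM, imax, km, root_length_cm,
                              volume_ml, cmin = 0) {
  if (!all(is.finite(c(c0_uM, imax, km, root_length_cm, volume_ml, cmin)))) {
    abort("mm_depletion_conc: non-finite parameter")
  }
  stopifnot(km > 0, imax >= 0, cmin >= 0, c0_uM > cmin,
            root_length_cm > 0, volume_ml > 0, all(t_h >= 0))
  k <- imax * root_length_cm / (volume_ml / 1000) # uM per h
  s0 <- c0_uM - cmin
  a <- log(s0 / km) + (s0 - k * t_h) / km
  pmax(cmin + km * lambert_w_exp(a), cmin)
}

.new_mm_fit <- function(params, data, method, diagnostics) {
  structure(list(params = params, data = data, method = method,
                 diagnostics = diagnostics), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> method: %s, n = %d, converged: %s\n",
              x$method, x$diagnostics$n, x$diagnostics$converged))
  print(x$params)
  invisible(x)
}

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit` from [fit_depletion()] or [fit_rates()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) x$params

#' One-row fit summary
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return Tibble with `n`, `rss`, `sigma`, `converged`, `km_reliable`,
#'   `method`.
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble(n = d$n, rss = d$rss, sigma = d$sigma, converged = d$converged,
         km_reliable = d$km_reliable, method = x$method)
}

#' Model predictions from a Michaelis-Menten fit
#'
#' @param object An `mm_fit`.
#' @param newdata Optional tibble with `time_h` (depletion fits) or `conc_uM`
#'   (rate fits); defaults to the fitted data.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations or rates.
#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  p <- setNames(object$params$estimate, object$params$term)
  d <- object$diagnostics
  if (object$method == "depletion") {
    t_h <- (newdata %||% object$data)$time_h
    mm_depletion_conc(t_h, d$c0_uM, p[["imax"]], p[["km"]],
                      d$root_length_cm, d$volume_ml,
                      cmin = if ("cmin" %in% names(p)) p[["cmin"]] else d$cmin)
  } else {
    conc <- (newdata %||% object$data)$conc_uM
    mm_rate(conc, p[["imax"]], p[["km"]],
            cmin = if ("cmin" %in% names(p)) p[["cmin"]] else d$cmin)
  }
}

.mm_se <- function(fit, terms) {
  se <- rep(NA_real_, length(terms))
  v <- tryCatch(vcov(fit), error = function(e) NULL)
  if (!is.null(v)) se <- sqrt(pmax(diag(v), 0))[seq_along(terms)]
  se
}

.km_reliable <- function(min_conc, km_hat) {
  # series never leaving the saturating regime cannot pin Km
  is.finite(km_hat) && min_conc <= 10 * km_hat
}

#' Fit Michaelis-Menten kinetics to a depletion time series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of observed
#' concentrations against the closed-form depletion trajectory
#' [mm_depletion_conc()]. The loss is on concentrations, the observable.
#' Initialization is data-driven: the `Imax` start is the steepest early
#' two-point depletion slope times `V/L`, the `Km` start is `C0/2`, and an
#' optional deterministic multistart grid over `Km` guards against local
#' minima. Poor fits set a non-convergence flag rather than erroring; a
#' series that never leaves the saturating regime (all concentrations above
#' ten times the estimated `Km`) flags `km_reliable = FALSE`.
#'
#' @param series Tibble with `time_h` and `conc_uM` (at least 4 points; 5 if
#'   `fix_cmin = FALSE`).
#' @param root_length_cm,volume_ml Root length (cm) and chamber volume (mL).
#' @param c0_uM Initial concentration; defaults to the designed value being
#'   the first observation.
#' @param fix_cmin Keep the concentration floor fixed (at `cmin`); freeing it
#'   costs identifiability on short series. Default TRUE.
#' @param cmin Value of the fixed floor (µM), default 0.
#' @param multistart Use a deterministic 5-point `Km` start grid in addition
#'   to the data-driven start (default TRUE; the depletion objective can hold
#'   a spurious local minimum at the zero-order limit `Km -> 0`).
#' @return An `mm_fit` object; see [tidy.mm_fit()] and [glance.mm_fit()].
#' @export
fit_depletion <- function(series, root_length_cm, volume_ml = 250,
                          c0_uM = NULL, fix_cmin = TRUE, cmin = 0,
                          multistart = TRUE) {
  stopifnot(all(c("time_h", "conc_uM") %in% names(series)))
  series <- series[is.finite(series$time_h) & is.finite(series$conc_uM), ]
  series <- series[order(series$time_h), ]
  npar <- if (fix_cmin) 2L else 3L
  if (nrow(series) < npar + 2L) {
    abort(sprintf("fit_depletion: need at least %d timepoints for %d parameters",
                  npar + 2L, npar))
  }
  y <- series$conc_uM
  tt <- series$time_h
  if (diff(range(y)) == 0) abort("fit_depletion: constant series, no depletion signal")
  c0 <- c0_uM %||% y[1]
  slope <- max((y[1] - y[-1]) / pmax(tt[-1] - tt[1], 1e-12))
  i0 <- max(slope * (volume_ml / 1000) / root_length_cm, 1e-8)
  km_starts <- c0 / 2
  if (multistart) km_starts <- unique(c(km_starts, c0 * c(0.01, 0.1, 0.5, 2, 10)))
  cmin_start <- if (fix_cmin) NULL else max(min(y) * 0.5, 0)

  best <- NULL
  best_rss <- Inf
  for (km0 in km_starts) {
    fit <- tryCatch({
      if (fix_cmin) {
        minpack.lm::nlsLM(
          y ~ mm_depletion_conc(tt, c0, imax, km, root_length_cm, volume_ml, cmin),
          start = list(imax = i0, km = km0),
          lower = c(1e-12, 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        minpack.lm::nlsLM(
          y ~ mm_depletion_conc(tt, c0, imax, km, root_length_cm, volume_ml, cminf),
          start = list(imax = i0, km = km0, cminf = cmin_start),
          lower = c(1e-12, 1e-9, 0), upper = c(Inf, Inf, min(y) * (1 - 1e-9)),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  n <- length(y)
  if (is.null(best)) {
    params <- tibble(term = c("imax", "km", if (!fix_cmin) "cmin"),
                     estimate = NA_real_, std.error = NA_real_)
    diag <- list(n = n, rss = NA_real_, sigma = NA_real_, converged = FALSE,
                 km_reliable = FALSE, c0_uM = c0, cmin = cmin,
                 root_length_cm = root_length_cm, volume_ml = volume_ml)
    return(.new_mm_fit(params, series, "depletion", diag))
  }
  est <- coef(best)
  terms <- c("imax", "km", if (!fix_cmin) "cmin")
  params <- tibble(term = terms, estimate = unname(est),
                   std.error = .mm_se(best, terms))
  conv <- isTRUE(best$convInfo$isConv)
  diag <- list(n = n, rss = best_rss,
               sigma = sqrt(best_rss / max(n - npar, 1)),
               converged = conv,
               km_reliable = .km_reliable(min(y), est[["km"]]),
               c0_uM = c0, cmin = cmin,
               root_length_cm = root_length_cm, volume_ml = volume_ml)
  .new_mm_fit(params, series, "depletion", diag)
}

#' Fit Michaelis-Menten kinetics to rate-versus-concentration data
#'
#' Direct nonlinear least squares of specific uptake rates against the
#' Michaelis-Menten response [mm_rate()], for across-concentration
#' characterization. Shares bounds, initialization logic, and diagnostics
#' with [fit_depletion()]. Rates indistinguishable across concentrations
#' leave `Km` unidentified, which is reported via `km_reliable`/`converged`
#' rather than raised.
#'
#' @param data Tibble with `conc_uM` and `rate` (≥ 3 distinct concentrations).
#' @param cmin Fixed concentration floor (µM), default 0.
#' @return An `mm_fit` object.
#' @export
fit_rates <- function(data, cmin = 0) {
  stopifnot(all(c("conc_uM", "rate") %in% names(data)))
  data <- data[is.finite(data$conc_uM) & is.finite(data$rate), ]
  if (nrow(data) < 3 || length(unique(data$conc_uM)) < 3) {
    abort("fit_rates: need at least 3 distinct (concentration, rate) pairs")
  }
  conc <- data$conc_uM
  r <- data$rate
  i0 <- max(r, 1e-8)
  km_starts <- unique(pmax(median(conc) * c(0.01, 0.1, 0.5, 1, 5), 1e-6))
  fit <- NULL
  best_rss <- Inf
  for (km0 in km_starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(r ~ mm_rate(conc, imax, km, cmin),
                        start = list(imax = i0 * (km0 + median(conc)) / median(conc),
                                     km = km0),
                        lower = c(1e-12, 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(cand)) {
      rss_c <- sum(residuals(cand)^2)
      if (rss_c < best_rss) {
        fit <- cand
        best_rss <- rss_c
      }
    }
  }
  n <- nrow(data)
  if (is.null(fit)) {
    params <- tibble(term = c("imax", "km"), estimate = NA_real_,
                     std.error = NA_real_)
    diag <- list(n = n, rss = NA_real_, sigma = NA_real_, converged = FALSE,
                 km_reliable = FALSE, cmin = cmin)
    return(.new_mm_fit(params, data, "rates", diag))
  }
  est <- coef(fit)
  rss <- sum(residuals(fit)^2)
  se <- .mm_se(fit, c("imax", "km"))
  # flat response: Km SE dwarfing the estimate, or Km collapsed to a bound
  km_ok <- is.finite(se[2]) && se[2] < 10 * abs(est[["km"]]) &&
    .km_reliable(min(conc), est[["km"]])
  params <- tibble(term = c("imax", "km"), estimate = unname(est),
                   std.error = se)
  diag <- list(n = n, rss = rss, sigma = sqrt(rss / max(n - 2, 1)),
               converged = isTRUE(fit$convInfo$isConv) && km_ok,
               km_reliable = km_ok, cmin = cmin)
  .new_mm_fit(params, data, "rates", diag)
}

#' Interval rates and midpoint concentrations from a depletion series
#'
#' Converts a depletion series into per-interval specific rates (amount
#' removed per root length per hour) at interval-midpoint concentrations,
#' suitable for [fit_rates()].
#'
#' @param series Tibble with `time_h`, `conc_uM`.
#' @param root_length_cm,volume_ml Normalization as in [fit_depletion()].
#' @return Tibble `conc_uM` (midpoint), `rate`.
#' @export
depletion_to_rates <- function(series, root_length_cm, volume_ml = 250) {
  series <- series[order(series$time_h), ]
  tt <- series$time_h
  y <- series$conc_uM
  n <- length(tt)
  if (n < 2) abort("depletion_to_rates: need at least 2 timepoints")
  tibble(
    conc_uM = (y[-n] + y[-1]) / 2,
    rate = (y[-n] - y[-1]) * (volume_ml / 1000) / (tt[-1] - tt[-n]) / root_length_cm
  )
}
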