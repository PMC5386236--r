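#' Tidiers for fitted objects
#'
#' Broom-style `tidy()` and `glance()` methods: `tidy()` returns one row
#' per estimated quantity, `glance()` a one-row model summary.
#'
#' @param x A `q10_fit`, `warming_effect`, or `qc_calibration`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.q10_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("q10", "r_ref"),
    estimate = c(x$q10, x$r_ref),
    ## delta method: se(exp(10 b)) = exp(10 b) * 10 * se(b)
    std.error = c(x$q10 * x$se_log_q10, NA_real_),
    statistic = c(s[2, 3], NA_real_),
    p.value = c(s[2, 4], NA_real_)
  )
}

#' @rdname tidiers
#' @export
glance.q10_fit <- function(x, ...) {
  tibble::tibble(
    q10 = x$q10, r_ref = x$r_ref, t_ref = x$t_ref,
    r.squared = x$r_squared, nobs = x$n, n_excluded = x$n_excluded,
    t_span = x$t_span
  )
}

#' @rdname tidiers
#' @export
tidy.warming_effect <- function(x, ...) {
  tibble::tibble(
    term = c("fe", "dt", "rh_calibrated", "rhw_calibrated", "qc_h", "qc_hw"),
    estimate = c(x$fe, x$dt, x$rh_cal, x$rhw_cal, x$qch, x$qcw)
  )
}

#' @rdname tidiers
#' @export
glance.warming_effect <- function(x, ...) {
  tibble::tibble(fe = x$fe, dt = x$dt, n_hours = x$n_hours,
                 method = x$method)
}

#' @rdname tidiers
#' @export
tidy.qc_calibration <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
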