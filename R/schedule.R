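# Tension schedules: in-plane tension as a function of developmental time.

#' Build a tension schedule
#'
#' Tension values are in the recoil-velocity proxy units (um/s-like,
#' arbitrary); they must be nonnegative.
#'
#' * `constant`: `parameters = list(T0 = ...)`.
#' * `linear_ramp`: `list(T0, T1, t0, t1)`; linear between `(t0, T0)` and
#'   `(t1, T1)`, clamped outside.
#' * `piecewise_table`: `list(times = ..., tensions = ...)` with strictly
#'   increasing breakpoint times; linear interpolation, clamped outside.
#'
#' @param kind `"constant"`, `"linear_ramp"` or `"piecewise_table"`.
#' @param parameters named list as above.
#' @return A [TensionSchedule-class].
#' @export
makeTensionSchedule <- function(kind = c("constant", "linear_ramp", "piecewise_table"),
                                parameters) {
  kind <- match.arg(kind)
  p <- parameters
  bad <- switch(kind,
    constant = is.null(p$T0) || p$T0 < 0,
    linear_ramp = any(vapply(c("T0", "T1", "t0", "t1"), function(k) is.null(p[[k]]),
                             logical(1))) || p$T0 < 0 || p$T1 < 0 || p$t1 <= p$t0,
    piecewise_table = is.null(p$times) || is.null(p$tensions) ||
      length(p$times) != length(p$tensions) || any(diff(p$times) <= 0) ||
      any(p$tensions < 0))
  if (bad) .configError(sprintf("invalid parameters for %s tension schedule", kind))
  new("TensionSchedule", kind = kind, parameters = p)
}

#' Evaluate a tension schedule
#'
#' @param schedule a [TensionSchedule-class].
#' @param t developmental times (hAPF).
#' @return Nonnegative tension values (proxy units).
#' @export
tensionAt <- function(schedule, t) {
  p <- schedule@parameters
  switch(schedule@kind,
    constant = rep(p$T0, length(t)),
    linear_ramp = {
      tc <- pmin(pmax(t, p$t0), p$t1)
      p$T0 + (p$T1 - p$T0) * (tc - p$t0) / (p$t1 - p$t0)
    },
    piecewise_table = approx(p$times, p$tensions, xout = t, rule = 2)$y)
}
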