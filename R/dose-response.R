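#' Inhibitory Emax response
#'
#' Evaluates \eqn{E(c) = E_0 (1 - E_{max} c^\gamma / (IC_{50}^\gamma +
#' c^\gamma))}: the tumor growth response as a function of intracellular
#' payload concentration. Strictly decreasing in `conc`, from `E0` at zero
#' payload to `E0 * (1 - Emax)` at saturating payload, with the
#' half-maximal effect at `conc = IC50` for any Hill coefficient.
#'
#' @param conc Payload concentration, nM (vectorized, each >= 0).
#' @param params A [dose_response_params()] object.
#' @return Response in the units of `E0`.
#' @examples
#' dr <- dose_response_params()
#' emax_inhibition(c(0, 300), dr) # E0 and E0 * (1 - Emax/2)
#' @export
emax_inhibition <- function(conc, params) {
  stopifnot(inherits(params, "dose_response_params"))
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0)) {
    abort("`conc` must be non-negative finite payload concentrations (nM).")
  }
  cg <- conc^params$gamma_hill
  params$E0 * (1 - params$Emax * cg / (params$IC50^params$gamma_hill + cg))
}

#' Net tumor growth rate and regime at a payload concentration
#'
#' Under exponential growth the TGI equation reduces to
#' `dT/dt = (c E(conc) - lambda) T`, so the sign of
#' `c * E(conc) - lambda` decides whether the tumor grows or decays.
#' Rates within `tol` of zero are labelled `"critical"`.
#'
#' @param conc Payload concentration, nM (vectorized).
#' @param dr A [dose_response_params()] object.
#' @param c_growth Growth coefficient, per (nM day).
#' @param lam Degradation rate, per day.
#' @param tol Half-width of the critical band, per day.
#' @return Tibble with columns `conc`, `rate` (per day) and `regime`
#'   (`"growing"`, `"decaying"` or `"critical"`).
#' @examples
#' net_growth_rate(0, dose_response_params()) # drug-free: 0.052/day, growing
#' @export
net_growth_rate <- function(conc, dr, c_growth = 4.6e-3, lam = 0.5,
                            tol = 1e-9) {
  stopifnot(inherits(dr, "dose_response_params"))
  check_scalar(c_growth, "c_growth", lower = 0, strict = TRUE)
  check_scalar(lam, "lam", lower = 0)
  rate <- c_growth * emax_inhibition(conc, dr) - lam
  regime <- dplyr::case_when(
    rate > tol ~ "growing",
    rate < -tol ~ "decaying",
    .default = "critical"
  )
  tibble(conc = conc, rate = rate, regime = regime)
}

#' Critical efflux-to-influx ratio
#'
#' Finds the ratio `k = k_out / k_in` at which the long-run (equilibrium)
#' total intracellular payload `C0 / (1 + k)` puts the tumor exactly on
#' the growth/decay boundary, i.e. the root of
#' `c * E(C0 / (1 + k)) - lambda` in `k`. Because the response `E`
#' increases as payload falls and equilibrium payload falls as `k` rises,
#' the equilibrium regime is decaying below the root and growing above it.
#'
#' @param dr A [dose_response_params()] object.
#' @param payload A [payload_params()] object supplying `C0`.
#' @param c_growth,lam Growth coefficient and degradation rate as in
#'   [net_growth_rate()].
#' @param interval Search interval for `k` (positive, increasing pair).
#' @param tol Absolute tolerance on the root in `k`.
#' @return One-row tibble with `k_critical`, the equilibrium payload
#'   `conc_at_root`, and the residual `rate_at_root`.
#' @export
critical_efflux_ratio <- function(dr, payload = payload_params(),
                                  c_growth = 4.6e-3, lam = 0.5,
                                  interval = c(1e-6, 1e3), tol = 1e-10) {
  stopifnot(inherits(dr, "dose_response_params"),
            inherits(payload, "payload_params"))
  if (length(interval) != 2L || interval[1] <= 0 || diff(interval) <= 0) {
    abort("`interval` must be an increasing pair of positive k values.")
  }
  f <- function(k) {
    c_growth * emax_inhibition(payload$C0 / (1 + k), dr) - lam
  }
  flo <- f(interval[1]); fhi <- f(interval[2])
  if (sign(flo) == sign(fhi)) {
    lab <- function(v) if (v > 0) "growing" else if (v < 0) "decaying" else "critical"
    abort(sprintf(
      paste0("No growth/decay sign change on [%g, %g]: the equilibrium regime ",
             "is %s at both endpoints (rates %.4g and %.4g per day). ",
             "Widen the interval or adjust the dose."),
      interval[1], interval[2], lab(flo), flo, fhi))
  }
  root <- uniroot(f, interval = interval, tol = tol)
  tibble(
    k_critical = root$root,
    conc_at_root = payload$C0 / (1 + root$root),
    rate_at_root = f(root$root)
  )
}
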