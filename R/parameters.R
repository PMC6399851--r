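#' Payload-exchange parameters
#'
#' Rates and initial condition for the closed three-compartment payload
#' model: antigen-positive (Ag+) cells, antigen-negative (Ag-) cells, and
#' the shared extracellular space. Payload enters cells at rate `k_in`
#' (partitioned between Ag+ and Ag- cells by the Ag+ fraction `beta`) and
#' leaks back out at rate `k_out`. `k_out = 0` encodes an impermeable
#' payload, i.e. the bystander-killing effect switched off.
#'
#' The simulation convention is `k_in = 1/day` with the efflux-to-influx
#' ratio `k = k_out / k_in` as the tunable quantity; literature per-minute
#' rates can be brought to the day scale with
#' [convert_rate_minutes_to_days()]. `beta = 0` is rejected: the initial
#' payload concentration lives in Ag+ cells, so a tumor with no Ag+ cells
#' leaves it undefined.
#'
#' @param k_in Influx rate, per day. Must be positive.
#' @param k_out Efflux rate, per day. Non-negative; `0` switches the
#'   bystander-killing effect off.
#' @param beta Fraction of tumor cells that are Ag+, in `(0, 1]`.
#' @param C0 Initial payload concentration in Ag+ cells, nM. Non-negative.
#'
#' @return An object of class `payload_params`: a list with the validated
#'   fields plus the derived read-only ratio `k = k_out / k_in`.
#' @seealso [simulate_payload()], [payload_equilibrium()]
#' @examples
#' payload_params()                    # paper-style defaults: k = 2, beta = 0.7
#' payload_params(k_out = 0, beta = 1) # bystander off, all cells Ag+
#' @export
payload_params <- function(k_in = 1, k_out = 2, beta = 0.7, C0 = 200) {
  check_scalar(k_in, "k_in", lower = 0, strict = TRUE)
  check_scalar(k_out, "k_out", lower = 0)
  check_scalar(beta, "beta", lower = 0, upper = 1, strict = TRUE)
  check_scalar(C0, "C0", lower = 0)
  structure(
    list(k_in = k_in, k_out = k_out, beta = beta, C0 = C0,
         k = k_out / k_in),
    class = "payload_params"
  )
}

#' Emax dose-response parameters
#'
#' Parameters of the inhibitory Emax (Hill) function
#' \eqn{E(c) = E_0 (1 - E_{max} c^\gamma / (IC_{50}^\gamma + c^\gamma))}:
#' the response decreases from `E0` at zero payload towards
#' `E0 * (1 - Emax)` at saturating payload, passing through the half-maximal
#' effect at `c = IC50`.
#'
#' @param E0 Baseline response at zero payload (nM response units; > 0).
#' @param Emax Maximum killing effect, a dimensionless fraction in `(0, 1]`.
#' @param IC50 Half-maximal payload concentration, nM (> 0).
#' @param gamma_hill Hill (sigmoidicity) coefficient, dimensionless (> 0).
#'
#' @return An object of class `dose_response_params`.
#' @seealso [emax_inhibition()], [net_growth_rate()]
#' @export
dose_response_params <- function(E0 = 120, Emax = 0.6931, IC50 = 300,
                                 gamma_hill = 1) {
  check_scalar(E0, "E0", lower = 0, strict = TRUE)
  check_scalar(Emax, "Emax", lower = 0, upper = 1, strict = TRUE)
  check_scalar(IC50, "IC50", lower = 0, strict = TRUE)
  check_scalar(gamma_hill, "gamma_hill", lower = 0, strict = TRUE)
  structure(
    list(E0 = E0, Emax = Emax, IC50 = IC50, gamma_hill = gamma_hill),
    class = "dose_response_params"
  )
}

#' Tumor growth inhibition parameters
#'
#' Parameters of the TGI equation
#' \eqn{dT/dt = c\,E\,F(T)\,T - \lambda T} with growth modifier
#' \eqn{F = 1} (exponential) or \eqn{F = 1 - T/T_{max}} (logistic).
#' The product `c_growth * E` is a per-day growth rate, so `c_growth`
#' carries per-(nM day) units against an `E0` in nM units.
#'
#' @param c_growth Growth coefficient, per (nM day); > 0.
#' @param lam First-order tumor degradation rate, per day; >= 0.
#' @param T0 Initial total tumor size, mm^3; > 0.
#' @param Tmax Carrying capacity for the logistic form, mm^3; must exceed
#'   `T0` when `growth_form = "logistic"`.
#' @param growth_form `"logistic"` (default) or `"exponential"`.
#'
#' @return An object of class `tumor_params`.
#' @seealso [simulate_tgi()], [growth_modifier()]
#' @export
tumor_params <- function(c_growth = 4.6e-3, lam = 0.5, T0 = 1000,
                         Tmax = 2e4,
                         growth_form = c("logistic", "exponential")) {
  growth_form <- match.arg(growth_form)
  check_scalar(c_growth, "c_growth", lower = 0, strict = TRUE)
  check_scalar(lam, "lam", lower = 0)
  check_scalar(T0, "T0", lower = 0, strict = TRUE)
  check_scalar(Tmax, "Tmax", lower = 0, strict = TRUE)
  if (growth_form == "logistic" && Tmax <= T0) {
    abort("`Tmax` must exceed `T0` under logistic growth.")
  }
  structure(
    list(c_growth = c_growth, lam = lam, T0 = T0, Tmax = Tmax,
         growth_form = growth_form),
    class = "tumor_params"
  )
}

#' Erlang age-structure parameters
#'
#' Shape and rate of the Erlang kernel used by the age-structured TGI
#' model. The Erlang distribution with integer shape `n_shape` and rate
#' parameter `theta` (days per stage) is the waiting time through
#' `n_shape` sequential exponential stages; its mean, `n_shape * theta`,
#' is the mean lag between the payload-tumor interaction and the killing
#' effect. The default `n_shape = 20` with `theta = 0.1` days gives a
#' 2-day mean lag.
#'
#' @param theta Erlang rate parameter (days per stage); > 0.
#' @param n_shape Erlang shape parameter; a positive integer.
#'
#' @return An object of class `age_params`.
#' @seealso [erlang_pdf()], [simulate_age_structured()]
#' @export
age_params <- function(theta = 0.1, n_shape = 20) {
  check_scalar(theta, "theta", lower = 0, strict = TRUE)
  check_scalar(n_shape, "n_shape", lower = 0, strict = TRUE)
  if (n_shape != round(n_shape)) {
    abort("`n_shape` must be a positive integer.")
  }
  structure(
    list(theta = theta, n_shape = as.integer(n_shape)),
    class = "age_params"
  )
}

#' @export
print.payload_params <- function(x, ...) {
  cat("<payload_params>\n")
  cat(sprintf("  k_in  = %g /day   k_out = %g /day   (k = k_out/k_in = %g)\n",
              x$k_in, x$k_out, x$k))
  cat(sprintf("  beta  = %g (Ag+ fraction)   C0 = %g nM\n", x$beta, x$C0))
  if (x$k_out == 0) cat("  bystander-killing: off (k_out = 0)\n")
  invisible(x)
}

#' @export
print.dose_response_params <- function(x, ...) {
  cat("<dose_response_params>\n")
  cat(sprintf("  E0 = %g   Emax = %g   IC50 = %g nM   gamma = %g\n",
              x$E0, x$Emax, x$IC50, x$gamma_hill))
  invisible(x)
}

#' @export
print.tumor_params <- function(x, ...) {
  cat("<tumor_params>\n")
  cat(sprintf("  c = %g /(nM day)   lambda = %g /day   %s growth\n",
              x$c_growth, x$lam, x$growth_form))
  cat(sprintf("  T0 = %g mm^3   Tmax = %g mm^3\n", x$T0, x$Tmax))
  invisible(x)
}

#' @export
print.age_params <- function(x, ...) {
  cat("<age_params>\n")
  cat(sprintf("  theta = %g days   n = %d stages   mean lag = %g days\n",
              x$theta, x$n_shape, x$theta * x$n_shape))
  invisible(x)
}

# scalar validation shared by all constructors
check_scalar <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict) x > lower else x >= lower
  if (!lo_ok || x > upper) {
    bound <- if (strict) sprintf("in (%g, %g]", lower, upper)
             else sprintf("in [%g, %g]", lower, upper)
    if (is.infinite(upper)) {
      bound <- if (strict) sprintf("> %g", lower) else sprintf(">= %g", lower)
    }
    abort(sprintf("`%s` must be %s (got %g).", name, bound, x))
  }
  invisible(x)
}
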