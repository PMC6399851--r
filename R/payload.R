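#' Literature payload transport rates
#'
#' Per-minute membrane influx/efflux rates for an auristatin-class payload
#' reported in the in vitro literature, exposed as a convenience constant.
#' Simulations default to the day-scale convention `k_in = 1/day` with the
#' ratio `k` as the knob; these values are the physical anchors.
#'
#' @format A named numeric vector with elements `k_in_per_min` and
#'   `k_out_per_min`.
#' @seealso [convert_rate_minutes_to_days()]
#' @export
literature_rates <- c(k_in_per_min = 8.46e-2, k_out_per_min = 4.122e-2)

#' Convert a per-minute rate to a per-day rate
#'
#' @param rate First-order rate, per minute. Finite numeric (vectorized).
#' @return `rate * 1440`, per day.
#' @examples
#' convert_rate_minutes_to_days(8.46e-2) # 121.824 per day
#' @export
convert_rate_minutes_to_days <- function(rate) {
  if (!is.numeric(rate) || any(!is.finite(rate))) {
    abort("`rate` must be finite numeric.")
  }
  rate * 1440
}

#' Right-hand side of the payload-exchange ODE system
#'
#' Time derivative of the closed three-compartment system: extracellular
#' payload enters Ag+ cells at rate `beta * k_in` and Ag- cells at
#' `(1 - beta) * k_in`, while both cell types leak payload back out at
#' `k_out`. The three derivatives sum to exactly zero (closed system).
#'
#' @param state Named numeric vector with components `C_int_p`, `C_int_n`,
#'   `C_ext_p` (nM). Order is honoured if names are missing.
#' @param params A [payload_params()] object.
#' @return Named numeric vector of derivatives (nM/day) in the same order.
#' @export
payload_rhs <- function(state, params) {
  stopifnot(inherits(params, "payload_params"))
  state <- as_payload_state(state)
  d <- c(
    C_int_p = params$beta * params$k_in * state[["C_ext_p"]] -
      params$k_out * state[["C_int_p"]],
    C_int_n = (1 - params$beta) * params$k_in * state[["C_ext_p"]] -
      params$k_out * state[["C_int_n"]],
    C_ext_p = -params$k_in * state[["C_ext_p"]] +
      params$k_out * (state[["C_int_p"]] + state[["C_int_n"]])
  )
  d
}

as_payload_state <- function(state) {
  if (!is.numeric(state) || length(state) != 3L) {
    abort("A payload state has exactly 3 numeric components: C_int_p, C_int_n, C_ext_p.")
  }
  if (any(!is.finite(state))) {
    abort("Invalid payload state: all components must be finite.")
  }
  if (is.null(names(state))) names(state) <- c("C_int_p", "C_int_n", "C_ext_p")
  state[c("C_int_p", "C_int_n", "C_ext_p")]
}

# 3x3 rate matrix of the linear system, acting on (C_int_p, C_int_n, C_ext_p)
payload_rate_matrix <- function(params) {
  with(params, matrix(c(
    -k_out,      0,  beta * k_in,
    0,      -k_out, (1 - beta) * k_in,
    k_out,   k_out, -k_in
  ), nrow = 3, byrow = TRUE))
}

#' Exact solution of the payload-exchange system
#'
#' The system is linear, so from the initial state `(C0, 0, 0)` the
#' trajectory is a matrix exponential: `x(t) = expm(A t) x(0)` with `A`
#' the 3x3 rate matrix. Conservation
#' `C_int_p + C_int_n + C_ext_p = C0` holds to floating precision.
#'
#' @param params A [payload_params()] object.
#' @param t Times in days (vector, each >= 0).
#' @return A tibble with columns `time_days`, `C_int_p`, `C_int_n`,
#'   `C_ext_p`, `total_intracellular`.
#' @seealso [simulate_payload()] for the numerical route this solution
#'   cross-checks.
#' @export
payload_closed_form <- function(params, t) {
  stopifnot(inherits(params, "payload_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    abort("`t` must be non-negative finite times in days.")
  }
  A <- payload_rate_matrix(params)
  x0 <- c(params$C0, 0, 0)
  states <- vapply(
    t,
    function(ti) as.numeric(Matrix::expm(A * ti) %*% x0),
    numeric(3)
  )
  tibble(
    time_days = t,
    C_int_p = states[1, ],
    C_int_n = states[2, ],
    C_ext_p = states[3, ],
    total_intracellular = states[1, ] + states[2, ]
  )
}

#' Simulate the payload-exchange system numerically
#'
#' Integrates the closed three-compartment system from the initial state
#' `(C0, 0, 0)` — all payload starts inside Ag+ cells — over the given
#' time grid with `deSolve::lsoda`. Output values in `[-atol, 0)` are
#' clamped to zero; undershoots below `-atol` raise an error because they
#' indicate a failed integration, not round-off.
#'
#' @param params A [payload_params()] object.
#' @param times Strictly increasing time grid in days, starting at 0.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return A `payload_trajectory` tibble with columns `time_days`,
#'   `C_int_p`, `C_int_n`, `C_ext_p`, `total_intracellular`; the
#'   parameters are attached as the `params` attribute.
#' @examples
#' traj <- simulate_payload(payload_params(), times = seq(0, 30, by = 0.1))
#' tail(traj, 1) # near the equilibrium (beta*C0/3, (1-beta)*C0/3, 2*C0/3)
#' @export
simulate_payload <- function(params, times = seq(0, 30, by = 0.1),
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "payload_params"))
  check_time_grid(times)
  y0 <- c(C_int_p = params$C0, C_int_n = 0, C_ext_p = 0)
  rhs <- function(t, y, p) list(payload_rhs(y, p))
  sol <- integrate_ode(y0, times, rhs, params, rtol = rtol, atol = atol,
                       label = "payload")
  out <- tibble(
    time_days = sol[, "time"],
    C_int_p = clamp_negatives(sol[, "C_int_p"], atol, "C_int_p"),
    C_int_n = clamp_negatives(sol[, "C_int_n"], atol, "C_int_n"),
    C_ext_p = clamp_negatives(sol[, "C_ext_p"], atol, "C_ext_p")
  )
  out$total_intracellular <- out$C_int_p + out$C_int_n
  new_trajectory(out, params = list(payload = params),
                 class = "payload_trajectory")
}

#' Equilibrium of the payload-exchange system
#'
#' With `k = k_out / k_in > 0` the closed system relaxes to the unique
#' stationary point `(beta*C0/(1+k), (1-beta)*C0/(1+k), C0*k/(1+k))`,
#' strictly below the initial `C0` inside the cells. With `k_out = 0` the
#' system is degenerate (payload stays where it starts), so the
#' bystander-off case must be handled by the caller and raises an error
#' here.
#'
#' @param params A [payload_params()] object with `k_out > 0`.
#' @return One-row tibble with `C_int_p`, `C_int_n`, `C_ext_p`,
#'   `total_intracellular`; components sum to `C0`.
#' @examples
#' payload_equilibrium(payload_params(k_out = 2, beta = 0.7, C0 = 200))
#' # C_int_n = 20 nM, total intracellular = 200/3 nM
#' @export
payload_equilibrium <- function(params) {
  stopifnot(inherits(params, "payload_params"))
  if (params$k_out <= 0) {
    abort(paste0(
      "Equilibrium is undefined for k_out = 0 (bystander off): the initial ",
      "state (C0, 0, 0) is already stationary. Handle that case separately."
    ))
  }
  k <- params$k
  tibble(
    C_int_p = params$beta * params$C0 / (1 + k),
    C_int_n = (1 - params$beta) * params$C0 / (1 + k),
    C_ext_p = params$C0 * k / (1 + k),
    total_intracellular = params$C0 / (1 + k)
  )
}

#' Total intracellular payload series
#'
#' Pointwise sum `C_int_p + C_int_n` of a payload trajectory. Because the
#' sum obeys the beta-free reduced system
#' `dS/dt = k_in * C_ext - k_out * S`, this series is identical for every
#' Ag+ fraction `beta` at fixed `(k_in, k_out, C0)` — which is why a TGI
#' model driven by the total payload cannot see the Ag+/Ag- composition.
#'
#' @param traj A trajectory containing `time_days`, `C_int_p`, `C_int_n`.
#' @return Tibble with `time_days` and `total_intracellular` (nM).
#' @export
total_intracellular <- function(traj) {
  stopifnot(is.data.frame(traj),
            all(c("time_days", "C_int_p", "C_int_n") %in% names(traj)))
  tibble(
    time_days = traj$time_days,
    total_intracellular = traj$C_int_p + traj$C_int_n
  )
}

# ---- shared solver plumbing ------------------------------------------------

check_time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 2L || any(!is.finite(times))) {
    abort("`times` must be a finite numeric grid with at least two points.")
  }
  if (times[1] != 0) abort("`times` must start at 0 days.")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  invisible(times)
}

integrate_ode <- function(y0, times, rhs, params, rtol, atol, label) {
  sol <- tryCatch(
    deSolve::lsoda(y = y0, times = times, func = rhs, parms = params,
                   rtol = rtol, atol = atol),
    warning = function(w) {
      abort(sprintf("Integration of the %s system failed: %s",
                    label, conditionMessage(w)))
    }
  )
  if (nrow(sol) < length(times) || any(!is.finite(sol))) {
    abort(sprintf("Integration of the %s system did not reach the end of the grid.",
                  label))
  }
  sol
}

clamp_negatives <- function(x, atol, name) {
  if (any(x < -atol)) {
    abort(sprintf("`%s` undershoots below -atol (min %.3e): integration failure.",
                  name, min(x)))
  }
  pmax(x, 0)
}

new_trajectory <- function(df, params, class) {
  out <- as_tibble(df)
  attr(out, "params") <- params
  class(out) <- c(class, "bystandr_trajectory", class(out))
  out
}
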