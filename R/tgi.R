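#' Split the initial tumor between Ag+ and Ag- compartments
#'
#' The Ag+ fraction `beta` partitions the initial total tumor size:
#' `T1(0) = beta * T0` (Ag+) and `T2(0) = (1 - beta) * T0` (Ag-).
#'
#' @param T0 Initial total tumor size, mm^3 (> 0).
#' @param beta Ag+ fraction, in `(0, 1]`.
#' @return One-row tibble with `T1` and `T2` (mm^3), summing to `T0`.
#' @examples
#' split_initial_tumor(1000, 0.7) # 700 and 300 mm^3
#' @export
split_initial_tumor <- function(T0, beta) {
  check_scalar(T0, "T0", lower = 0, strict = TRUE)
  check_scalar(beta, "beta", lower = 0, upper = 1, strict = TRUE)
  tibble(T1 = beta * T0, T2 = (1 - beta) * T0)
}

#' Growth modifier F of the TGI equation
#'
#' `F = 1` under exponential growth; `F = 1 - T / Tmax` under logistic
#' growth, vanishing at the carrying capacity.
#'
#' @param T Tumor size, mm^3 (vectorized, each >= 0).
#' @param params A [tumor_params()] object.
#' @return Dimensionless modifier, same length as `T`.
#' @export
growth_modifier <- function(T, params) {
  stopifnot(inherits(params, "tumor_params"))
  if (!is.numeric(T) || any(!is.finite(T)) || any(T < 0)) {
    abort("`T` must be non-negative finite tumor sizes (mm^3).")
  }
  switch(params$growth_form,
    exponential = rep(1, length(T)),
    logistic = 1 - T / params$Tmax
  )
}

#' Simulate two-population tumor growth inhibition
#'
#' Integrates the coupled payload + tumor system: the three payload
#' compartments evolve as in [simulate_payload()] (one-way coupling —
#' tumor size never feeds back into the payload), while each tumor
#' subpopulation is driven by its own intracellular payload through the
#' Emax response,
#' \deqn{dT_1/dt = c\,E(C_{int,p})\,F(T_1)\,T_1 - \lambda T_1, \qquad
#'       dT_2/dt = c\,E(C_{int,n})\,F(T_2)\,T_2 - \lambda T_2.}
#' With `bystander = FALSE` the efflux rate is forced to zero: payload is
#' trapped in Ag+ cells, `C_int_n` stays at zero, and the Ag- population
#' grows at the drug-free rate. These bystander-off populations are the
#' `T3`/`T4` pair of the on/off comparison, represented here by the same
#' columns under a different scenario flag.
#'
#' `drive = "total"` substitutes the beta-independent total payload
#' `C_int_p + C_int_n` into both Emax terms. It exists as a diagnostic of
#' why that formulation cannot resolve the Ag+/Ag- composition — the
#' resulting trajectories are identical across `beta` — and is not the
#' model of interest.
#'
#' @param payload A [payload_params()] object (its `beta` also sets the
#'   initial tumor split).
#' @param dr A [dose_response_params()] object.
#' @param tumor A [tumor_params()] object.
#' @param bystander Logical; `FALSE` forces `k_out = 0`.
#' @param times Strictly increasing time grid in days, starting at 0.
#' @param drive `"independent"` (each population sees its own payload;
#'   default) or `"total"` (diagnostic).
#' @param capacity Under logistic growth, `"common"` applies
#'   `F_i = 1 - T_i / Tmax` with the full `Tmax` to each subpopulation;
#'   `"proportional"` allots each subpopulation its share `beta * Tmax`
#'   and `(1 - beta) * Tmax`.
#' @param rtol,atol Solver tolerances.
#' @return A `tgi_trajectory` tibble with columns `time_days`, `C_int_p`,
#'   `C_int_n`, `C_ext_p`, `T1`, `T2`, `T_total`.
#' @examples
#' traj <- simulate_tgi(payload_params(), dose_response_params(),
#'                      tumor_params(), times = seq(0, 60, by = 0.5))
#' tail(traj, 2)
#' @export
simulate_tgi <- function(payload, dr, tumor, bystander = TRUE,
                         times = seq(0, 60, by = 0.1),
                         drive = c("independent", "total"),
                         capacity = c("common", "proportional"),
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(payload, "payload_params"),
            inherits(dr, "dose_response_params"),
            inherits(tumor, "tumor_params"))
  drive <- match.arg(drive)
  capacity <- match.arg(capacity)
  check_time_grid(times)
  bystander <- isTRUE(bystander) || identical(bystander, "on")
  p_eff <- if (bystander) payload else
    payload_params(k_in = payload$k_in, k_out = 0, beta = payload$beta,
                   C0 = payload$C0)

  caps <- subpopulation_capacities(tumor, payload$beta, capacity)
  init <- split_initial_tumor(tumor$T0, payload$beta)
  y0 <- c(C_int_p = p_eff$C0, C_int_n = 0, C_ext_p = 0,
          T1 = init$T1, T2 = init$T2)

  rhs <- function(t, y, parms) {
    dC <- payload_rhs(y[1:3], p_eff)
    conc <- tgi_drive_conc(y, drive)
    E1 <- emax_inhibition(max(conc[1], 0), dr)
    E2 <- emax_inhibition(max(conc[2], 0), dr)
    F1 <- growth_modifier_capped(y[["T1"]], tumor, caps[1])
    F2 <- growth_modifier_capped(y[["T2"]], tumor, caps[2])
    dT1 <- tumor$c_growth * E1 * F1 * y[["T1"]] - tumor$lam * y[["T1"]]
    dT2 <- tumor$c_growth * E2 * F2 * y[["T2"]] - tumor$lam * y[["T2"]]
    list(c(dC, dT1, dT2))
  }
  sol <- integrate_ode(y0, times, rhs, NULL, rtol = rtol, atol = atol,
                       label = "two-population TGI")
  out <- tibble(
    time_days = sol[, "time"],
    C_int_p = clamp_negatives(sol[, "C_int_p"], atol, "C_int_p"),
    C_int_n = clamp_negatives(sol[, "C_int_n"], atol, "C_int_n"),
    C_ext_p = clamp_negatives(sol[, "C_ext_p"], atol, "C_ext_p"),
    T1 = clamp_negatives(sol[, "T1"], sqrt(atol), "T1"),
    T2 = clamp_negatives(sol[, "T2"], sqrt(atol), "T2")
  )
  out$T_total <- out$T1 + out$T2
  new_trajectory(out,
                 params = list(payload = payload, dose_response = dr,
                               tumor = tumor, bystander = bystander,
                               drive = drive, capacity = capacity),
                 class = "tgi_trajectory")
}

tgi_drive_conc <- function(y, drive) {
  if (drive == "total") rep(y[["C_int_p"]] + y[["C_int_n"]], 2)
  else c(y[["C_int_p"]], y[["C_int_n"]])
}

subpopulation_capacities <- function(tumor, beta, capacity) {
  if (tumor$growth_form != "logistic") return(c(NA_real_, NA_real_))
  if (capacity == "proportional") c(beta, 1 - beta) * tumor$Tmax
  else rep(tumor$Tmax, 2)
}

growth_modifier_capped <- function(T, tumor, cap) {
  if (tumor$growth_form == "exponential") return(1)
  if (cap <= 0) return(0)   # empty subpopulation under proportional capacity
  1 - T / cap
}

#' Percent change of a tumor series relative to its initial size
#'
#' Normalization `100 * (T(t) / T0 - 1)` used to compare subpopulations of
#' different initial sizes on a common scale.
#'
#' @param Ti Tumor size series, mm^3.
#' @param Ti_0 Initial size of that series, mm^3 (> 0).
#' @return Percent change series.
#' @export
normalized_percent_change <- function(Ti, Ti_0) {
  check_scalar(Ti_0, "Ti_0", lower = 0, strict = TRUE)
  if (!is.numeric(Ti)) abort("`Ti` must be numeric.")
  100 * (Ti / Ti_0 - 1)
}

#' Bystander-killing gap between paired trajectories
#'
#' Difference between total tumor size without and with the
#' bystander-killing effect, relative to the initial tumor size:
#' `100 * ((T3 + T4) - (T1 + T2)) / T0` per time point, where `(T1, T2)`
#' is the bystander-on pair and `(T3, T4)` the bystander-off pair. A
#' positive gap means the bystander effect yields extra suppression.
#'
#' @param traj_with Bystander-on trajectory from [simulate_tgi()] or
#'   [simulate_age_structured()].
#' @param traj_without Bystander-off trajectory on the same time grid.
#' @param T0 Initial total tumor size, mm^3.
#' @return Tibble with `time_days` and `gap_pct`.
#' @export
bystander_gap <- function(traj_with, traj_without, T0) {
  stopifnot(is.data.frame(traj_with), is.data.frame(traj_without))
  check_scalar(T0, "T0", lower = 0, strict = TRUE)
  if (nrow(traj_with) != nrow(traj_without) ||
      any(abs(traj_with$time_days - traj_without$time_days) > 1e-12)) {
    abort("The two trajectories must share the same time grid.")
  }
  tibble(
    time_days = traj_with$time_days,
    gap_pct = 100 * (traj_without$T_total - traj_with$T_total) / T0
  )
}
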