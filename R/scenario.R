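#' Build a validated scenario configuration
#'
#' A scenario bundles everything one simulation run needs: payload,
#' dose-response and tumor parameters, an optional age structure (which
#' switches the run to the delayed model), the bystander flag, the output
#' grid and solver tolerances. Defaults are the package's reference
#' parameter set: `k_in = 1/day`, `k = 2`, `beta = 0.7`, `C0 = 200` nM,
#' `E0 = 120`, `Emax = 0.6931`, `IC50 = 300` nM, `gamma = 1`,
#' `c = 4.6e-3`, `lambda = 0.5/day`, `T0 = 1000` mm^3, `Tmax = 2e4` mm^3,
#' `theta = 0.1` d.
#'
#' @param payload A [payload_params()] object.
#' @param dose_response A [dose_response_params()] object.
#' @param tumor A [tumor_params()] object.
#' @param age_structure An [age_params()] object, or `NULL` for the
#'   memoryless model.
#' @param bystander `"on"` or `"off"`.
#' @param horizon Simulation horizon, days (> 0).
#' @param output_step Output grid step, days (> 0, <= horizon).
#' @param solver List with `rtol` and `atol`.
#' @param label Free-text scenario label.
#' @return An object of class `scenario_config`.
#' @seealso [load_config()], [run_scenario()]
#' @export
scenario_config <- function(payload = payload_params(),
                            dose_response = dose_response_params(),
                            tumor = tumor_params(),
                            age_structure = NULL,
                            bystander = c("on", "off"),
                            horizon = 60, output_step = 0.1,
                            solver = list(rtol = 1e-8, atol = 1e-10),
                            label = "default") {
  bystander <- match.arg(bystander)
  stopifnot(inherits(payload, "payload_params"),
            inherits(dose_response, "dose_response_params"),
            inherits(tumor, "tumor_params"))
  if (!is.null(age_structure)) stopifnot(inherits(age_structure, "age_params"))
  check_scalar(horizon, "horizon", lower = 0, strict = TRUE)
  check_scalar(output_step, "output_step", lower = 0, strict = TRUE)
  if (output_step > horizon) abort("`output_step` must not exceed `horizon`.")
  check_scalar(solver$rtol %||% NA_real_, "solver$rtol", lower = 0, strict = TRUE)
  check_scalar(solver$atol %||% NA_real_, "solver$atol", lower = 0, strict = TRUE)
  if (!is.character(label) || length(label) != 1L) {
    abort("`label` must be a single string.")
  }
  structure(
    list(payload = payload, dose_response = dose_response, tumor = tumor,
         age_structure = age_structure, bystander = bystander,
         horizon = horizon, output_step = output_step,
         solver = list(rtol = solver$rtol, atol = solver$atol),
         label = label),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> '%s'\n", x$label))
  cat(sprintf("  model: %s, bystander %s, horizon %g d (step %g d)\n",
              if (is.null(x$age_structure)) "memoryless TGI"
              else sprintf("age-structured TGI (n = %d, theta = %g d)",
                           x$age_structure$n_shape, x$age_structure$theta),
              x$bystander, x$horizon, x$output_step))
  print(x$payload); print(x$dose_response); print(x$tumor)
  invisible(x)
}

config_section_builders <- list(
  payload = payload_params,
  dose_response = dose_response_params,
  tumor = tumor_params,
  age_structure = age_params
)

#' Read a scenario configuration from YAML or JSON
#'
#' An empty file yields the full default configuration. Section and field
#' names mirror the constructor arguments (`payload: {k_in, k_out, beta,
#' C0}` and so on); unknown keys are rejected with the offending name,
#' and field values go through the same validation as the constructors,
#' so errors name the key and the violated constraint.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [scenario_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(raw %||% list())
}

config_from_list <- function(raw) {
  if (!is.list(raw)) abort("Config must be a mapping of sections to fields.")
  known <- c(names(config_section_builders),
             "bystander", "horizon", "output_step", "solver", "label")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s. Known keys: %s.",
                  paste(unknown, collapse = ", "),
                  paste(known, collapse = ", ")))
  }
  sections <- lapply(names(config_section_builders), function(sec) {
    builder <- config_section_builders[[sec]]
    given <- raw[[sec]]
    if (is.null(given)) {
      if (sec == "age_structure") return(NULL)
      return(builder())
    }
    bad <- setdiff(names(given), names(formals(builder)))
    if (length(bad)) {
      abort(sprintf("Unknown key(s) in `%s`: %s.", sec,
                    paste(bad, collapse = ", ")))
    }
    do.call(builder, given)
  })
  names(sections) <- names(config_section_builders)
  solver <- modifyList(list(rtol = 1e-8, atol = 1e-10),
                       raw$solver %||% list())
  scenario_config(
    payload = sections$payload,
    dose_response = sections$dose_response,
    tumor = sections$tumor,
    age_structure = sections$age_structure,
    bystander = raw$bystander %||% "on",
    horizon = raw$horizon %||% 60,
    output_step = raw$output_step %||% 0.1,
    solver = solver,
    label = raw$label %||% "default"
  )
}

#' Write a scenario configuration to YAML or JSON
#'
#' The written file round-trips losslessly through [load_config()].
#'
#' @param config A [scenario_config()] object.
#' @param path Destination path; a `.json` suffix selects JSON, anything
#'   else YAML.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  lst <- config_as_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(lst, precision = 15), path)
  }
  invisible(path)
}

config_as_list <- function(config) {
  strip <- function(p, drop = character()) {
    p <- unclass(p)
    p[setdiff(names(p), drop)]
  }
  out <- list(
    payload = strip(config$payload, drop = "k"),
    dose_response = strip(config$dose_response),
    tumor = strip(config$tumor),
    bystander = config$bystander,
    horizon = config$horizon,
    output_step = config$output_step,
    solver = config$solver,
    label = config$label
  )
  if (!is.null(config$age_structure)) {
    out$age_structure <- strip(config$age_structure)
  }
  out
}

#' Run a scenario configuration
#'
#' Dispatches to [simulate_tgi()] or, when the configuration carries an
#' age structure, to [simulate_age_structured()]. With `pair = TRUE` the
#' scenario is run with the bystander effect both on and off and the
#' suppression gap between the pair is attached.
#'
#' @param config A [scenario_config()] object.
#' @param pair If `TRUE`, return a list with elements `with`, `without`
#'   and `gap` (see [bystander_gap()]); otherwise a single trajectory.
#' @return A trajectory tibble, or the paired list.
#' @export
run_scenario <- function(config, pair = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  times <- seq(0, config$horizon, by = config$output_step)
  run1 <- function(bystander) {
    args <- list(payload = config$payload, dr = config$dose_response,
                 tumor = config$tumor, bystander = bystander, times = times,
                 rtol = config$solver$rtol, atol = config$solver$atol)
    traj <- if (is.null(config$age_structure)) {
      do.call(simulate_tgi, args)
    } else {
      do.call(simulate_age_structured, c(args, list(age = config$age_structure)))
    }
    attr(traj, "label") <- config$label
    traj
  }
  if (!pair) return(run1(config$bystander == "on"))
  with_b <- run1(TRUE)
  without_b <- run1(FALSE)
  list(with = with_b, without = without_b,
       gap = bystander_gap(with_b, without_b, config$tumor$T0))
}

#' Export a trajectory to CSV or JSON
#'
#' CSV uses a comma separator, `.` decimal mark, a header row and UTF-8;
#' JSON writes one record per time point.
#'
#' @param traj A trajectory tibble.
#' @param path Destination path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(traj))
  if (format == "csv") {
    readr::write_csv(as_tibble(as.data.frame(traj)), path)
  } else {
    jsonlite::write_json(as.data.frame(traj), path, dataframe = "rows",
                         digits = NA)
  }
  invisible(path)
}

#' Built-in figure-style scenario sweeps
#'
#' Parameter sweeps mirroring the reference simulation settings:
#' * `"fig2"` — payload dynamics over `k` in `{1, 2, 3}` crossed with an
#'   Ag+ fraction grid (payload subsystem only);
#' * `"fig3"` — two-population logistic TGI at `k = 2` across the Ag+
#'   fraction grid;
#' * `"fig4"` — paired bystander on/off TGI runs across the Ag+ fraction
#'   grid, with the suppression gap;
#' * `"fig5"` — paired bystander on/off age-structured runs at
#'   `beta = 0.7`, `theta = 0.1` d, `n = 20`, with the gap.
#'
#' @param name One of `"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`.
#' @param beta_grid Ag+ fraction grid for the sweeps.
#' @param horizon Simulation horizon, days.
#' @param output_step Output step, days.
#' @return For `"fig2"`/`"fig3"`: a tibble of stacked trajectories with
#'   `k` and `beta` columns. For `"fig4"`/`"fig5"`: a list with elements
#'   `with`, `without` and `gap`, each a stacked tibble.
#' @export
run_figure <- function(name = c("fig2", "fig3", "fig4", "fig5"),
                       beta_grid = seq(0.1, 1, by = 0.1),
                       horizon = 60, output_step = 0.1) {
  name <- match.arg(name)
  times <- seq(0, horizon, by = output_step)
  stack <- function(grid, f) {
    purrr::pmap(grid, f) |> purrr::list_rbind()
  }
  switch(name,
    fig2 = {
      grid <- tidyr::expand_grid(k = c(1, 2, 3), beta = beta_grid)
      stack(grid, function(k, beta) {
        traj <- simulate_payload(payload_params(k_out = k, beta = beta),
                                 times = times)
        dplyr::mutate(as_tibble(as.data.frame(traj)), k = k, beta = beta,
                      .before = 1)
      })
    },
    fig3 = {
      grid <- tibble(beta = beta_grid)
      stack(grid, function(beta) {
        traj <- simulate_tgi(payload_params(beta = beta),
                             dose_response_params(), tumor_params(),
                             times = times)
        dplyr::mutate(as_tibble(as.data.frame(traj)), beta = beta,
                      .before = 1)
      })
    },
    fig4 = run_paired_sweep(beta_grid, times, age = NULL),
    fig5 = run_paired_sweep(0.7, times, age = age_params())
  )
}

run_paired_sweep <- function(beta_grid, times, age) {
  runs <- purrr::map(beta_grid, function(beta) {
    cfg <- scenario_config(
      payload = payload_params(beta = beta),
      age_structure = age,
      horizon = max(times), output_step = diff(times)[1],
      label = sprintf("beta=%g", beta)
    )
    pair <- run_scenario(cfg, pair = TRUE)
    lapply(pair, function(x) {
      dplyr::mutate(as_tibble(as.data.frame(x)), beta = beta, .before = 1)
    })
  })
  list(
    with = purrr::list_rbind(purrr::map(runs, "with")),
    without = purrr::list_rbind(purrr::map(runs, "without")),
    gap = purrr::list_rbind(purrr::map(runs, "gap"))
  )
}

#' Add lognormal measurement noise to exported tumor series
#'
#' Downstream-testing convenience: multiplies the selected columns by
#' i.i.d. lognormal factors. Off by default everywhere; the simulation
#' pipeline itself is fully deterministic.
#'
#' @param traj A trajectory tibble.
#' @param cols Columns to perturb.
#' @param sdlog Lognormal sd on the log scale.
#' @param seed Optional integer seed for reproducibility.
#' @return The perturbed tibble.
#' @export
add_measurement_noise <- function(traj, cols = c("T1", "T2", "T_total"),
                                  sdlog = 0.1, seed = NULL) {
  stopifnot(is.data.frame(traj))
  cols <- intersect(cols, names(traj))
  if (!is.null(seed)) set.seed(seed)
  for (cl in cols) {
    traj[[cl]] <- traj[[cl]] * rlnorm(nrow(traj), meanlog = 0, sdlog = sdlog)
  }
  traj
}
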