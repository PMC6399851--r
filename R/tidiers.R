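#' Tidy a simulation trajectory into long format
#'
#' Pivots the value columns of a trajectory into `(time_days, series,
#' value)` rows, the shape ggplot2 and dplyr summaries want.
#'
#' @param x A trajectory from [simulate_payload()], [simulate_tgi()] or
#'   [simulate_age_structured()].
#' @param ... Unused.
#' @return A long tibble with columns `time_days`, `series`, `value`.
#' @export
tidy.bystandr_trajectory <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(as.data.frame(x)),
                      cols = -"time_days",
                      names_to = "series", values_to = "value")
}

#' One-row summary of a simulation trajectory
#'
#' Reports the grid size and horizon plus, where the columns exist, the
#' final and extreme values a reader checks first: final total tumor
#' size, its minimum over the run, the post-dose peak time, and the final
#' total intracellular payload.
#'
#' @param x A trajectory tibble.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.bystandr_trajectory <- function(x, ...) {
  out <- tibble(
    n_times = nrow(x),
    horizon_days = max(x$time_days)
  )
  if ("T_total" %in% names(x)) {
    out$T_total_final <- x$T_total[nrow(x)]
    out$T_total_min <- min(x$T_total)
    out$peak_time_days <- peak_time(x)
  }
  if (all(c("C_int_p", "C_int_n") %in% names(x))) {
    out$total_payload_final <- x$C_int_p[nrow(x)] + x$C_int_n[nrow(x)]
  }
  out
}

#' @export
print.bystandr_trajectory <- function(x, ...) {
  prm <- attr(x, "params")
  kind <- class(x)[1]
  cat(sprintf("# %s: %d time points over %g days\n",
              kind, nrow(x), max(x$time_days)))
  if (!is.null(prm$bystander)) {
    cat(sprintf("# bystander-killing: %s\n",
                if (isTRUE(prm$bystander)) "on" else "off"))
  }
  NextMethod()
}
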