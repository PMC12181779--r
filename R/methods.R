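# Print, summary and plot methods for the simulator's result objects.

#' @export
print.co2_scenario <- function(x, ...) {
  cat(sprintf("Closed-loop CO2 scenario: setpoint %g ppm (%g%%), %s control\n",
              x$setpoint_ppm, x$setpoint_ppm / 10000, toupper(x$controller)))
  cat(sprintf("  plant: V=%g L, q=%g L/s, leak=%g /s, ambient=%g ppm\n",
              x$plant$volume_L, x$plant$injection_flow_Lps,
              x$plant$leak_rate_per_s, x$plant$ambient_ppm))
  cat(sprintf("  sensor: T90=%g s, bias=%g, noise sd=%g ppm, min read %g ms\n",
              x$sensor$t90_s, x$sensor$bias_fraction, x$sensor$noise_sd_ppm,
              x$sensor$min_read_interval_ms))
  cat(sprintf("  run: %g s at tick %g s from %g ppm, seed %d\n",
              x$duration_s, x$tick_s, x$initial_co2_ppm, x$seed))
  invisible(x)
}

#' @export
print.stability_metrics <- function(x, ...) {
  cat(sprintf("Stability over [%g, %g] s:\n", x$window[1], x$window[2]))
  cat(sprintf("  mean %.1f ppm; max deviation from mean %.1f ppm (%.2f%% of setpoint)\n",
              x$mean_ppm, x$max_dev_from_mean_ppm, x$pct_of_setpoint))
  cat(sprintf("  settling time %s s; %d valve actuations, %.1f s open in window\n",
              format(x$settling_time_s), x$valve_actuations,
              x$total_open_s))
  invisible(x)
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("Strategy comparison at setpoint %g ppm, window [%g, %g] s\n",
              x$setpoint_ppm, x$window[1], x$window[2]))
  for (k in names(x$metrics)) {
    m <- x$metrics[[k]]
    cat(sprintf("  %-3s  max dev %8.1f ppm  (%5.2f%% of setpoint)  %3d actuations\n",
                toupper(k), m$max_dev_from_mean_ppm, m$pct_of_setpoint,
                m$valve_actuations))
  }
  cat(sprintf("  TC:TAC fluctuation ratio = %.1f\n", x$ratio_tc_tac))
  invisible(x)
}

#' @export
summary.co2_trace <- function(object, ...) {
  m <- object$measured_ppm[!is.na(object$measured_ppm)]
  cat(sprintf("Closed-loop trace: %d ticks over %g s, %d accepted reads\n",
              nrow(object), max(object$time_s), length(m)))
  if (length(m))
    cat(sprintf("  measured: %g-%g ppm (final %g)\n", min(m), max(m),
                m[length(m)]))
  ev <- object$event[nzchar(object$event)]
  if (length(ev)) {
    tab <- table(unlist(strsplit(ev, ";", fixed = TRUE)))
    cat("  events: ",
        paste(sprintf("%s x%d", names(tab), as.integer(tab)),
              collapse = ", "), "\n", sep = "")
  }
  invisible(object)
}

#' Plot a closed-loop trace
#'
#' True and measured concentration against time, with valve activity
#' marked along the bottom and the setpoint (when known) as a dashed line.
#'
#' @param x a `"co2_trace"`.
#' @param ... passed to [plot()].
#' @export
plot.co2_trace <- function(x, ...) {
  plot(x$time_s, x$true_ppm, type = "l", col = "grey50",
       xlab = "time (s)", ylab = "CO2 (ppm)", ...)
  ok <- !is.na(x$measured_ppm)
  graphics::lines(x$time_s[ok], x$measured_ppm[ok], col = "black")
  sp <- attr(x, "setpoint_ppm")
  if (!is.null(sp)) graphics::abline(h = sp, lty = 2, col = "red")
  open <- x$valve_fraction > 0
  if (any(open))
    graphics::points(x$time_s[open],
                     rep(graphics::par("usr")[3], sum(open)),
                     pch = "|", col = "blue")
  invisible(x)
}
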