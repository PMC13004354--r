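#' Summarise residual-flow durations
#'
#' Mean and sample standard deviation (n - 1 denominator) of the
#' post-injection residual-flow duration per (pressure, condition) cell.
#' Cells with a single replicate report `sd = 0` and are flagged.
#'
#' @param observations Data frame with columns `pressure_psi`, `condition`,
#'   `duration_s` (replicate-level).
#' @return Data frame with `pressure_psi`, `condition`, `mean_s`, `sd_s`, `n`,
#'   `single_replicate`, sorted by condition then pressure.
#' @export
summarize_residuals <- function(observations) {
  stopifnot(is.data.frame(observations),
            all(c("pressure_psi", "condition", "duration_s") %in%
                  names(observations)))
  if (nrow(observations) == 0) {
    warning("no observations to summarise", call. = FALSE)
    return(data.frame(pressure_psi = numeric(), condition = character(),
                      mean_s = numeric(), sd_s = numeric(), n = integer(),
                      single_replicate = logical()))
  }
  key <- interaction(observations$condition, observations$pressure_psi,
                     drop = TRUE)
  cells <- lapply(split(observations, key), function(g) {
    n <- nrow(g)
    data.frame(pressure_psi = g$pressure_psi[1],
               condition = g$condition[1],
               mean_s = mean(g$duration_s),
               sd_s = if (n > 1) stats::sd(g$duration_s) else 0,
               n = n,
               single_replicate = n == 1)
  })
  out <- do.call(rbind, cells)
  out <- out[order(out$condition, out$pressure_psi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the logarithmic duration-pressure model
#'
#' Least-squares fit of `duration = a + b * log(P)` on replicate-level
#' residual-flow durations. The duration rises steeply at low pressures and
#' flattens towards 20 psi, which a logarithm captures better than a straight
#' line. The natural logarithm is used; the base only rescales `b`.
#'
#' @param observations Data frame with columns `pressure_psi` and `duration_s`.
#' @param regressor `"machine"` (default) regresses on the machine pressure in
#'   psi; `"driving"` regresses on `P - P_min` (psi), for exploring the
#'   friction-corrected alternative.
#' @param min_pressure_psi Minimum syringe pressure used by the `"driving"`
#'   regressor (default 5).
#' @return An object of class `residual_logfit`: list with `a` (intercept, s),
#'   `b` (slope, s per log-psi), `rss`, `n`, `regressor`, `pressure_range`
#'   (psi, of the fitted data), and the underlying `lm` fit.
#' @export
fit_log_model <- function(observations, regressor = c("machine", "driving"),
                          min_pressure_psi = 5) {
  stopifnot(is.data.frame(observations),
            all(c("pressure_psi", "duration_s") %in% names(observations)))
  regressor <- match.arg(regressor)
  p <- observations$pressure_psi
  if (regressor == "driving") p <- p - min_pressure_psi
  if (any(p <= 0)) {
    stop("all pressures must be positive on the chosen regressor scale",
         call. = FALSE)
  }
  if (length(unique(observations$pressure_psi)) < 3) {
    stop("unfittable: need >= 3 distinct pressures", call. = FALSE)
  }
  dat <- data.frame(logp = log(p), duration_s = observations$duration_s)
  fit <- stats::lm(duration_s ~ logp, data = dat)
  structure(list(
    a = unname(stats::coef(fit)[1]),
    b = unname(stats::coef(fit)[2]),
    rss = sum(stats::residuals(fit)^2),
    n = nrow(dat),
    regressor = regressor,
    min_pressure_psi = min_pressure_psi,
    pressure_range = range(observations$pressure_psi),
    lm = fit
  ), class = "residual_logfit")
}

#' @export
print.residual_logfit <- function(x, ...) {
  cat(sprintf(
    "<residual_logfit> duration = %.3g + %.3g * log(P) [%s pressure, psi]\n",
    x$a, x$b, x$regressor))
  cat(sprintf("  n = %d, RSS = %.3g s^2, fitted over %g-%g psi\n",
              x$n, x$rss, x$pressure_range[1], x$pressure_range[2]))
  invisible(x)
}

#' Predicted residual duration from a logarithmic fit
#'
#' @param fit A [fit_log_model()] result.
#' @param pressure_psi Machine pressure(s) in psi.
#' @return Predicted duration(s) in s.
#' @export
predict_residual_duration <- function(fit, pressure_psi) {
  stopifnot(inherits(fit, "residual_logfit"))
  p <- pressure_psi
  if (fit$regressor == "driving") p <- p - fit$min_pressure_psi
  fit$a + fit$b * log(p)
}

#' Recommend a post-injection pause before cannula withdrawal
#'
#' Residual flow continues after the injection command stops; withdrawing the
#' cannula during it leaks vector into the vitreous. The recommended pause is
#' the fitted residual duration at the chosen pressure plus a safety margin,
#' floored at the longest duration actually observed at that pressure and
#' condition when observations are supplied. Pressures below the flow
#' threshold produce no flow and hence a zero pause, with a warning;
#' extrapolation beyond the fitted pressure range is flagged with a warning.
#'
#' @param fit A [fit_log_model()] result.
#' @param pressure_psi Machine pressure in psi.
#' @param condition Optional condition label used to filter `observations`.
#' @param observations Optional replicate-level data frame (`pressure_psi`,
#'   `condition`, `duration_s`) providing the observed floor.
#' @param safety_margin Extra seconds added on top of the prediction (default 0).
#' @param flow_threshold_psi Pressure below which no flow occurs (default 6,
#'   the lowest machine pressure that produces a detectable jet).
#' @return Recommended pause in s.
#' @export
predict_pause <- function(fit, pressure_psi, condition = NULL,
                          observations = NULL, safety_margin = 0,
                          flow_threshold_psi = 6) {
  stopifnot(inherits(fit, "residual_logfit"), length(pressure_psi) == 1)
  if (pressure_psi < flow_threshold_psi) {
    warning("pressure below the flow threshold; no residual flow expected",
            call. = FALSE)
    return(0)
  }
  if (pressure_psi < fit$pressure_range[1] ||
      pressure_psi > fit$pressure_range[2]) {
    warning("extrapolating outside the fitted pressure range", call. = FALSE)
  }
  pause <- predict_residual_duration(fit, pressure_psi) + safety_margin
  if (!is.null(observations)) {
    sel <- observations$pressure_psi == pressure_psi
    if (!is.null(condition)) sel <- sel & observations$condition == condition
    if (any(sel)) {
      pause <- max(pause, max(observations$duration_s[sel]) + safety_margin)
    }
  }
  pause
}

#' Compare residual flow (or jet speed) between conditions
#'
#' Classic equal-variance one-way ANOVA across condition groups, the standard
#' test for whether priming technique or ambient pressure shifts the measured
#' durations.
#'
#' @param observations Data frame of replicate-level measurements.
#' @param group_col Name of the grouping column (default `"condition"`).
#' @param value_col Name of the response column (default `"duration_s"`).
#' @return List with `f`, `df1`, `df2`, `p_value`, and the per-group `n`.
#' @export
compare_conditions <- function(observations, group_col = "condition",
                               value_col = "duration_s") {
  stopifnot(is.data.frame(observations),
            all(c(group_col, value_col) %in% names(observations)))
  g <- factor(observations[[group_col]])
  y <- observations[[value_col]]
  n_by <- table(g)
  if (length(n_by) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(n_by < 2)) {
    stop("degenerate group(s) with < 2 replicates: ",
         paste(names(n_by)[n_by < 2], collapse = ", "), call. = FALSE)
  }
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  # identical groups: 0/0 F statistic; define F = 0, p = 1
  f <- unname(ow$statistic)
  p <- unname(ow$p.value)
  if (!is.finite(f)) {
    f <- 0
    p <- 1
  }
  list(f = f,
       df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]),
       p_value = p,
       n = as.integer(n_by))
}
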