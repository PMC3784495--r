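# Lead-lag transfer-function models and magnitude-Bode fitting.
#
# A variable's steady-state amplitude response across forcing frequencies
# is modeled by the stable, minimum-phase single-state lead-lag system
#   G(s) = K_p (tau_z s + 1) / (tau_p s + 1),  tau_p > 0, tau_z >= 0,
# whose amplitude ratio at angular frequency w is
#   AR(w) = K_p sqrt((tau_z w)^2 + 1) / sqrt((tau_p w)^2 + 1).
# Time constants are stored in ps; w is in rad/ns, so taus are converted
# to ns inside the formulas. Bode magnitudes are handled on the standard
# 20*log10(AR) dB scale.

#' Lead-lag model constructor
#'
#' @param K_p steady-state gain (> 0; output units per input unit).
#' @param tau_z lead time constant in ps (>= 0).
#' @param tau_p lag time constant in ps (> 0).
#' @return object of class \code{leadlag_model}.
#' @export
leadlag_model <- function(K_p, tau_z, tau_p) {
  if (K_p <= 0) stop("K_p must be positive", call. = FALSE)
  if (tau_z < 0) stop("tau_z must be >= 0", call. = FALSE)
  if (tau_p <= 0) stop("tau_p must be > 0", call. = FALSE)
  structure(list(K_p = K_p, tau_z = tau_z, tau_p = tau_p),
            class = "leadlag_model")
}

#' @export
print.leadlag_model <- function(x, ...) {
  cat(sprintf("leadlag_model: K_p = %.4g, tau_z = %.4g ps, tau_p = %.4g ps\n",
              x$K_p, x$tau_z, x$tau_p))
  invisible(x)
}

#' Amplitude ratio of a lead-lag system
#'
#' @param model a \code{\link{leadlag_model}}.
#' @param w angular frequency in rad/ns (> 0; vectorized).
#' @return amplitude ratio AR(w).
#' @export
ar <- function(model, w) {
  tz <- model$tau_z / 1000; tp <- model$tau_p / 1000  # ps -> ns
  model$K_p * sqrt((tz * w)^2 + 1) / sqrt((tp * w)^2 + 1)
}

#' Unit-step response of a lead-lag system
#'
#' \eqn{y(t) = K_p (1 - (1 - \tau_z/\tau_p) e^{-t/\tau_p})}: a fraction
#' \eqn{\tau_z/\tau_p} of the final displacement is realized immediately,
#' the remainder relaxes first-order with time constant \eqn{\tau_p}
#' (overshoot and decay when \eqn{\tau_z > \tau_p}).
#'
#' @param model a \code{\link{leadlag_model}}.
#' @param t time in ps (>= 0; vectorized).
#' @return response in output units.
#' @export
step_response <- function(model, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  model$K_p * (1 - (1 - model$tau_z / model$tau_p) * exp(-t / model$tau_p))
}

#' Breakpoint frequency of a first-order lag
#'
#' The corner where the flat low-frequency and decreasing high-frequency
#' Bode asymptotes intersect: \eqn{w_c = 1/\tau_p}. Forcing above this
#' frequency is attenuated (low-pass behavior).
#'
#' @param tau_p lag time constant in ps.
#' @return list with \code{w_c} (rad/ns) and \code{f_c} (ns^-1).
#' @export
breakpoint <- function(tau_p) {
  if (tau_p <= 0) stop("tau_p must be > 0", call. = FALSE)
  w_c <- 1 / (tau_p / 1000)
  list(w_c = w_c, f_c = w_c / (2 * pi))
}

#' Bode data container
#'
#' @param w angular frequencies in rad/ns (strictly increasing).
#' @param AR amplitude ratios (>= 0, finite).
#' @param id variable identifier.
#' @return object of class \code{bode_data}.
#' @export
bode_data <- function(w, AR, id = "var") {
  if (length(w) != length(AR)) stop("w and AR lengths differ")
  if (any(diff(w) <= 0)) stop("w must be strictly increasing",
                              call. = FALSE)
  stopifnot_finite(AR, "amplitude ratios")
  if (any(AR < 0)) stop("AR must be >= 0", call. = FALSE)
  structure(list(w = w, AR = AR, id = id), class = "bode_data")
}

#' Fit a lead-lag model to magnitude Bode data
#'
#' Least squares of the measured dB magnitudes \code{20*log10(AR)}
#' against the model curve, via deterministic multi-start L-BFGS-B on
#' log10-transformed parameters (time constants bounded to
#' [1e-3, 1e4] ps). Points with AR = 0 are dropped; at least 4 positive
#' points are required. Flat data yield a degenerate fit
#' (\code{tau_z = tau_p}, goodness \code{NA}).
#'
#' @param data a \code{\link{bode_data}}.
#' @return list with \code{model} (a \code{leadlag_model}),
#'   \code{goodness} (R^2 of the dB-scale fit; \code{NA} when
#'   degenerate), and \code{degenerate} flag.
#' @export
fit_leadlag <- function(data) {
  keep <- data$AR > 0
  w <- data$w[keep]; AR <- data$AR[keep]
  if (length(w) < 4)
    stop("need at least 4 points with AR > 0", call. = FALSE)
  y <- 20 * log10(AR)
  if (diff(range(y)) < 1e-10) {
    return(list(model = leadlag_model(mean(AR), 100, 100),
                goodness = NA_real_, degenerate = TRUE))
  }
  dbcurve <- function(th) {
    K <- 10^th[1]; tz <- 10^th[2] / 1000; tp <- 10^th[3] / 1000
    20 * log10(K) + 10 * log10((tz * w)^2 + 1) - 10 * log10((tp * w)^2 + 1)
  }
  obj <- function(th) sum((y - dbcurve(th))^2)
  lb <- c(-8, -3, -3); ub <- c(8, 4, 4)
  grid <- expand.grid(tz = c(0, 1, 2, 3), tp = c(0, 1, 2, 3))
  k0 <- log10(AR[1])  # low-frequency AR approximates the gain
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    th0 <- c(k0, grid$tz[g], grid$tp[g])
    fit <- tryCatch(
      optim(th0, obj, method = "L-BFGS-B", lower = lb, upper = ub),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  th <- best$par
  model <- leadlag_model(10^th[1], 10^th[2], 10^th[3])
  r2 <- 1 - best$value / sum((y - mean(y))^2)
  list(model = model, goodness = r2, degenerate = FALSE)
}

#' Classify a variable's frequency response
#'
#' Lead-lag categories require an acceptable dB-scale fit
#' (R^2 >= \code{r2_threshold}): lag-dominant when \eqn{\tau_p > \tau_z}
#' (decreasing AR), lead-dominant when \eqn{\tau_z > \tau_p}. Responses
#' that are monotone by Spearman correlation but not well fitted are
#' \code{monotone_unfit}; everything else (interior humps, flat, no
#' trend) is \code{second_order_or_none}.
#'
#' @param data a \code{\link{bode_data}} with >= 4 points.
#' @param r2_threshold minimum R^2 for lead-lag acceptance (default 0.8).
#' @return object of class \code{response_class}: \code{category},
#'   \code{goodness}, \code{model}.
#' @export
classify_response <- function(data, r2_threshold = 0.8) {
  if (length(data$w) < 4) stop("need at least 4 points", call. = FALSE)
  fit <- tryCatch(fit_leadlag(data), error = function(e) NULL)
  category <- NULL
  if (!is.null(fit) && !fit$degenerate &&
      !is.na(fit$goodness) && fit$goodness >= r2_threshold) {
    category <- if (fit$model$tau_p > fit$model$tau_z)
      "leadlag_lag_dominant" else "leadlag_lead_dominant"
  } else {
    rho <- suppressWarnings(cor(data$w, data$AR, method = "spearman"))
    category <- if (!is.na(rho) && abs(rho) >= 0.8) "monotone_unfit"
                else "second_order_or_none"
  }
  structure(list(category = category,
                 goodness = if (is.null(fit)) NA_real_ else fit$goodness,
                 model = if (is.null(fit)) NULL else fit$model),
            class = "response_class")
}

#' @export
print.response_class <- function(x, ...) {
  cat(sprintf("response_class: %s (R^2 = %s)\n", x$category,
              if (is.na(x$goodness)) "NA" else sprintf("%.3f", x$goodness)))
  invisible(x)
}

#' Default Bode experiment design
#'
#' Thirteen forcing periods logarithmically spaced from 30 ps to 5 ns,
#' matching the period range of the multi-frequency forcing protocol.
#'
#' @param n number of periods (default 13).
#' @param from,to period range in ps (defaults 30 and 5000).
#' @return numeric vector of periods in ps (increasing).
#' @export
bode_periods <- function(n = 13, from = 30, to = 5000) {
  exp(seq(log(from), log(to), length.out = n))
}
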