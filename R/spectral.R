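# Discrete Fourier analysis of variable series.
#
# Conventions (fixed across the package):
#   forward DFT  X_k = sum_n x_n exp(-2*pi*i*k*n/N), no normalization;
#   one-sided spectral density after mean-centering,
#     P_k = 2 |X_k|^2 / N^2  for 0 < k < N/2,
#     P_{N/2} = |X_{N/2}|^2 / N^2 for even N (Nyquist, not doubled);
#   sum of contributions equals the mean square fluctuation (Parseval);
#   band reconstruction r_n = a cos(2*pi*k*n/N + phi), phi = Arg(X_k).
# Frequencies are reported in ns^-1: f_k = k / (N * dt[ps]) * 1000.

#' Discrete Fourier transform of a scalar series
#'
#' @param series a \code{\link{scalar_series}} (or plain numeric vector).
#' @return object of class \code{spectrum} holding the complex
#'   coefficients \code{X_k}, k = 0..N-1, plus \code{n}, \code{dt},
#'   \code{id}.
#' @export
dft <- function(series) {
  x <- if (inherits(series, "scalar_series")) series$values else series
  if (length(x) < 4) stop("need at least 4 samples", call. = FALSE)
  stopifnot_finite(x)
  structure(list(coefficients = fft(x), n = length(x),
                 dt = if (inherits(series, "scalar_series")) series$dt else 1,
                 id = if (inherits(series, "scalar_series")) series$id else "x"),
            class = "spectrum")
}

#' Inverse DFT
#'
#' @param spectrum a \code{spectrum} object (or complex coefficient
#'   vector).
#' @return the recovered real series.
#' @export
idft <- function(spectrum) {
  X <- if (inherits(spectrum, "spectrum")) spectrum$coefficients else spectrum
  Re(fft(X, inverse = TRUE)) / length(X)
}

# component frequencies in ns^-1 for k = 1..kmax given N, dt [ps]
component_freqs <- function(n, dt, kmax = floor(n / 2)) {
  (seq_len(kmax)) / (n * dt) * 1000
}

#' One-sided MSF-normalized spectral density
#'
#' The series is mean-centered first, so the total power equals the mean
#' square fluctuation (MSF) and each component's contribution P_k is the
#' share of the MSF carried by that frequency.
#'
#' @param series a \code{\link{scalar_series}}.
#' @return object of class \code{spectral_density}: \code{frequencies}
#'   (ns^-1, k = 1..floor(N/2)), \code{msf_contrib} (P_k, units^2),
#'   \code{total_msf}, \code{n_components}, \code{nyquist} (TRUE when the
#'   last component is the undoubled Nyquist term), plus \code{n},
#'   \code{dt}, \code{id}, \code{kind}.
#' @export
power_spectrum <- function(series) {
  x <- series$values
  n <- length(x)
  xc <- x - mean(x)
  X <- fft(xc)
  kmax <- floor(n / 2)
  P <- 2 * Mod(X[2:(kmax + 1)])^2 / n^2
  nyq <- n %% 2 == 0
  if (nyq) P[kmax] <- P[kmax] / 2   # Nyquist appears once, not twice
  structure(list(frequencies = component_freqs(n, series$dt, kmax),
                 msf_contrib = P, total_msf = mean(xc^2),
                 n_components = kmax, nyquist = nyq,
                 n = n, dt = series$dt, id = series$id,
                 kind = series$kind),
            class = "spectral_density")
}

#' @export
print.spectral_density <- function(x, ...) {
  cat(sprintf("spectral_density '%s' (%s): %d components, MSF = %.4g\n",
              x$id, x$kind, x$n_components, x$total_msf))
  invisible(x)
}

#' Sum spectral densities over a group of series
#'
#' Aggregates component-wise over series sharing N and dt — e.g. the x, y
#' and z coordinates of one atom, giving the per-atom spectral density
#' whose total is the atomic MSF in Angstrom^2.
#'
#' @param series_list list of \code{\link{scalar_series}} sharing length
#'   and dt.
#' @param id identifier for the aggregate.
#' @return a \code{spectral_density}.
#' @export
power_spectrum_group <- function(series_list, id = NULL) {
  if (!length(series_list)) stop("empty series list", call. = FALSE)
  sds <- lapply(series_list, power_spectrum)
  n <- sds[[1]]$n; dt <- sds[[1]]$dt
  for (s in sds)
    if (s$n != n || s$dt != dt)
      stop("all series must share length and dt", call. = FALSE)
  out <- sds[[1]]
  out$msf_contrib <- Reduce(`+`, lapply(sds, `[[`, "msf_contrib"))
  out$total_msf <- sum(vapply(sds, `[[`, 0, "total_msf"))
  out$id <- id %||% paste0(sds[[1]]$id, "+", length(sds) - 1)
  out
}

#' Spectral density of a circular variable
#'
#' The angle series is embedded on the unit circle as (cos, sin)
#' components (radians), each mean-centered, and the two component
#' densities are summed. The result is dimensionless.
#'
#' @param series a \code{\link{circular_series}} (degrees).
#' @return a \code{spectral_density} with \code{kind} carried over.
#' @export
circular_density <- function(series) {
  th <- series$angles * pi / 180
  comp <- list(scalar_series(cos(th), series$dt, paste0(series$id, ".cos")),
               scalar_series(sin(th), series$dt, paste0(series$id, ".sin")))
  out <- power_spectrum_group(comp, id = series$id)
  out$kind <- series$kind
  out
}

#' Band-limited reconstruction at one frequency component
#'
#' Zeroes every DFT component except k (and its conjugate) and inverts,
#' which analytically gives the single sinusoid
#' \eqn{r_n = a \cos(2\pi k n/N + \phi)} with \eqn{a = 2|X_k|/N} and
#' \eqn{\phi = \mathrm{Arg}(X_k)}.
#'
#' @param series a \code{\link{scalar_series}}.
#' @param k component index, 1 <= k < N/2.
#' @return object of class \code{reconstructed_signal}: \code{series},
#'   \code{amplitude}, \code{phase} (rad in (-pi, pi]; \code{NA} when the
#'   amplitude is zero), \code{k}, \code{fraction_msf}, plus \code{n},
#'   \code{dt}, \code{id}, \code{kind}.
#' @export
band_reconstruct <- function(series, k) {
  x <- series$values
  n <- length(x)
  if (k < 1 || k >= n / 2)
    stop("component index k must satisfy 1 <= k < N/2", call. = FALSE)
  Xk <- fft(x - mean(x))[k + 1]
  a <- 2 * Mod(Xk) / n
  phi <- if (a == 0) NA_real_ else Arg(Xk)
  idx <- seq_len(n) - 1
  rec <- if (a == 0) numeric(n) else a * cos(2 * pi * k * idx / n + phi)
  sdens <- power_spectrum(series)
  frac <- if (sdens$total_msf > 0) sdens$msf_contrib[k] / sdens$total_msf
          else 0
  structure(list(series = rec, amplitude = a, phase = phi, k = k,
                 fraction_msf = frac, n = n, dt = series$dt,
                 id = series$id, kind = series$kind),
            class = "reconstructed_signal")
}

#' @export
print.reconstructed_signal <- function(x, ...) {
  cat(sprintf(
    "reconstructed_signal '%s': k = %d, a = %.4g, phi = %s rad, %.1f%% of MSF\n",
    x$id, x$k, x$amplitude,
    if (is.na(x$phase)) "undefined" else sprintf("%.4f", x$phase),
    100 * x$fraction_msf))
  invisible(x)
}

#' Export a spectral density as a TSV table
#'
#' @param sd a \code{spectral_density} (or list of them).
#' @param path output file.
#' @export
write_spectral_density <- function(sd, path) {
  if (inherits(sd, "spectral_density")) sd <- list(sd)
  rows <- do.call(rbind, lapply(sd, function(s)
    data.frame(id = s$id, f = s$frequencies, P = s$msf_contrib)))
  write_tsv(rows, path)
}
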