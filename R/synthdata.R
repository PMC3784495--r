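# Synthetic-data generation: every input the pipeline needs, without
# external downloads. All generators are bit-reproducible given a seed.

#' 1/f^beta noise with planted on-bin sinusoids
#'
#' Spectral synthesis: Fourier coefficients with expected squared
#' magnitude proportional to k^(-beta), inverse DFT, exact rescaling of
#' the realized MSF to \code{msf}, then planted components added as exact
#' on-bin sinusoids \eqn{A \cos(2\pi k n/N + \phi)}.
#'
#' Two amplitude modes are provided. \code{"rayleigh"} (default) draws
#' complex-Gaussian coefficients, the standard construction for Gaussian
#' power-law noise, so the periodogram ordinates scatter about the
#' power law as in real fluctuation data. \code{"fixed"} uses
#' deterministic magnitudes |X_k| proportional to k^(-beta/2) with random
#' phases only, which yields an exactly linear log-log spectrum (useful
#' for analytic checks, degenerate for baseline-residual statistics).
#'
#' @param n number of samples (>= 16).
#' @param dt sampling interval in ps.
#' @param beta spectral exponent (>= 0; 1 = pink noise, 0 = white).
#' @param msf target mean square fluctuation of the noise part (units^2);
#'   0 gives pure planted signal.
#' @param planted list of planted components, each a list with elements
#'   \code{k} (1 <= k < N/2), \code{amplitude}, \code{phase} (rad); a
#'   single component may be given unwrapped.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @param amplitudes \code{"rayleigh"} or \code{"fixed"} (see above).
#' @param id variable identifier.
#' @return a \code{\link{scalar_series}}.
#' @export
pink_noise <- function(n, dt = 1, beta = 1, msf = 1, planted = list(),
                       seed = NULL, amplitudes = c("rayleigh", "fixed"),
                       id = "pink") {
  amplitudes <- match.arg(amplitudes)
  if (n < 16) stop("n must be >= 16", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  planted <- normalize_planted(planted, n)
  x <- with_seed(seed, {
    if (msf > 0) {
      even <- n %% 2 == 0
      kk <- seq_len(if (even) n / 2 - 1 else (n - 1) / 2)
      sdk <- kk^(-beta / 2)
      X <- if (amplitudes == "rayleigh")
        complex(real = rnorm(length(kk), 0, sdk / sqrt(2)),
                imaginary = rnorm(length(kk), 0, sdk / sqrt(2)))
      else sdk * exp(1i * runif(length(kk), -pi, pi))
      full <- c(0, X, if (even) 0, Conj(rev(X)))
      v <- Re(fft(full, inverse = TRUE)) / n
      v <- v - mean(v)
      realized <- mean(v^2)
      if (realized > 0) v <- v * sqrt(msf / realized)
      v
    } else numeric(n)
  })
  idx <- seq_len(n) - 1
  for (p in planted)
    x <- x + p$amplitude * cos(2 * pi * p$k * idx / n + p$phase)
  scalar_series(x, dt, id = id, kind = "coordinate")
}

normalize_planted <- function(planted, n) {
  if (!length(planted)) return(list())
  if (!is.null(planted$k)) planted <- list(planted)
  for (p in planted) {
    if (is.null(p$k) || is.null(p$amplitude) || is.null(p$phase))
      stop("each planted component needs k, amplitude, phase",
           call. = FALSE)
    if (p$k < 1 || p$k >= n / 2)
      stop("planted component k must satisfy 1 <= k < N/2", call. = FALSE)
  }
  planted
}

#' Synthetic circular variable with rotamer jumps
#'
#' A dihedral-like angle series: a base rotamer state, Gaussian angular
#' noise, seeded Poisson-timed jumps between rotamer targets, and an
#' optional planted on-bin sinusoid. Rotamer jumps inflate the lowest
#' frequency components, emulating the slow side-chain transitions that
#' dominate dihedral spectra.
#'
#' @param n samples; @param dt ps.
#' @param base initial angle in degrees on (-180, 180].
#' @param noise_sd angular noise SD in degrees.
#' @param jumps \code{NULL}, or list with \code{targets} (rotamer angles,
#'   degrees) and \code{rate} (jumps per ns).
#' @param planted optional planted component (\code{k},
#'   \code{amplitude} in degrees, \code{phase} in rad).
#' @param seed RNG seed.
#' @param id variable identifier.
#' @param kind dihedral kind label.
#' @return a \code{\link{circular_series}}.
#' @export
synth_circular <- function(n, dt = 1, base = -60, noise_sd = 0,
                           jumps = NULL, planted = list(), seed = NULL,
                           id = "chi", kind = "sidechain_dihedral") {
  planted <- normalize_planted(planted, n)
  ang <- with_seed(seed, {
    state <- rep(base, n)
    if (!is.null(jumps) && jumps$rate > 0 && length(jumps$targets) > 1) {
      if (any(jumps$targets <= -180 | jumps$targets > 180))
        stop("jump targets must lie in (-180, 180]", call. = FALSE)
      rate_ps <- jumps$rate / 1000
      t_ev <- cumsum(rexp(ceiling(4 * rate_ps * n * dt) + 10,
                          rate_ps))
      t_ev <- t_ev[t_ev < n * dt]
      cur <- base
      for (te in t_ev) {
        others <- setdiff(jumps$targets, cur)
        cur <- if (length(others) == 1) others
               else sample(others, 1)
        state[seq.int(floor(te / dt) + 1, n)] <- cur
      }
    }
    if (noise_sd > 0) state <- state + rnorm(n, 0, noise_sd)
    state
  })
  idx <- seq_len(n) - 1
  for (p in planted)
    ang <- ang + p$amplitude * cos(2 * pi * p$k * idx / n + p$phase)
  circular_series(wrap_deg(ang), dt, id = id, kind = kind)
}

## ---- forcing schedules ------------------------------------------------

#' Periodic forcing schedule
#'
#' Defines the target-alternation waveform of a restrained-TMD run: the
#' restraint target moves linearly from conformation A to B over each
#' half-period and back over the next (symmetric triangle, the waveform
#' implied by a linearly ramped target RMSD), or switches discretely
#' (square). The fundamental frequency is 1/period, which is on-bin by
#' construction since the total duration is n_cycles * period.
#'
#' @param period forcing period in ps (must be a multiple of dt).
#' @param n_cycles number of complete cycles (>= 1).
#' @param dt output sampling interval in ps.
#' @param waveform \code{"triangle"} (default) or \code{"square"}.
#' @return object of class \code{target_schedule} with \code{f0} in
#'   ns^-1.
#' @export
target_schedule <- function(period, n_cycles, dt = 1,
                            waveform = c("triangle", "square")) {
  waveform <- match.arg(waveform)
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  if (abs(period / dt - round(period / dt)) > 1e-9)
    stop("period must be an integer multiple of dt ",
         "(spectral leakage guard)", call. = FALSE)
  structure(list(period = period, n_cycles = n_cycles, dt = dt,
                 waveform = waveform, f0 = 1000 / period),
            class = "target_schedule")
}

# schedule weight in [0,1] at continuous time t (ps)
schedule_value <- function(s, t) {
  tau <- (t %% s$period) / s$period
  if (s$waveform == "triangle") ifelse(tau < 0.5, 2 * tau, 2 - 2 * tau)
  else as.numeric(tau >= 0.5)
}

#' Sampled forcing waveform
#'
#' @param s a \code{\link{target_schedule}}.
#' @return a \code{\link{scalar_series}} of the waveform in [0, 1],
#'   sampled at t = 0, dt, ..., (N-1) dt with N = n_cycles * period / dt.
#' @export
schedule_series <- function(s) {
  n <- round(s$n_cycles * s$period / s$dt)
  t <- (seq_len(n) - 1) * s$dt
  scalar_series(schedule_value(s, t), s$dt, id = "forcing",
                kind = "coordinate")
}

#' Fundamental amplitude and phase of a forcing schedule
#'
#' @param s a \code{\link{target_schedule}}.
#' @return list with \code{amplitude}, \code{phase} (rad), \code{k}
#'   (= n_cycles) and \code{f0} (ns^-1) of the fundamental DFT component
#'   of the sampled waveform.
#' @export
forcing_fundamental <- function(s) {
  br <- band_reconstruct(schedule_series(s), k = s$n_cycles)
  list(amplitude = br$amplitude, phase = br$phase, k = s$n_cycles,
       f0 = s$f0)
}

## ---- toy restrained-TMD simulator -------------------------------------

# compact helical bead chain: deterministic "toy fold" whose adjacent
# turns fall within a typical contact cutoff
helix_chain <- function(n, bond = 3.8, n_per_turn = 7, rise = 0.8) {
  ang <- 2 * pi / n_per_turn
  chord2 <- bond^2 - rise^2
  if (chord2 <= 0) stop("rise too large for bond length", call. = FALSE)
  radius <- sqrt(chord2) / (2 * sin(ang / 2))
  i <- seq_len(n) - 1
  cbind(radius * cos(i * ang), radius * sin(i * ang), i * rise)
}

#' Toy network specification for the restrained-TMD simulator
#'
#' Defaults define a 60-bead compact helical chain with contacts within
#' 8 Angstrom, network stiffness and friction chosen so the slowest
#' network relaxation is a few hundred ps (the regime in which forcing
#' periods of a few ns are transmitted, while tens-of-ps forcing is
#' attenuated), and a 6-bead contiguous restrained "loop" driven between
#' its reference conformation and a radially displaced target.
#'
#' @param n_beads chain length.
#' @param bond_length virtual bond length in Angstrom.
#' @param contact_cutoff network contact cutoff in Angstrom.
#' @param k_net network spring constant (kcal/mol/A^2).
#' @param gamma friction coefficient (kcal/mol/A^2 * ps; force per
#'   velocity).
#' @param kT thermal energy (kcal/mol; 0.593 ~ 300 K).
#' @param restrained bead indices of the driven subset.
#' @param target_displacement radial displacement of target B from target
#'   A (= reference) in Angstrom.
#' @param k_tmd restraint spring constant (kcal/mol/A^2); 0 disables the
#'   restraint (equilibrium run).
#' @param schedule a \code{\link{target_schedule}} (its dt is the output
#'   sampling interval).
#' @param integration_dt Euler-Maruyama step in ps (must divide the
#'   schedule dt).
#' @param seed RNG seed.
#' @return object of class \code{toy_network_spec}.
#' @export
toy_network_spec <- function(n_beads = 60, bond_length = 3.8,
                             contact_cutoff = 8, k_net = 2,
                             gamma = 20, kT = 0.593,
                             restrained = 28:33,
                             target_displacement = 3, k_tmd = 20,
                             schedule = target_schedule(5000, 16, 1),
                             integration_dt = 0.5, seed = 1) {
  if (!length(restrained) || max(restrained) > n_beads ||
      min(restrained) < 1)
    stop("restrained subset must be a nonempty subset of beads",
         call. = FALSE)
  if (k_tmd < 0) stop("k_tmd must be >= 0", call. = FALSE)
  stride <- schedule$dt / integration_dt
  if (abs(stride - round(stride)) > 1e-9)
    stop("integration_dt must divide the schedule dt", call. = FALSE)
  structure(list(n_beads = n_beads, bond_length = bond_length,
                 contact_cutoff = contact_cutoff, k_net = k_net,
                 gamma = gamma, kT = kT, restrained = restrained,
                 target_displacement = target_displacement,
                 k_tmd = k_tmd, schedule = schedule,
                 integration_dt = integration_dt,
                 stride = round(stride), seed = seed),
            class = "toy_network_spec")
}

toy_reference <- function(spec) {
  helix_chain(spec$n_beads, spec$bond_length)
}

toy_edges <- function(ref, cutoff) {
  d <- as.matrix(dist(ref))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2], r0 = d[idx])
}

# largest eigenvalue of the spring-network Hessian at the reference
network_lambda_max <- function(ref, ed, k_net) {
  n <- nrow(ref)
  H <- matrix(0, 3 * n, 3 * n)
  for (e in seq_along(ed$i)) {
    i <- ed$i[e]; j <- ed$j[e]
    u <- ref[i, ] - ref[j, ]
    u <- u / sqrt(sum(u^2))
    B <- k_net * (u %o% u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + B; H[jj, jj] <- H[jj, jj] + B
    H[ii, jj] <- H[ii, jj] - B; H[jj, ii] <- H[jj, ii] - B
  }
  max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
}

#' Overdamped Langevin simulation of a periodically driven bead network
#'
#' Builds a harmonic contact network on the reference chain, adds a
#' per-bead harmonic restraint pulling the driven subset toward the
#' schedule-interpolated target (a simplification of a holonomic
#' RMSD-ramp restraint that preserves the forcing's spectral structure),
#' and integrates overdamped (Brownian) dynamics with a seeded
#' Euler-Maruyama scheme. Frames are recorded at t = 0, dt, ...,
#' (N-1) dt, aligned with \code{\link{schedule_series}}.
#'
#' @param spec a \code{\link{toy_network_spec}}.
#' @return list with \code{traj} (a \code{\link{trajectory_ensemble}}),
#'   and \code{truth}: the planted \code{displacement} field (target B
#'   minus target A over all beads), the \code{forcing} fundamental
#'   (amplitude/phase/k/f0 from \code{\link{forcing_fundamental}}), and
#'   the \code{spec}.
#' @export
toy_tmd_simulate <- function(spec) {
  ref <- toy_reference(spec)
  n <- spec$n_beads
  ed <- toy_edges(ref, spec$contact_cutoff)
  ne <- length(ed$i)
  # Euler stability: the fastest relaxation (largest Hessian eigenvalue
  # at the reference, plus the restraint stiffness) must be resolved
  lam_max <- network_lambda_max(ref, ed, spec$k_net)
  if (spec$integration_dt * (lam_max + spec$k_tmd) / spec$gamma >= 2)
    stop("integration unstable for these constants; ",
         "decrease integration_dt", call. = FALSE)
  # incidence matrix for force accumulation
  M <- matrix(0, n, ne)
  M[cbind(ed$i, seq_len(ne))] <- 1
  M[cbind(ed$j, seq_len(ne))] <- -1
  # targets: A = reference subset, B = radially displaced
  restr <- spec$restrained
  radial <- ref[restr, 1:2, drop = FALSE]
  radial <- radial / sqrt(rowSums(radial^2))
  tgtA <- ref[restr, , drop = FALSE]
  tgtB <- tgtA + spec$target_displacement * cbind(radial, 0)
  n_out <- round(spec$schedule$n_cycles * spec$schedule$period /
                   spec$schedule$dt)
  dti <- spec$integration_dt
  sig <- sqrt(2 * spec$kT * dti / spec$gamma)
  out <- matrix(NA_real_, n_out, 3 * n)
  with_seed(spec$seed, {
    X <- ref
    step <- 0L
    for (f in seq_len(n_out)) {
      out[f, ] <- as.vector(t(X))
      for (ss in seq_len(spec$stride)) {
        d <- X[ed$i, , drop = FALSE] - X[ed$j, , drop = FALSE]
        len <- sqrt(rowSums(d * d))
        co <- -spec$k_net * (len - ed$r0) / len
        F <- M %*% (d * co)
        if (spec$k_tmd > 0) {
          s <- schedule_value(spec$schedule, step * dti)
          tgt <- tgtA + s * (tgtB - tgtA)
          F[restr, ] <- F[restr, ] -
            spec$k_tmd * (X[restr, , drop = FALSE] - tgt)
        }
        X <- X + F * (dti / spec$gamma) +
          matrix(rnorm(3 * n, 0, sig), n, 3)
        step <- step + 1L
      }
      if (!all(is.finite(X)) || max(abs(X - ref)) > 1e4)
        stop("integration diverged; decrease integration_dt",
             call. = FALSE)
    }
  })
  traj <- trajectory_ensemble(out, dt = spec$schedule$dt,
                              source = "toy_tmd_simulate")
  vec <- matrix(0, n, 3)
  vec[restr, ] <- tgtB - tgtA
  truth <- list(
    displacement = structure(list(vectors = vec,
                                  magnitudes = sqrt(rowSums(vec^2)),
                                  selection = seq_len(n)),
                             class = "displacement_field"),
    forcing = forcing_fundamental(spec$schedule),
    spec = spec)
  list(traj = traj, truth = truth)
}

## ---- benchmark sets ---------------------------------------------------

# expected noise MSF share of component k under 1/f^beta synthesis
noise_share <- function(n, beta, k) {
  even <- n %% 2 == 0
  kk <- seq_len(if (even) n / 2 - 1 else (n - 1) / 2)
  k^(-beta) / sum(kk^(-beta))
}

#' Benchmark variable set with planted perturbations
#'
#' Generates \code{n_vars} scalar 1/f^beta noise series (plus optionally
#' some circular ones); a subset carries planted on-bin sinusoids at
#' component \code{k_b} with cluster-structured phases. The planted
#' amplitude is set so the planted spectral power is \code{snr} times
#' the expected noise power at \code{k_b}.
#'
#' @param n_vars total number of variables.
#' @param n_perturbed number carrying a planted sinusoid.
#' @param phases folded phase angles assigned round-robin to perturbed
#'   variables (defaults: the four quadrant centers).
#' @param snr planted-to-background power ratio at the forcing component.
#' @param seed RNG seed.
#' @param n,dt,beta,msf noise parameters (see \code{\link{pink_noise}}).
#' @param k_b forcing component index.
#' @param n_circular how many of the variables are circular (rotamer-type;
#'   perturbed circular variables get a planted angular sinusoid).
#' @return list with \code{series} (named list of series), \code{truth}
#'   (data.frame: id, type, perturbed, k, amplitude, theta, cluster), and
#'   \code{f_b} (ns^-1).
#' @export
benchmark_set <- function(n_vars = 100, n_perturbed = 20,
                          phases = pi / 8 + (0:3) * pi / 4, snr = 100,
                          seed = 1, n = 4096, dt = 1, beta = 1, msf = 1,
                          k_b = 16, n_circular = 0) {
  if (n_perturbed > n_vars)
    stop("n_perturbed must be <= n_vars", call. = FALSE)
  amp <- sqrt(2 * snr * msf * noise_share(n, beta, k_b))
  series <- vector("list", n_vars)
  truth <- data.frame(id = sprintf("v%03d", seq_len(n_vars)),
                      type = rep(c(rep("circular", n_circular),
                                   rep("scalar", n_vars - n_circular)),
                                 length.out = n_vars),
                      perturbed = seq_len(n_vars) <= n_perturbed,
                      k = k_b, amplitude = 0, theta = NA_real_,
                      cluster = NA_integer_, stringsAsFactors = FALSE)
  with_seed(seed, {
    for (v in seq_len(n_vars)) {
      pert <- truth$perturbed[v]
      theta <- if (pert) phases[(v - 1) %% length(phases) + 1] else NA
      if (truth$type[v] == "circular") {
        pl <- if (pert)
          list(k = k_b, amplitude = 15, phase = theta) else list()
        series[[v]] <- synth_circular(n, dt, base = -60, noise_sd = 6,
                                      planted = pl, id = truth$id[v])
        if (pert) truth$amplitude[v] <- 15
      } else {
        pl <- if (pert)
          list(k = k_b, amplitude = amp, phase = theta) else list()
        series[[v]] <- pink_noise(n, dt, beta, msf, planted = pl,
                                  id = truth$id[v])
        if (pert) truth$amplitude[v] <- amp
      }
      if (pert) {
        truth$theta[v] <- fold_phase(theta)
        truth$cluster[v] <- pmin(floor(fold_phase(theta) / (pi / 4)), 3) + 1
      }
    }
  })
  names(series) <- truth$id
  list(series = series, truth = truth, f_b = k_b / (n * dt) * 1000)
}
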