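## Synthetic-data generators with known ground truth: steered-ion Langevin
## logs, hexamer trajectories, and force-ramp pulling traces.  These
## emulate the statistical structure of the MD outputs the analysis stages
## consume, so every downstream operation can be tested against a
## prescribed truth (PMF shape, anisotropy, rupture force).

#' Specify a one-dimensional free-energy profile
#'
#' Describes the potential of mean force W(z) a synthetic steered ion
#' moves in. Shapes: `flat` (W = 0), `linear` (constant slope),
#' `gaussian_barrier` (height, center, width), or `tabulated`
#' (explicit (z, W) table, interpolated linearly).
#'
#' @param kind one of `"flat"`, `"linear"`, `"gaussian_barrier"`,
#'   `"tabulated"`.
#' @param z_range numeric length-2, pulling range in nm (`z_max > z_min`).
#' @param height,center,width Gaussian barrier parameters (kJ/mol, nm, nm);
#'   `width` must be positive.
#' @param slope linear slope in kJ/mol/nm.
#' @param table data frame with columns `z`, `W` for `kind = "tabulated"`.
#' @return An object of class `pmf_spec`.
#' @export
pmf_spec <- function(kind = c("flat", "linear", "gaussian_barrier", "tabulated"),
                     z_range = c(0, 8.6),
                     height = 20, center = mean(z_range), width = 0.5,
                     slope = 0, table = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(z_range) == 2, is.finite(z_range), z_range[2] > z_range[1])
  if (kind == "gaussian_barrier") stopifnot(width > 0, is.finite(height))
  if (kind == "tabulated") {
    stopifnot(is.data.frame(table), all(c("z", "W") %in% names(table)),
              nrow(table) >= 2, all(diff(table$z) > 0), all(is.finite(table$W)))
  }
  structure(list(kind = kind, z_range = as.numeric(z_range), height = height,
                 center = center, width = width, slope = slope, table = table),
            class = "pmf_spec")
}

#' Evaluate a pmf_spec at positions z
#' @param spec a [pmf_spec()].
#' @param z numeric positions (nm).
#' @return W(z) in kJ/mol.
#' @export
pmf_eval <- function(spec, z) {
  stopifnot(inherits(spec, "pmf_spec"))
  w <- switch(spec$kind,
    flat = rep(0, length(z)),
    linear = spec$slope * (z - spec$z_range[1]),
    gaussian_barrier = spec$height *
      exp(-0.5 * ((z - spec$center) / spec$width)^2),
    tabulated = stats::approx(spec$table$z, spec$table$W, xout = z,
                              rule = 2)$y)
  if (any(!is.finite(w)))
    stop("pmf_spec evaluates to non-finite values in z_range")
  w
}

## dW/dz for the Langevin force; tabulated specs use central differences
pmf_grad_table <- function(spec, n = 4096) {
  z <- seq(spec$z_range[1], spec$z_range[2], length.out = n)
  w <- pmf_eval(spec, z)
  g <- c(diff(w[1:2]) / diff(z[1:2]),
         (w[-(1:2)] - w[1:(n - 2)]) / (z[-(1:2)] - z[1:(n - 2)]),
         diff(w[(n - 1):n]) / diff(z[(n - 1):n]))
  list(z = z, dW = g)
}

#' Parameters of the overdamped Langevin steering integrator
#'
#' @param k trap spring constant (kJ mol^-1 nm^-2).
#' @param v trap velocity along z (nm/ns); `v = 0` holds the trap still, in
#'   which case `gen_smd_log()` needs an explicit `t_max`.
#' @param dt integration time step (ns).
#' @param T temperature (K); sets the thermal energy and, through the
#'   Einstein relation, the friction.
#' @param D ion diffusion coefficient (nm^2/ns).
#' @param noise logical; `FALSE` switches thermal noise off (the
#'   zero-temperature drift limit) while keeping the deterministic drift.
#' @param seed integer RNG seed; the same seed reproduces the log bitwise.
#' @return An object of class `langevin_params`.
#' @export
langevin_params <- function(k = 2000, v = 0.5, dt = 2e-5, T = 300,
                            D = 1.957, noise = TRUE, seed = 1L) {
  stopifnot(k > 0, v >= 0, dt > 0, T > 0, D > 0)
  structure(list(k = k, v = v, dt = dt, T = T, D = D,
                 noise = isTRUE(noise), seed = as.integer(seed)),
            class = "langevin_params")
}

#' Generate a steered-pulling force log by overdamped Langevin dynamics
#'
#' Integrates the Euler--Maruyama scheme for an ion in the profile
#' `pmf`, attached to a harmonic trap that moves from `z_min` to `z_max`
#' at constant velocity. Records time, trap position, ion position and
#' spring force `k * (z_trap - z_ion)`.
#'
#' The scheme is only stable when the trap relaxation is resolved:
#' `k * dt * D / kBT < 0.1` is enforced and violating it is an error, not
#' a warning.
#'
#' @param pmf a [pmf_spec()].
#' @param lp a [langevin_params()].
#' @param record_dt sampling interval of the log (ns); rounded to a whole
#'   number of integration steps.
#' @param t_max total simulated time (ns), required when `lp$v == 0`.
#' @return An [smd_log()] object.
#' @export
gen_smd_log <- function(pmf, lp, record_dt = 10 * lp$dt, t_max = NULL) {
  stopifnot(inherits(pmf, "pmf_spec"), inherits(lp, "langevin_params"))
  kBT <- kBT_kJmol(lp$T)
  stab <- lp$k * lp$dt * lp$D / kBT
  if (stab >= 0.1)
    stop(sprintf(
      "unstable step size: k*dt*D/kBT = %.3g >= 0.1; reduce dt below %.3g ns",
      stab, 0.1 * kBT / (lp$k * lp$D)))
  if (lp$v == 0 && is.null(t_max))
    stop("v = 0 requires an explicit t_max")
  pmf_eval(pmf, seq(pmf$z_range[1], pmf$z_range[2], length.out = 64)) # finiteness
  kind <- match(pmf$kind, c("flat", "linear", "gaussian_barrier", "tabulated")) - 1L
  par <- switch(pmf$kind,
    flat = 0, linear = spec_slope(pmf),
    gaussian_barrier = c(pmf$height, pmf$center, pmf$width),
    tabulated = 0)
  tab <- if (pmf$kind == "tabulated") pmf_grad_table(pmf)
         else list(z = c(0, 1), dW = c(0, 0))
  stride <- max(1L, as.integer(round(record_dt / lp$dt)))
  set.seed(lp$seed)
  m <- langevin_steer_cpp(
    z0 = pmf$z_range[1], z_min = pmf$z_range[1], z_max = pmf$z_range[2],
    k = lp$k, v = lp$v, dt = lp$dt, D = lp$D, kBT = kBT, noise = lp$noise,
    t_max = if (is.null(t_max)) 0 else t_max,
    kind = kind, par = as.numeric(par),
    tab_z = tab$z, tab_dW = tab$dW, stride = stride)
  smd_log(t = m[, 1], z_trap = m[, 2], z_ion = m[, 3], F_spring = m[, 4],
          k = lp$k, v = lp$v)
}

spec_slope <- function(pmf) pmf$slope

#' Specify a synthetic hexamer trajectory
#'
#' Six protomer vertices per residue are placed at 0, 60, ..., 300 degrees
#' on a circle of the residue's radius; the x axis is scaled by the
#' anisotropy factor `a`, then i.i.d. Gaussian noise is added to every
#' coordinate in every frame. The noiseless eccentricity is the analytic
#' `hex_eccentricity_aniso(a)`.
#'
#' @param n_frames number of frames (>= 1).
#' @param residues integer residue ids.
#' @param radius mean vertex radius per residue (nm); recycled.
#' @param a anisotropy factor >= 1 applied to x.
#' @param noise_sd per-coordinate Gaussian noise sd (nm), >= 0.
#' @param dt_frame frame spacing (ns).
#' @param seed integer RNG seed.
#' @return An object of class `hex_synth_spec`.
#' @export
hex_synth_spec <- function(n_frames = 100, residues = 2:14, radius = 1.0,
                           a = 1.0, noise_sd = 0, dt_frame = 0.18, seed = 1L) {
  stopifnot(n_frames >= 1, length(residues) >= 1, all(radius > 0),
            a >= 1, noise_sd >= 0)
  radius <- rep_len(radius, length(residues))
  structure(list(n_frames = as.integer(n_frames),
                 residues = as.integer(residues), radius = radius, a = a,
                 noise_sd = noise_sd, dt_frame = dt_frame,
                 seed = as.integer(seed)),
            class = "hex_synth_spec")
}

#' Eccentricity of the noiseless stretched hexagon
#'
#' For vertices on a circle with x scaled by `a >= 1`, the three main
#' diagonals are `2 a r` and (twice) `2 r sqrt(a^2/4 + 3/4)`, so
#' `E = a / sqrt(a^2/4 + 3/4)`.
#'
#' @param a anisotropy factor >= 1.
#' @return Noiseless eccentricity E(a).
#' @export
hex_eccentricity_aniso <- function(a) a / sqrt(a^2 / 4 + 3 / 4)

#' Generate a synthetic hexamer trajectory
#'
#' @param spec a [hex_synth_spec()].
#' @return A [hex_frame_series()] with 6 protomers per frame.
#' @export
gen_hex_traj <- function(spec) {
  stopifnot(inherits(spec, "hex_synth_spec"))
  set.seed(spec$seed)
  nf <- spec$n_frames; nr <- length(spec$residues)
  th <- (0:5) * pi / 3
  base <- array(0, dim = c(6, nr, 3))
  for (j in seq_len(nr)) {
    base[, j, 1] <- spec$a * spec$radius[j] * cos(th)
    base[, j, 2] <- spec$radius[j] * sin(th)
    base[, j, 3] <- 0.15 * (j - 1)          # helix-like rise along z
  }
  coords <- array(rep(base, nf), dim = c(6, nr, 3, nf))
  if (spec$noise_sd > 0)
    coords <- coords + array(stats::rnorm(length(coords), 0, spec$noise_sd),
                             dim = dim(coords))
  coords <- aperm(coords, c(4, 1, 2, 3))    # frame, protomer, residue, xyz
  hex_frame_series(coords, residues = spec$residues,
                   time = (seq_len(nf) - 1) * spec$dt_frame)
}

#' Specify synthetic force-ramp pulling traces
#'
#' Each trace ramps at slope `k * v` until a per-trace rupture force drawn
#' from N(`rupture_mean`, `rupture_sd`), then relaxes exponentially to
#' `residual` with time constant `tau_relax`; Gaussian noise of sd
#' `noise_sd` is added throughout.
#'
#' @param n_traces number of traces (helices).
#' @param k spring constant (kJ mol^-1 nm^-2).
#' @param v pull velocity (nm/ns).
#' @param rupture_mean,rupture_sd rupture force distribution
#'   (kJ mol^-1 nm^-1); mean must be positive and reachable within
#'   `t_max` (`k * v * t_max > rupture_mean`).
#' @param residual post-rupture force level (kJ mol^-1 nm^-1).
#' @param tau_relax post-rupture relaxation time constant (ns).
#' @param noise_sd additive Gaussian noise sd (kJ mol^-1 nm^-1).
#' @param dt,t_max sampling step and trace length (ns).
#' @param seed integer RNG seed.
#' @return An object of class `pull_synth_spec`.
#' @export
pull_synth_spec <- function(n_traces = 6, k = 100, v = 1,
                            rupture_mean = 105, rupture_sd = 5,
                            residual = 10, tau_relax = 0.05,
                            noise_sd = 5, dt = 0.001, t_max = 3,
                            seed = 1L) {
  stopifnot(n_traces >= 1, k > 0, v > 0, rupture_mean > 0, rupture_sd >= 0,
            noise_sd >= 0, dt > 0, t_max > dt)
  if (t_max * k * v <= rupture_mean)
    stop(sprintf(
      "rupture force %g not reachable: ramp only attains %g by t_max",
      rupture_mean, t_max * k * v))
  structure(list(n_traces = as.integer(n_traces), k = k, v = v,
                 rupture_mean = rupture_mean, rupture_sd = rupture_sd,
                 residual = residual, tau_relax = tau_relax,
                 noise_sd = noise_sd, dt = dt, t_max = t_max,
                 seed = as.integer(seed)),
            class = "pull_synth_spec")
}

#' Generate force-ramp pulling traces with known rupture forces
#'
#' @param spec a [pull_synth_spec()].
#' @return A [pull_trace_set()]; the drawn rupture forces and times are
#'   attached as attributes `rupture_forces` and `rupture_times`
#'   (the ground truth).
#' @export
gen_pull_traces <- function(spec) {
  stopifnot(inherits(spec, "pull_synth_spec"))
  set.seed(spec$seed)
  t <- seq(0, spec$t_max, by = spec$dt)
  slope <- spec$k * spec$v
  f_rup <- stats::rnorm(spec$n_traces, spec$rupture_mean, spec$rupture_sd)
  if (any(f_rup <= 0) || any(f_rup >= slope * spec$t_max))
    stop("drawn rupture force outside the reachable ramp range; ",
         "increase t_max or reduce rupture_sd")
  t_rup <- f_rup / slope
  traces <- lapply(seq_len(spec$n_traces), function(j) {
    f <- ifelse(t <= t_rup[j],
                slope * t,
                spec$residual +
                  (f_rup[j] - spec$residual) * exp(-(t - t_rup[j]) / spec$tau_relax))
    if (spec$noise_sd > 0) f <- f + stats::rnorm(length(t), 0, spec$noise_sd)
    data.frame(t = t, F = f)
  })
  out <- pull_trace_set(traces, k = spec$k, v = spec$v)
  attr(out, "rupture_forces") <- f_rup
  attr(out, "rupture_times") <- t_rup
  out
}
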