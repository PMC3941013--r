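## Unitary conductance from a full-channel PMF.
##
## The permeation of a single ion is modelled as 1-D diffusion in the
## profile U(z); the mean first passage time from one channel end to the
## other (absorbing far end, reflecting near end) is the double integral
##
##   tau = (1/D) int_l^r exp(+beta U(y)) [ int e^{-beta U(z)} dz ] dy
##
## evaluated in both directions. Rates kappa = 1/tau give the net current
## I = q (kappa_lr - kappa_rl) under a membrane potential applied as a
## linear tilt of the profile, and the unitary conductance gamma0 is the
## slope of the I-V line. A Debye-screening argument then scales gamma0 by
## the number of ions that can occupy the channel simultaneously.

#' Channel and electrolyte parameters
#'
#' @param T temperature (K).
#' @param c monovalent salt concentration (mol/L).
#' @param D bulk ion diffusion coefficient (m^2/s).
#' @param L full-channel length (nm).
#' @param q ion charge in units of the proton charge.
#' @param epsr relative permittivity of the solvent.
#' @return An object of class `channel_params`. `beta = 1/(kB T)` is always
#'   derived from `T`, never stored.
#' @export
channel_params <- function(T = 300, c = 0.15, D = 1.957e-9, L = 17.2,
                           q = 1, epsr = 78.4) {
  stopifnot(T > 0, c > 0, D > 0, L > 0, epsr > 0)
  structure(list(T = T, c = c, D = D, L = L, q = q, epsr = epsr),
            class = "channel_params")
}

#' Debye screening length of the electrolyte
#'
#' `lambda_D = sqrt(eps0 epsr kB T / (2 e^2 NA c))` with the concentration
#' converted to mol/m^3. Charges farther apart than about two Debye
#' lengths are mutually screened.
#'
#' @param p a [channel_params()].
#' @return Debye length in nm.
#' @export
debye_length <- function(p) {
  stopifnot(inherits(p, "channel_params"))
  c_m3 <- p$c * 1000
  lam_m <- sqrt(phys_const$eps0 * p$epsr * phys_const$kB * p$T /
                  (2 * phys_const$e^2 * phys_const$N_A * c_m3))
  lam_m * 1e9
}

#' Number of simultaneously permeating ions
#'
#' Ions spaced by at least one Debye diameter interact negligibly, so a
#' channel of length `L` can host `N_I = L / (2 lambda_D)` nearly
#' independent ions.
#'
#' @param p a [channel_params()].
#' @param lambda_D Debye length (nm); defaults to [debye_length()] of `p`.
#' @param rounding `"printed"` first rounds `lambda_D` to two decimals
#'   before doubling and dividing (the convention used when quoting the
#'   count alongside a 2-decimal Debye length, e.g. 17.2 / (2 x 0.79) =
#'   17.2 / 1.58); `"none"` divides directly.
#' @return N_I (dimensionless).
#' @export
ion_count <- function(p, lambda_D = debye_length(p),
                      rounding = c("printed", "none")) {
  stopifnot(inherits(p, "channel_params"), lambda_D > 0)
  rounding <- match.arg(rounding)
  denom <- if (rounding == "printed") 2 * round(lambda_D, 2) else 2 * lambda_D
  p$L / denom
}

#' Tilt a full-channel PMF by an applied membrane potential
#'
#' The electrical potential is assumed linear in z across the channel, so
#' a potential difference `dV` adds `q * dV * (L - zeta) / L` to the
#' profile (zeta = distance from the left end), expressed in kJ/mol. The
#' full drop is applied across the grid; a window-center grid may stop up
#' to one grid spacing short of the nominal length `p$L`.
#'
#' @param W a [pmf_profile()] whose grid extent equals `p$L` (within one
#'   grid spacing).
#' @param dV applied potential difference (mV).
#' @param p a [channel_params()].
#' @return A [pmf_profile()] tagged `tilted` (or `W` unchanged at
#'   `dV = 0`).
#' @export
tilt_potential <- function(W, dV, p) {
  stopifnot(inherits(W, "pmf_profile"), inherits(p, "channel_params"))
  n <- nrow(W)
  extent <- W$z[n] - W$z[1]
  h <- stats::median(diff(W$z))
  # window-center grids may stop half a window short of each channel end
  if (abs(extent - p$L) > h + 1e-9 * p$L)
    stop("PMF grid spans ", format(extent), " nm but channel length is ",
         p$L, " nm")
  if (dV == 0) return(W)
  u <- W$W + emV_to_kJmol(p$q * dV) * (W$z[n] - W$z) / extent
  pmf_profile(W$z, u, tag = "tilted")
}

#' Mean first passage time across a 1-D free-energy profile
#'
#' Evaluates the Smoluchowski double integral by the trapezoid rule on the
#' profile grid: the inner integral of `exp(-beta U)` is accumulated once
#' as a prefix sum and reused across the outer integral of `exp(+beta U)`,
#' so the cost is O(n). `l_to_r` starts the ion at the left end
#' (reflecting) with the right end absorbing; `r_to_l` is the mirrored
#' problem. The mid-range of `beta U` is factored out of both exponentials
#' before exponentiating, so barriers of 100+ kJ/mol do not overflow.
#'
#' @param U a [pmf_profile()] on a grid of at least 16 points.
#' @param p a [channel_params()] (supplies `T` and `D`).
#' @param direction `"l_to_r"` or `"r_to_l"`.
#' @return Mean first passage time in ns.
#' @export
mfpt <- function(U, p, direction = c("l_to_r", "r_to_l")) {
  stopifnot(inherits(U, "pmf_profile"), inherits(p, "channel_params"))
  direction <- match.arg(direction)
  z <- U$z; u <- U$W; n <- length(z)
  if (n < 16) stop("MFPT quadrature needs a grid of at least 16 points")
  if (any(!is.finite(u))) stop("profile contains non-finite values")
  beta <- 1 / kBT_kJmol(p$T)
  bu <- beta * u
  bu <- bu - (max(bu) + min(bu)) / 2        # overflow guard; cancels exactly
  ep <- exp(bu); em <- exp(-bu)
  dz <- diff(z)
  ## prefix trapezoid of exp(-beta U) from the left end
  inner_l <- c(0, cumsum(dz * (em[-n] + em[-1]) / 2))
  if (direction == "l_to_r") {
    g <- ep * inner_l                       # integrand of the outer integral
  } else {
    inner_r <- inner_l[n] - inner_l         # integral from y to the right end
    g <- ep * inner_r
  }
  D_nm <- m2s_to_nm2ns(p$D)
  sum(dz * (g[-n] + g[-1]) / 2) / D_nm
}

#' Unitary conductance from a full-channel PMF
#'
#' For each applied potential the profile is tilted, the forward and
#' reverse mean-first-passage rates are computed, and the net single-ion
#' current is `I = q (kappa_lr - kappa_rl)`. The unitary conductance
#' `gamma0` is the least-squares slope of the I-V line (intercept fitted
#' and checked to be ~0: a large intercept signals a quadrature asymmetry).
#'
#' @param W a full-channel [pmf_profile()] spanning `p$L`.
#' @param p a [channel_params()].
#' @param dV_list applied potentials (mV), at least two distinct values,
#'   symmetric about 0; default +/-5, +/-10, ..., +/-25 mV — the
#'   small-signal regime, where the cubic term of the exact I-V relation
#'   biases the fitted slope by well under 1%.
#' @return An object of class `conductance_result`: list with `dV` (mV),
#'   `I` (pA), `kappa_forward`, `kappa_reverse` (s^-1), `gamma0` (pS),
#'   `intercept` (pA) and `residual` (RMS of the fit, pA).
#' @export
compute_conductance <- function(W, p, dV_list = c(-(5:1), 1:5) * 5) {
  stopifnot(inherits(W, "pmf_profile"), inherits(p, "channel_params"))
  dV_list <- sort(unique(as.numeric(dV_list)))
  if (length(dV_list) < 2) stop("need at least 2 distinct potentials")
  if (max(abs(dV_list + rev(dV_list))) > 1e-9)
    stop("dV_list must be placed symmetrically about 0")
  kf <- kr <- numeric(length(dV_list))
  for (i in seq_along(dV_list)) {
    U <- tilt_potential(W, dV_list[i], p)
    kf[i] <- per_ns_to_per_s(1 / mfpt(U, p, "l_to_r"))
    kr[i] <- per_ns_to_per_s(1 / mfpt(U, p, "r_to_l"))
  }
  I_pA <- p$q * phys_const$e * (kf - kr) * 1e12
  fit <- stats::lm.fit(cbind(1, dV_list), I_pA)
  gamma0 <- unname(fit$coefficients[2]) * 1000   # pA/mV -> pS
  intercept <- unname(fit$coefficients[1])
  if (abs(intercept) > 0.01 * max(abs(I_pA)))
    warning("I-V intercept ", format(intercept),
            " pA exceeds 1% of max |I|; check quadrature symmetry")
  structure(list(dV = dV_list, I = I_pA, kappa_forward = kf,
                 kappa_reverse = kr, gamma0 = gamma0,
                 intercept = intercept,
                 residual = sqrt(mean(fit$residuals^2))),
            class = "conductance_result")
}

#' Debye multi-ion correction of the unitary conductance
#'
#' Scales the single-ion-occupancy conductance by the number of ions that
#' occupy the channel simultaneously: `gamma = N_I * gamma0`.
#'
#' @param gamma0 single-ion unitary conductance (pS), >= 0.
#' @param N_I simultaneous ion count, >= 1.
#' @return Corrected conductance (pS).
#' @export
multi_ion_correction <- function(gamma0, N_I) {
  stopifnot(gamma0 >= 0, N_I >= 1)
  N_I * gamma0
}

#' Full multi-ion conductance summary
#'
#' Convenience wrapper chaining [debye_length()], [ion_count()] and
#' [multi_ion_correction()].
#'
#' @param gamma0 single-ion unitary conductance (pS).
#' @param p a [channel_params()].
#' @param rounding passed to [ion_count()].
#' @return List with `lambda_D` (nm), `N_I`, `gamma0` and `gamma` (pS).
#' @export
ion_count_result <- function(gamma0, p, rounding = "printed") {
  lam <- debye_length(p)
  ni <- ion_count(p, lam, rounding = rounding)
  list(lambda_D = lam, N_I = ni, gamma0 = gamma0,
       gamma = multi_ion_correction(gamma0, ni))
}

#' @export
print.conductance_result <- function(x, ...) {
  cat("Unitary conductance (single-ion): gamma0 =",
      format(x$gamma0, digits = 4), "pS\n")
  cat("I-V fit intercept:", format(x$intercept, digits = 3),
      "pA; RMS residual:", format(x$residual, digits = 3), "pA\n")
  cat("Potentials (mV):", paste(x$dV, collapse = ", "), "\n")
  invisible(x)
}
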