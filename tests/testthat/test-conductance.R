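# Debye screening, ion count, potential tilt, MFPT quadrature and the
# unitary-conductance pipeline, checked against closed forms and a naive
# independent quadrature.

p_default <- channel_params()

flat_profile <- function(n = 1025, L = 17.2, W = 0)
  pmf_profile(seq(0, L, length.out = n), rep(W, n), tag = "full_channel")

test_that("Debye length matches the closed form and its scalings", {
  lam <- debye_length(p_default)
  expect_equal(round(lam, 2), 0.79)
  # lambda ~ c^(-1/2): quadrupling c halves it
  lam4 <- debye_length(channel_params(c = 0.6))
  expect_equal(lam4, lam / 2)
  expect_equal(round(lam4, 2), 0.39)
  # T/c invariance
  expect_equal(debye_length(channel_params(T = 1200, c = 0.6)), lam)
})

test_that("ion count follows L / (2 lambda_D) with both rounding modes", {
  expect_equal(round(ion_count(p_default, rounding = "printed"), 2), 10.89)
  expect_equal(ion_count(p_default, lambda_D = 8.6, rounding = "none"), 1)
  # unrounded division is slightly different: sensitivity to the
  # 2-decimal intermediate
  expect_equal(round(ion_count(p_default, lambda_D = 0.7874,
                               rounding = "none"), 2), 10.92)
})

test_that("potential tilt adds the linear electrical term in kJ/mol", {
  W <- flat_profile(n = 173)
  U <- tilt_potential(W, 100, p_default)
  expect_equal(U$W[1], 9.64853321233, tolerance = 1e-9)
  expect_equal(U$W[nrow(U)], 0)
  expect_equal(diff(U$W), rep(diff(U$W)[1], nrow(U) - 1))
  # dV = 0 is the identity
  expect_identical(tilt_potential(W, 0, p_default), W)
  # subtracting the linear term recovers W on the same grid
  lin <- emV_to_kJmol(p_default$q * 100) * (p_default$L - U$z) / p_default$L
  expect_equal(U$W - lin, W$W)
  expect_error(tilt_potential(flat_profile(L = 8.6), 10, p_default),
               "channel length")
})

test_that("MFPT reproduces closed forms for flat and linearly tilted profiles", {
  D_nm <- 1.957
  tau_flat <- mfpt(flat_profile(), p_default)
  expect_equal(tau_flat, 17.2^2 / (2 * D_nm), tolerance = 1e-5)
  # linear downhill tilt with beta*q*dV = 1:
  # tau = (L^2/D) * [1 - (1 - e^-1)] = e^-1 L^2 / D
  kBT <- 8.31446261815324e-3 * 300
  dv1 <- kBT / emV_to_kJmol(1)          # mV giving beta q dV = 1
  U <- tilt_potential(flat_profile(n = 4097), dv1, p_default)
  expect_equal(mfpt(U, p_default, "l_to_r"),
               exp(-1) * 17.2^2 / D_nm, tolerance = 1e-5)
  # cross-check the same tilt against naive O(n^2) quadrature
  u_fun <- function(z) emV_to_kJmol(dv1) * (17.2 - z) / 17.2
  expect_equal(mfpt(U, p_default, "l_to_r"),
               oracle_mfpt_quad(u_fun, 17.2, D_nm), tolerance = 1e-4)
  expect_equal(mfpt(U, p_default, "r_to_l"),
               oracle_mfpt_quad(u_fun, 17.2, D_nm, direction = "r_to_l"),
               tolerance = 1e-4)
})

test_that("MFPT is gauge invariant and survives 100+ kJ/mol barriers", {
  z <- seq(0, 17.2, length.out = 513)
  w <- 120 * exp(-0.5 * ((z - 8.6) / 1.5)^2)
  U1 <- pmf_profile(z, w, tag = "full_channel")
  U2 <- pmf_profile(z, w + 500, tag = "full_channel")
  t1 <- mfpt(U1, p_default); t2 <- mfpt(U2, p_default)
  expect_true(is.finite(t1) && t1 > 0)
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("flat-profile conductance matches 4 q^2 D / (3 kBT L^2) within 1%", {
  r <- compute_conductance(flat_profile(), p_default)
  expect_equal(r$gamma0, oracle_flat_gamma0(), tolerance = 0.01)
  expect_lt(abs(r$intercept), 1e-10)
  # I(0) = 0: interpolate the fitted line at the origin
  expect_lt(abs(r$intercept), 0.01 * max(abs(r$I)))
})

test_that("currents are odd in dV for a symmetric profile", {
  z <- seq(0, 17.2, length.out = 513)
  W <- pmf_profile(z, 15 * exp(-0.5 * ((z - 8.6) / 1.2)^2),
                   tag = "full_channel")
  r <- compute_conductance(W, p_default)
  expect_equal(r$I, -rev(r$I), tolerance = 1e-9)
  # kappa_lr(dV) = kappa_rl(-dV) for the z-symmetric profile
  expect_equal(r$kappa_forward, rev(r$kappa_reverse), tolerance = 1e-9)
})

test_that("conductance is gauge invariant and decreases as a barrier grows", {
  z <- seq(0, 17.2, length.out = 513)
  mk <- function(h, off = 0)
    pmf_profile(z, h * exp(-0.5 * ((z - 8.6) / 1)^2) + off,
                tag = "full_channel")
  g0 <- compute_conductance(mk(12), p_default)$gamma0
  g0s <- compute_conductance(mk(12, off = 25), p_default)$gamma0
  expect_equal(g0s, g0, tolerance = 1e-9)
  gs <- sapply(c(0, 5, 10, 20, 30), function(h)
    compute_conductance(mk(h), p_default)$gamma0)
  expect_true(all(diff(gs) < 0))
  expect_true(all(gs > 0))
})

test_that("gamma0 is grid-converged at the default resolution", {
  mk <- function(n) {
    z <- seq(0, 17.2, length.out = n)
    pmf_profile(z, 20 * exp(-0.5 * ((z - 8.6) / 1)^2), tag = "full_channel")
  }
  g512 <- compute_conductance(mk(513), p_default)$gamma0
  g1024 <- compute_conductance(mk(1025), p_default)$gamma0
  expect_lt(abs(g1024 - g512) / g512, 0.005)
})

test_that("multi-ion correction scales gamma0 by the ion count", {
  ni <- ion_count(p_default, rounding = "printed")
  expect_equal(round(multi_ion_correction(9.64, ni)), 105)
  expect_equal(round(multi_ion_correction(0.92, ni)), 10)
  expect_equal(multi_ion_correction(0, ni), 0)
  # conductance ratios are unchanged by the correction: N_I cancels
  expect_equal(multi_ion_correction(0.92, ni) / multi_ion_correction(9.64, ni),
               0.92 / 9.64)
  expect_equal(round(100 * 0.92 / 9.64, 1), 9.5)
})

test_that("unit conversions round-trip", {
  expect_equal(emV_to_kJmol(1), 0.0964853, tolerance = 1e-6)
  expect_equal(m2s_to_nm2ns(1.957e-9), 1.957)
  expect_equal(per_ns_to_per_s(1) * 1e-9, 1)
  expect_equal(S_to_pS(1e-12), 1)
})
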