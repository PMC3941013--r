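# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force geometry, exhaustive rank
# enumeration, and naive O(n^2) quadrature.

# Eccentricity and angles of a hexagon by direct enumeration of the three
# opposite-vertex pairs and explicit edge-vector trigonometry (2-D input).
oracle_hexagon <- function(v) {
  d <- sapply(1:3, function(i) sqrt(sum((v[i, ] - v[i + 3, ])^2)))
  ang <- sapply(1:6, function(i) {
    a <- v[if (i == 1) 6 else i - 1, ] - v[i, ]
    b <- v[if (i == 6) 1 else i + 1, ] - v[i, ]
    acos(sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))) * 180 / pi
  })
  list(E = max(d) / min(d), D_max = max(d), d_min = min(d), angles = ang)
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# C(n1+n2, n1) group assignments of the pooled sample (no ties assumed).
oracle_mwu_exact <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pool), n1)
  u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(idx, 2, function(i)
    sum(rank(pool)[i]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Mean first passage time by naive nested quadrature (O(n^2) double
# trapezoid on an independent fine grid), for a profile given as a
# function u_fun (kJ/mol) on [0, L].
oracle_mfpt_quad <- function(u_fun, L, D_nm2ns, T = 300, n = 2001,
                             direction = "l_to_r") {
  beta <- 1 / (8.31446261815324e-3 * T)
  z <- seq(0, L, length.out = n)
  u <- u_fun(z)
  em <- exp(-beta * u); ep <- exp(beta * u)
  h <- z[2] - z[1]
  trap <- function(y) if (length(y) < 2) 0 else h * (sum(y) - (y[1] + y[length(y)]) / 2)
  if (direction == "l_to_r") {
    outer_vals <- sapply(seq_len(n), function(i) ep[i] * trap(em[1:i]))
  } else {
    outer_vals <- sapply(seq_len(n), function(i) ep[i] * trap(em[i:n]))
  }
  trap(outer_vals) / D_nm2ns
}

# Analytic closed form: small-signal unitary conductance of a flat
# profile, 4 q^2 D / (3 kB T L^2), in pS (q in units of e, D in m^2/s,
# L in nm).
oracle_flat_gamma0 <- function(q = 1, D = 1.957e-9, T = 300, L = 17.2) {
  e <- 1.602176634e-19; kB <- 1.380649e-23
  4 * (q * e)^2 * D / (3 * kB * T * (L * 1e-9)^2) * 1e12
}
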