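## From steered-pulling force logs to free-energy profiles: window-average
## the spring force, integrate the mean force along z (the work profile is
## the PMF), and reflect a hemichannel profile into a full-channel one.

#' Steered-pulling log
#'
#' Container for a constant-velocity steered-pulling record: time, trap
#' position, ion position and spring force, together with the spring
#' constant and pull velocity. When all three series are present the
#' spring force must equal `k * (z_trap - z_ion)` up to numeric tolerance.
#'
#' @param t time (ns), sorted increasing.
#' @param z_trap trap (spring end) position (nm).
#' @param z_ion ion position (nm); may be `NULL` if only forces were kept.
#' @param F_spring spring force (kJ mol^-1 nm^-1).
#' @param k spring constant (kJ mol^-1 nm^-2).
#' @param v trap velocity (nm/ns).
#' @return An object of class `smd_log` (a data frame with attributes).
#' @export
smd_log <- function(t, z_trap, z_ion = NULL, F_spring, k, v) {
  stopifnot(length(t) == length(z_trap), length(t) == length(F_spring),
            !is.unsorted(t), k > 0, v >= 0)
  if (!is.null(z_ion)) {
    stopifnot(length(z_ion) == length(t))
    resid <- max(abs(F_spring - k * (z_trap - z_ion)))
    if (resid > 1e-6 * max(1, k))
      stop("F_spring inconsistent with k * (z_trap - z_ion); max residual ",
           format(resid))
  }
  df <- data.frame(t = t, z_trap = z_trap, F_spring = F_spring)
  if (!is.null(z_ion)) df$z_ion <- z_ion
  structure(df, k = k, v = v, class = c("smd_log", "data.frame"))
}

#' Window-average the spring force of a steered-pulling log
#'
#' Partitions the log into consecutive windows of fixed duration and
#' returns one (z, F) pair per complete window: the mean trap position and
#' the mean spring force. An incomplete trailing window is dropped.
#'
#' @param log an [smd_log()].
#' @param window window duration (ns); must cover at least two samples and
#'   not exceed the log span.
#' @param bin_on `"trap"` (default) bins on the controlled trap position;
#'   `"ion"` uses the mean ion position instead.
#' @return Data frame with columns `z` (nm) and `F` (kJ mol^-1 nm^-1).
#' @export
window_average_force <- function(log, window, bin_on = c("trap", "ion")) {
  stopifnot(inherits(log, "smd_log"), nrow(log) > 0, window > 0)
  bin_on <- match.arg(bin_on)
  span <- log$t[nrow(log)] - log$t[1]
  if (window > span) stop("window (", window, " ns) exceeds log span (",
                          format(span), " ns)")
  idx <- floor((log$t - log$t[1]) / window)
  if (max(tabulate(idx + 1L)) < 2) stop("window covers fewer than 2 samples")
  ## complete windows = all but possibly the trailing partial one
  n_win <- floor(span / window + 1e-9)
  keep <- idx < n_win
  idx <- idx[keep] + 1L
  zsrc <- if (bin_on == "trap") log$z_trap[keep] else log$z_ion[keep]
  if (is.null(zsrc)) stop("log has no ion positions to bin on")
  z <- as.numeric(tapply(zsrc, idx, mean))
  f <- as.numeric(tapply(log$F_spring[keep], idx, mean))
  data.frame(z = z, F = f)
}

#' Free-energy profile along the pore axis
#'
#' @param z positions (nm), strictly increasing.
#' @param W free energy (kJ/mol), finite.
#' @param tag `"hemichannel"`, `"full_channel"` or `"tilted"`; hemichannel
#'   profiles are anchored at `W(z[1]) = 0`.
#' @return An object of class `pmf_profile` (a data frame with a `tag`
#'   attribute).
#' @export
pmf_profile <- function(z, W, tag = c("hemichannel", "full_channel", "tilted")) {
  tag <- match.arg(tag)
  stopifnot(length(z) == length(W), length(z) >= 2, all(is.finite(z)),
            all(is.finite(W)), all(diff(z) > 0))
  if (tag == "hemichannel" && abs(W[1]) > 1e-9)
    stop("hemichannel profile must be anchored at W(z_min) = 0")
  structure(data.frame(z = z, W = W), tag = tag,
            class = c("pmf_profile", "data.frame"))
}

#' Integrate a mean-force table into a PMF
#'
#' The work profile W(z) is the cumulative line integral of the mean force
#' along the pulling axis, evaluated by the trapezoid rule and anchored at
#' `W(z_min) = 0`.
#'
#' @param force_table data frame with columns `z` (strictly increasing)
#'   and `F`.
#' @param friction_correction optional constant force (kJ mol^-1 nm^-1) to
#'   subtract before integrating, e.g. the Stokes drag `kBT/D * v` of the
#'   steering itself. Default 0 (no correction).
#' @return A [pmf_profile()] tagged `hemichannel`.
#' @export
integrate_pmf <- function(force_table, friction_correction = 0) {
  stopifnot(is.data.frame(force_table), all(c("z", "F") %in% names(force_table)))
  z <- force_table$z; f <- force_table$F - friction_correction
  if (length(z) < 2) stop("need at least 2 force points to integrate")
  if (any(diff(z) <= 0)) stop("z must be strictly increasing")
  w <- c(0, cumsum(diff(z) * (utils::head(f, -1) + utils::tail(f, -1)) / 2))
  pmf_profile(z, w, tag = "hemichannel")
}

#' Differentiate a PMF back into a mean-force table
#'
#' Central differences in the interior, one-sided at the ends; the inverse
#' (up to trapezoid error) of [integrate_pmf()].
#'
#' @param p a [pmf_profile()].
#' @return Data frame with columns `z`, `F`.
#' @export
differentiate_pmf <- function(p) {
  stopifnot(inherits(p, "pmf_profile"))
  z <- p$z; w <- p$W; n <- length(z)
  f <- numeric(n)
  f[1] <- (w[2] - w[1]) / (z[2] - z[1])
  f[n] <- (w[n] - w[n - 1]) / (z[n] - z[n - 1])
  if (n > 2) f[2:(n - 1)] <- (w[3:n] - w[1:(n - 2)]) / (z[3:n] - z[1:(n - 2)])
  data.frame(z = z, F = f)
}

#' Reflect a hemichannel PMF into a full-channel PMF
#'
#' Mirrors the profile about a vertical axis through `z_mirror` (the
#' extracellular end of the hemichannel): two hemichannels docked head to
#' head share that plane, so `W(z_mirror + d) = W(z_mirror - d)`. The
#' mirror point itself is not duplicated.
#'
#' @param p a [pmf_profile()].
#' @param z_mirror mirror coordinate (nm); must lie at the last grid point
#'   or at most one grid spacing beyond it (window-center grids end half a
#'   window short of the pulled range).
#' @return A [pmf_profile()] tagged `full_channel` spanning
#'   `[z_min, 2 * z_mirror - z_min]`.
#' @export
reflect_pmf <- function(p, z_mirror = NULL) {
  stopifnot(inherits(p, "pmf_profile"))
  z <- p$z; w <- p$W; n <- length(z)
  if (is.null(z_mirror)) z_mirror <- z[n]
  h <- stats::median(diff(z))
  if (z_mirror < z[n] - 1e-9 * h || z_mirror > z[n] + h * (1 + 1e-9))
    stop("z_mirror (", z_mirror, ") is not at or just beyond the last grid ",
         "point (", z[n], ")")
  if (abs(z_mirror - z[n]) <= 1e-9 * max(h, 1)) {
    z_out <- c(z, 2 * z_mirror - rev(z[-n]))   # mirror point not duplicated
    w_out <- c(w, rev(w[-n]))
  } else {
    z_out <- c(z, 2 * z_mirror - rev(z))
    w_out <- c(w, rev(w))
  }
  pmf_profile(z_out, w_out, tag = "full_channel")
}
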