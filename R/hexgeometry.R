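## Departure of a hexameric assembly from six-fold symmetry.
##
## A hexagon is built on the alpha carbons of the structurally equivalent
## residue in the six protomers. Its three main diagonals (opposite-vertex
## distances) give the eccentricity coefficient E = D_max / d_min, and the
## six interior angles track shape fluctuations over time. Conditions are
## compared with the Mann-Whitney U test.

#' Per-frame alpha-carbon coordinates of a 6-protomer assembly
#'
#' @param coords numeric array `[frame, protomer, residue, xyz]` in nm;
#'   exactly 6 protomers, ordered by adjacency around the pore.
#' @param residues integer residue ids (third dimension labels).
#' @param time optional frame times (ns).
#' @return An object of class `hex_frame_series`.
#' @export
hex_frame_series <- function(coords, residues, time = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 4, dim(coords)[2] == 6,
            dim(coords)[4] == 3, dim(coords)[3] == length(residues))
  if (!is.null(time)) stopifnot(length(time) == dim(coords)[1])
  structure(list(coords = coords, residues = as.integer(residues),
                 time = time),
            class = "hex_frame_series")
}

#' @export
print.hex_frame_series <- function(x, ...) {
  cat("hex_frame_series:", dim(x$coords)[1], "frames, 6 protomers,",
      length(x$residues), "residues (",
      paste(range(x$residues), collapse = "-"), ")\n")
  invisible(x)
}

## 2-D vertex coordinates in the least-squares plane, order preserved.
project_hexagon <- function(v) {
  if (ncol(v) == 2) return(v)
  ctr <- colMeans(v)
  s <- svd(sweep(v, 2, ctr))
  sweep(v, 2, ctr) %*% s$v[, 1:2]
}

#' Eccentricity and interior angles of a hexagon
#'
#' The vertices are projected onto their least-squares plane (a no-op for
#' planar input). The three diameters are the opposite-vertex distances
#' (1-4, 2-5, 3-6); `E = D_max / d_min`. Interior angles at each vertex
#' are computed from the edge vectors to its two neighbours, in degrees.
#'
#' @param vertices 6 x 3 (or 6 x 2) numeric matrix, vertices in cyclic
#'   order.
#' @return List with `D_max`, `d_min`, `E`, `angles` (length 6, degrees)
#'   and `convex` (logical).
#' @export
hexagon_metrics <- function(vertices) {
  v <- as.matrix(vertices)
  stopifnot(nrow(v) == 6, ncol(v) %in% c(2, 3), all(is.finite(v)))
  edge_len <- sqrt(rowSums((v[c(2:6, 1), ] - v)^2))
  if (any(edge_len < 1e-12)) stop("coincident adjacent vertices")
  p <- project_hexagon(v)
  diam <- sqrt(rowSums((p[1:3, ] - p[4:6, ])^2))
  d_min <- min(diam)
  if (d_min < 1e-12) stop("degenerate hexagon: a main diagonal has zero length")
  ang <- cross <- numeric(6)
  for (i in 1:6) {
    u <- p[ifelse(i == 1, 6, i - 1), ] - p[i, ]
    w <- p[ifelse(i == 6, 1, i + 1), ] - p[i, ]
    ang[i] <- acos(pmin(1, pmax(-1,
      sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
    cross[i] <- u[1] * w[2] - u[2] * w[1]
  }
  list(D_max = max(diam), d_min = d_min, E = max(diam) / d_min,
       angles = ang, convex = all(cross > 0) || all(cross < 0))
}

#' Select n equally spaced frames from the last part of a trajectory
#'
#' @param traj a [hex_frame_series()].
#' @param last_ns window at the end of the trajectory (ns); requires frame
#'   times. `NULL` uses the whole trajectory.
#' @param n number of frames to keep (`NULL` = all in the window).
#' @return Integer frame indices.
#' @export
frames_last <- function(traj, last_ns = NULL, n = NULL) {
  stopifnot(inherits(traj, "hex_frame_series"))
  nf <- dim(traj$coords)[1]
  idx <- seq_len(nf)
  if (!is.null(last_ns)) {
    if (is.null(traj$time)) stop("trajectory has no frame times")
    idx <- which(traj$time >= max(traj$time) - last_ns)
  }
  if (!is.null(n)) {
    if (n > length(idx)) stop("requested ", n, " frames but only ",
                              length(idx), " available in the window")
    idx <- idx[unique(round(seq(1, length(idx), length.out = n)))]
  }
  idx
}

#' Eccentricity across residues and frames
#'
#' Computes one E per (residue, frame) pair and summarizes with a mean and
#' standard error. Default aggregation averages over residues within each
#' frame first and takes the s.e.m. over the frame means (`n` = number of
#' frames); `"pooled"` treats every (residue, frame) value as one
#' observation.
#'
#' @param traj a [hex_frame_series()].
#' @param residues residue ids to use (default: all in the trajectory).
#' @param frames frame indices (default: all; see [frames_last()]).
#' @param aggregate `"per_frame"` or `"pooled"`.
#' @return List with `E` (frames x residues matrix), `values` (the sample
#'   the summary is computed from), `mean`, `sem`, `n`, `aggregate`.
#' @export
eccentricity_series <- function(traj, residues = traj$residues, frames = NULL,
                                aggregate = c("per_frame", "pooled")) {
  stopifnot(inherits(traj, "hex_frame_series"))
  aggregate <- match.arg(aggregate)
  if (is.null(frames)) frames <- seq_len(dim(traj$coords)[1])
  if (length(frames) == 0) stop("empty frame selection")
  ri <- match(residues, traj$residues)
  if (anyNA(ri)) stop("residue(s) ", paste(residues[is.na(ri)], collapse = ", "),
                      " not present in the trajectory")
  E <- matrix(NA_real_, length(frames), length(ri),
              dimnames = list(NULL, residues))
  for (fi in seq_along(frames)) for (j in seq_along(ri))
    E[fi, j] <- hexagon_metrics(traj$coords[frames[fi], , ri[j], ])$E
  vals <- if (aggregate == "per_frame") rowMeans(E) else as.numeric(E)
  list(E = E, values = vals, mean = mean(vals),
       sem = stats::sd(vals) / sqrt(length(vals)), n = length(vals),
       aggregate = aggregate)
}

#' Interior-angle time series at one residue
#'
#' @param traj a [hex_frame_series()].
#' @param residue residue id.
#' @param frames frame indices (default all).
#' @return Matrix (frames x 6) of interior angles in degrees; pool with
#'   `as.numeric()` for distribution-level comparisons.
#' @export
angle_series <- function(traj, residue, frames = NULL) {
  stopifnot(inherits(traj, "hex_frame_series"), length(residue) == 1)
  if (is.null(frames)) frames <- seq_len(dim(traj$coords)[1])
  ri <- match(residue, traj$residues)
  if (is.na(ri)) stop("residue ", residue, " not present in the trajectory")
  t(vapply(frames, function(f)
    hexagon_metrics(traj$coords[f, , ri, ])$angles, numeric(6)))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. The exact
#' null distribution is used for small samples without ties
#' (`n1 + n2 <= 12` under `mode = "auto"`); otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param a,b numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return List with `U` (statistic for sample `a`), `p` (two-sided),
#'   `n1`, `n2`, `method`.
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(a) > 0, length(b) > 0)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- switch(mode,
    auto = (length(a) + length(b) <= 12) && !ties,
    exact = TRUE,
    normal = FALSE)
  if (use_exact && ties)
    stop("exact Mann-Whitney p-value is not defined with ties; use mode = \"normal\"")
  res <- if (use_exact) {
    stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
  } else {
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  }
  list(U = unname(res$statistic), p = res$p.value,
       n1 = length(a), n2 = length(b),
       method = if (use_exact) "exact" else "normal_approx")
}
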