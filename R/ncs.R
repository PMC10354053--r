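#' Natural cubic spline configuration
#'
#' Defines the knot layout used for the longitudinal trajectory basis.
#' Defaults place two internal knots at the 33rd and 66th percentiles of the
#' observation times and boundary knots at 0.5 and 13 years, the follow-up
#' window of a 15-year relapse-onset MS cohort assessed from 6 months on.
#'
#' @param internal_knots Numeric vector of internal knot locations (years).
#' @param boundary_knots Length-2 numeric vector bracketing the internal knots.
#' @return An object of class `spline_config`.
#' @examples
#' spline_config(internal_knots = c(3, 7))
#' @export
spline_config <- function(internal_knots = c(3, 7), boundary_knots = c(0.5, 13)) {
  internal_knots <- sort(as.numeric(internal_knots))
  boundary_knots <- as.numeric(boundary_knots)
  if (length(boundary_knots) != 2L || diff(boundary_knots) <= 0)
    stop("boundary_knots must be two increasing values", call. = FALSE)
  knots <- c(boundary_knots[1L], internal_knots, boundary_knots[2L])
  if (is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing and bracketed by the boundary knots",
         call. = FALSE)
  structure(list(internal_knots = internal_knots,
                 boundary_knots = boundary_knots,
                 all_knots = knots),
            class = "spline_config")
}

#' Spline configuration from observed times
#'
#' Places internal knots at the 33rd and 66th percentiles of the pooled
#' observation times; the knots are frozen into the returned object so that
#' later prediction does not depend on the data at hand.
#'
#' @param times Numeric vector of observation times (years).
#' @param boundary_knots Boundary knots (years); defaults to `c(0.5, 13)`.
#' @return A `spline_config`.
#' @export
spline_config_from_times <- function(times, boundary_knots = c(0.5, 13)) {
  qs <- stats::quantile(times, probs = c(1, 2) / 3, names = FALSE, type = 7)
  # keep internal knots strictly inside the boundary
  eps <- 1e-6 * diff(range(boundary_knots))
  qs <- pmin(pmax(qs, boundary_knots[1L] + eps), boundary_knots[2L] - eps)
  if (diff(qs) <= 0) qs[2L] <- qs[1L] + eps
  spline_config(internal_knots = qs, boundary_knots = boundary_knots)
}

# Truncated-power representation of the natural cubic spline family:
# with knots xi_1 < ... < xi_K (boundary + internal), the K-1 basis functions
# (no intercept) are N_1(x) = x and N_{k+1}(x) = d_k(x) - d_{K-1}(x) for
# k = 1..K-2, where d_k(x) = [(x-xi_k)_+^3 - (x-xi_K)_+^3] / (xi_K - xi_k).
# Linear beyond both boundary knots, C2 everywhere; derivatives and running
# integrals are available in closed form, which predict_trajectory and the
# cumulative-effects association rely on.
tp3 <- function(x, k, deriv) {
  u <- pmax(x - k, 0)
  switch(as.character(deriv),
         "0"  = u^3,
         "1"  = 3 * u^2,
         "2"  = 6 * u,
         "-1" = u^4 / 4, # antiderivative vanishing at x = k (knots >= 0 assumed)
         stop("unsupported derivative order", call. = FALSE))
}

#' Natural cubic spline basis
#'
#' Evaluates the natural cubic spline basis (linear beyond the boundary
#' knots, continuous second derivative) without an intercept column. The
#' basis dimension is `length(internal_knots) + 1`. `deriv = 1` gives the
#' exact first-derivative basis, `deriv = 2` the second derivative, and
#' `deriv = -1` the running integral from 0 (all knots must be non-negative
#' for the latter).
#'
#' @param times Numeric vector of evaluation times.
#' @param spline A [spline_config()].
#' @param deriv Derivative order: 0 (values), 1, 2, or -1 (integral from 0).
#' @return Matrix with `length(times)` rows and `#internal knots + 1` columns.
#' @examples
#' B <- ncs_basis(seq(1, 12, by = 0.5), spline_config(c(3, 7)))
#' dim(B)
#' @export
ncs_basis <- function(times, spline = spline_config(), deriv = 0) {
  if (!inherits(spline, "spline_config")) stop("spline must be a spline_config")
  if (any(!is.finite(times))) stop("times must be finite", call. = FALSE)
  kn <- spline$all_knots
  K <- length(kn)
  if (deriv == -1 && any(kn < 0))
    stop("integral basis requires non-negative knots", call. = FALSE)
  d_fun <- function(k_idx) {
    (tp3(times, kn[k_idx], deriv) - tp3(times, kn[K], deriv)) / (kn[K] - kn[k_idx])
  }
  lin <- switch(as.character(deriv),
                "0" = times, "1" = rep(1, length(times)),
                "2" = rep(0, length(times)), "-1" = times^2 / 2)
  out <- matrix(0, length(times), K - 1L)
  out[, 1L] <- lin
  if (K > 2L) {
    dlast <- d_fun(K - 1L)
    for (k in seq_len(K - 2L)) out[, k + 1L] <- d_fun(k) - dlast
  }
  colnames(out) <- paste0("ncs", seq_len(K - 1L))
  out
}

# Design matrix with intercept, as used by the trajectory model: [1, N(t)].
# deriv > 0 zeroes the intercept column; deriv = -1 integrates it to t.
ncs_design <- function(times, spline, deriv = 0) {
  icol <- switch(as.character(deriv),
                 "0" = rep(1, length(times)),
                 "1" = , "2" = rep(0, length(times)),
                 "-1" = times)
  cbind(`(Intercept)` = icol, ncs_basis(times, spline, deriv = deriv))
}

#' Cubic B-spline basis on an equidistant knot grid
#'
#' Basis used for the penalized P-spline baseline log-hazard and for
#' time-varying association coefficients. Knots are equally spaced over
#' `range` with the usual boundary-knot replication.
#'
#' @param times Evaluation times.
#' @param n_basis Number of basis functions (>= 4).
#' @param range Support interval `c(lo, hi)`.
#' @return `length(times)` x `n_basis` matrix of basis values.
#' @export
bspline_basis <- function(times, n_basis = 12, range = c(0, 15)) {
  if (n_basis < 4) stop("n_basis must be at least 4 for a cubic basis", call. = FALSE)
  if (any(times < range[1L] - 1e-12 | times > range[2L] + 1e-12))
    stop("time outside the basis support", call. = FALSE)
  times <- pmin(pmax(times, range[1L]), range[2L])
  degree <- 3L
  n_inner <- n_basis - degree - 1L
  inner <- if (n_inner > 0)
    seq(range[1L], range[2L], length.out = n_inner + 2L)[-c(1L, n_inner + 2L)]
  else numeric(0)
  knots <- c(rep(range[1L], degree + 1L), inner, rep(range[2L], degree + 1L))
  # right-closed at the upper boundary
  x <- ifelse(times >= range[2L], range[2L] - 1e-9 * diff(range), times)
  B <- .bspline_eval(x, knots, degree)
  colnames(B) <- paste0("bs", seq_len(ncol(B)))
  B
}

# Cox-de Boor recursion, vectorised over x.
.bspline_eval <- function(x, knots, degree) {
  n_basis <- length(knots) - degree - 1L
  B <- matrix(0, length(x), n_basis + degree)
  for (j in seq_len(n_basis + degree)) {
    B[, j] <- as.numeric(x >= knots[j] & x < knots[j + 1L])
  }
  for (d in seq_len(degree)) {
    for (j in seq_len(n_basis + degree - d)) {
      den1 <- knots[j + d] - knots[j]
      den2 <- knots[j + d + 1L] - knots[j + 1L]
      t1 <- if (den1 > 0) (x - knots[j]) / den1 * B[, j] else 0
      t2 <- if (den2 > 0) (knots[j + d + 1L] - x) / den2 * B[, j + 1L] else 0
      B[, j] <- t1 + t2
    }
  }
  B[, seq_len(n_basis), drop = FALSE]
}

# Second-order difference penalty matrix t(D2) %*% D2 for a P-spline.
pspline_penalty <- function(n_basis, order = 2L) {
  D <- diff(diag(n_basis), differences = order)
  crossprod(D)
}
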