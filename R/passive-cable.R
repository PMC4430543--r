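#' Green's function of the fractional passive cable
#'
#' Impulse response of the normalized fractional cable equation
#' \deqn{\partial^\alpha u/\partial t^\alpha = \partial^2 u/\partial x^2 - u + I(x,t)}
#' (x in space constants \eqn{\lambda}, t in time constants \eqn{\tau}).
#' Fourier transforming in space reduces each wavenumber to a linear
#' fractional relaxation whose solution is exact in terms of the
#' Mittag-Leffler function,
#' \eqn{\hat G(k,t) = t^{\alpha-1} E_{\alpha,\alpha}(-(1+k^2)t^\alpha)},
#' and the spatial inverse transform is evaluated by quadrature:
#' \deqn{G(x,t) = \frac{1}{\pi}\int_0^\infty \cos(kx)\, t^{\alpha-1}
#'   E_{\alpha,\alpha}(-(1+k^2)t^\alpha)\, dk.}
#' For \eqn{\alpha = 1} this reproduces the classical cable kernel
#' \eqn{e^{-t-x^2/(4t)}/\sqrt{4\pi t}}.
#'
#' @param alpha order in (0, 1].
#' @param x_grid positions (units of lambda).
#' @param t_grid times (units of tau), all > 0.
#' @param k_max,n_k wavenumber cutoff and number of quadrature nodes.
#' @return an object of class `"cable_green"`: `x_grid`, `t_grid`, and
#'   matrix `G` (rows = x, columns = t).
#' @export
cable_green <- function(alpha, x_grid, t_grid, k_max = 60, n_k = 600L) {
  check_alpha(alpha)
  stopifnot(all(t_grid > 0))
  gq <- gauss_legendre_interval(0, k_max, n_k)
  G <- matrix(NA_real_, length(x_grid), length(t_grid))
  for (jt in seq_along(t_grid)) {
    tt <- t_grid[jt]
    ml <- mittag_leffler(alpha, alpha, -(1 + gq$x^2) * tt^alpha)
    f <- tt^(alpha - 1) * ml
    for (ix in seq_along(x_grid))
      G[ix, jt] <- sum(gq$w * cos(gq$x * x_grid[ix]) * f) / pi
  }
  structure(list(alpha = alpha, x_grid = x_grid, t_grid = t_grid, G = G),
            class = "cable_green")
}

# Gauss-Legendre rule mapped to [a, b], assembled from panels of 16 nodes.
gauss_legendre_interval <- function(a, b, n) {
  base <- gauss_legendre(16L)
  n_panels <- max(1L, ceiling(n / 16L))
  edges <- seq(a, b, length.out = n_panels + 1L)
  x <- c(); w <- c()
  for (i in seq_len(n_panels)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    x <- c(x, (lo + hi) / 2 + (hi - lo) / 2 * base$x)
    w <- c(w, (hi - lo) / 2 * base$w)
  }
  list(x = x, w = w)
}

#' Sub-threshold step response along the passive cable
#'
#' Voltage response (normalized units: x in lambda, t in tau, steady state
#' at the origin \eqn{= 1/2} in units of \eqn{R_m I_m/\lambda}) to a step
#' current applied at the origin, \eqn{I(x,t) = I_m u(t)\delta(x)}.  In the
#' wavenumber domain the response is
#' \eqn{t^\alpha E_{\alpha,\alpha+1}(-(1+k^2)t^\alpha)}; the inversion
#' subtracts the analytically known steady-state integrand
#' \eqn{1/(1+k^2)} so the quadrature only handles a rapidly decaying
#' remainder:
#' \deqn{V(x,t) = \frac{e^{-|x|}}{2} + \frac{1}{\pi}\int_0^\infty \cos(kx)
#'  \left[t^\alpha E_{\alpha,\alpha+1}(-(1+k^2)t^\alpha) - \frac{1}{1+k^2}\right] dk.}
#' The steady state \eqn{V_{ss}(x) = e^{-|x|}/2} is independent of
#' \eqn{\alpha}.
#'
#' @param x position (units of lambda), scalar.
#' @param t times (units of tau), vectorized, > 0.
#' @param alpha order in (0, 1].
#' @param k_max,n_k quadrature cutoff and nodes.
#' @return list with `V` (response), `V_ss` (local steady state), and
#'   `normalized` (= `V/V_ss`).
#' @export
cable_step_response <- function(x, t, alpha, k_max = 40, n_k = 480L) {
  check_alpha(alpha)
  stopifnot(length(x) == 1L, all(t > 0))
  gq <- gauss_legendre_interval(0, k_max, n_k)
  ck <- cos(gq$x * abs(x))
  Vss <- exp(-abs(x)) / 2
  V <- vapply(t, function(tt) {
    ml <- mittag_leffler(alpha, alpha + 1, -(1 + gq$x^2) * tt^alpha)
    integrand <- tt^alpha * ml - 1 / (1 + gq$x^2)
    Vss + sum(gq$w * ck * integrand) / pi
  }, numeric(1))
  list(V = V, V_ss = Vss, normalized = V / Vss)
}

#' Pseudo-velocity of sub-threshold propagation
#'
#' For a step current at the origin, the time at which the normalized
#' response \eqn{V(x,t)/V_{ss}(x)} first reaches 0.5 defines a position-time
#' locus; its least-squares slope over a near-field window (default
#' \eqn{x \in [0.05\lambda, 0.25\lambda]}) is the pseudo-velocity, in
#' \eqn{\lambda/\tau}.  For \eqn{\alpha=1} it is close to 2 and it
#' increases as \eqn{\alpha} decreases (the fractional response spreads
#' faster near the source).  The window matters: far from the source the
#' ordering reverses, because the sub-diffusive front position grows
#' sublinearly in time for \eqn{\alpha<1} (see the methods vignette).
#'
#' @param alpha order in (0, 1].
#' @param x_fit positions used for the fit (units of lambda).
#' @param t_bracket time bracket (units of tau) within which each
#'   half-crossing must lie.
#' @return list with `velocity` (lambda/tau), `x` and `t_cross`.
#' @export
pseudo_velocity <- function(alpha, x_fit = seq(0.05, 0.25, by = 0.025),
                            t_bracket = c(1e-6, 30)) {
  check_alpha(alpha)
  t_cross <- vapply(x_fit, function(xx) {
    f <- function(tt) cable_step_response(xx, tt, alpha)$normalized - 0.5
    flo <- f(t_bracket[1]); fhi <- f(t_bracket[2])
    if (flo * fhi > 0)
      stop(sprintf("half-crossing not bracketed on the time grid at x = %g", xx),
           call. = FALSE)
    stats::uniroot(f, t_bracket, tol = 1e-6)$root
  }, numeric(1))
  fit <- stats::lm.fit(cbind(1, t_cross), x_fit)
  list(velocity = unname(fit$coefficients[2]), x = x_fit, t_cross = t_cross)
}
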