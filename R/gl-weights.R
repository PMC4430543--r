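#' Grunwald-Letnikov memory weights
#'
#' Computes the weights \eqn{c_k^\alpha} of the explicit Grunwald-Letnikov
#' (GL) scheme for a fractional derivative of order `alpha`, using the stable
#' recursion \eqn{c_1 = \alpha}, \eqn{c_k = (1 - (1+\alpha)/k)\, c_{k-1}}.
#' The recursion is numerically identical (to round-off) to the closed-form
#' binomial expression
#' \eqn{c_k = (-1)^{k-1}\Gamma(\alpha+1)/(\Gamma(k+1)\Gamma(\alpha-k+1))},
#' which overflows in the gamma function for large `k` and is therefore only
#' used as a cross-check in the test suite.
#'
#' For \eqn{0<\alpha<1} the weights are strictly positive, strictly
#' decreasing, and sum to 1 (binomial theorem at \eqn{z=1}); their slow
#' power-law decay \eqn{c_k \sim \alpha k^{-(1+\alpha)}/\Gamma(1-\alpha)} is
#' what gives the fractional membrane its long capacitive memory.  For
#' \eqn{\alpha=1} the first weight is 1 and all others vanish: the scheme
#' collapses to forward Euler.
#'
#' @param alpha fractional order, in (0, 1].
#' @param n number of weights to generate (positive integer).
#' @return an object of class `"gl_weights"`: a list with elements `alpha`,
#'   `n`, and `weights` (numeric vector of length `n`, `weights[1] == alpha`).
#' @examples
#' w <- gl_weights(0.5, 5)
#' w$weights[1:2]   # 0.5, 0.125
#' @export
gl_weights <- function(alpha, n) {
  check_alpha(alpha)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  k <- seq_len(n)
  # c_k = c_{k-1} * (1 - (1+alpha)/k): cumulative product of the per-step ratios
  ratios <- 1 - (1 + alpha) / k
  ratios[1] <- alpha
  w <- cumprod(ratios)
  if (alpha == 1 && n > 1L) w[2:n] <- 0  # exact locality of the integer-order derivative
  structure(list(alpha = alpha, n = n, weights = w), class = "gl_weights")
}

#' @export
print.gl_weights <- function(x, ...) {
  cat(sprintf("Grunwald-Letnikov weights: alpha = %g, n = %d\n", x$alpha, x$n))
  cat(sprintf("  c_1..c_%d: ", min(x$n, 5L)))
  cat(signif(x$weights[seq_len(min(x$n, 5L))], 6), sep = ", ")
  if (x$n > 5L) cat(", ...")
  cat(sprintf("\n  partial sum: %.6f\n", sum(x$weights)))
  invisible(x)
}

#' Dropped tail mass of a truncated GL memory
#'
#' Upper bound on \eqn{\sum_{k>L} c_k^\alpha}, the total weight discarded by a
#' short-memory (truncated) policy keeping `L` terms.  Since the weights sum
#' to 1, the tail equals `1 - sum(weights[1:L])` exactly when the weights are
#' available; this helper computes it from the recursion without storing more
#' than `L` terms.
#'
#' @param alpha fractional order in (0, 1].
#' @param L number of retained terms.
#' @return the tail mass, a single number in [0, 1).
#' @export
gl_tail_mass <- function(alpha, L) {
  check_alpha(alpha)
  if (alpha == 1) return(0)
  w <- gl_weights(alpha, L)
  max(0, 1 - sum(w$weights))
}

#' Voltage memory trace
#'
#' The weighted sum of past membrane potentials, excluding the immediately
#' preceding sample:
#' \deqn{v_{mem}(t_{n+1}) = \sum_{k=1}^{n} c_{k+1}^\alpha\, v(t_{n-k}),\quad n \ge 1,}
#' with \eqn{v_{mem}(t_0) = v_{mem}(t_1) = 0}.  This isolates the contribution
#' of capacitive memory to the GL update: the immediate-past term
#' \eqn{c_1 v_n = \alpha v_n} is the part any local one-step method would have,
#' so what remains measures how strongly older history pulls on the present.
#'
#' @param v_history numeric vector of membrane potential samples
#'   \eqn{v(t_0), v(t_1), \ldots}
#' @param weights a [gl_weights] object with at least `length(v_history)`
#'   weights.
#' @return numeric vector of the same length as `v_history`; element `i`
#'   is \eqn{v_{mem}} at \eqn{t_{i-1}}.
#' @export
memory_trace <- function(v_history, weights) {
  stopifnot(inherits(weights, "gl_weights"))
  nv <- length(v_history)
  if (weights$n < nv)
    stop("need at least as many GL weights as history samples", call. = FALSE)
  out <- numeric(nv)
  if (nv <= 2L) return(out)
  w <- weights$weights
  # out[i] = v_mem(t_{i-1}); t_{n+1} corresponds to i = n + 2
  for (n in 1:(nv - 2L)) {
    k <- 1:n
    out[n + 2L] <- sum(w[k + 1L] * v_history[n - k + 1L])
  }
  out
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("'alpha' must be a single number in (0, 1]", call. = FALSE)
  invisible(alpha)
}
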