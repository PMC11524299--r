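#' Logistic growth mean function
#'
#' Evaluates the three-parameter logistic growth curve
#' \eqn{\mu(t) = a / (1 + b e^{-rt})}, the mean model used throughout the
#' functional-mapping machinery: \code{a} is the asymptotic trait value,
#' \code{b} sets the initial condition (\eqn{\mu(0) = a/(1+b)}), and \code{r}
#' is the relative growth rate.
#'
#' @param t numeric vector of ages; must be finite.
#' @param a asymptotic trait value, > 0.
#' @param b initial-condition shape parameter, > 0.
#' @param r relative growth rate (1/time units), > 0.
#' @return numeric vector of trait values, same length as \code{t}.
#' @examples
#' logistic_mean(0, a = 10, b = 9, r = 0.5)        # 1 = a/(1+b)
#' logistic_mean(log(9) / 0.5, a = 10, b = 9, r = 0.5)  # half-asymptote
#' @export
logistic_mean <- function(t, a, b, r) {
  if (any(!is.finite(t))) stop("ages 't' must be finite")
  stopifnot(a > 0, b > 0, r > 0)
  a / (1 + b * exp(-r * t))
}

#' SAD(1) residual covariance matrix
#'
#' Covariance of the first-order structured antedependence process
#' \eqn{e_t = \phi e_{t-1} + \epsilon_t}, \eqn{\epsilon_t \sim N(0, \nu^2)},
#' started at \eqn{e_0 = 0} at the first measurement age.  The lag index is
#' the position in the grid (ordinal), so unequal age spacing is handled
#' without a stationarity assumption:
#' \eqn{Var(e_t) = \nu^2 (1-\phi^{2t})/(1-\phi^2)} (\eqn{t\nu^2} at
#' \eqn{\phi = \pm 1}) and \eqn{Cov(e_t, e_s) = \phi^{|t-s|} Var(e_{\min(t,s)})}.
#'
#' @param times strictly increasing age grid (only its length matters for the
#'   covariance; ages label the rows).
#' @param phi antedependence parameter (any finite value; variance grows with
#'   the lag index when \eqn{|\phi| \ge 1}).
#' @param nu2 innovation variance, > 0.
#' @return a \code{T x T} symmetric positive-definite matrix.
#' @export
sad1_covariance <- function(times, phi, nu2) {
  T <- length(times)
  if (T < 1) stop("time grid must have length >= 1")
  if (!is.finite(phi)) stop("phi must be finite")
  if (!(nu2 > 0)) stop("innovation variance nu2 must be positive")
  tt <- seq_len(T)
  v <- if (abs(1 - phi^2) < 1e-12) tt * nu2 else nu2 * (1 - phi^(2 * tt)) / (1 - phi^2)
  S <- matrix(0, T, T)
  for (i in seq_len(T)) {
    for (j in seq_len(T)) {
      S[i, j] <- phi^(abs(i - j)) * v[min(i, j)]
    }
  }
  dimnames(S) <- list(times, times)
  S
}

#' Closed-form log-determinant and inverse of the SAD(1) covariance
#'
#' The antedependence factorization \eqn{\Sigma = L D L'} (with \eqn{L} unit
#' lower triangular carrying powers of \eqn{\phi} and \eqn{D = \nu^2 I})
#' gives \eqn{\log|\Sigma| = T \log \nu^2} and a tridiagonal inverse
#' \eqn{\Sigma^{-1} = (L^{-1})' D^{-1} L^{-1}} where \eqn{L^{-1}} is unit
#' lower bidiagonal with \eqn{-\phi} on the subdiagonal.  Cost is O(T).
#'
#' @inheritParams sad1_covariance
#' @return list with components \code{logdet} (scalar) and \code{inverse}
#'   (\code{T x T} tridiagonal matrix).
#' @export
sad1_logdet_inverse <- function(times, phi, nu2) {
  T <- length(times)
  if (T < 1) stop("time grid must have length >= 1")
  if (!(nu2 > 0)) stop("innovation variance nu2 must be positive")
  M <- matrix(0, T, T)
  d <- rep((1 + phi^2) / nu2, T)
  d[T] <- 1 / nu2
  diag(M) <- d
  if (T > 1) {
    idx <- seq_len(T - 1)
    M[cbind(idx, idx + 1)] <- -phi / nu2
    M[cbind(idx + 1, idx)] <- -phi / nu2
  }
  list(logdet = T * log(nu2), inverse = M)
}

#' Legendre orthogonal polynomial basis
#'
#' Values \eqn{(P_0(x), \ldots, P_K(x))} by the Bonnet recurrence
#' \eqn{(k+1) P_{k+1}(x) = (2k+1) x P_k(x) - k P_{k-1}(x)}.  The basis is
#' orthogonal on \eqn{[-1, 1]}; arguments on other scales should be mapped
#' with \code{\link{lop_map}} first.
#'
#' @param x numeric vector of evaluation points (nominally in \eqn{[-1,1]}).
#' @param order highest polynomial degree K, >= 0.
#' @return a \code{length(x) x (K+1)} matrix of basis values.
#' @export
lop_basis <- function(x, order) {
  stopifnot(order >= 0)
  B <- matrix(0, length(x), order + 1)
  B[, 1] <- 1
  if (order >= 1) B[, 2] <- x
  if (order >= 2) {
    for (k in 1:(order - 1)) {
      B[, k + 2] <- ((2 * k + 1) * x * B[, k + 1] - k * B[, k]) / (k + 1)
    }
  }
  B
}

#' Derivatives of the Legendre basis
#'
#' \eqn{P'_k(x)} via the recurrence \eqn{P'_k = P'_{k-2} + (2k-1) P_{k-1}},
#' returned on the same layout as \code{\link{lop_basis}}.  Combine with the
#' chain-rule factor \code{2/diff(range)} when the argument was mapped from a
#' raw scale.
#'
#' @inheritParams lop_basis
#' @return a \code{length(x) x (K+1)} matrix of derivative values.
#' @export
lop_basis_deriv <- function(x, order) {
  stopifnot(order >= 0)
  P <- lop_basis(x, order)
  D <- matrix(0, length(x), order + 1)
  if (order >= 1) D[, 2] <- 1
  if (order >= 2) {
    for (k in 2:order) {
      D[, k + 1] <- (if (k >= 2) D[, k - 1] else 0) + (2 * k - 1) * P[, k]
    }
  }
  D
}

#' Affine map onto the Legendre domain [-1, 1]
#'
#' @param t numeric vector.
#' @param range length-2 vector giving the pooled domain \code{(t_min, t_max)};
#'   a single shared range keeps polynomial coefficients comparable across
#'   markers.
#' @return \code{t} rescaled so that \code{range} maps to \code{c(-1, 1)}.
#' @export
lop_map <- function(t, range) {
  stopifnot(length(range) == 2)
  if (range[2] <= range[1]) stop("range must satisfy t_max > t_min")
  2 * (t - range[1]) / (range[2] - range[1]) - 1
}

# Design matrix of LOP values on a raw-scale grid.
lop_design <- function(t, order, range = base::range(t)) {
  lop_basis(lop_map(t, range), order)
}
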