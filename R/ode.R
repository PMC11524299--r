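#' Fourth-order Runge-Kutta solver
#'
#' Classic RK4 with fixed substeps between requested output times.  Used to
#' integrate the planted effect-dynamics systems of the synthetic-data
#' generator; the node-fitting objective uses an equivalent compiled kernel.
#'
#' @param f derivative function \code{f(t, y)} returning \code{dy/dt}
#'   (numeric vector, same length as \code{y}).
#' @param y0 initial state at \code{times[1]}.
#' @param times output times (strictly increasing).
#' @param nsub substeps between consecutive output times.
#' @return matrix \code{length(times) x length(y0)} of states.
#' @export
rk4 <- function(f, y0, times, nsub = 1L) {
  stopifnot(length(times) >= 2, all(diff(times) > 0), nsub >= 1)
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y <- as.numeric(y0)
  t <- times[1]
  for (i in 2:length(times)) {
    h <- (times[i] - times[i - 1]) / nsub
    for (s in seq_len(nsub)) {
      k1 <- f(t, y)
      k2 <- f(t + h / 2, y + h / 2 * k1)
      k3 <- f(t + h / 2, y + h / 2 * k2)
      k4 <- f(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
      if (any(!is.finite(y))) {
        out[i:nrow(out), ] <- NA_real_
        return(out)
      }
    }
    out[i, ] <- y
    t <- times[i]
  }
  out
}

# LOP smoothing fit of a single curve: coefficients, fitted values, analytic
# derivative and a cubic interpolant of the fitted curve.
lop_smooth <- function(y, grid, order = 5) {
  order <- min(order, length(grid) - 2)
  rng <- range(grid)
  B <- lop_design(grid, order, rng)
  coef <- qr.coef(qr(B), y)
  fitted <- as.numeric(B %*% coef)
  Dm <- lop_basis_deriv(lop_map(grid, rng), order)
  deriv <- as.numeric(Dm %*% coef) * 2 / diff(rng)
  list(coef = coef, fitted = fitted, deriv = deriv, order = order,
       grid = grid, fun = stats::splinefun(grid, fitted, method = "natural"))
}

#' Smoothed derivative of an effect curve
#'
#' Fits a Legendre-polynomial smoother to the curve and differentiates the
#' fit analytically (no raw finite differences), returning values on the
#' same grid.
#'
#' @param y curve values on \code{grid}.
#' @param grid age grid (length >= 5).
#' @param order LOP smoothing order (capped at \code{length(grid) - 2}).
#' @return numeric vector of derivative values on \code{grid}.
#' @export
estimate_derivatives <- function(y, grid, order = 5) {
  if (length(grid) < 5) stop("grid must have at least 5 points")
  lop_smooth(y, grid, order)$deriv
}

# Map a state value onto the Legendre domain of a node, clamping outside the
# (slightly padded) observed range so polynomial extrapolation stays tame.
state_map <- function(z, rng) {
  x <- lop_map(z, rng)
  pmin(pmax(x, -1), 1)
}

# Padded argument range for a node's Q-function.
arg_range <- function(z, pad = 0.1) {
  r <- range(z)
  w <- diff(r)
  if (w < 1e-10) w <- max(abs(r[1]), 1) * 1e-3
  c(r[1] - pad * w, r[2] + pad * w)
}

# Per-layer precomputation shared by regulator selection and node fitting:
# smoothed curves, derivatives and Q-function argument ranges.
ode_context <- function(curves, grid, smooth_order = 14) {
  curves <- unclass(as.matrix(curves))
  if (is.null(rownames(curves))) rownames(curves) <- paste0("s", seq_len(nrow(curves)))
  sm <- apply(curves, 1, lop_smooth, grid = grid, order = smooth_order,
              simplify = FALSE)
  list(curves = curves, grid = grid, ids = rownames(curves), sm = sm,
       ranges = lapply(sm, function(s) arg_range(s$fitted)))
}

# Gradient-matching design blocks for one target node: an unpenalised self
# block (orders 0..K_ind of the target's own smoothed state) and one
# penalised block per candidate regulator (orders 1..K_dep of its smoothed
# state; the constant is identifiable only once and lives in the self block).
ode_design <- function(target, ctx, K_ind, K_dep) {
  zs <- ctx$sm[[target]]$fitted
  blocks <- list(self = lop_basis(state_map(zs, ctx$ranges[[target]]), K_ind))
  for (sp in seq_along(ctx$sm)) {
    if (sp == target) next
    xp <- lop_basis(state_map(ctx$sm[[sp]]$fitted, ctx$ranges[[sp]]), K_dep)
    blocks[[paste0("reg", sp)]] <- xp[, -1, drop = FALSE]
  }
  blocks
}

# RK4 stage times for a grid with nsub substeps: step k occupies rows
# 2k, 2k+1, 2k+2 (0-based) -- start, midpoint, end -- with endpoints shared
# between adjacent steps.
stage_times <- function(grid, nsub) {
  out <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    h <- (grid[i + 1] - grid[i]) / nsub
    starts <- grid[i] + h * (seq_len(nsub) - 1)
    out <- c(out, as.numeric(rbind(starts, starts + h / 2)))
  }
  c(out, grid[length(grid)])
}

#' Fit one node's Lotka-Volterra effect-dynamics ODE
#'
#' Estimates the coefficients of
#' \eqn{dz_s/dt = Q_s(z_s; \Phi_s) + \sum_{s'} Q_{ss'}(z_{s'}(t); \Phi_{ss'})}
#' by nonlinear least squares: the ODE is solved by RK4 from the first
#' observed value, with regulator curves treated as known forcing functions
#' (cubic interpolants of their smoothed curves, evaluated once at all RK4
#' stage times), and the sum of squared deviations from the observed curve
#' is minimised by Nelder-Mead started from the gradient-matching regression
#' estimate.
#'
#' @inheritParams select_regulators
#' @param K_dep LOP order of the dependent component functions.
#' @param regulators integer indices of the selected regulators (possibly
#'   empty).
#' @param nsub RK4 substeps between grid ages.
#' @param maxit optimiser iteration cap.
#' @return object of class \code{ode_node}: coefficient blocks, fitted net
#'   curve, RMSE and the state mappings needed for decomposition.
#' @export
fit_node_ode <- function(target, regulators, curves,
                         grid = attr(curves, "grid"), K_ind = 3, K_dep = 3,
                         smooth_order = 14, nsub = 4L, maxit = 2000L,
                         context = NULL) {
  ctx <- if (is.null(context)) ode_context(curves, grid, smooth_order) else context
  if (is.character(target)) target <- match(target, ctx$ids)
  grid <- ctx$grid
  zobs <- ctx$curves[target, ]
  rng_t <- ctx$ranges[[target]]
  d <- length(regulators)
  p_self <- K_ind + 1
  hsteps <- diff(grid)
  st <- stage_times(grid, nsub)
  Fb <- NULL
  block_of <- integer(0)
  if (d > 0) {
    Fb <- do.call(cbind, lapply(seq_len(d), function(j) {
      sp <- regulators[j]
      vals <- ctx$sm[[sp]]$fun(st)
      lop_basis(state_map(vals, ctx$ranges[[sp]]), K_dep)[, -1, drop = FALSE]
    }))
    block_of <- rep(seq_len(d) - 1L, each = K_dep)
  }
  objective <- function(th) {
    ode_rk4_sse_cpp(th[seq_len(p_self)],
                    if (d > 0) th[-seq_len(p_self)] else numeric(0),
                    K_ind, rng_t[1], rng_t[2], zobs, hsteps, nsub, Fb)
  }
  # gradient-matching initialisation: full-order self block plus the linear
  # term of each regulator block (higher dependent orders start at zero --
  # the full-order joint regression is ill-conditioned and can scramble the
  # split between collinear regulators)
  dz <- ctx$sm[[target]]$deriv
  blocks <- ode_design(target, ctx, K_ind, K_dep)
  keep <- 1L + match(regulators, setdiff(seq_along(ctx$sm), target))
  X0 <- cbind(blocks[[1]],
              do.call(cbind, c(lapply(blocks[keep], function(b) b[, 1]),
                               list(matrix(0, length(dz), 0)))))
  th_lin <- as.numeric(qr.coef(qr(X0), dz))
  th_lin[!is.finite(th_lin)] <- 0
  npar <- p_self + d * K_dep
  th0 <- numeric(npar)
  th0[seq_len(p_self)] <- th_lin[seq_len(p_self)]
  if (d > 0) {
    th0[p_self + (seq_len(d) - 1) * K_dep + 1] <- th_lin[p_self + seq_len(d)]
  }
  opt <- stats::optim(th0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  th <- opt$par
  path <- ode_rk4_path_cpp(th[seq_len(p_self)],
                           if (d > 0) th[-seq_len(p_self)] else numeric(0),
                           K_ind, rng_t[1], rng_t[2], zobs[1], length(grid),
                           hsteps, nsub, Fb, block_of)
  structure(list(id = ctx$ids[target], target = target,
                 regulators = regulators,
                 regulator_ids = ctx$ids[regulators],
                 coef_self = th[seq_len(p_self)],
                 coef_dep = if (d > 0) matrix(th[-seq_len(p_self)], K_dep, d,
                                              dimnames = list(NULL, ctx$ids[regulators]))
                            else matrix(0, K_dep, 0),
                 dep_anchor = if (d > 0) vapply(seq_len(d), function(j) {
                   x0 <- state_map(0, ctx$ranges[[regulators[j]]])
                   cols <- p_self + (j - 1) * K_dep + seq_len(K_dep)
                   sum(lop_basis(x0, K_dep)[, -1] * th[cols])
                 }, numeric(1)) else numeric(0),
                 K_ind = K_ind, K_dep = K_dep,
                 grid = grid, obs = zobs, fitted = path$z,
                 rmse = sqrt(mean((path$z - zobs)^2)),
                 range = rng_t, Fb = Fb, block_of = block_of,
                 hsteps = hsteps, nsub = nsub,
                 convergence = opt$convergence),
            class = "ode_node")
}

#' @export
print.ode_node <- function(x, ...) {
  cat("ode_node", x$id, ": ", length(x$regulators), "regulator(s)",
      if (length(x$regulators)) paste0("(", paste(x$regulator_ids, collapse = ", "), ")"),
      " rmse =", format(x$rmse, digits = 4), "\n")
  invisible(x)
}

#' Decompose a fitted node into independent and dependent effect curves
#'
#' Integrates, along the fitted trajectory and with the same RK4 stages used
#' to solve it, \eqn{I_s(\tau) = z_s(\tau_1) + \int Q_s(z_s(u)) du} and
#' \eqn{D_{ss'}(\tau) = \int Q_{ss'}(z_{s'}(u)) du}, so that
#' \eqn{I_s + \sum_{s'} D_{ss'}} reproduces the fitted net curve to rounding
#' error (the conservation identity).
#'
#' @param node a fitted \code{\link{fit_node_ode}} object.
#' @return object of class \code{effect_decomposition} with the net
#'   (observed and fitted), independent and per-regulator dependent curves
#'   on the node's grid.
#' @export
decompose_node <- function(node) {
  d <- length(node$regulators)
  path <- ode_rk4_path_cpp(node$coef_self, as.numeric(node$coef_dep),
                           node$K_ind, node$range[1], node$range[2],
                           node$obs[1], length(node$grid), node$hsteps,
                           node$nsub, node$Fb, node$block_of)
  elapsed <- node$grid - node$grid[1]
  indep <- path$independent
  dep <- matrix(0, 0, length(node$grid))
  if (d > 0) {
    # constant-rate re-attribution: each dependent function is anchored so
    # that a regulator at zero raw effect exerts zero regulation; the
    # independent component absorbs the compensating constants (the split
    # of constants is otherwise non-identifiable)
    dep <- t(path$dependent) - node$dep_anchor %o% elapsed
    indep <- indep + sum(node$dep_anchor) * elapsed
    rownames(dep) <- node$regulator_ids
  }
  structure(list(id = node$id, grid = node$grid,
                 net_obs = node$obs, net_fitted = path$z,
                 independent = indep, dependent = dep,
                 regulator_ids = node$regulator_ids),
            class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, ...) {
  cons <- max(abs(x$independent + colSums(rbind(x$dependent, 0)) - x$net_fitted))
  cat("effect_decomposition", x$id, ":", nrow(x$dependent),
      "dependent curve(s); conservation residual", format(cons, digits = 3), "\n")
  invisible(x)
}

#' Fit the interaction system for one network layer
#'
#' For every node among a set of effect curves: select regulators by LASSO,
#' fit the node ODE by RK4 least squares and decompose it.
#'
#' @inheritParams select_regulators
#' @param K_dep LOP order of the dependent component functions in the ODE
#'   fit.
#' @param nsub,maxit passed to \code{\link{fit_node_ode}}.
#' @return object of class \code{layer_fit}: lists of \code{ode_node} fits
#'   and \code{effect_decomposition}s plus the grid.
#' @export
fit_layer <- function(curves, grid = attr(curves, "grid"), K_ind = 3,
                      K_dep = 3, K_sel = 1, d_max = 5, smooth_order = 14,
                      ebic_gamma = 2, nsub = 4L, maxit = 2000L) {
  ctx <- ode_context(curves, grid, smooth_order)
  m <- nrow(ctx$curves)
  fits <- decomps <- vector("list", m)
  for (s in seq_len(m)) {
    sel <- select_regulators(s, context = ctx, K_ind = K_ind, K_sel = K_sel,
                             d_max = d_max, ebic_gamma = ebic_gamma)
    fits[[s]] <- fit_node_ode(s, sel$regulators, context = ctx,
                              K_ind = K_ind, K_dep = K_dep, nsub = nsub,
                              maxit = maxit)
    decomps[[s]] <- decompose_node(fits[[s]])
  }
  names(fits) <- names(decomps) <- ctx$ids
  structure(list(fits = fits, decomps = decomps, grid = ctx$grid),
            class = "layer_fit")
}
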