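#' Functional clustering of effect curves by an EM mixture
#'
#' Fits a K-component multivariate-normal mixture to effect curves sharing a
#' common age grid.  Component mean curves are Legendre-polynomial (LOP)
#' expansions of order \code{Q}; the within-component residual covariance is
#' SAD(1)-structured with parameters shared across components.  Estimation is
#' by EM with k-means initialisation and multiple restarts; inside each
#' M-step the mean coefficients are updated by generalised least squares and
#' \code{(phi, nu2)} by their closed-form conditional maximisers (a
#' generalised EM step, so the log-likelihood is non-decreasing).
#'
#' @param curves numeric matrix, curves (rows) x grid ages (columns).
#' @param grid common age grid (defaults to the \code{grid} attribute of
#'   \code{curves} when present).
#' @param K number of mixture components.
#' @param Q LOP order of the component mean curves.
#' @param n_init number of k-means restarts (best likelihood kept).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return object of class \code{curve_mixture}: coefficients, mixing
#'   proportions, SAD parameters, responsibilities, hard assignments
#'   (maximum posterior, ties to the lowest component index), log-likelihood
#'   and BIC.
#' @export
fit_curve_mixture <- function(curves, grid = attr(curves, "grid"), K, Q = 4,
                              n_init = 5, max_iter = 200, tol = 1e-8) {
  curves <- unclass(as.matrix(curves))
  N <- nrow(curves); T <- ncol(curves)
  if (is.null(grid)) stop("no age grid supplied")
  stopifnot(length(grid) == T, K >= 1, Q >= 1)
  if (N < 2 * K) stop("need at least 2*K curves (have ", N, ", K = ", K, ")")
  B <- lop_design(grid, Q, range(grid))
  best <- NULL
  n_init <- if (K == 1) 1 else n_init
  for (init in seq_len(n_init)) {
    assign0 <- if (K == 1) rep(1L, N) else
      stats::kmeans(curves, K, nstart = 2, iter.max = 50)$cluster
    resp <- matrix(0, N, K)
    resp[cbind(seq_len(N), assign0)] <- 1
    em <- curve_mixture_em(curves, B, resp, max_iter, tol)
    if (is.null(best) || em$loglik > best$loglik) best <- em
  }
  p <- K * (Q + 1) + (K - 1) + 2
  structure(c(best,
              list(K = K, Q = Q, grid = grid, n_params = p,
                   bic = -2 * best$loglik + p * log(N),
                   assign = max.col(best$resp, ties.method = "first"),
                   means = t(B %*% best$coef))),
            class = "curve_mixture")
}

# One EM run from given responsibilities.  Mean coefficients by whitened GLS,
# (phi, nu2) by closed-form conditional updates.
curve_mixture_em <- function(Y, B, resp, max_iter, tol) {
  N <- nrow(Y); T <- ncol(Y); K <- ncol(resp)
  whiten <- function(M, phi) M - phi * cbind(0, M[, -ncol(M), drop = FALSE])
  phi <- 0; nu2 <- stats::var(as.numeric(Y)) + 1e-8
  coef <- matrix(0, ncol(B), K)
  loglik_old <- -Inf
  loglik <- NA_real_
  trace <- numeric(0)
  reinit <- integer(K)
  for (iter in seq_len(max_iter)) {
    Nk <- colSums(resp)
    # guard against collapsed components
    for (k in seq_len(K)) {
      if (Nk[k] < 1e-8) {
        if (reinit[k] >= 3) stop("mixture component ", k,
                                 " stayed empty after 3 re-initialisations")
        reinit[k] <- reinit[k] + 1L
        far <- which.min(apply(resp, 1, max))
        resp[far, ] <- 0; resp[far, k] <- 1
        Nk <- colSums(resp)
      }
    }
    pi_k <- Nk / N
    # phi from previous residuals (coordinate ascent), then GLS means, nu2
    R_list <- lapply(seq_len(K), function(k) Y - rep(1, N) %o% as.numeric(B %*% coef[, k]))
    if (iter > 1) {
      num <- den <- 0
      for (k in seq_len(K)) {
        R <- R_list[[k]]
        num <- num + sum(resp[, k] * rowSums(R[, -1, drop = FALSE] * R[, -T, drop = FALSE]))
        den <- den + sum(resp[, k] * rowSums(R[, -T, drop = FALSE]^2))
      }
      phi <- if (den > 0) max(min(num / den, 2), -2) else 0
    }
    WB <- whiten(t(B), phi)  # careful: whitening acts along the grid
    WB <- t(WB)
    WY <- whiten(Y, phi)
    G <- crossprod(WB)
    ss <- 0
    for (k in seq_len(K)) {
      ybar <- colSums(resp[, k] * Y) / Nk[k]
      wybar <- as.numeric(whiten(matrix(ybar, 1), phi))
      coef[, k] <- solve(G, crossprod(WB, wybar))
      WR <- WY - rep(1, N) %o% as.numeric(WB %*% coef[, k])
      ss <- ss + sum(resp[, k] * rowSums(WR^2))
    }
    nu2 <- ss / (N * T)
    # E-step + observed-data log-likelihood
    logd <- matrix(0, N, K)
    for (k in seq_len(K)) {
      WR <- WY - rep(1, N) %o% as.numeric(WB %*% coef[, k])
      logd[, k] <- -0.5 * (T * log(2 * pi) + T * log(nu2) +
                             rowSums(WR^2) / nu2) + log(pi_k[k])
    }
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    loglik <- sum(lse)
    resp <- exp(logd - lse)
    if (loglik < loglik_old - 1e-6 * (abs(loglik_old) + 1)) {
      stop("EM log-likelihood decreased (", loglik_old, " -> ", loglik, ")")
    }
    trace <- c(trace, loglik)
    if (is.finite(loglik_old) &&
        abs(loglik - loglik_old) < tol * (abs(loglik_old) + 1)) break
    loglik_old <- loglik
  }
  list(coef = coef, pi = colSums(resp) / N, phi = phi, nu2 = nu2,
       resp = resp, loglik = loglik, loglik_trace = trace)
}

#' @export
print.curve_mixture <- function(x, ...) {
  cat("curve_mixture: K =", x$K, " Q =", x$Q,
      " logLik =", format(x$loglik, digits = 6),
      " BIC =", format(x$bic, digits = 6), "\n")
  cat("sizes:", table(factor(x$assign, levels = seq_len(x$K))), "\n")
  invisible(x)
}

#' Select the number of curve clusters by BIC
#'
#' Fits \code{\link{fit_curve_mixture}} for each K in \code{K_range} and
#' picks the minimiser of \eqn{BIC = -2 \log L + p \log N}, with
#' \eqn{p = K(Q+1) + (K-1) + 2} and N the number of curves.
#'
#' @inheritParams fit_curve_mixture
#' @param K_range candidate component counts (values needing more than
#'   \code{N/2} curves per component are skipped).
#' @return list with \code{best_K}, the fitted \code{best} model and a
#'   \code{table} of (K, logLik, BIC).
#' @export
select_K <- function(curves, grid = attr(curves, "grid"), K_range = 1:6,
                     Q = 4, n_init = 5, max_iter = 200, tol = 1e-8) {
  stopifnot(length(K_range) >= 1)
  N <- nrow(curves)
  K_range <- sort(unique(K_range[K_range >= 1 & 2 * K_range <= N]))
  fits <- lapply(K_range, function(K) {
    fit_curve_mixture(curves, grid, K, Q, n_init, max_iter, tol)
  })
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  i <- which.min(bic)
  list(best_K = K_range[i], best = fits[[i]],
       table = data.frame(K = K_range,
                          loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                          bic = bic))
}

#' Recursive module hierarchy of effect curves
#'
#' Recursively applies BIC model selection and mixture fitting: any node with
#' more than \code{max_size} members is split into its BIC-selected number of
#' clusters, until every leaf holds at most \code{max_size} curves, K = 1 is
#' selected, or the depth cap is reached.  This yields the module /
#' submodule / sub-submodule hierarchy whose layers later host the
#' interaction networks.
#'
#' @inheritParams select_K
#' @param max_size leaf-size cap M (markers per leaf tractable for the ODE
#'   stage); must be >= 5.
#' @param max_depth recursion cap; deeper nodes are kept as (flagged) leaves.
#' @return object of class \code{module_tree}; each node records its id
#'   path, member ids, member-mean curve and children.
#' @export
build_module_tree <- function(curves, grid = attr(curves, "grid"),
                              max_size = 30, K_range = 1:6, Q = 4,
                              n_init = 5, max_depth = 6) {
  stopifnot(max_size >= 5)
  curves <- as.matrix(curves)
  if (is.null(rownames(curves))) rownames(curves) <- paste0("s", seq_len(nrow(curves)))
  rec <- function(members, path, depth) {
    node <- list(id = path, members = members, size = length(members),
                 mean_curve = colMeans(curves[members, , drop = FALSE]),
                 children = list(), flagged = FALSE)
    if (length(members) <= max_size) return(node)
    if (depth > max_depth) {
      warning("node ", path, " exceeds the depth cap; kept as a leaf of size ",
              length(members))
      node$flagged <- TRUE
      return(node)
    }
    sel <- select_K(curves[members, , drop = FALSE], grid,
                    K_range = K_range, Q = Q, n_init = n_init)
    if (sel$best_K == 1) {
      warning("BIC selects a single component at node ", path,
              "; leaf retained with size ", length(members))
      return(node)
    }
    for (k in seq_len(sel$best_K)) {
      sub <- members[sel$best$assign == k]
      node$children[[k]] <- rec(sub, paste0(path, "/", k), depth + 1)
    }
    node
  }
  structure(list(root = rec(rownames(curves), "root", 1),
                 grid = grid, max_size = max_size),
            class = "module_tree")
}

#' Leaf assignment table of a module tree
#'
#' @param tree a \code{\link{build_module_tree}} result.
#' @return data.frame with one row per curve: its id and leaf path.
#' @export
tree_assignments <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (length(node$children) == 0) {
      out[[length(out) + 1]] <<- data.frame(id = node$members,
                                            path = node$id,
                                            stringsAsFactors = FALSE)
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(tree$root)
  do.call(rbind, out)
}

# All nodes of a module tree as a flat list.
tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1]] <<- node
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

#' @export
print.module_tree <- function(x, ...) {
  nodes <- tree_nodes(x)
  leaves <- Filter(function(n) length(n$children) == 0, nodes)
  cat("module_tree:", x$root$size, "curves,", length(nodes), "nodes,",
      length(leaves), "leaves (max size", max(vapply(leaves, `[[`, numeric(1), "size")),
      ")\n")
  invisible(x)
}
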