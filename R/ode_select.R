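# Regulator selection for the effect-dynamics ODEs.
#
# The working regression is the integral form of the node ODE: integrating
# dz_s/dt = Q_s(z_s) + sum Q_ss'(z_s') from the first age gives
#   z_s(t_k) - z_s(t_1) = Int Q_s + sum_s' Int Q_ss' + (noise),
# so the response is the vector of raw observed increments (whose errors are
# the original measurement errors, not smoothness-amplified derivative
# errors) and each candidate block is the running time-integral of the LOP
# expansion of a smoothed state curve.  An intercept absorbs the shared
# -error(t_1) term of all increments.

# running trapezoid integral of v(t) sampled at x
cumtrap <- function(x, v) {
  c(0, cumsum(diff(x) * (v[-length(v)] + v[-1]) / 2))
}

# Integral-design blocks for one target: self block (orders 0..K_ind of the
# target's smoothed state) and one block per candidate regulator (orders
# 1..K_sel of its smoothed state; constants are identifiable only once).
integral_design <- function(target, ctx, K_ind, K_sel) {
  tt <- ctx$grid
  zs <- ctx$sm[[target]]$fitted
  self <- apply(lop_basis(state_map(zs, ctx$ranges[[target]]), K_ind),
                2, cumtrap, x = tt)
  blocks <- list(self)
  reg_of <- NA_integer_
  for (sp in seq_along(ctx$sm)) {
    if (sp == target) next
    xb <- lop_basis(state_map(ctx$sm[[sp]]$fitted, ctx$ranges[[sp]]),
                    K_sel)[, -1, drop = FALSE]
    blocks[[length(blocks) + 1]] <- apply(xb, 2, cumtrap, x = tt)
    reg_of <- c(reg_of, sp)
  }
  list(blocks = blocks, reg_of = reg_of)
}

#' Select a node's regulators
#'
#' Sparse selection of the nodes whose effect curves drive a focal node's
#' effect dynamics.  The observed increments of the target curve are
#' regressed (with intercept) on the time-integrated Legendre expansion of
#' its own smoothed state (always kept, so the independent component is
#' never selected away) plus one integrated block per candidate regulator.
#' When there are many candidates a LASSO path (penalising only regulator
#' blocks) screens them by entry order; the retained support is then chosen
#' by best-subset search over the screened blocks (exhaustive up to
#' \code{kex} regulators, greedy with swap refinement beyond) under the
#' extended BIC
#' \eqn{T \log(RSS/T) + p \log T + 2\gamma \log {m-1 \choose k}}.
#'
#' @param target index (or row name) of the focal node in \code{curves}.
#' @param curves matrix, nodes (rows) x grid ages (columns).
#' @param grid common age grid.
#' @param K_ind LOP order of the self (independent) block.
#' @param K_sel LOP order of the regulator blocks used for selection
#'   (parsimonious screening; the subsequent ODE fit uses \code{K_dep}).
#' @param d_max maximum number of regulators retained.
#' @param smooth_order LOP order for curve smoothing.
#' @param ebic_gamma extended-BIC weight (0 = plain BIC); the default is
#'   conservative because candidate curve blocks are few-sample and highly
#'   collinear.
#' @param kex exhaustive best-subset depth (capped at \code{d_max}).
#' @param screen candidate-count cap before best-subset search (blocks
#'   ranked by LASSO path entry order and by marginal residual fit).
#' @param context optional precomputed layer context (internal reuse).
#' @return list with \code{regulators} (integer indices), \code{strength}
#'   (per-regulator fitted contribution SD), and the search criterion value.
#' @export
select_regulators <- function(target, curves, grid = attr(curves, "grid"),
                              K_ind = 3, K_sel = 1, d_max = 5,
                              smooth_order = 14, ebic_gamma = 2,
                              kex = 3, screen = 24, context = NULL) {
  ctx <- if (is.null(context)) ode_context(curves, grid, smooth_order) else context
  m <- length(ctx$sm)
  if (m < 3) stop("need at least 2 candidate regulators")
  if (is.character(target)) target <- match(target, ctx$ids)
  tt <- ctx$grid
  Tn <- length(tt) - 1
  yresp <- (ctx$curves[target, ] - ctx$curves[target, 1])[-1]
  if (all(abs(yresp) < 1e-12)) {
    return(list(regulators = integer(0), strength = numeric(0),
                criterion = NA_real_))
  }
  des <- integral_design(target, ctx, K_ind, K_sel)
  Xb <- lapply(des$blocks, function(b) b[-1, , drop = FALSE])
  base <- cbind(1, Xb[[1]])
  nb <- length(Xb)

  # residualise response and regulator blocks on [intercept, self block]
  qb <- qr(base)
  yres <- qr.resid(qb, yresp)
  Rres <- lapply(Xb[-1], function(b) qr.resid(qb, b))
  rss0 <- sum(yres^2)

  # best-subset search on residualised blocks under extended BIC
  pself <- ncol(base)
  Rmat <- do.call(cbind, Rres)
  bcols <- split(seq_len(ncol(Rmat)), rep(seq_len(nb - 1),
                                          vapply(Rres, ncol, integer(1))))
  G <- crossprod(Rmat)
  gy <- as.numeric(crossprod(Rmat, yres))
  rss_of <- function(sel) {
    if (length(sel) == 0) return(rss0)
    cols <- unlist(bcols[sel], use.names = FALSE)
    q <- tryCatch(solve(G[cols, cols, drop = FALSE] +
                          diag(1e-10, length(cols)), gy[cols]),
                  error = function(e) NULL)
    if (is.null(q)) return(rss0)
    max(rss0 - sum(gy[cols] * q), 1e-12)
  }
  crit_of <- function(sel) {
    k <- length(sel)
    p <- pself + length(unlist(bcols[sel], use.names = FALSE))
    Tn * log(rss_of(sel) / Tn) + p * log(Tn) +
      2 * ebic_gamma * lchoose(m - 1, k)
  }
  cand <- seq_len(nb - 1)
  if (length(cand) > screen) {
    # screen by the union of LASSO path entry order and marginal fit: entry
    # order finds blocks that matter jointly, the marginal ranking protects
    # blocks whose signal is partly collinear with the unpenalised self
    # block (they enter the path late)
    X <- do.call(cbind, Xb)
    block_id <- rep(seq_len(nb), vapply(Xb, ncol, integer(1)))
    fit <- glmnet::glmnet(X, yresp, intercept = TRUE, standardize = TRUE,
                          penalty.factor = as.numeric(block_id != 1))
    entry <- apply(fit$beta != 0, 1, function(b) {
      w <- which(b); if (length(w)) min(w) else Inf
    })
    be <- vapply(cand, function(j) min(entry[block_id == j + 1]), numeric(1))
    by_entry <- cand[order(be)]
    by_marg <- cand[order(vapply(cand, rss_of, numeric(1)))]
    merged <- unique(as.numeric(rbind(by_marg, by_entry)))
    cand <- sort(merged[seq_len(min(screen, length(merged)))])
  }
  best <- integer(0)
  best_crit <- crit_of(best)
  kex <- min(kex, d_max, length(cand))
  for (k in seq_len(kex)) {
    cc <- utils::combn(cand, k)
    for (j in seq_len(ncol(cc))) {
      cr <- crit_of(cc[, j])
      if (cr < best_crit) { best_crit <- cr; best <- cc[, j] }
    }
  }
  chosen <- best
  pool <- setdiff(cand, chosen)
  while (length(chosen) < d_max && length(pool)) {
    cr <- vapply(pool, function(b) crit_of(c(chosen, b)), numeric(1))
    if (min(cr) >= best_crit) break
    b <- pool[which.min(cr)]
    chosen <- c(chosen, b)
    pool <- setdiff(pool, b)
    best_crit <- min(cr)
    best <- chosen
  }
  if (length(best) > 1) {
    repeat {
      improved <- FALSE
      for (j in seq_along(best)) {
        for (b in setdiff(cand, best)) {
          trial <- best; trial[j] <- b
          cr <- crit_of(trial)
          if (cr < best_crit - 1e-9) {
            best_crit <- cr; best <- trial; improved <- TRUE
          }
        }
      }
      for (j in seq_along(best)) {
        cr <- crit_of(best[-j])
        if (cr < best_crit - 1e-9) {
          best_crit <- cr; best <- best[-j]; improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  best <- sort(best)
  strength <- vapply(best, function(b) {
    cols <- unlist(bcols[b], use.names = FALSE)
    q <- solve(G[cols, cols, drop = FALSE] + diag(1e-10, length(cols)),
               gy[cols])
    stats::sd(Rmat[, cols, drop = FALSE] %*% q)
  }, numeric(1))
  regs <- des$reg_of[best + 1]
  list(regulators = regs,
       strength = stats::setNames(strength, ctx$ids[regs]),
       criterion = best_crit)
}
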