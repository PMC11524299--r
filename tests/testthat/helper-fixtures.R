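# Shared fixture builders (everything is generated in code at test time).

# Brute-force SAD(1) covariance by accumulating the recursion
# e_t = phi e_{t-1} + eps_t over the process algebra (independent oracle for
# the closed form).
sad1_cov_bruteforce <- function(T, phi, nu2) {
  # e_t = sum_{k=1..t} phi^(t-k) eps_k  =>  Cov(e_t, e_s) by eps independence
  S <- matrix(0, T, T)
  for (t in 1:T) {
    for (s in 1:T) {
      kmax <- min(t, s)
      S[t, s] <- nu2 * sum(phi^((t - 1:kmax) + (s - 1:kmax)))
    }
  }
  S
}

# Dense multivariate-normal log-density (generic linear-algebra oracle).
dmvnorm_log <- function(y, mu, Sigma) {
  Tn <- length(y)
  L <- chol(Sigma)
  r <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (Tn * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
}

# Small mapping population with one planted QTL, two genotype classes.
make_qtl_pop <- function(n = 200, m = 1, seed = NULL, nu2 = 0.25, maf = 0.5,
                         times = seq(1, 12, length.out = 8)) {
  if (!is.null(seed)) set.seed(seed)
  simulate_population(n = n, m = m, qtl = 1, maf = maf,
                      base = c(10, 9, 0.5), qtl_alt = c(12, 9, 0.6),
                      sad = c(0.3, nu2), times = times, n_classes = 2)
}

# Three well-separated planted curve families on a shared grid.
make_curve_families <- function(n_per = 50, noise_frac = 0.1, seed = NULL,
                                grid = seq(0, 10, length.out = 20)) {
  if (!is.null(seed)) set.seed(seed)
  shapes <- list(function(t) 1 + 0.2 * t,
                 function(t) 3 - 0.25 * t,
                 function(t) 2 + sin(t / 2))
  Z <- do.call(rbind, lapply(shapes, function(f) {
    base <- f(grid)
    sd <- noise_frac * diff(range(base))
    t(replicate(n_per, base + rnorm(length(grid), 0, sd)))
  }))
  rownames(Z) <- paste0("c", seq_len(nrow(Z)))
  attr(Z, "grid") <- grid
  attr(Z, "labels") <- rep(seq_along(shapes), each = n_per)
  Z
}

# Edge-set comparison helpers for planted-network recovery.
edge_keys <- function(df) paste(df$from, df$to)

estimated_edges <- function(layer) {
  do.call(rbind, lapply(layer$decomps, function(dc) {
    if (nrow(dc$dependent) == 0) return(NULL)
    data.frame(from = rownames(dc$dependent), to = dc$id,
               w = apply(dc$dependent, 1, edge_weight, grid = dc$grid),
               stringsAsFactors = FALSE)
  }))
}
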