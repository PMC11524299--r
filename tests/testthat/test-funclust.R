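test_that("K = 1 mixture reduces to a GLS Legendre fit of the pooled mean", {
  set.seed(21)
  Z <- make_curve_families(n_per = 20, noise_frac = 0.05)
  grid <- attr(Z, "grid")
  fit <- fit_curve_mixture(Z, grid, K = 1, Q = 4)
  expect_equal(fit$pi, 1)
  expect_true(all(fit$assign == 1))
  # dense GLS oracle at the fitted SAD parameters
  B <- fungraph:::lop_design(grid, 4, range(grid))
  S <- sad1_covariance(grid, fit$phi, fit$nu2)
  W <- solve(S)
  ybar <- colMeans(Z)
  c_oracle <- solve(t(B) %*% W %*% B, t(B) %*% W %*% ybar)
  expect_equal(as.numeric(fit$coef), as.numeric(c_oracle), tolerance = 1e-6)
})

test_that("planted families are recovered with the right K and partition", {
  skip_if_not_installed("mclust")
  set.seed(22)
  Z <- make_curve_families(n_per = 50, noise_frac = 0.1)
  sel <- select_K(Z, K_range = 1:5, Q = 4)
  expect_equal(sel$best_K, 3)
  ari <- mclust::adjustedRandIndex(sel$best$assign, attr(Z, "labels"))
  expect_gte(ari, 0.95)
})

test_that("EM log-likelihood trace is non-decreasing", {
  set.seed(23)
  Z <- make_curve_families(n_per = 25, noise_frac = 0.15)
  fit <- fit_curve_mixture(Z, attr(Z, "grid"), K = 3, Q = 4, n_init = 2)
  expect_true(all(diff(fit$loglik_trace) > -1e-6 * (abs(fit$loglik) + 1)))
})

test_that("duplicating every curve leaves the component means unchanged", {
  set.seed(24)
  Z <- make_curve_families(n_per = 30, noise_frac = 0.08)
  grid <- attr(Z, "grid")
  Z2 <- rbind(Z, Z)
  rownames(Z2) <- paste0("d", seq_len(nrow(Z2)))
  set.seed(100); f1 <- fit_curve_mixture(Z, grid, K = 3, Q = 4)
  set.seed(100); f2 <- fit_curve_mixture(Z2, grid, K = 3, Q = 4)
  # compare the two sets of mean curves irrespective of label order
  m1 <- f1$means[order(f1$means[, 1]), ]
  m2 <- f2$means[order(f2$means[, 1]), ]
  expect_equal(m1, m2, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("partition is stable across initialisations on separated families", {
  set.seed(25)
  Z <- make_curve_families(n_per = 30, noise_frac = 0.05)
  part <- function(seed) {
    set.seed(seed)
    f <- fit_curve_mixture(Z, attr(Z, "grid"), K = 3, Q = 4, n_init = 3)
    # compare as set-of-sets
    unname(lapply(split(rownames(Z), f$assign), sort)[order(
      vapply(split(rownames(Z), f$assign), function(s) sort(s)[1], ""))])
  }
  expect_equal(part(1), part(2))
})

test_that("BIC uses the stated parameter count and sample size", {
  set.seed(26)
  Z <- make_curve_families(n_per = 15, noise_frac = 0.1)
  f <- fit_curve_mixture(Z, attr(Z, "grid"), K = 2, Q = 3)
  p <- 2 * (3 + 1) + (2 - 1) + 2
  expect_equal(f$n_params, p)
  expect_equal(f$bic, -2 * f$loglik + p * log(nrow(Z)))
})

test_that("small curve sets are kept as a single unsplit root", {
  set.seed(27)
  Z <- make_curve_families(n_per = 13, noise_frac = 0.1)  # 39 curves
  tr <- build_module_tree(Z, max_size = 50, K_range = 1:3)
  expect_length(tr$root$children, 0)
  expect_equal(tr$root$size, 39)
})

test_that("module tree splits planted families and partitions the markers", {
  set.seed(28)
  Z <- make_curve_families(n_per = 40, noise_frac = 0.08)  # 120 curves
  tr <- build_module_tree(Z, max_size = 60, K_range = 1:4)
  asg <- tree_assignments(tr)
  # exact partition of the input set
  expect_setequal(asg$id, rownames(Z))
  expect_equal(nrow(asg), nrow(Z))
  # leaves align with the planted families
  expect_gte(length(unique(asg$path)), 3)
  tab <- table(asg$path, attr(Z, "labels"))
  purity <- sum(apply(tab, 1, max)) / nrow(Z)
  expect_gte(purity, 0.95)
})

test_that("a single homogeneous family mostly selects K = 1", {
  set.seed(29)
  hits <- 0
  for (rep in 1:5) {
    grid <- seq(0, 10, length.out = 20)
    base <- 2 + 0.1 * grid
    Z <- t(replicate(40, base + rnorm(20, 0, 0.15)))
    rownames(Z) <- paste0("h", 1:40)
    attr(Z, "grid") <- grid
    hits <- hits + (select_K(Z, K_range = 1:3, Q = 3)$best_K == 1)
  }
  expect_gte(hits, 3)
})
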