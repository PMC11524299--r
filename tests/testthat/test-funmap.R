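test_that("single observation log-density reduces to the normal constant", {
  tr <- long_trait(data.frame(id = "i1", time = 1, value = 3))
  ll <- group_loglik(tr, genotypes = c(i1 = 0),
                     growth = rbind(c(3 * (1 + 9 * exp(-0.5)), 9, 0.5)),
                     phi = 0.2, nu2 = 1, min_obs = 1)
  # mu at t=1 equals y=3 when a = 3*(1+9e^-0.5): residual 0
  expect_equal(ll, -0.5 * log(2 * pi))
})

test_that("group log-likelihood matches a dense multivariate-normal oracle", {
  set.seed(3)
  for (rep in 1:20) {
    n <- 10
    T <- sample(4:8, 1)
    times <- sort(runif(T, 0, 12))
    phi <- runif(1, -0.8, 0.8); nu2 <- runif(1, 0.1, 2)
    growth <- rbind(c(10, 9, 0.5), c(12, 8, 0.6))
    g <- rep(0:1, length.out = n)
    y <- matrix(rnorm(n * T, 5, 2), n, T)
    df <- data.frame(id = rep(sprintf("i%02d", 1:n), each = T),
                     time = rep(times, n), value = as.numeric(t(y)))
    tr <- long_trait(df)
    ll <- group_loglik(tr, setNames(g, sprintf("i%02d", 1:n)), growth, phi, nu2)
    S <- sad1_covariance(times, phi, nu2)
    ll_oracle <- sum(vapply(1:n, function(i) {
      mu <- logistic_mean(times, growth[g[i] + 1, 1], growth[g[i] + 1, 2],
                          growth[g[i] + 1, 3])
      dmvnorm_log(y[i, ], mu, S)
    }, numeric(1)))
    expect_equal(ll, ll_oracle, tolerance = 1e-8)
  }
})

test_that("identical H1 and H0 parameters give identical likelihoods", {
  set.seed(4)
  pop <- make_qtl_pop(n = 40)
  growth1 <- rbind(c(10, 9, 0.5), c(10, 9, 0.5))
  growth0 <- rbind(c(10, 9, 0.5))
  g <- pop$geno[1, ]
  l1 <- group_loglik(pop$trait, g, growth1, 0.3, 0.25)
  l0 <- group_loglik(pop$trait, rep(0, length(g)), growth0, 0.3, 0.25)
  expect_equal(l1, l0)
})

test_that("marker fit recovers planted genotype-specific growth curves", {
  set.seed(5)
  pop <- make_qtl_pop(n = 200)
  fit <- fit_marker(pop$trait, pop$geno[1, ])
  expect_s3_class(fit, "funmap_fit")
  expect_equal(unname(fit$growth[, "a"]), c(10, 12), tolerance = 0.1)
  expect_equal(unname(fit$growth[, "r"]), c(0.5, 0.6), tolerance = 0.15)
  expect_gt(fit$lr, 50)
  expect_gte(fit$lr, 0)
})

test_that("degenerate genotype input raises an informative error", {
  set.seed(6)
  pop <- make_qtl_pop(n = 30)
  expect_error(fit_marker(pop$trait, rep(1, 30)), "insufficient genotype classes")
})

test_that("lr_test applies the chi-square reference and clips at zero", {
  fit <- list(logl1 = -100, logl0 = -100, J = 2)
  out <- lr_test(fit)
  expect_equal(out$lr, 0)
  expect_equal(out$p_value, 1)
  fit2 <- list(logl1 = -95, logl0 = -100, J = 2)
  out2 <- lr_test(fit2)
  expect_equal(out2$lr, 10)
  expect_equal(out2$p_value, pchisq(10, df = 3, lower.tail = FALSE))
  expect_equal(out2$p_value, 0.0186, tolerance = 1e-2)
  fit3 <- list(logl1 = -100.00001, logl0 = -100, J = 3)
  expect_equal(lr_test(fit3)$lr, 0)
})

test_that("scan ranks the planted QTL first and keeps LR non-negative", {
  set.seed(8)
  pop <- simulate_population(n = 150, m = 12, qtl = 3, maf = 0.5,
                             base = c(10, 9, 0.5), qtl_alt = c(12, 9, 0.6),
                             sad = c(0.3, 0.25), n_classes = 2)
  sc <- scan_markers(pop$trait, pop$geno)
  expect_true(all(sc$table$lr >= 0, na.rm = TRUE))
  expect_equal(which.max(sc$table$lr), 3)
})

test_that("permutation threshold is the empirical quantile of scan maxima", {
  set.seed(9)
  pop <- simulate_population(n = 60, m = 6, qtl = integer(0), maf = 0.4,
                             times = seq(1, 12, length.out = 5))
  sc <- scan_markers(pop$trait, pop$geno)
  expect_error(permutation_threshold(sc, B = 5), "at least 10")
  pt <- suppressWarnings(permutation_threshold(sc, B = 20, alpha = 0.05))
  expect_length(pt$maxima, 20)
  expect_equal(pt$threshold, unname(quantile(pt$maxima, 0.95)))
})

test_that("effect curve formula reproduces hand-computed cases", {
  # symmetric two-class case: z equals half the gap
  fit <- list(growth = rbind(c(12, 1e-9, 1), c(8, 1e-9, 1)), n_j = c(50, 50))
  z <- effect_curve(fit, grid = c(1, 5, 10))
  expect_equal(z, rep(2, 3), tolerance = 1e-6)
  # identical classes: zero curve
  fit0 <- list(growth = rbind(c(10, 9, 0.5), c(10, 9, 0.5)), n_j = c(30, 70))
  expect_equal(effect_curve(fit0, 1:5), rep(0, 5))
  # three classes, direct arithmetic oracle at a single age
  fit3 <- list(growth = rbind(c(2, 1e-12, 1), c(5, 1e-12, 1), c(8, 1e-12, 1)),
               n_j = c(25, 50, 25))
  z3 <- effect_curve(fit3, grid = 100)
  expect_equal(z3, sqrt((25 * 9 + 50 * 0 + 25 * 9) / 100), tolerance = 1e-6)
})

test_that("effect curves are invariant to genotype-class relabeling", {
  fit <- list(growth = rbind(c(12, 9, 0.4), c(9, 7, 0.6)), n_j = c(40, 60))
  fit_swapped <- list(growth = fit$growth[2:1, ], n_j = fit$n_j[2:1])
  grid <- seq(1, 10, length.out = 7)
  expect_equal(effect_curve(fit, grid), effect_curve(fit_swapped, grid))
})

test_that("plasticity trait subtracts stress from control", {
  df <- data.frame(id = rep(c("a", "b"), each = 4),
                   time = rep(1:4, 2), value = rnorm(8))
  ctrl <- long_trait(df)
  strs <- long_trait(transform(df, value = value - 2))
  pl <- plasticity_trait(ctrl, strs)
  expect_equal(unlist(pl$values, use.names = FALSE), rep(2, 8))
  same <- plasticity_trait(ctrl, ctrl)
  expect_equal(unlist(same$values, use.names = FALSE), rep(0, 8))
})

test_that("plasticity interpolates misaligned grids like a hand oracle", {
  ctrl <- long_trait(data.frame(id = "a", time = c(0, 2, 4), value = c(0, 4, 8)))
  strs <- long_trait(data.frame(id = "a", time = c(1, 3), value = c(1, 2)))
  pl <- plasticity_trait(ctrl, strs)
  # shared grid = {1, 2, 3}; control interpolates to (2, 4, 6), stress to (1, 1.5, 2)
  expect_equal(pl$times[["a"]], c(1, 2, 3))
  expect_equal(pl$values[["a"]], c(2 - 1, 4 - 1.5, 6 - 2), tolerance = 1e-10)
})

test_that("individuals missing from one condition are excluded with a message", {
  ctrl <- long_trait(data.frame(id = rep(c("a", "b"), each = 3),
                                time = rep(1:3, 2), value = 1:6))
  strs <- long_trait(data.frame(id = rep("a", 3), time = 1:3, value = 4:6))
  expect_message(pl <- plasticity_trait(ctrl, strs), "only one condition")
  expect_equal(pl$ids, "a")
})
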