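test_that("population simulation is reproducible under a fixed seed", {
  set.seed(51); a <- simulate_population(n = 20, m = 5, qtl = 1, n_classes = 2)
  set.seed(51); b <- simulate_population(n = 20, m = 5, qtl = 1, n_classes = 2)
  expect_identical(a$geno, b$geno)
  expect_identical(a$trait$values, b$trait$values)
})

test_that("noise-free trajectories equal the genotype-class logistic curves", {
  set.seed(52)
  pop <- simulate_population(n = 12, m = 2, qtl = 1, maf = 0.5,
                             base = c(10, 9, 0.5), qtl_alt = c(12, 9, 0.6),
                             sad = c(0.3, 0), n_classes = 2)
  times <- pop$truth$times
  for (i in seq_along(pop$trait$ids)) {
    id <- pop$trait$ids[i]
    g <- pop$geno[1, id]
    pars <- if (g == 0) c(10, 9, 0.5) else c(12, 9, 0.6)
    expect_equal(pop$trait$values[[id]],
                 logistic_mean(times, pars[1], pars[2], pars[3]),
                 ignore_attr = TRUE)
  }
})

test_that("simulated allele frequencies match the requested maf", {
  set.seed(53)
  pop <- simulate_population(n = 10000, m = 3, maf = 0.3,
                             times = seq(1, 3, length.out = 3))
  freq <- rowMeans(pop$geno) / 2
  expect_equal(unname(freq), rep(0.3, 3), tolerance = 0.01)
})

test_that("SAD(1) residual sample covariance matches the closed form", {
  set.seed(54)
  n <- 1e5
  times <- 1:4
  pop <- simulate_population(n = n, m = 1, qtl = integer(0), maf = 0.5,
                             base = c(10, 9, 0.5), sad = c(0.6, 0.8),
                             times = times)
  Y <- do.call(rbind, pop$trait$values)
  mu <- logistic_mean(times, 10, 9, 0.5)
  E <- sweep(Y, 2, mu)
  S_emp <- crossprod(E) / n
  S_th <- sad1_covariance(times, 0.6, 0.8)
  expect_lt(max(abs(S_emp - S_th) / max(abs(S_th))), 0.02)
})

test_that("stress condition shares individuals and genotypes", {
  set.seed(55)
  pop <- simulate_population(n = 15, m = 4, qtl = 2, n_classes = 2,
                             stress = list(base = c(8, 9, 0.4),
                                           qtl_alt = c(9, 9, 0.45)))
  expect_setequal(pop$trait$ids, pop$stress_trait$ids)
  pl <- plasticity_trait(pop$trait, pop$stress_trait)
  expect_length(pl$ids, 15)
})

test_that("edgeless zero-rate system yields constant curves", {
  set.seed(56)
  sys <- simulate_effect_system(m = 4, topology = "relaxation", alpha = 0,
                                z0 = c(1, 2, 3, 4), noise_frac = 0)
  for (i in 1:4) expect_equal(unname(sys$curves[i, ]), rep(i, ncol(sys$curves)))
})

test_that("single-node constant drift integrates to a straight line", {
  sys <- simulate_effect_system(m = 2, topology = "relaxation", alpha = 0,
                                drift = 0.5, z0 = c(1, 1), noise_frac = 0,
                                times = seq(0, 8, length.out = 17))
  expect_equal(unname(sys$curves[1, ]), 1 + 0.5 * sys$grid, tolerance = 1e-9)
})

test_that("effect-system generation is deterministic and bounded", {
  set.seed(57); a <- simulate_effect_system(m = 10)
  set.seed(57); b <- simulate_effect_system(m = 10)
  expect_identical(a$curves, b$curves)
  expect_identical(a$edges, b$edges)
  expect_true(all(is.finite(a$curves)))
})

test_that("trajectory blow-up is reported with the offending node", {
  expect_error(
    simulate_effect_system(m = 2, topology = "relaxation", alpha = 0,
                           drift = c(100, 0), z0 = c(1, 1), noise_frac = 0,
                           bound = 50),
    "blow-up.*s1")
})

test_that("planted oscillator networks average two regulators per node", {
  set.seed(58)
  sys <- simulate_effect_system(m = 20)
  indeg <- table(factor(sys$edges$to, levels = paste0("s", 1:20)))
  expect_equal(mean(indeg), 2)
  # every node keeps its partner coupling
  expect_true(all(indeg >= 1))
})
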