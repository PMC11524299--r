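test_that("edge weight is the span-normalised terminal dependent effect", {
  grid <- seq(2, 4, length.out = 9)
  expect_equal(edge_weight(rep(0, 9), grid), 0)
  D <- seq(0, 4, length.out = 9)
  expect_equal(edge_weight(D, grid), 2)
})

test_that("classify_epistasis reproduces the seven canonical patterns", {
  eps <- 0.1; delta <- 0.2
  expect_equal(classify_epistasis(2, 2, eps, delta), "symmetric_positive")
  expect_equal(classify_epistasis(3, 1, eps, delta), "asymmetric_positive")
  expect_equal(classify_epistasis(2, 0, eps, delta), "directional_positive")
  expect_equal(classify_epistasis(-2, -2, eps, delta), "symmetric_negative")
  expect_equal(classify_epistasis(-3, -1, eps, delta), "asymmetric_negative")
  expect_equal(classify_epistasis(0, -2, eps, delta), "directional_negative")
  expect_equal(classify_epistasis(2, -1, eps, delta), "altruistic_repressive")
  expect_equal(classify_epistasis(-1, 2, eps, delta), "altruistic_repressive")
  expect_equal(classify_epistasis(0.05, -0.01, eps, delta), "none")
})

test_that("classification is exhaustive, exclusive, and sign-mirrored", {
  set.seed(41)
  labels <- c("symmetric_positive", "asymmetric_positive",
              "directional_positive", "symmetric_negative",
              "asymmetric_negative", "directional_negative",
              "altruistic_repressive", "none")
  flip <- function(lab) {
    map <- c(symmetric_positive = "symmetric_negative",
             asymmetric_positive = "asymmetric_negative",
             directional_positive = "directional_negative",
             symmetric_negative = "symmetric_positive",
             asymmetric_negative = "asymmetric_positive",
             directional_negative = "directional_positive",
             altruistic_repressive = "altruistic_repressive",
             none = "none")
    unname(map[lab])
  }
  for (i in 1:500) {
    u <- runif(1, -3, 3); v <- runif(1, -3, 3)
    lab <- classify_epistasis(u, v, eps = 0.2, delta = 0.3)
    expect_length(lab, 1)
    expect_true(lab %in% labels)
    expect_equal(classify_epistasis(-u, -v, eps = 0.2, delta = 0.3), flip(lab))
  }
})

test_that("a planted network is assembled with its edges and attributes", {
  set.seed(42)
  sys <- simulate_effect_system(m = 6, noise_frac = 0.01)
  lay <- fit_layer(sys$curves, sys$grid, maxit = 500)
  net <- assemble_network(NULL, lay)
  g <- net$layers$root
  expect_equal(igraph::vcount(g), 6)
  expect_gt(igraph::ecount(g), 0)
  # pair couplings (strong edges) are recovered
  expect_true(igraph::are_adjacent(g, "s2", "s1"))
  expect_true(all(igraph::E(g)$epistasis_type %in%
                    c("symmetric_positive", "asymmetric_positive",
                      "directional_positive", "symmetric_negative",
                      "asymmetric_negative", "directional_negative",
                      "altruistic_repressive", "none")))
  # mean out-degree respects the sparsity cap
  expect_lte(mean(igraph::degree(g, mode = "out")), 5)
})

test_that("network export round-trips the edge list", {
  set.seed(43)
  sys <- simulate_effect_system(m = 4, noise_frac = 0.01)
  lay <- fit_layer(sys$curves, sys$grid, maxit = 300)
  net <- assemble_network(NULL, lay)
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(file.exists(file.path(dir, "edges.tsv")))
  ed <- read.delim(file.path(dir, "edges.tsv"))
  g <- net$layers$root
  expect_equal(nrow(ed), igraph::ecount(g))
  g2 <- igraph::read_graph(grep("graphml$", paths, value = TRUE)[1],
                           format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_equal(sort(igraph::E(g2)$weight), sort(igraph::E(g)$weight),
               tolerance = 1e-10)
})

test_that("single-node layers yield empty edge sets with a warning", {
  lay <- structure(list(fits = list(), decomps = list(), grid = 1:5),
                   class = "layer_fit")
  expect_warning(net <- assemble_network(NULL, list(lonely = lay)), "empty")
  expect_equal(igraph::ecount(net$layers$lonely), 0)
})
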