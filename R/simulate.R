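#' Simulate a genotype-phenotype mapping population
#'
#' Draws biallelic genotypes binomially at the stated allele frequencies and
#' generates longitudinal phenotypes as the genotype-class logistic mean
#' plus SAD(1) residual noise on each individual's grid.  Markers listed in
#' \code{qtl} shift the growth parameters between genotype classes; all
#' other markers are phenotype-independent.  With three genotype classes the
#' heterozygote's growth parameters are midway between the homozygotes'
#' (no dominance).
#'
#' @param n individuals.
#' @param m markers.
#' @param qtl integer indices of planted QTLs (possibly empty).
#' @param maf alt-allele frequency, recycled over markers.
#' @param base growth parameters \code{c(a, b, r)} of the reference
#'   homozygote (and of everyone at non-QTL markers).
#' @param qtl_alt growth parameters \code{c(a, b, r)} of the alternate
#'   homozygote at each QTL (list, one per QTL, or a single vector reused).
#' @param sad SAD(1) residual parameters \code{c(phi, nu2)}; \code{nu2 = 0}
#'   gives noise-free trajectories.
#' @param times measurement age grid shared by all individuals.
#' @param n_classes 3 (codes 0/1/2, binomial(2, maf)) or 2 (codes 0/1,
#'   Bernoulli(maf)).
#' @param stress optional second-condition parameter list with elements
#'   \code{base}, \code{qtl_alt} (and optionally \code{sad}); when given, a
#'   stress trait sharing individuals and genotypes is generated too.
#' @return list with \code{geno} (markers x individuals), \code{trait} (a
#'   \code{\link{long_trait}}), optionally \code{stress_trait}, and
#'   \code{truth} (the planted parameters).
#' @export
simulate_population <- function(n = 100, m = 50, qtl = integer(0), maf = 0.3,
                                base = c(a = 10, b = 9, r = 0.5),
                                qtl_alt = c(a = 12, b = 9, r = 0.6),
                                sad = c(phi = 0.3, nu2 = 0.25),
                                times = seq(1, 12, length.out = 8),
                                n_classes = 3, stress = NULL) {
  stopifnot(all(qtl >= 1 & qtl <= m), all(maf > 0 & maf < 1),
            n_classes %in% c(2, 3))
  maf <- rep_len(maf, m)
  geno <- matrix(stats::rbinom(m * n, n_classes - 1, rep(maf, n)), m, n,
                 dimnames = list(paste0("m", seq_len(m)),
                                 paste0("ind", seq_len(n))))
  if (!is.list(qtl_alt)) qtl_alt <- rep(list(qtl_alt), length(qtl))
  gen_condition <- function(base_p, alt_list, sad_p) {
    mu <- matrix(rep(logistic_mean(times, base_p[1], base_p[2], base_p[3]),
                     each = n), n, length(times))
    for (k in seq_along(qtl)) {
      g <- geno[qtl[k], ]
      frac <- g / (n_classes - 1)   # 0, (1/2,) 1 -> interpolate base -> alt
      pars <- cbind(base_p[1] + frac * (alt_list[[k]][1] - base_p[1]),
                    base_p[2] + frac * (alt_list[[k]][2] - base_p[2]),
                    base_p[3] + frac * (alt_list[[k]][3] - base_p[3]))
      for (i in seq_len(n)) {
        mu[i, ] <- logistic_mean(times, pars[i, 1], pars[i, 2], pars[i, 3])
      }
    }
    if (sad_p[2] > 0) {
      eps <- matrix(stats::rnorm(n * length(times), 0, sqrt(sad_p[2])),
                    n, length(times))
      e <- eps
      for (t in 2:length(times)) e[, t] <- sad_p[1] * e[, t - 1] + eps[, t]
      mu <- mu + e
    }
    long_trait(data.frame(
      id = rep(colnames(geno), each = length(times)),
      time = rep(times, n),
      value = as.numeric(t(mu))))
  }
  out <- list(geno = geno,
              trait = gen_condition(base, qtl_alt, sad),
              truth = list(qtl = qtl, base = base, qtl_alt = qtl_alt,
                           sad = sad, maf = maf, times = times,
                           n_classes = n_classes))
  if (!is.null(stress)) {
    s_sad <- if (is.null(stress$sad)) sad else stress$sad
    s_alt <- if (is.list(stress$qtl_alt)) stress$qtl_alt
             else rep(list(stress$qtl_alt), length(qtl))
    out$stress_trait <- gen_condition(stress$base, s_alt, s_sad)
    out$truth$stress <- stress
  }
  out
}

#' Simulate a planted Lotka-Volterra effect-curve system
#'
#' Integrates a planted interaction system of the form the inference fits:
#' each node has an independent relaxation term
#' \eqn{Q_s(z) = \alpha_s (c_s - z) + drift_s} and each planted edge
#' contributes \eqn{Q_{ss'}(z_{s'}) = \beta_{ss'} z_{s'}}, so the sign of
#' the planted \eqn{\beta} is the sign of the time-integrated dependent
#' effect.  Curves are solved by RK4 and observation noise with standard
#' deviation \code{noise_frac} times each curve's range is added.
#'
#' Two planted topologies are available.  The default (\code{edges = NULL},
#' \code{topology = "oscillator"}) builds the benchmark system used to
#' validate network recovery: nodes are grouped into antisymmetrically
#' coupled pairs whose coupling strengths place each pair's oscillation at
#' a distinct frequency, half the pairs act as sources and half as sinks,
#' and every sink node receives cross edges from two source pairs (two
#' regulators per node on average).  Phase-diverse oscillations at
#' well-separated frequencies are what make sparse support recovery from a
#' single trajectory identifiable; slowly relaxing trajectories are too
#' collinear for any selection method.  Passing \code{topology =
#' "relaxation"} (or an explicit edge list) gives plain relaxation dynamics.
#'
#' @param m nodes (even for the oscillator topology).
#' @param edges planted cross-edge list as a data.frame with columns
#'   \code{from}, \code{to}, \code{beta} (node indices or "s<i>" ids); or
#'   \code{NULL} to draw the default topology.
#' @param topology \code{"oscillator"} (paired oscillators + cross edges)
#'   or \code{"relaxation"} (independent relaxers + \code{edges}).
#' @param times output age grid.
#' @param noise_frac observation noise SD as a fraction of each curve's
#'   range.
#' @param alpha,eq,z0,drift optional per-node overrides of the relaxation
#'   rate, equilibrium, initial value and constant drift (recycled).
#' @param w_range frequency range (rad/time) of the pair couplings.
#' @param cross_range magnitude range of cross-edge coefficients.
#' @param pair_asym within-pair coupling asymmetry range (amplitude
#'   contrast between the two members of a pair).
#' @param bound blow-up guard: any |z| beyond it aborts with the offending
#'   node named.
#' @param nsub RK4 substeps between grid ages.
#' @return list with \code{curves} (m x T, \code{grid} attribute), the
#'   noise-free \code{curves_true}, the planted \code{edges} (including
#'   pair couplings), and the node parameters.
#' @export
simulate_effect_system <- function(m = 20, edges = NULL,
                                   topology = c("oscillator", "relaxation"),
                                   times = seq(0, 12, length.out = 121),
                                   noise_frac = 0.02,
                                   alpha = NULL, eq = NULL, z0 = NULL,
                                   drift = 0,
                                   w_range = c(0.8, 1.8),
                                   cross_range = c(0.6, 0.9),
                                   pair_asym = c(1.2, 2.0),
                                   bound = 50, nsub = 4L) {
  topology <- match.arg(topology)
  ids <- paste0("s", seq_len(m))
  drift <- rep_len(drift, m)
  ed <- NULL
  if (topology == "oscillator") {
    if (m %% 2 != 0) stop("oscillator topology needs an even node count")
    npair <- m / 2
    if (is.null(alpha)) alpha <- stats::runif(m, 0.05, 0.2)
    if (is.null(eq)) eq <- stats::runif(m, 1.8, 3.0)
    if (is.null(z0)) z0 <- eq + sample(c(-1, 1), m, TRUE) * stats::runif(m, 0.5, 1.0)
    w <- exp(seq(log(w_range[1]), log(w_range[2]), length.out = npair)) *
      exp(stats::runif(npair, -0.03, 0.03))
    w <- sample(w)
    asym <- stats::runif(npair, pair_asym[1], pair_asym[2])
    for (k in seq_len(npair)) {
      a <- 2 * k - 1; b <- 2 * k
      ed <- rbind(ed, data.frame(from = c(b, a), to = c(a, b),
                                 beta = c(w[k] * asym[k], -w[k] / asym[k])))
    }
    if (is.null(edges) && npair >= 2) {
      # balanced source allocation: sources = first half of the pairs, each
      # forcing two sink pairs; every sink node gets one edge from each of
      # its pair's two source pairs
      nsrc <- ceiling(npair / 2)
      src_pairs <- seq_len(nsrc)
      snk_pairs <- setdiff(seq_len(npair), src_pairs)
      alloc <- sample(rep(src_pairs, length.out = 2 * length(snk_pairs)))
      i <- 1
      for (k in snk_pairs) {
        srcs <- alloc[c(i, i + 1)]; i <- i + 2
        while (length(src_pairs) > 1 && srcs[1] == srcs[2]) {
          srcs[2] <- sample(src_pairs, 1)
        }
        for (jj in 1:2) {
          tgt_node <- 2 * k - 2 + jj
          froms <- if (srcs[1] == srcs[2]) {
            sample(c(2 * srcs[1] - 1, 2 * srcs[1]))  # both members, distinct
          } else {
            NULL  # drawn one at a time below
          }
          for (q in 1:2) {
            sp <- srcs[if (q == 1) jj else 3 - jj]
            from <- if (is.null(froms)) sample(c(2 * sp - 1, 2 * sp), 1) else froms[q]
            ed <- rbind(ed, data.frame(
              from = from, to = tgt_node,
              beta = sample(c(-1, 1), 1) *
                stats::runif(1, cross_range[1], cross_range[2])))
          }
        }
      }
    } else if (!is.null(edges)) {
      ed <- rbind(ed, normalize_edges(edges, ids))
    }
  } else {
    if (is.null(alpha)) alpha <- stats::runif(m, 0.25, 0.7)
    if (is.null(eq)) eq <- stats::runif(m, 0.8, 2.8)
    if (is.null(z0)) z0 <- stats::runif(m, 0.3, 1.8)
    if (!is.null(edges)) ed <- normalize_edges(edges, ids)
  }
  alpha <- rep_len(alpha, m); eq <- rep_len(eq, m); z0 <- rep_len(z0, m)
  fi <- ed$from; ti <- ed$to
  if (topology == "oscillator") {
    # constant production term placing the coupled system's fixed point at
    # eq (> 0), so curves oscillate around positive levels and the sign of
    # a planted beta is the sign of its time-integrated contribution
    B <- matrix(0, m, m)
    if (!is.null(ed)) B[cbind(ti, fi)] <- ed$beta
    drift <- drift + as.numeric((diag(alpha, m) - B) %*% eq) - alpha * eq
  }
  f <- function(t, z) {
    dz <- alpha * (eq - z) + drift
    if (!is.null(ed)) {
      contrib <- ed$beta * z[fi]
      for (k in seq_along(contrib)) dz[ti[k]] <- dz[ti[k]] + contrib[k]
    }
    dz
  }
  sol <- rk4(f, z0, times, nsub)
  if (any(!is.finite(sol)) || any(abs(sol) > bound, na.rm = TRUE)) {
    bad <- which(apply(sol, 2, function(col) any(!is.finite(col) | abs(col) > bound)))
    stop("trajectory blow-up at node(s): ", paste(ids[bad], collapse = ", "))
  }
  Z <- t(sol)
  rownames(Z) <- ids
  colnames(Z) <- signif(times, 6)
  noisy <- Z
  if (noise_frac > 0) {
    rng <- apply(Z, 1, function(z) diff(range(z)))
    noisy <- Z + matrix(stats::rnorm(length(Z), 0, rep(noise_frac * rng, ncol(Z))),
                        nrow(Z), ncol(Z))
  }
  attr(noisy, "grid") <- times
  attr(Z, "grid") <- times
  ed_out <- if (is.null(ed)) {
    data.frame(from = character(0), to = character(0), beta = numeric(0),
               sign = numeric(0))
  } else {
    data.frame(from = ids[ed$from], to = ids[ed$to], beta = ed$beta,
               sign = sign(ed$beta), stringsAsFactors = FALSE)
  }
  list(curves = noisy, curves_true = Z, edges = ed_out,
       alpha = alpha, eq = eq, z0 = z0, grid = times)
}

# Accept edge lists with integer indices or "s<i>" ids.
normalize_edges <- function(edges, ids) {
  stopifnot(all(c("from", "to", "beta") %in% names(edges)))
  fi <- if (is.character(edges$from)) match(edges$from, ids) else as.integer(edges$from)
  ti <- if (is.character(edges$to)) match(edges$to, ids) else as.integer(edges$to)
  if (any(is.na(fi)) || any(is.na(ti))) stop("edge endpoints must be node ids")
  data.frame(from = fi, to = ti, beta = edges$beta)
}
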