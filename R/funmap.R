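#' Longitudinal trait container
#'
#' Builds a longitudinal-trait object from a long-format table with one row
#' per individual x measurement age.  Per-individual age grids may differ in
#' both length and spacing.
#'
#' @param data data.frame with columns \code{id}, \code{time}, \code{value}
#'   (names configurable).
#' @param id,time,value column names.
#' @return an object of class \code{long_trait}: parallel lists of per-
#'   individual age grids and observation vectors.
#' @export
long_trait <- function(data, id = "id", time = "time", value = "value") {
  stopifnot(all(c(id, time, value) %in% names(data)))
  data <- data[order(data[[id]], data[[time]]), ]
  ids <- as.character(unique(data[[id]]))
  times <- split(data[[time]], factor(as.character(data[[id]]), levels = ids))
  values <- split(data[[value]], factor(as.character(data[[id]]), levels = ids))
  for (i in seq_along(ids)) {
    ti <- times[[i]]
    if (any(!is.finite(ti)) || any(diff(ti) <= 0)) {
      stop("ages for individual '", ids[i], "' must be finite and strictly increasing")
    }
    if (length(ti) != length(values[[i]])) {
      stop("observation count mismatch for individual '", ids[i], "'")
    }
  }
  structure(list(ids = ids, times = times, values = values),
            class = "long_trait")
}

#' @export
print.long_trait <- function(x, ...) {
  nt <- lengths(x$times)
  cat("long_trait:", length(x$ids), "individuals,",
      sum(nt), "observations (", min(nt), "-", max(nt), "per individual)\n")
  invisible(x)
}

# Flatten a long_trait for the compiled likelihood kernel; optionally keep
# only individuals with at least min_obs measurements.
lt_flat <- function(trait, min_obs = 3L) {
  keep <- lengths(trait$times) >= min_obs
  if (!all(keep)) {
    message(sum(!keep), " individual(s) with < ", min_obs,
            " observations excluded from fitting")
  }
  times <- trait$times[keep]
  values <- trait$values[keep]
  list(ids = trait$ids[keep],
       y = as.numeric(unlist(values, use.names = FALSE)),
       tt = as.numeric(unlist(times, use.names = FALSE)),
       off = c(0L, cumsum(lengths(times))),
       n = sum(keep))
}

# Map raw genotype codes for one marker to 0-based class labels, dropping
# classes below the membership floor (their individuals are excluded at this
# marker) and individuals with missing genotype.
relabel_classes <- function(g, min_class = 3L) {
  cls <- rep(-1L, length(g))
  tab <- table(g[!is.na(g)])
  keep_codes <- names(tab)[tab >= min_class]
  merged <- length(tab) - length(keep_codes)
  for (j in seq_along(keep_codes)) {
    cls[!is.na(g) & as.character(g) == keep_codes[j]] <- j - 1L
  }
  list(cls = cls, J = length(keep_codes), codes = keep_codes,
       n_j = as.integer(tab[keep_codes]), merged = merged > 0L)
}

# Heuristic log-scale (a, b, r) starting values from pooled trajectories.
h0_heuristic <- function(flat) {
  ymax <- max(flat$y)
  y0 <- mean(flat$y[flat$off[-length(flat$off)] + 1])
  a0 <- max(ymax * 1.05, 1e-6)
  b0 <- max(a0 / max(y0, 1e-6) - 1, 0.1)
  r0 <- 2 / max(diff(range(flat$tt)), 1e-6)
  log(c(a0, b0, r0))
}

# Pooled single-curve (H0) fit used to seed all marker fits.
pooled_fit <- function(flat, n_starts = 5L, maxit = 2000L, reltol = 1e-8) {
  init <- h0_heuristic(flat)
  inits <- matrix(rep(init, each = n_starts), n_starts, 3)
  if (n_starts > 1) {
    inits[-1, ] <- inits[-1, , drop = FALSE] +
      matrix(stats::rnorm(3 * (n_starts - 1), 0, 0.25), n_starts - 1, 3)
  }
  fm_fit_cpp(flat$y, flat$tt, flat$off, rep(0L, flat$n), 1L, inits,
             maxit = maxit, reltol = reltol)
}

#' Genotype-grouped log-likelihood
#'
#' Log-likelihood of a longitudinal trait under the functional-mapping model:
#' individuals in genotype class \code{j} follow a multivariate normal with
#' logistic mean \code{(a_j, b_j, r_j)} evaluated on their own age grid and a
#' shared SAD(1) covariance \code{(phi, nu2)}.
#'
#' @param trait a \code{\link{long_trait}}.
#' @param genotypes vector of genotype codes, one per individual in
#'   \code{trait$ids} order; \code{NA} drops the individual.
#' @param growth a \code{J x 3} matrix of per-class \code{(a, b, r)}, rows in
#'   the order of sorted observed genotype codes.
#' @param phi,nu2 shared SAD(1) parameters.
#' @param min_obs minimum observations per individual (default 3).
#' @return scalar log-likelihood.
#' @export
group_loglik <- function(trait, genotypes, growth, phi, nu2, min_obs = 3L) {
  if (!(nu2 > 0)) stop("singular covariance: nu2 must be positive")
  flat <- lt_flat(trait, min_obs)
  g <- align_genovec(genotypes, flat$ids, trait$ids)
  codes <- sort(unique(g[!is.na(g)]))
  growth <- as.matrix(growth)
  if (nrow(growth) != length(codes)) {
    stop("growth must have one row per observed genotype class (J = ",
         length(codes), ")")
  }
  cls <- rep(-1L, flat$n)
  for (j in seq_along(codes)) cls[!is.na(g) & g == codes[j]] <- j - 1L
  fm_loglik_cpp(flat$y, flat$tt, flat$off, cls, length(codes),
                as.numeric(t(growth)), phi, nu2)
}

#' Fit the functional-mapping model at one marker
#'
#' Maximum-likelihood fit of genotype-specific logistic growth curves with a
#' shared SAD(1) covariance (H1) against a single pooled curve (H0), by
#' multi-start Nelder-Mead simplex on log-transformed positive parameters
#' with \code{(phi, nu2)} profiled out in closed form.
#'
#' @inheritParams group_loglik
#' @param min_class genotype classes with fewer members are dropped at this
#'   marker (the marker is flagged).
#' @param n_starts simplex restarts (first start is seeded from the pooled
#'   fit; extras are jittered).
#' @param maxit,reltol simplex control.
#' @return object of class \code{funmap_fit}: per-class growth parameter
#'   matrix, SAD parameters, H0/H1 log-likelihoods and the LR statistic.
#' @export
fit_marker <- function(trait, genotypes, min_class = 3L, n_starts = 5L,
                       maxit = 2000L, reltol = 1e-8, min_obs = 3L) {
  flat <- lt_flat(trait, min_obs)
  g <- align_genovec(genotypes, flat$ids, trait$ids)
  lab <- relabel_classes(g, min_class)
  if (lab$J < 2) stop("insufficient genotype classes (J = ", lab$J, ")")
  h0 <- pooled_fit(flat, n_starts, maxit, reltol)
  base1 <- rep(h0$theta, lab$J)
  inits <- matrix(rep(base1, each = n_starts), n_starts, 3 * lab$J)
  if (n_starts > 1) {
    inits[-1, ] <- inits[-1, , drop = FALSE] +
      matrix(stats::rnorm(length(base1) * (n_starts - 1), 0, 0.15),
             n_starts - 1, length(base1))
  }
  f1 <- fm_fit_cpp(flat$y, flat$tt, flat$off, lab$cls, lab$J, inits,
                   maxit = maxit, reltol = reltol)
  growth <- matrix(f1$par, lab$J, 3, byrow = TRUE,
                   dimnames = list(lab$codes, c("a", "b", "r")))
  lr_raw <- 2 * (f1$loglik - h0$loglik)
  structure(list(growth = growth,
                 growth0 = stats::setNames(h0$par, c("a", "b", "r")),
                 phi = f1$phi, nu2 = f1$nu2,
                 logl1 = f1$loglik, logl0 = h0$loglik,
                 lr = max(lr_raw, 0), lr_raw = lr_raw,
                 J = lab$J, n_j = stats::setNames(lab$n_j, lab$codes),
                 flagged = lab$merged,
                 converged = f1$converged && h0$converged),
            class = "funmap_fit")
}

#' @export
print.funmap_fit <- function(x, ...) {
  cat("funmap_fit: J =", x$J, " LR =", format(x$lr, digits = 4),
      " phi =", format(x$phi, digits = 3),
      " nu2 =", format(x$nu2, digits = 3), "\n")
  print(round(x$growth, 4))
  invisible(x)
}

#' Likelihood-ratio test for a fitted marker
#'
#' \eqn{LR = 2(\log L_1 - \log L_0)}, clipped at zero, with an advisory
#' nominal p-value from a chi-square with \code{3 (J - 1)} degrees of freedom
#' (the number of growth parameters constrained under H0).  Genome-wide
#' inference should use \code{\link{permutation_threshold}}.
#'
#' @param fit a \code{funmap_fit}.
#' @return list with \code{lr}, \code{df} and \code{p_value}.
#' @export
lr_test <- function(fit) {
  df <- 3 * (fit$J - 1)
  lr <- max(2 * (fit$logl1 - fit$logl0), 0)
  list(lr = lr, df = df, p_value = stats::pchisq(lr, df, lower.tail = FALSE))
}

#' Likelihood-ratio scan over a marker panel
#'
#' Runs the H0/H1 functional-mapping fit at every marker of a genotype
#' matrix.  All markers share a pooled-fit seed; fits run in compiled code.
#'
#' @inheritParams fit_marker
#' @param geno integer matrix, markers x individuals (codes 0/1/2, \code{NA}
#'   missing); column names must match \code{trait$ids} when present.
#' @param n_starts simplex starts per hypothesis per marker.
#' @return object of class \code{funmap_scan} with a per-marker results
#'   table (\code{$table}) and fitted parameter matrices.
#' @export
scan_markers <- function(trait, geno, min_class = 3L, n_starts = 2L,
                         maxit = 1500L, reltol = 1e-8, min_obs = 3L) {
  geno <- as.matrix(geno)
  flat <- lt_flat(trait, min_obs)
  geno <- align_geno(geno, flat$ids)
  m <- nrow(geno)
  lab <- lapply(seq_len(m), function(s) relabel_classes(geno[s, ], min_class))
  J <- vapply(lab, `[[`, integer(1), "J")
  usable <- J >= 2
  if (!any(usable)) stop("no marker has >= 2 genotype classes")
  cls <- t(vapply(lab, `[[`, integer(length(flat$ids)), "cls"))
  h0 <- pooled_fit(flat, max(n_starts, 3L), maxit, reltol)
  sc <- fm_scan_cpp(flat$y, flat$tt, flat$off,
                    cls[usable, , drop = FALSE], J[usable],
                    h0$theta, NULL, nstart = n_starts,
                    maxit = maxit, reltol = reltol)
  Jmax <- max(J[usable])
  ids <- rownames(geno)
  if (is.null(ids)) ids <- paste0("m", seq_len(m))
  lr <- p <- logl0 <- logl1 <- phi <- nu2 <- rep(NA_real_, m)
  lr[usable] <- sc$lr
  logl0[usable] <- sc$logl0
  logl1[usable] <- sc$logl1
  phi[usable] <- sc$phi
  nu2[usable] <- sc$nu2
  p[usable] <- stats::pchisq(sc$lr, 3 * (J[usable] - 1), lower.tail = FALSE)
  par1 <- matrix(NA_real_, m, 3 * Jmax)
  par1[usable, seq_len(ncol(sc$par1))] <- sc$par1
  n_j <- matrix(NA_integer_, m, Jmax)
  for (s in which(usable)) n_j[s, seq_len(J[s])] <- lab[[s]]$n_j
  structure(list(
    table = data.frame(id = ids, J = J, lr = lr, p_nominal = p,
                       p_bonferroni = pmin(p * sum(usable), 1),
                       logl0 = logl0, logl1 = logl1, phi = phi, nu2 = nu2,
                       flagged = vapply(lab, `[[`, logical(1), "merged"),
                       usable = usable, stringsAsFactors = FALSE),
    par1 = par1, n_j = n_j, Jmax = Jmax,
    time_range = range(flat$tt),
    cls = cls, Jv = J, flat = flat, h0_theta = h0$theta),
    class = "funmap_scan")
}

#' @export
print.funmap_scan <- function(x, ...) {
  cat("funmap_scan:", nrow(x$table), "markers,", x$flat$n, "individuals; ",
      "max LR =", format(max(x$table$lr, na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

# Align a per-individual genotype vector to a set of ids: by name when the
# vector is named, positionally (against the trait's id order) otherwise.
align_genovec <- function(genotypes, flat_ids, trait_ids) {
  if (!is.null(names(genotypes))) {
    missing_ids <- setdiff(flat_ids, names(genotypes))
    if (length(missing_ids) > 0) {
      stop("individuals absent from genotype vector: ",
           paste(missing_ids, collapse = ", "))
    }
    genotypes[flat_ids]
  } else {
    if (length(genotypes) != length(trait_ids)) {
      stop("unnamed genotype vector must have one entry per trait individual")
    }
    genotypes[match(flat_ids, trait_ids)]
  }
}

# Match genotype columns to trait individual ids.
align_geno <- function(geno, ids) {
  if (!is.null(colnames(geno))) {
    missing_ids <- setdiff(ids, colnames(geno))
    if (length(missing_ids) > 0) {
      stop("individuals absent from genotype matrix: ",
           paste(missing_ids, collapse = ", "))
    }
    geno <- geno[, ids, drop = FALSE]
  } else if (ncol(geno) != length(ids)) {
    stop("genotype matrix has ", ncol(geno), " columns but the trait has ",
         length(ids), " fitted individuals (and no column names to match by)")
  }
  geno
}

#' Genome-wide LR threshold by permutation
#'
#' Re-pairs phenotype trajectories with genotypes by permuting individuals
#' (each trajectory kept intact), reruns the LR scan for each permutation and
#' records the genome-wide maximum; the threshold is the empirical
#' \code{1 - alpha} quantile of the maxima.  Permutation scans are warm-
#' started from the observed-data fits.
#'
#' @param scan a \code{\link{scan_markers}} result on the observed data.
#' @param B number of permutations (>= 10; >= 100 recommended).
#' @param alpha genome-wide significance level.
#' @param n_starts simplex starts per permuted marker fit; one start (seeded
#'   from the pooled fit, which is the truth under permutation) is the
#'   default.
#' @param use_warm also start each permuted fit from the observed-data H1
#'   estimates.
#' @param maxit,reltol simplex control for permutation fits.
#' @return object of class \code{perm_threshold}: the threshold and the B
#'   genome-wide maxima.
#' @export
permutation_threshold <- function(scan, B = 1000L, alpha = 0.05,
                                  n_starts = 1L, use_warm = FALSE,
                                  maxit = 600L, reltol = 1e-6) {
  if (B < 10) stop("B must be at least 10 permutations")
  if (B < 100) warning("B < 100 permutations gives an unstable threshold")
  flat <- scan$flat
  usable <- scan$table$usable
  cls <- scan$cls[usable, , drop = FALSE]
  Jv <- scan$Jv[usable]
  warm <- if (use_warm) log(scan$par1[usable, , drop = FALSE]) else NULL
  maxima <- numeric(B)
  for (b in seq_len(B)) {
    perm <- sample.int(flat$n)
    sc <- fm_scan_cpp(flat$y, flat$tt, flat$off,
                      cls[, perm, drop = FALSE], Jv,
                      scan$h0_theta, warm, nstart = n_starts,
                      maxit = maxit, reltol = reltol)
    maxima[b] <- max(sc$lr)
  }
  structure(list(threshold = as.numeric(stats::quantile(maxima, 1 - alpha)),
                 maxima = maxima, B = B, alpha = alpha),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat("perm_threshold:", x$B, "permutations, alpha =", x$alpha,
      "-> LR threshold", format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' Age-varying genetic effect curve of a marker
#'
#' The genetic standard deviation at age \eqn{\tau},
#' \eqn{z_s(\tau) = \sqrt{ \frac{1}{n}\sum_j n_j (\mu_j(\tau) -
#' \bar\mu_s(\tau))^2 }} with \eqn{\bar\mu_s(\tau) = \sum_j (n_j/n)
#' \mu_j(\tau)}, using observed genotype-class frequencies.
#'
#' @param fit a \code{\link{fit_marker}} result (or a list with a
#'   \code{growth} matrix and \code{n_j} counts).
#' @param grid common evaluation ages.
#' @param scale \code{"sd"} (genetic standard deviation, the default) or
#'   \code{"variance"}.
#' @return numeric vector \code{z(grid)}, all values >= 0.
#' @export
effect_curve <- function(fit, grid, scale = c("sd", "variance")) {
  scale <- match.arg(scale)
  growth <- fit$growth
  n_j <- fit$n_j
  mu <- vapply(seq_len(nrow(growth)), function(j) {
    logistic_mean(grid, growth[j, 1], growth[j, 2], growth[j, 3])
  }, numeric(length(grid)))
  w <- n_j / sum(n_j)
  mbar <- as.numeric(mu %*% w)
  v <- as.numeric((mu - mbar)^2 %*% w)
  if (scale == "sd") sqrt(v) else v
}

#' Effect curves for every scanned marker
#'
#' @param scan a \code{\link{scan_markers}} result.
#' @param grid common evaluation ages (default: 30 points over the pooled
#'   measurement range).
#' @param markers optional subset (indices or ids).
#' @param scale \code{"sd"} or \code{"variance"} (see
#'   \code{\link{effect_curve}}).
#' @return an \code{effect_curves} matrix (markers x ages) with the grid as
#'   an attribute.
#' @export
effect_curves <- function(scan, grid = NULL, markers = NULL,
                          scale = c("sd", "variance")) {
  if (is.null(grid)) grid <- seq(scan$time_range[1], scan$time_range[2],
                                 length.out = 30)
  tab <- scan$table
  idx <- which(tab$usable)
  if (!is.null(markers)) {
    idx <- if (is.character(markers)) match(markers, tab$id) else markers
  }
  Z <- matrix(NA_real_, length(idx), length(grid),
              dimnames = list(tab$id[idx], signif(grid, 6)))
  for (k in seq_along(idx)) {
    s <- idx[k]
    J <- tab$J[s]
    growth <- matrix(scan$par1[s, seq_len(3 * J)], J, 3, byrow = TRUE)
    Z[k, ] <- effect_curve(list(growth = growth,
                                n_j = scan$n_j[s, seq_len(J)]), grid, scale)
  }
  structure(Z, grid = grid, class = c("effect_curves", "matrix"))
}

#' Phenotypic plasticity trait
#'
#' Per-individual difference between two growth conditions,
#' \code{control - stress}, so that larger values mean stronger suppression
#' of growth by the stress.  Individuals present in only one condition are
#' excluded (with a message).  When the two age grids differ, both
#' trajectories are linearly interpolated onto the sorted union of ages
#' inside the overlapping range.
#'
#' @param control,stress \code{\link{long_trait}} objects sharing individual
#'   ids.
#' @return a \code{long_trait} of plasticity values.
#' @export
plasticity_trait <- function(control, stress) {
  shared <- intersect(control$ids, stress$ids)
  dropped <- setdiff(union(control$ids, stress$ids), shared)
  if (length(dropped) > 0) {
    message(length(dropped), " individual(s) present in only one condition ",
            "excluded: ", paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  if (length(shared) == 0) stop("no shared individuals between conditions")
  times <- values <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    id <- shared[i]
    tc <- control$times[[id]]; yc <- control$values[[id]]
    ts <- stress$times[[id]]; ys <- stress$values[[id]]
    if (length(tc) == length(ts) && all(tc == ts)) {
      times[[i]] <- tc
      values[[i]] <- yc - ys
    } else {
      lo <- max(min(tc), min(ts)); hi <- min(max(tc), max(ts))
      gg <- sort(unique(c(tc[tc >= lo & tc <= hi], ts[ts >= lo & ts <= hi])))
      if (length(gg) < 2) stop("age grids for individual '", id,
                               "' do not overlap")
      times[[i]] <- gg
      values[[i]] <- stats::approx(tc, yc, gg)$y - stats::approx(ts, ys, gg)$y
    }
  }
  names(times) <- names(values) <- shared
  structure(list(ids = shared, times = times, values = values),
            class = "long_trait")
}
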