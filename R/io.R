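#' Read a genotype matrix
#'
#' Reads either a CSV dosage matrix (rows = markers, columns = individuals,
#' header row of individual ids, first column marker ids) or a VCF of
#' biallelic sites with genotypes coded as alt-allele dosage 0/1/2.
#' Multi-allelic VCF records are skipped (with a message) or split according
#' to \code{multiallelic}; missing genotypes become \code{NA}.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"csv"} or \code{"vcf"}.
#' @param multiallelic \code{"skip"} (drop such sites) or \code{"error"}.
#' @return integer matrix markers x individuals with \code{chrom} and
#'   \code{pos} attributes (VCF input).
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "vcf"),
                           multiallelic = c("skip", "error")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    g <- as.matrix(df)
    storage.mode(g) <- "integer"
    return(g)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    if (multiallelic == "error") stop(sum(multi), " multi-allelic site(s) in ", path)
    message("skipping ", sum(multi), " multi-allelic site(s)")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  ids <- vcfR::getID(v)
  if (any(is.na(ids))) {
    ids[is.na(ids)] <- paste0(vcfR::getCHROM(v)[is.na(ids)], "_",
                              vcfR::getPOS(v)[is.na(ids)])
  }
  rownames(dose) <- ids
  attr(dose, "chrom") <- vcfR::getCHROM(v)
  attr(dose, "pos") <- vcfR::getPOS(v)
  dose
}

#' Read longitudinal phenotypes
#'
#' Long-format CSV with columns \code{id}, \code{time}, \code{value} and an
#' optional \code{condition} column; with conditions present one
#' \code{\link{long_trait}} per condition is returned.
#'
#' @param path file path.
#' @return a \code{long_trait}, or a named list of them by condition.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("id", "time", "value") %in% names(df)))
  if ("condition" %in% names(df)) {
    lapply(split(df, df$condition), long_trait)
  } else {
    long_trait(df)
  }
}

#' Check genotype / phenotype individual agreement
#'
#' @param geno genotype matrix with individual column names.
#' @param trait a \code{long_trait}.
#' @return invisibly \code{TRUE}; errors listing offending ids otherwise.
#' @export
check_ids <- function(geno, trait) {
  gids <- colnames(geno)
  only_g <- setdiff(gids, trait$ids)
  only_p <- setdiff(trait$ids, gids)
  if (length(only_g) || length(only_p)) {
    stop("id mismatch between genotypes and phenotypes; genotype-only: ",
         paste(only_g, collapse = ", "), "; phenotype-only: ",
         paste(only_p, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a genotype matrix as a minimal VCF
#'
#' @param geno integer dosage matrix markers x individuals.
#' @param path output path.
#' @param chrom,pos optional marker coordinates (defaults: chromosome
#'   \code{"1"}, positions 1-based marker index).
#' @return invisibly \code{path}.
#' @export
write_vcf <- function(geno, path, chrom = NULL, pos = NULL) {
  m <- nrow(geno)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m)
  gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", m, ncol(geno))
  for (code in 0:2) gt[which(geno == code)] <- gtmap[as.character(code)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(geno)), collapse = "\t")), con)
  body <- cbind(chrom, pos, rownames(geno), "A", "T", ".", "PASS", ".", "GT", gt)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a long_trait as long-format CSV
#'
#' @param trait a \code{long_trait} (or named list of them; names become the
#'   \code{condition} column).
#' @param path output path.
#' @return invisibly \code{path}.
#' @export
write_phenotypes <- function(trait, path) {
  as_df <- function(tr, cond = NULL) {
    df <- data.frame(id = rep(tr$ids, lengths(tr$times)),
                     time = unlist(tr$times, use.names = FALSE),
                     value = unlist(tr$values, use.names = FALSE))
    if (!is.null(cond)) df$condition <- cond
    df
  }
  df <- if (inherits(trait, "long_trait")) as_df(trait) else
    do.call(rbind, Map(as_df, trait, names(trait)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full mapping-to-network pipeline
#'
#' Executes scan -> permutation threshold -> effect curves -> module tree ->
#' layer networks -> export, writing each stage's output plus a manifest
#' (configuration, package version, seed, thresholds) under \code{out_dir}.
#' Stages whose output files already exist are skipped when
#' \code{resume = TRUE}.
#'
#' @param geno genotype matrix (markers x individuals) or path readable by
#'   \code{\link{read_genotypes}}.
#' @param pheno a \code{long_trait} or path readable by
#'   \code{\link{read_phenotypes}}.
#' @param out_dir output directory.
#' @param B permutations for the genome-wide threshold (0 disables).
#' @param alpha genome-wide significance level.
#' @param grid_points evaluation ages for effect curves.
#' @param K_range,leaf_size,Q clustering controls
#'   (\code{\link{build_module_tree}}).
#' @param d_max,K_ind,K_dep network controls (\code{\link{fit_layer}}).
#' @param eps_frac,delta epistasis-classification thresholds.
#' @param seed integer seed fixing all randomness.
#' @param resume skip stages whose outputs exist.
#' @return invisibly, the manifest list.
#' @export
run_fungraph <- function(geno, pheno, out_dir, B = 200, alpha = 0.05,
                         grid_points = 30, K_range = 1:6, leaf_size = 30,
                         Q = 4, d_max = 5, K_ind = 3, K_dep = 3,
                         eps_frac = 0.05, delta = 0.2, seed = 1,
                         resume = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(geno)) geno <- read_genotypes(geno)
  if (is.character(pheno)) pheno <- read_phenotypes(pheno)
  if (!inherits(pheno, "long_trait")) {
    stop("pheno resolves to multiple conditions; pass one condition or a ",
         "plasticity_trait() of two")
  }
  if (!is.null(colnames(geno))) check_ids(geno, pheno)
  config <- list(B = B, alpha = alpha, grid_points = grid_points,
                 K_range = K_range, leaf_size = leaf_size, Q = Q,
                 d_max = d_max, K_ind = K_ind, K_dep = K_dep,
                 eps_frac = eps_frac, delta = delta, seed = seed)
  manifest <- list(package = "fungraph",
                   version = as.character(utils::packageVersion("fungraph")),
                   config = config, stages = list())
  mpath <- file.path(out_dir, "manifest.json")
  save_manifest <- function() jsonlite::write_json(manifest, mpath,
                                                   auto_unbox = TRUE, digits = NA)
  stage_file <- function(name) file.path(out_dir, name)
  set.seed(seed)

  scan_path <- stage_file("scan.tsv")
  curves_path <- stage_file("effect_curves.csv")
  tree_path <- stage_file("module_tree.json")
  run_scan <- !(resume && file.exists(scan_path) && file.exists(curves_path))
  tryCatch({
    if (run_scan) {
      scan <- scan_markers(pheno, geno)
      thr <- NA_real_
      if (B > 0) thr <- permutation_threshold(scan, B = B, alpha = alpha)$threshold
      tab <- scan$table
      if (!is.null(attr(geno, "chrom"))) tab$chrom <- attr(geno, "chrom")
      if (!is.null(attr(geno, "pos"))) tab$pos <- attr(geno, "pos")
      tab$threshold <- thr
      tab$significant <- !is.na(tab$lr) & !is.na(thr) & tab$lr >= thr
      pars <- scan$par1
      colnames(pars) <- paste0(rep(c("a", "b", "r"), scan$Jmax),
                               rep(seq_len(scan$Jmax), each = 3))
      tab <- cbind(tab, round(pars, 6))
      utils::write.table(tab, scan_path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      grid <- seq(scan$time_range[1], scan$time_range[2],
                  length.out = grid_points)
      Z <- effect_curves(scan, grid)
      utils::write.csv(data.frame(id = rownames(Z), unclass(Z),
                                  check.names = FALSE),
                       curves_path, row.names = FALSE)
    } else {
      # resume: reload the scan and curve stages from their outputs
      tab <- utils::read.delim(scan_path)
      thr <- tab$threshold[1]
      Zdf <- utils::read.csv(curves_path, check.names = FALSE)
      Z <- as.matrix(Zdf[, -1, drop = FALSE])
      rownames(Z) <- Zdf$id
      grid <- as.numeric(colnames(Z))
      attr(Z, "grid") <- grid
    }
    manifest$stages$scan <- list(markers = nrow(tab),
                                 usable = sum(tab$usable),
                                 threshold = thr,
                                 significant = sum(tab$significant),
                                 resumed = !run_scan)
    manifest$stages$curves <- list(markers = nrow(Z), grid_points = length(grid))

    tree <- build_module_tree(Z, grid, max_size = leaf_size,
                              K_range = K_range, Q = Q)
    jsonlite::write_json(tree_assignments(tree), tree_path, digits = NA)
    manifest$stages$cluster <-
      list(leaves = length(unique(tree_assignments(tree)$path)))

    net <- network_from_tree(tree, Z, eps_frac = eps_frac, delta = delta,
                             K_ind = K_ind, K_dep = K_dep, d_max = d_max)
    write_network(net, file.path(out_dir, "network"))
    manifest$stages$network <- list(
      layers = length(net$layers),
      edges = sum(vapply(net$layers, igraph::ecount, numeric(1))))
    manifest$complete <- TRUE
  }, error = function(e) {
    manifest$complete <<- FALSE
    manifest$error <<- conditionMessage(e)
    save_manifest()
    stop(e)
  })
  save_manifest()
  invisible(manifest)
}
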