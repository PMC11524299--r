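#' Signed weight of a dependent-effect edge
#'
#' Time-averaged net contribution of a regulator to a target:
#' \eqn{W_{s \leftarrow s'} = D_{ss'}(\tau_T) / (\tau_T - \tau_1)}.
#'
#' @param dependent dependent-effect curve \eqn{D_{ss'}} on \code{grid}.
#' @param grid age grid.
#' @return signed scalar weight.
#' @export
edge_weight <- function(dependent, grid) {
  stopifnot(length(dependent) == length(grid), length(grid) >= 2)
  dependent[length(grid)] / (grid[length(grid)] - grid[1])
}

#' Classify a reciprocal edge pair into an epistasis type
#'
#' Seven qualitative types from the reciprocal weights between loci a and b:
#' with \code{u} the effect of a on b and \code{v} the effect of b on a,
#' both positive and of similar size give symmetric positive epistasis, both
#' positive but unequal asymmetric positive, one positive and one null
#' directional positive; the mirrored rules give the negative types; and
#' opposite signs give altruistic/repressive epistasis (one locus activates
#' the other while being suppressed by it).  Weights with \code{|.| <= eps}
#' count as null; \code{|u - v| <= delta * max(|u|, |v|)} counts as "the
#' same extent".  Exactly one label (possibly \code{"none"}) applies to any
#' pair.
#'
#' @param u effect of a on b (weight of edge a -> b).
#' @param v effect of b on a.
#' @param eps zero threshold (> 0).
#' @param delta relative symmetry tolerance in (0, 1).
#' @return one of \code{"symmetric_positive"}, \code{"asymmetric_positive"},
#'   \code{"directional_positive"}, \code{"symmetric_negative"},
#'   \code{"asymmetric_negative"}, \code{"directional_negative"},
#'   \code{"altruistic_repressive"}, \code{"none"}.
#' @export
classify_epistasis <- function(u, v, eps = 1e-8, delta = 0.2) {
  stopifnot(eps > 0, delta > 0, delta < 1)
  nu <- abs(u) <= eps
  nv <- abs(v) <= eps
  if (nu && nv) return("none")
  if (nu || nv) {
    w <- if (nu) v else u
    return(if (w > 0) "directional_positive" else "directional_negative")
  }
  if (u > 0 && v > 0) {
    return(if (abs(u - v) <= delta * max(u, v)) "symmetric_positive"
           else "asymmetric_positive")
  }
  if (u < 0 && v < 0) {
    return(if (abs(u - v) <= delta * max(-u, -v)) "symmetric_negative"
           else "asymmetric_negative")
  }
  "altruistic_repressive"
}

# Edge table of one fitted layer: one row per regulator -> target pair,
# with the time-averaged signed weight.
layer_edges <- function(layer) {
  rows <- lapply(layer$decomps, function(dc) {
    if (nrow(dc$dependent) == 0) return(NULL)
    data.frame(from = rownames(dc$dependent), to = dc$id,
               weight = apply(dc$dependent, 1, edge_weight, grid = dc$grid),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(from = character(0), to = character(0),
                               weight = numeric(0)) else out
}

#' Assemble the multilayer epistasis network
#'
#' Builds one directed, signed, weighted graph per module-tree node from the
#' fitted ODE decompositions of its children: an edge s' -> s means s'
#' regulates s, with weight the time-averaged dependent effect; nodes carry
#' the time-average of their independent effect curve.  Each reciprocal pair
#' is classified into one of the seven epistasis types with the zero
#' threshold \code{eps = eps_frac * max(|W|)} of its layer.
#'
#' @param tree a \code{\link{build_module_tree}} result (or \code{NULL} for
#'   a single flat layer).
#' @param layer_fits named list of \code{\link{fit_layer}} results, one per
#'   internal tree node (names = node ids); or a single \code{layer_fit}
#'   when \code{tree} is \code{NULL}.
#' @param eps_frac zero threshold as a fraction of the layer's largest
#'   absolute weight.
#' @param delta relative symmetry tolerance for type classification.
#' @return object of class \code{fungraph_network}: a named list of
#'   \code{igraph} layers plus the thresholds used.
#' @export
assemble_network <- function(tree, layer_fits, eps_frac = 0.05, delta = 0.2) {
  if (inherits(layer_fits, "layer_fit")) layer_fits <- list(root = layer_fits)
  node_index <- if (is.null(tree)) NULL else tree_nodes(tree)
  layers <- list()
  for (layer_id in names(layer_fits)) {
    lf <- layer_fits[[layer_id]]
    if (is.null(lf) || length(lf$fits) < 2) {
      warning("layer ", layer_id, " has no usable fit; emitted empty")
      layers[[layer_id]] <- igraph::make_empty_graph(directed = TRUE)
      next
    }
    ids <- names(lf$fits)
    ed <- layer_edges(lf)
    eps <- eps_frac * max(abs(ed$weight), 0)
    if (eps <= 0) eps <- 1e-12
    ind_mean <- vapply(lf$decomps, function(dc) mean(dc$independent), numeric(1))
    g <- igraph::graph_from_data_frame(
      ed, directed = TRUE,
      vertices = data.frame(name = ids, independent_mean = ind_mean[ids]))
    if (nrow(ed) > 0) {
      igraph::E(g)$sign <- ifelse(abs(ed$weight) <= eps, 0L,
                                  ifelse(ed$weight > 0, 1L, -1L))
      wmat <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
      wmat[cbind(ed$from, ed$to)] <- ed$weight
      igraph::E(g)$epistasis_type <- vapply(seq_len(nrow(ed)), function(k) {
        a <- ed$from[k]; b <- ed$to[k]
        classify_epistasis(wmat[a, b], wmat[b, a], eps, delta)
      }, character(1))
    }
    igraph::graph_attr(g, "layer") <- layer_id
    igraph::graph_attr(g, "eps") <- eps
    igraph::graph_attr(g, "delta") <- delta
    layers[[layer_id]] <- g
  }
  structure(list(layers = layers, eps_frac = eps_frac, delta = delta),
            class = "fungraph_network")
}

#' @export
print.fungraph_network <- function(x, ...) {
  cat("fungraph_network:", length(x$layers), "layer(s)\n")
  for (nm in names(x$layers)) {
    g <- x$layers[[nm]]
    cat("  ", nm, ": ", igraph::vcount(g), " nodes, ",
        igraph::ecount(g), " edges\n", sep = "")
  }
  invisible(x)
}

#' Export a multilayer network
#'
#' Writes each layer as GraphML plus a combined edge-list TSV and node table
#' TSV.  Threshold metadata (\code{eps_frac}, \code{delta}, per-layer
#' \code{eps}) is recorded in the node/edge tables' companion JSON.
#'
#' @param net a \code{\link{assemble_network}} result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  edges <- nodes <- list()
  for (nm in names(net$layers)) {
    g <- net$layers[[nm]]
    p <- file.path(dir, paste0("layer_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".graphml"))
    igraph::write_graph(g, p, format = "graphml")
    paths <- c(paths, p)
    if (igraph::ecount(g) > 0) {
      ed <- igraph::as_data_frame(g, what = "edges")
      ed$layer <- nm
      edges[[nm]] <- ed
    }
    if (igraph::vcount(g) > 0) {
      nd <- igraph::as_data_frame(g, what = "vertices")
      nd$layer <- nm
      nodes[[nm]] <- nd
    }
  }
  ep <- file.path(dir, "edges.tsv")
  np <- file.path(dir, "nodes.tsv")
  mp <- file.path(dir, "network_meta.json")
  utils::write.table(do.call(rbind, edges), ep, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(do.call(rbind, nodes), np, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(eps_frac = net$eps_frac, delta = net$delta,
                            layers = lapply(net$layers, function(g)
                              list(eps = igraph::graph_attr(g, "eps")))),
                       mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, ep, np, mp))
}

#' Fit and assemble networks over a module hierarchy
#'
#' Runs \code{\link{fit_layer}} inside every module-tree node with at least
#' two children (top layer: module mean curves; leaf layers: the member
#' effect curves) and assembles the result into a multilayer network.
#'
#' @param tree a \code{\link{build_module_tree}} result.
#' @param curves the effect-curve matrix the tree was built from.
#' @param ... passed to \code{\link{fit_layer}}.
#' @inheritParams assemble_network
#' @return a \code{fungraph_network}.
#' @export
network_from_tree <- function(tree, curves, eps_frac = 0.05, delta = 0.2, ...) {
  curves <- as.matrix(curves)
  grid <- tree$grid
  fits <- list()
  for (node in tree_nodes(tree)) {
    if (length(node$children) >= 2) {
      child_curves <- do.call(rbind, lapply(node$children, `[[`, "mean_curve"))
      rownames(child_curves) <- vapply(node$children, `[[`, character(1), "id")
      fits[[node$id]] <- fit_layer(child_curves, grid, ...)
    } else if (length(node$children) == 0 && node$size >= 2) {
      fits[[node$id]] <- fit_layer(curves[node$members, , drop = FALSE], grid, ...)
    }
  }
  assemble_network(tree, fits, eps_frac, delta)
}
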