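#' Markov clustering of a metabolic network
#'
#' A from-scratch Markov Cluster (MCL) algorithm on the undirected,
#' unit-weight adjacency of the bipartite compound-enzyme graph. Every node
#' gets a self-loop of weight 1; the matrix is column-normalized and then
#' alternates expansion (matrix self-product) with inflation (entrywise
#' power followed by column renormalization), pruning entries below
#' \code{prune} after each inflation, until the largest entrywise change
#' falls below 1e-8 or \code{max_iter} is reached. Clusters are the
#' attractor basins of the converged matrix: attractors are nodes retaining
#' positive self-flow, and each node joins the basin of the attractor with
#' the smallest node index among those attracting it, which makes the result
#' a deterministic partition.
#'
#' @param net a [merge_networks()] / [filter_by_ezs()] result, non-empty.
#' @param inflation inflation exponent, > 1; larger values give finer
#'   clusters. Default 1.5.
#' @param prune entries below this are zeroed after each inflation.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with a warning and \code{converged = FALSE}.
#' @param keep_matrix also return the converged column-stochastic matrix
#'   (field \code{stochastic_matrix}); off by default, it is dense.
#' @return an object of class \code{"mcl_clusters"}: list with
#'   \code{clusters} (list of character node-label vectors), \code{kinds}
#'   (named lookup label -> kind), \code{ec_counts}, \code{intersections}
#'   (filled by [pathway_intersections()]), \code{parameters},
#'   \code{converged} and \code{iterations}.
#' @examples
#' paths <- generate_kgml(n_pathways = 2, ecs_per_pathway = 4,
#'                        shared_fraction = 0, seed = 1)
#' net <- merge_networks(lapply(paths$kgml, parse_kgml))
#' mcl_cluster(net)
#' @export
mcl_cluster <- function(net, inflation = 1.5, prune = 1e-5, max_iter = 200L,
                        keep_matrix = FALSE) {
  stopifnot(inherits(net, "metabolic_network"), inflation > 1)
  labels <- net$nodes$label
  n <- length(labels)
  if (n == 0L) stop("empty network", call. = FALSE)
  kinds <- stats::setNames(net$nodes$kind, labels)

  adj <- matrix(0, n, n, dimnames = list(labels, labels))
  if (nrow(net$edges)) {
    i <- match(net$edges$enzyme, labels)
    j <- match(net$edges$compound, labels)
    adj[cbind(i, j)] <- 1
    adj[cbind(j, i)] <- 1
  }
  diag(adj) <- 1
  m <- normalize_columns(adj)

  converged <- FALSE
  iterations <- 0L
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    expanded <- m %*% m
    inflated <- normalize_columns(expanded^inflation)
    inflated[inflated < prune] <- 0
    inflated <- normalize_columns(inflated)
    delta <- max(abs(inflated - m))
    m <- inflated
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }

  attractors <- which(diag(m) > 0)
  assign_to <- integer(n)
  for (j in seq_len(n)) {
    pull <- attractors[m[attractors, j] > 0]
    assign_to[j] <- if (length(pull)) min(pull) else which.max(m[, j])
  }
  # attractors of one attractor system pull each other: follow the
  # assignment of each basin's attractor so the system collapses to one id
  repeat {
    remapped <- assign_to[assign_to]
    if (identical(remapped, assign_to)) break
    assign_to <- remapped
  }
  ids <- sort(unique(assign_to))
  clusters <- lapply(ids, function(a) labels[assign_to == a])
  names(clusters) <- paste0("cluster_", seq_along(clusters))
  structure(
    list(clusters = clusters,
         kinds = kinds,
         ec_counts = vapply(clusters, function(cl) {
           sum(kinds[cl] == "enzyme")
         }, integer(1)),
         intersections = NULL,
         parameters = list(inflation = inflation, prune = prune,
                           max_iter = max_iter, min_ec = NA_integer_),
         converged = converged,
         iterations = iterations,
         stochastic_matrix = if (keep_matrix) m),
    class = "mcl_clusters"
  )
}

normalize_columns <- function(m) {
  cs <- colSums(m)
  cs[cs == 0] <- 1
  sweep(m, 2, cs, "/")
}

#' @export
print.mcl_clusters <- function(x, ...) {
  cat("<mcl_clusters> ", length(x$clusters), " clusters (inflation ",
      x$parameters$inflation, "), EC counts: ",
      paste(x$ec_counts, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Drop clusters with too few enzymes
#'
#' Retains clusters holding at least \code{min_ec} enzyme nodes; compound
#' nodes do not count toward the threshold, so compound-only clusters are
#' removed whenever \code{min_ec >= 1}. With \code{min_ec = 0} the cluster
#' set is returned unchanged. Intersection rows, if present, are subset
#' accordingly.
#'
#' @param cs an [mcl_cluster()] result.
#' @param min_ec minimum enzyme count per cluster, default 4.
#' @return the filtered \code{mcl_clusters}.
#' @export
filter_clusters <- function(cs, min_ec = 4L) {
  stopifnot(inherits(cs, "mcl_clusters"), min_ec >= 0)
  keep <- cs$ec_counts >= min_ec
  cs$clusters <- cs$clusters[keep]
  cs$ec_counts <- cs$ec_counts[keep]
  if (!is.null(cs$intersections)) {
    cs$intersections <- cs$intersections[keep, , drop = FALSE]
  }
  cs$parameters$min_ec <- as.integer(min_ec)
  cs
}

#' Cluster-by-pathway intersection counts
#'
#' For every cluster and pathway, counts the enzymes of the cluster that
#' belong to the pathway according to the network's membership map. Enzymes
#' belonging to several pathways are counted once per pathway, so a row can
#' sum to more than the cluster's enzyme count.
#'
#' @param cs an [mcl_cluster()] result.
#' @param net the \code{metabolic_network} the clusters came from.
#' @return \code{cs} with its \code{intersections} matrix (clusters x
#'   pathways) filled in.
#' @export
pathway_intersections <- function(cs, net) {
  stopifnot(inherits(cs, "mcl_clusters"), inherits(net, "metabolic_network"))
  pathways <- sort(unique(net$pathway_ids))
  mat <- matrix(0L, length(cs$clusters), length(pathways),
                dimnames = list(names(cs$clusters), pathways))
  for (ci in seq_along(cs$clusters)) {
    ecs <- cs$clusters[[ci]][cs$kinds[cs$clusters[[ci]]] == "enzyme"]
    for (ec in ecs) {
      for (p in net$membership[[ec]]) {
        mat[ci, p] <- mat[ci, p] + 1L
      }
    }
  }
  cs$intersections <- mat
  cs
}

#' Write cluster membership and intersection tables
#'
#' @param cs an \code{mcl_clusters} result.
#' @param path output path for the cluster table (cluster_id, node, kind);
#'   when intersections are present they are written to
#'   \code{<path>.intersections.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_clusters <- function(cs, path) {
  stopifnot(inherits(cs, "mcl_clusters"))
  rows <- do.call(rbind, c(
    list(data.frame(cluster_id = character(0), node = character(0),
                    kind = character(0))),
    lapply(names(cs$clusters), function(id) {
      data.frame(cluster_id = id, node = cs$clusters[[id]],
                 kind = unname(cs$kinds[cs$clusters[[id]]]))
    })))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cs$intersections)) {
    utils::write.table(
      data.frame(cluster_id = rownames(cs$intersections), cs$intersections,
                 check.names = FALSE),
      paste0(path, ".intersections.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
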