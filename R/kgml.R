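#' Parse a KGML pathway file into a bipartite compound-enzyme graph
#'
#' Supports the enzyme-map KGML dialect: a \code{<pathway>} root with
#' \code{name}/\code{title}; \code{<entry>} elements of type \code{enzyme},
#' \code{compound} or \code{map} (maps are ignored); and \code{<reaction>}
#' elements whose \code{id} references the enzyme entry catalyzing them,
#' with \code{<substrate>}/\code{<product>} children referencing compound
#' entries. An enzyme entry naming several space-separated ECs expands to
#' one node per EC. \code{<relation>} elements are ignored: edges come only
#' from reaction substrate/product links, which define the
#' compound-reaction-enzyme network. Node labels are stripped of their
#' \code{ec:}/\code{cpd:} prefixes.
#'
#' @param xml KGML text, a file path, or anything [xml2::read_xml()] accepts.
#' @return an object of class \code{"kgml_pathway"}: a list with
#'   \code{pathway_id}, \code{name}, \code{nodes} (data frame label/kind)
#'   and \code{edges} (data frame enzyme/compound/role/reaction/reversible).
#' @export
parse_kgml <- function(xml) {
  doc <- xml2::read_xml(xml)
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("not a KGML document: no <pathway> root", call. = FALSE)
  pathway_id <- sub("^path:", "", xml2::xml_attr(root, "name"))
  title <- xml2::xml_attr(root, "title")

  entries <- xml2::xml_find_all(root, "entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")
  entry_name <- xml2::xml_attr(entries, "name")
  keep <- entry_type %in% c("enzyme", "compound")
  labels_of <- function(name, type) {
    parts <- strsplit(name, "[[:space:]]+")[[1]]
    sub("^(ec|cpd):", "", parts[nzchar(parts)])
  }
  entry_labels <- stats::setNames(
    lapply(which(keep), function(i) labels_of(entry_name[i], entry_type[i])),
    entry_id[keep])
  entry_kind <- stats::setNames(entry_type[keep], entry_id[keep])

  nodes <- unique(do.call(rbind, c(list(data.frame(label = character(0), kind = character(0))),
    lapply(names(entry_labels), function(id) {
      data.frame(label = entry_labels[[id]], kind = entry_kind[[id]])
    }))))

  reactions <- xml2::xml_find_all(root, "reaction")
  edges <- do.call(rbind, c(
    list(data.frame(enzyme = character(0), compound = character(0),
                    role = character(0), reaction = character(0),
                    reversible = logical(0))),
    lapply(reactions, function(rx) {
      rid <- xml2::xml_attr(rx, "id")
      rname <- xml2::xml_attr(rx, "name")
      reversible <- identical(xml2::xml_attr(rx, "type"), "reversible")
      if (!rid %in% names(entry_labels) ||
          entry_kind[[rid]] != "enzyme") {
        stop("reaction ", rname, " references unknown enzyme entry id ", rid,
             call. = FALSE)
      }
      ecs <- entry_labels[[rid]]
      side <- function(role) {
        refs <- xml2::xml_attr(xml2::xml_find_all(rx, role), "id")
        bad <- !refs %in% names(entry_labels)
        if (any(bad)) {
          stop("reaction ", rname, " references unknown entry id(s) ",
               paste(refs[bad], collapse = ", "), call. = FALSE)
        }
        cpds <- unlist(entry_labels[refs], use.names = FALSE)
        if (length(cpds) == 0L) return(NULL)
        expand.grid(enzyme = ecs, compound = cpds, role = role,
                    stringsAsFactors = FALSE)
      }
      d <- rbind(side("substrate"), side("product"))
      if (is.null(d)) return(NULL)
      d$reaction <- sub("^rn:", "", rname)
      d$reversible <- reversible
      d
    })))
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(pathway_id = pathway_id, name = title,
                 nodes = nodes, edges = edges),
            class = "kgml_pathway")
}

#' Merge pathway graphs into one global metabolic network
#'
#' Union by node label: an EC appearing in several pathways becomes a single
#' enzyme node whose membership records every containing pathway. Edges are
#' deduplicated by (enzyme, compound, role).
#'
#' @param graphs list of [parse_kgml()] results (at least one).
#' @return an object of class \code{"metabolic_network"}: list with
#'   \code{nodes}, \code{edges}, \code{membership} (named list EC ->
#'   character vector of pathway ids) and \code{pathway_ids}.
#' @export
merge_networks <- function(graphs) {
  if (inherits(graphs, "kgml_pathway")) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1L,
            all(vapply(graphs, inherits, logical(1), "kgml_pathway")))
  nodes <- unique(do.call(rbind, lapply(graphs, `[[`, "nodes")))
  edges <- do.call(rbind, lapply(graphs, `[[`, "edges"))
  edges <- edges[!duplicated(edges[, c("enzyme", "compound", "role")]), ,
                 drop = FALSE]
  membership <- list()
  for (g in graphs) {
    for (ec in g$nodes$label[g$nodes$kind == "enzyme"]) {
      membership[[ec]] <- union(membership[[ec]], g$pathway_id)
    }
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, membership = membership,
                 pathway_ids = vapply(graphs, `[[`, character(1), "pathway_id")),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", sum(x$nodes$kind == "enzyme"), " enzymes, ",
      sum(x$nodes$kind == "compound"), " compounds, ",
      nrow(x$edges), " edges, ", length(x$pathway_ids), " pathways\n", sep = "")
  invisible(x)
}

#' Restrict a network to non-depleted enzymes
#'
#' Removes enzyme nodes whose EZS is strictly below \code{min_z} (the
#' boundary value is retained: only scores lower than the threshold are
#' depleted). Enzymes without a score are removed unless
#' \code{keep_unscored}. Compound nodes left without any incident edge are
#' dropped, and memberships are restricted to the surviving enzymes.
#'
#' @param net a [merge_networks()] result.
#' @param scores an [score_metagenome()] result.
#' @param min_z removal threshold, default -1.
#' @param keep_unscored keep enzymes that have no score?
#' @return the filtered \code{metabolic_network}.
#' @export
filter_by_ezs <- function(net, scores, min_z = -1, keep_unscored = FALSE) {
  stopifnot(inherits(net, "metabolic_network"), inherits(scores, "ezs_scores"))
  ezs <- stats::setNames(scores$ezs, scores$ec)
  is_enz <- net$nodes$kind == "enzyme"
  lab <- net$nodes$label
  z <- ezs[lab]
  drop <- is_enz & ((is.na(z) & !keep_unscored) | (!is.na(z) & z < min_z))
  dropped_ecs <- lab[drop]
  nodes <- net$nodes[!drop, , drop = FALSE]
  edges <- net$edges[!net$edges$enzyme %in% dropped_ecs, , drop = FALSE]
  keep_cpd <- nodes$kind != "compound" | nodes$label %in% edges$compound
  nodes <- nodes[keep_cpd, , drop = FALSE]
  membership <- net$membership[intersect(names(net$membership),
                                         nodes$label[nodes$kind == "enzyme"])]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, membership = membership,
                 pathway_ids = net$pathway_ids),
            class = "metabolic_network")
}

#' Write network edge and node tables as TSV
#'
#' @param net a \code{metabolic_network}.
#' @param path output path for the edge table; pathways containing each
#'   enzyme are joined with \code{";"}.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  edges <- net$edges
  edges$pathways <- vapply(edges$enzyme, function(ec) {
    paste(sort(net$membership[[ec]]), collapse = ";")
  }, character(1))
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
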