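#' Configuration for an end-to-end run
#'
#' Bundles the input paths and every tunable threshold of the pipeline. All
#' defaults are the method's standard settings: overrepresentation at EZS >=
#' 2, underrepresentation below -1, network retention at EZS >= -1, clusters
#' kept at >= 4 enzymes, MCL inflation 1.5.
#'
#' @param counts paths to reference count tables (long TSV files), or a
#'   directory containing them.
#' @param queries paths to query count tables.
#' @param kgml_dir optional directory of KGML XML files (\code{.xml});
#'   when given, the network and cluster stages run.
#' @param mapping optional path to an EC -> class TSV (columns ec, class)
#'   for class summaries.
#' @param exclude_pathways pathway ids dropped before merging (e.g. a glycan
#'   exclusion list); matched against the KGML pathway name.
#' @param over,under,min_z,min_ec,inflation thresholds, see above.
#' @param selection distribution-selection rule, see [select_distribution()].
#' @param drop_incomplete,known_ec_set EC filtering, see [annotation_filter()].
#' @return an object of class \code{"ezref_config"}.
#' @export
run_config <- function(counts, queries = character(0), kgml_dir = NULL,
                       mapping = NULL, exclude_pathways = character(0),
                       over = 2, under = -1, min_z = -1, min_ec = 4L,
                       inflation = 1.5, selection = "normal-first",
                       drop_incomplete = TRUE, known_ec_set = character(0)) {
  if (length(counts) == 1L && dir.exists(counts)) {
    counts <- list.files(counts, pattern = "\\.tsv$", full.names = TRUE)
  }
  structure(
    list(counts = counts, queries = queries, kgml_dir = kgml_dir,
         mapping = mapping, exclude_pathways = exclude_pathways,
         over = over, under = under, min_z = min_z,
         min_ec = as.integer(min_ec), inflation = inflation,
         selection = selection,
         filter = annotation_filter(drop_incomplete = drop_incomplete,
                                    known_ec_set = known_ec_set)),
    class = "ezref_config"
  )
}

#' Run the full pipeline: reference, scores, network, clusters
#'
#' Executes the stages in order — build the reference model from the
#' reference count tables, score each query, summarize by class when a
#' mapping is supplied, reconstruct and EZS-filter the metabolic network
#' when KGML files are supplied, and cluster it with MCL — writing every
#' table plus a machine-readable manifest under \code{out_dir}. Outputs are
#' pure functions of (inputs, config): rerunning with identical inputs
#' reproduces byte-identical files.
#'
#' @param config an [run_config()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the manifest and the paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "ezref_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  paths <- character(0)
  stages_done <- character(0)

  # -- reference ---------------------------------------------------------
  model <- stage("build-reference", {
    if (length(config$counts) < 2L) stop("need at least 2 reference tables")
    tables <- lapply(config$counts, function(p) {
      filter_ecs(read_count_table(p), config$filter)
    })
    build_reference(tables, selection = config$selection)
  })
  model_path <- file.path(out_dir, "model.tsv")
  write_reference_model(model, model_path)
  paths <- c(paths, model_path)
  stages_done <- c(stages_done, "build-reference")

  mapping <- NULL
  if (!is.null(config$mapping)) {
    mapping <- stage("mapping",
      utils::read.delim(config$mapping, comment.char = "#",
                        stringsAsFactors = FALSE))
  }

  # -- scoring -----------------------------------------------------------
  all_scores <- list()
  for (qpath in config$queries) {
    sc <- stage("score", {
      q <- filter_ecs(read_count_table(qpath), config$filter)
      score_metagenome(q, model, over = config$over, under = config$under)
    })
    id <- attr(sc, "metagenome_id")
    all_scores[[id]] <- sc
    p <- file.path(out_dir, paste0("scores_", id, ".tsv"))
    write_score_table(sc, p)
    paths <- c(paths, p)
    if (!is.null(mapping)) {
      sm <- summarize_by_class(sc, mapping)
      p2 <- file.path(out_dir, paste0("class_summary_", id, ".tsv"))
      utils::write.table(sm, p2, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p2)
    }
  }
  if (length(config$queries)) stages_done <- c(stages_done, "score")

  # -- network + clusters ------------------------------------------------
  if (!is.null(config$kgml_dir)) {
    net <- stage("network", {
      if (!dir.exists(config$kgml_dir)) {
        stop("kgml directory not found: ", config$kgml_dir)
      }
      files <- list.files(config$kgml_dir, pattern = "\\.xml$",
                          full.names = TRUE)
      if (length(files) == 0L) stop("no .xml files in ", config$kgml_dir)
      graphs <- lapply(files, parse_kgml)
      keep <- !vapply(graphs, `[[`, character(1), "pathway_id") %in%
        config$exclude_pathways
      merge_networks(graphs[keep])
    })
    stages_done <- c(stages_done, "network")
    for (id in names(all_scores)) {
      sub <- filter_by_ezs(net, all_scores[[id]], min_z = config$min_z)
      p <- file.path(out_dir, paste0("network_", id, ".tsv"))
      write_network(sub, p)
      paths <- c(paths, p)
      cs <- stage("cluster", {
        cs <- mcl_cluster(sub, inflation = config$inflation)
        cs <- filter_clusters(cs, min_ec = config$min_ec)
        pathway_intersections(cs, sub)
      })
      p2 <- file.path(out_dir, paste0("clusters_", id, ".tsv"))
      write_clusters(cs, p2)
      paths <- c(paths, p2, paste0(p2, ".intersections.tsv"))
    }
    if (length(all_scores)) stages_done <- c(stages_done, "cluster")
  }

  # -- manifest ----------------------------------------------------------
  inputs <- c(config$counts, config$queries)
  manifest <- list(
    package = "ezref",
    version = as.character(utils::packageVersion("ezref")),
    stages = stages_done,
    options = config[c("over", "under", "min_z", "min_ec", "inflation",
                       "selection")],
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = basename(paths))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, paths = c(paths, manifest_path)))
}
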