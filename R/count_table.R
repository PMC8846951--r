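#' Enzyme annotation count tables
#'
#' A count table holds one metagenome's enzyme annotations: a named vector of
#' non-negative integer counts keyed by EC number, plus the annotation total
#' used as the denominator of per-million rates. The total is always the sum
#' of the retained counts, so it is recomputed whenever rows are dropped.
#'
#' @param counts named non-negative integer vector; names are EC numbers.
#' @param metagenome_id identifier for the sample.
#' @return an object of class \code{"ec_count_table"}.
#' @seealso [read_count_table()], [filter_ecs()], [compute_rates()]
#' @examples
#' count_table(c("1.1.1.35" = 210, "2.8.3.8" = 7), "demo")
#' @export
count_table <- function(counts, metagenome_id = "metagenome") {
  counts <- unlist(counts)
  if (length(counts) == 0L) {
    counts <- stats::setNames(numeric(0), character(0))
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by EC number", call. = FALSE)
  }
  ec_validate(names(counts))
  if (anyDuplicated(names(counts))) {
    stop("duplicate EC keys: ",
         paste(unique(names(counts)[duplicated(names(counts))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(
    list(metagenome_id = as.character(metagenome_id),
         counts = counts,
         total = sum(counts)),
    class = "ec_count_table"
  )
}

#' @export
print.ec_count_table <- function(x, ...) {
  cat("<ec_count_table> ", x$metagenome_id, ": ", length(x$counts),
      " ECs, total ", format(x$total, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Read enzyme count tables from TSV
#'
#' Two dialects are accepted: long format with header \code{ec<TAB>count}
#' (one table), or a wide matrix with an \code{ec} column plus one column per
#' metagenome (a list of tables, one per column). Files are UTF-8, unquoted;
#' lines starting with \code{#} are ignored.
#'
#' @param path path to a TSV file.
#' @param metagenome_id sample identifier for long-format input; defaults to
#'   the file name without extension. Ignored for wide input.
#' @return an \code{ec_count_table}, or a named list of them for wide input.
#' @export
read_count_table <- function(path, metagenome_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!"ec" %in% names(df)) {
    stop("missing 'ec' column in ", path, call. = FALSE)
  }
  parse_counts <- function(values, label) {
    num <- suppressWarnings(as.numeric(values))
    bad <- is.na(num) | num != round(num) | num < 0
    if (any(bad)) {
      stop("non-integer count in column '", label, "' at data line(s) ",
           paste(which(bad), collapse = ", "), " of ", path, call. = FALSE)
    }
    num
  }
  bad_ec <- !ec_is_valid(df$ec)
  if (any(bad_ec)) {
    stop("malformed EC at data line(s) ",
         paste(which(bad_ec), collapse = ", "), " of ", path, ": ",
         paste(unique(df$ec[bad_ec]), collapse = ", "), call. = FALSE)
  }
  value_cols <- setdiff(names(df), "ec")
  if (identical(value_cols, "count")) {
    counts <- stats::setNames(parse_counts(df$count, "count"), df$ec)
    id <- metagenome_id %||% sub("\\.[^.]*$", "", basename(path))
    return(count_table(counts, id))
  }
  if (length(value_cols) == 0L) {
    stop("no count columns in ", path, call. = FALSE)
  }
  tables <- lapply(value_cols, function(col) {
    count_table(stats::setNames(parse_counts(df[[col]], col), df$ec), col)
  })
  stats::setNames(tables, value_cols)
}

#' Write a count table as long-format TSV
#'
#' Inverse of [read_count_table()]: the written file re-reads to an
#' identical table.
#'
#' @param table an \code{ec_count_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "ec_count_table"))
  df <- data.frame(ec = names(table$counts),
                   count = unname(table$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Annotation filter settings
#'
#' \code{min_identity} and \code{max_evalue} describe the thresholds the
#' upstream annotator applied (45\% identity, e-value 1e-4 by default); this
#' package never sees sequences, so they are provenance metadata, recorded in
#' outputs but not applied here. \code{drop_incomplete} governs removal of
#' incomplete EC descriptors such as \code{"1.1.-.-"}; ECs in
#' \code{known_ec_set} are exempt (the "present in KEGG" exemption).
#'
#' @param min_identity percent identity threshold, in [0, 100].
#' @param max_evalue e-value threshold, > 0.
#' @param drop_incomplete drop incomplete EC descriptors?
#' @param known_ec_set character vector of ECs exempt from removal.
#' @return an object of class \code{"annotation_filter"}.
#' @export
annotation_filter <- function(min_identity = 45, max_evalue = 1e-4,
                              drop_incomplete = TRUE,
                              known_ec_set = character(0)) {
  stopifnot(min_identity >= 0, min_identity <= 100, max_evalue > 0)
  structure(
    list(min_identity = min_identity, max_evalue = max_evalue,
         drop_incomplete = isTRUE(drop_incomplete),
         known_ec_set = as.character(known_ec_set)),
    class = "annotation_filter"
  )
}

#' Filter a count table by EC completeness
#'
#' Removes incomplete EC descriptors (any dash field) when the filter says
#' so, except those in the filter's \code{known_ec_set}. The total is
#' recomputed from the surviving rows. The removed rows are attached as
#' attribute \code{"removed"} (a data frame of ec/count) for reporting.
#'
#' @param table an \code{ec_count_table}.
#' @param filter an [annotation_filter()].
#' @return the filtered \code{ec_count_table}.
#' @export
filter_ecs <- function(table, filter = annotation_filter()) {
  stopifnot(inherits(table, "ec_count_table"),
            inherits(filter, "annotation_filter"))
  drop <- rep(FALSE, length(table$counts))
  if (filter$drop_incomplete) {
    drop <- !ec_is_complete(names(table$counts)) &
      !(names(table$counts) %in% filter$known_ec_set)
  }
  removed <- data.frame(ec = names(table$counts)[drop],
                        count = unname(table$counts[drop]))
  out <- count_table(table$counts[!drop], table$metagenome_id)
  attr(out, "removed") <- removed
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
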