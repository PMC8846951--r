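#' Build a reference model from count tables
#'
#' Runs the reference pipeline: per-million rates for every table, selection
#' of the enzymes present (rate > 0) in every reference metagenome, then a
#' distribution fit per shared enzyme with [select_distribution()]. Enzymes
#' whose fit fails outright are excluded and listed in the model's
#' \code{failed} field.
#'
#' @param tables list of at least two [count_table()] objects.
#' @param selection passed to [select_distribution()].
#' @return an object of class \code{"ezs_reference"}: a list with
#'   \code{distributions} (named list of [fitted_distribution()]),
#'   \code{reference_ids}, \code{created}, \code{options} and \code{failed}.
#' @examples
#' spec <- simulation_spec(n_references = 6,
#'   enzymes = data.frame(ec = "1.1.1.35", family = "normal",
#'                        p1 = 2291, p2 = 177), seed = 1)
#' model <- build_reference(simulate_reference(spec))
#' model$distributions[["1.1.1.35"]]
#' @export
build_reference <- function(tables, selection = "normal-first") {
  stopifnot(is.list(tables))
  if (length(tables) < 2L) {
    stop("a reference needs at least 2 count tables", call. = FALSE)
  }
  vectors <- lapply(tables, compute_rates)
  shared <- select_shared_enzymes(vectors)
  if (length(shared) == 0L) stop("no shared enzymes", call. = FALSE)
  rate_matrix <- vapply(vectors, function(v) v$rates[shared],
                        numeric(length(shared)))
  if (length(shared) == 1L) rate_matrix <- matrix(rate_matrix, nrow = 1L)
  rownames(rate_matrix) <- shared
  fits <- list()
  failed <- character(0)
  for (ec in shared) {
    fit <- tryCatch(select_distribution(rate_matrix[ec, ], ec, selection),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failed[ec] <- conditionMessage(fit)
    } else {
      fits[[ec]] <- fit
    }
  }
  if (length(failed)) {
    warning(length(failed), " enzyme(s) excluded for failed fits: ",
            paste(names(failed), collapse = ", "), call. = FALSE)
  }
  structure(
    list(distributions = fits,
         reference_ids = vapply(vectors, function(v) v$metagenome_id,
                                character(1)),
         created = format(Sys.time(), tz = "UTC"),
         options = list(selection = selection),
         failed = failed),
    class = "ezs_reference"
  )
}

#' @export
print.ezs_reference <- function(x, ...) {
  fams <- table(vapply(x$distributions, function(f) f$family, character(1)))
  cat("<ezs_reference> ", length(x$distributions), " enzymes from ",
      length(x$reference_ids), " reference metagenomes\n", sep = "")
  if (length(fams)) {
    cat("  families:", paste(names(fams), fams, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize / restore a reference model
#'
#' The model is written as a TSV (one row per enzyme: ec, family, p1, p2,
#' loglik, aic, ad_statistic, ad_pvalue, n) plus a JSON sidecar
#' (\code{<path>.json}) holding the reference metagenome ids and fitting
#' options. The round trip is lossless for everything needed to score
#' queries; per-candidate diagnostics are not serialized.
#'
#' @param model an \code{ezs_reference}.
#' @param path TSV output path; the sidecar is written next to it.
#' @return \code{write_reference_model()} returns \code{path} invisibly;
#'   \code{read_reference_model()} returns the restored model.
#' @export
write_reference_model <- function(model, path) {
  stopifnot(inherits(model, "ezs_reference"))
  rows <- do.call(rbind, lapply(model$distributions, function(f) {
    data.frame(ec = f$ec, family = f$family, p1 = f$p1, p2 = f$p2,
               loglik = f$loglik, aic = f$aic,
               ad_statistic = f$ad_statistic, ad_pvalue = f$ad_pvalue,
               n = f$n)
  }))
  utils::write.table(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(reference_ids = model$reference_ids, options = model$options),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_reference_model
#' @export
read_reference_model <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(df)), function(i) {
    fitted_distribution(df$ec[i], df$family[i], df$p1[i], df$p2[i],
                        df$loglik[i], df$ad_statistic[i], df$ad_pvalue[i],
                        df$n[i])
  })
  names(fits) <- df$ec
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  structure(
    list(distributions = fits,
         reference_ids = meta$reference_ids %||% character(0),
         created = NA_character_,
         options = as.list(meta$options),
         failed = character(0)),
    class = "ezs_reference"
  )
}
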