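#' Per-million enzyme annotation rates
#'
#' Converts counts to rates \eqn{\lambda_g = y_g / N \times 10^6}{lambda_g =
#' y_g / N * 1e6}, the count of annotations for enzyme \eqn{g} per million
#' annotated enzymes. Under the filtered-total convention (the total is the
#' sum of retained counts) the rates of a table sum exactly to \eqn{10^6}.
#'
#' @param table an [count_table()] with \code{total > 0}.
#' @return an object of class \code{"ec_rate_vector"}: a list with
#'   \code{metagenome_id} and \code{rates}, a named numeric vector.
#' @examples
#' tab <- count_table(c("1.1.1.35" = 5, "2.8.3.8" = 1995), "demo")
#' compute_rates(tab)$rates
#' @export
compute_rates <- function(table) {
  stopifnot(inherits(table, "ec_count_table"))
  if (table$total <= 0) {
    stop("cannot compute rates for '", table$metagenome_id,
         "': annotation total is 0", call. = FALSE)
  }
  structure(
    list(metagenome_id = table$metagenome_id,
         rates = table$counts / table$total * 1e6),
    class = "ec_rate_vector"
  )
}

#' @export
print.ec_rate_vector <- function(x, ...) {
  cat("<ec_rate_vector> ", x$metagenome_id, ": ", length(x$rates),
      " ECs (per million)\n", sep = "")
  invisible(x)
}

#' Enzymes shared by every reference metagenome
#'
#' Returns the ECs with a strictly positive rate in every supplied rate
#' vector. Only these enzymes enter the reference model: positivity in all
#' references guarantees the positive-support families (gamma, lognormal,
#' Weibull) can be fitted.
#'
#' @param vectors a list of [compute_rates()] results (at least two).
#' @return a character vector of EC numbers, sorted.
#' @export
select_shared_enzymes <- function(vectors) {
  stopifnot(is.list(vectors), length(vectors) >= 2L)
  shared <- NULL
  for (v in vectors) {
    stopifnot(inherits(v, "ec_rate_vector"))
    present <- names(v$rates)[v$rates > 0]
    shared <- if (is.null(shared)) present else intersect(shared, present)
  }
  sort(shared)
}
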