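#' Enzyme Commission number helpers
#'
#' EC numbers are dotted four-field identifiers such as \code{"1.1.1.35"}.
#' A field may be a dash (\code{"-"}), marking an incomplete activity
#' descriptor (e.g. \code{"1.1.-.-"}); the final field may carry KEGG's
#' preliminary \code{"n"} prefix (e.g. \code{"3.5.1.n3"}), which still counts
#' as a complete descriptor.
#'
#' @param x character vector of candidate EC strings.
#' @return \code{ec_is_valid()} and \code{ec_is_complete()} return logical
#'   vectors; \code{ec_validate()} returns \code{x} invisibly or stops with
#'   the offending entries.
#' @examples
#' ec_is_valid(c("1.1.1.35", "1.1.1", "2.8.-.-"))
#' ec_is_complete(c("1.1.1.35", "1.1.-.-", "3.5.1.n3"))
#' @export
ec_is_valid <- function(x) {
  grepl("^\\d+\\.(\\d+|-)\\.(\\d+|-)\\.(n?\\d+|-)$", x)
}

#' @rdname ec_is_valid
#' @export
ec_is_complete <- function(x) {
  ec_is_valid(x) & !grepl("-", x, fixed = TRUE)
}

#' @rdname ec_is_valid
#' @export
ec_validate <- function(x) {
  bad <- !ec_is_valid(x)
  if (any(bad)) {
    stop("malformed EC number(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}
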