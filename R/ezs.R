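#' Tail probability of an observed rate under a reference fit
#'
#' Returns \eqn{P = F(\lambda)}, the probability that the reference
#' distribution produces a rate at or below the observed one. Values in the
#' upper tail are computed through the distribution's upper tail
#' (\code{lower.tail = FALSE}) to keep precision near 1.
#'
#' @param fit an [fitted_distribution()].
#' @param lam observed per-million rate, >= 0.
#' @return the lower-tail probability in [0, 1].
#' @export
tail_probability <- function(fit, lam) {
  stopifnot(inherits(fit, "ec_fit"))
  if (any(lam < 0)) stop("rate must be >= 0", call. = FALSE)
  p <- fit_cdf(fit, lam)
  hi <- !is.na(p) & p > 0.5
  if (any(hi)) {
    upper <- switch(fit$family,
      normal    = stats::pnorm(lam[hi], fit$p1, fit$p2, lower.tail = FALSE),
      lognormal = stats::plnorm(lam[hi], fit$p1, fit$p2, lower.tail = FALSE),
      gamma     = stats::pgamma(lam[hi], shape = fit$p1, rate = fit$p2,
                                lower.tail = FALSE),
      weibull   = stats::pweibull(lam[hi], shape = fit$p1, scale = fit$p2,
                                  lower.tail = FALSE))
    p[hi] <- 1 - upper
  }
  p
}

#' Equivalent z-score of a tail probability
#'
#' The equivalent z-score (EZS) is the standard normal quantile
#' \eqn{\Phi^{-1}(P)} of the tail probability, so an enzyme whose rate sits
#' at the reference's 97.72th percentile maps to an EZS of 2 regardless of
#' the family fitted. Probabilities of exactly 0 or 1 are mapped to the
#' finite sentinels -8 / +8 and flagged via attribute \code{"clamped"}.
#'
#' @param p probability in [0, 1] (vectorized).
#' @param clamp absolute cap applied when \code{p} is exactly 0 or 1.
#' @return the EZS, with logical attribute \code{"clamped"}.
#' @examples
#' to_ezs(0.5)     # 0
#' to_ezs(0.9772)  # ~2
#' @export
to_ezs <- function(p, clamp = 8) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("probability outside [0, 1]", call. = FALSE)
  }
  z <- stats::qnorm(p)
  clamped <- !is.na(p) & (p == 0 | p == 1)
  z[clamped] <- sign(z[clamped]) * clamp
  z <- pmin(pmax(z, -clamp), clamp)
  attr(z, "clamped") <- clamped
  z
}

#' Classify an EZS into the over/shared/under categories
#'
#' Overrepresented at \code{ezs >= over}, underrepresented at
#' \code{ezs < under}, shared in between. The boundary choices make an
#' enzyme at exactly the lower threshold survive the network filter, which
#' removes only scores strictly below it.
#'
#' @param ezs numeric EZS values.
#' @param over,under thresholds, defaults 2 and -1; \code{over > under}.
#' @return character vector of categories.
#' @export
classify <- function(ezs, over = 2, under = -1) {
  stopifnot(over > under)
  out <- ifelse(is.na(ezs), "unscored",
         ifelse(ezs >= over, "overrepresented",
         ifelse(ezs < under, "underrepresented", "shared")))
  out
}

#' Score a query metagenome against a reference model
#'
#' Computes the query's per-million rates, then, for every enzyme in the
#' reference model, the tail probability and EZS of the query rate under
#' that enzyme's reference distribution. Reference enzymes absent from the
#' query are scored at rate 0 (for positive-support families that gives
#' \eqn{P = 0}, EZS clamped at -8). Query enzymes with no reference
#' distribution are listed with category \code{"unscored"}, never silently
#' dropped.
#'
#' @param query an [count_table()] with positive total.
#' @param model an \code{ezs_reference}.
#' @param over,under classification thresholds (see [classify()]).
#' @return a data frame of class \code{"ezs_scores"} with columns
#'   \code{ec}, \code{lambda}, \code{p}, \code{ezs}, \code{category},
#'   \code{clamped}; attributes \code{metagenome_id} and \code{thresholds}.
#' @export
score_metagenome <- function(query, model, over = 2, under = -1) {
  stopifnot(inherits(query, "ec_count_table"),
            inherits(model, "ezs_reference"))
  if (length(model$distributions) == 0L) stop("empty reference model", call. = FALSE)
  rates <- compute_rates(query)$rates
  ecs <- names(model$distributions)
  lambda <- ifelse(ecs %in% names(rates), rates[ecs], 0)
  p <- numeric(length(ecs))
  for (i in seq_along(ecs)) {
    p[i] <- tail_probability(model$distributions[[ecs[i]]], lambda[i])
  }
  z <- to_ezs(p)
  scored <- data.frame(
    ec = ecs, lambda = unname(lambda), p = p, ezs = as.numeric(z),
    category = classify(as.numeric(z), over, under),
    clamped = attr(z, "clamped"),
    stringsAsFactors = FALSE)
  extra <- setdiff(names(rates), ecs)
  if (length(extra)) {
    scored <- rbind(scored, data.frame(
      ec = extra, lambda = unname(rates[extra]), p = NA_real_,
      ezs = NA_real_, category = "unscored", clamped = FALSE,
      stringsAsFactors = FALSE))
  }
  rownames(scored) <- NULL
  structure(scored,
            class = c("ezs_scores", "data.frame"),
            metagenome_id = query$metagenome_id,
            thresholds = c(over = over, under = under))
}

#' Summarize EZS scores by functional class
#'
#' Aggregates scored enzymes into functional classes (typically KEGG BRITE
#' B-level classes) and reports, per class, the number of enzymes, the
#' quartiles of the EZS (linear-interpolation quantile convention), and the
#' counts beyond the thresholds. An enzyme mapping to several classes
#' contributes to each; scored enzymes absent from the mapping are pooled
#' under \code{"unclassified"}.
#'
#' @param scores an [score_metagenome()] result.
#' @param mapping a data frame with columns \code{ec} and \code{class}, or
#'   \code{NULL} for no mapping.
#' @return a data frame with one row per class: \code{class}, \code{n},
#'   \code{q1}, \code{median}, \code{q3}, \code{n_over}, \code{n_under}.
#' @export
summarize_by_class <- function(scores, mapping = NULL) {
  stopifnot(inherits(scores, "ezs_scores"))
  th <- attr(scores, "thresholds")
  scored <- scores[scores$category != "unscored", , drop = FALSE]
  if (is.null(mapping) || nrow(mapping) == 0L) {
    mapping <- data.frame(ec = character(0), class = character(0))
  }
  stopifnot(all(c("ec", "class") %in% names(mapping)))
  cls <- merge(scored[, c("ec", "ezs")], mapping, by = "ec", all.x = TRUE)
  cls$class[is.na(cls$class)] <- "unclassified"
  out <- do.call(rbind, lapply(split(cls, cls$class), function(d) {
    q <- stats::quantile(d$ezs, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(class = d$class[1], n = nrow(d),
               q1 = q[1], median = q[2], q3 = q[3],
               n_over = sum(d$ezs >= th["over"]),
               n_under = sum(d$ezs < th["under"]))
  }))
  rownames(out) <- NULL
  out
}

#' Write a score table as TSV
#'
#' Provenance (metagenome id and thresholds) is recorded in \code{#}-prefixed
#' header lines, which [read_count_table()]-style readers skip.
#'
#' @param scores an \code{ezs_scores} data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(inherits(scores, "ezs_scores"))
  th <- attr(scores, "thresholds")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# metagenome_id=", attr(scores, "metagenome_id")),
    paste0("# over=", th["over"], " under=", th["under"])), con)
  utils::write.table(as.data.frame(scores), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
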