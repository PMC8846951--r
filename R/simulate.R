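#' Specification for synthetic reference/query data
#'
#' Describes a simulated study: how many reference metagenomes, which
#' enzymes with which true reference distribution, the per-metagenome
#' annotation totals, and (for queries) the target percentile at which
#' selected enzymes are planted. Totals default to one million so that
#' per-million rates coincide with counts up to rounding, keeping parameter
#' recovery tests sharp.
#'
#' @param n_references number of reference metagenomes, >= 2.
#' @param enzymes data frame with columns \code{ec}, \code{family},
#'   \code{p1}, \code{p2} (see [fit_family] for parameter meanings).
#' @param totals annotation totals, recycled over metagenomes. Default 1e6.
#' @param planted_effects named numeric vector mapping EC -> target
#'   percentile in (0, 1) for [simulate_query()].
#' @param seed integer seed; every generator is a pure function of it.
#' @return an object of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(n_references, enzymes, totals = 1e6,
                            planted_effects = numeric(0), seed = 1L) {
  stopifnot(n_references >= 2,
            is.data.frame(enzymes),
            all(c("ec", "family", "p1", "p2") %in% names(enzymes)),
            all(enzymes$family %in% c("normal", "lognormal", "gamma", "weibull")),
            all(enzymes$p2 > 0), all(totals > 0))
  if (length(planted_effects)) {
    stopifnot(!is.null(names(planted_effects)),
              all(planted_effects > 0 & planted_effects < 1))
  }
  structure(
    list(n_references = as.integer(n_references),
         enzymes = enzymes,
         totals = rep_len(as.numeric(totals), n_references),
         planted_effects = planted_effects,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

draw_rate <- function(family, p1, p2, n = 1L) {
  switch(family,
    normal    = stats::rnorm(n, p1, p2),
    lognormal = stats::rlnorm(n, p1, p2),
    gamma     = stats::rgamma(n, shape = p1, rate = p2),
    weibull   = stats::rweibull(n, shape = p1, scale = p2))
}

# Turn per-million rates into an integer count table: counts are rounded
# rates scaled by the total (floored at 1 so every planted enzyme survives
# shared-enzyme selection), and the remainder of the total goes to a filler
# enzyme so the annotation total is exactly as specified.
rates_to_table <- function(rates, total, id, filler_ec = "9.9.9.9") {
  counts <- pmax(round(rates * total / 1e6), 1)
  filler <- total - sum(counts)
  if (filler > 0) {
    if (filler_ec %in% names(counts)) {
      counts[filler_ec] <- counts[filler_ec] + filler
    } else {
      counts <- c(counts, stats::setNames(filler, filler_ec))
    }
  }
  count_table(counts, id)
}

#' Simulate reference count tables with known distributional truth
#'
#' For each metagenome and enzyme, a rate is drawn from the enzyme's true
#' family, truncated below at 1 per million (so every planted enzyme is
#' present in every reference and shared-enzyme selection keeps it), and
#' converted to an integer count; the remainder of the annotation total is
#' assigned to a filler enzyme. Bitwise-reproducible from the spec's seed.
#'
#' @param spec a [simulation_spec()].
#' @return a list of \code{n_references} [count_table()] objects.
#' @export
simulate_reference <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  lapply(seq_len(spec$n_references), function(m) {
    rates <- vapply(seq_len(nrow(spec$enzymes)), function(i) {
      max(1, draw_rate(spec$enzymes$family[i], spec$enzymes$p1[i],
                       spec$enzymes$p2[i]))
    }, numeric(1))
    names(rates) <- spec$enzymes$ec
    rates_to_table(rates, spec$totals[m], sprintf("ref_%02d", m))
  })
}

#' Simulate a query metagenome with planted atypical enzymes
#'
#' Enzymes named in the spec's \code{planted_effects} get their rate set to
#' the fitted reference distribution's quantile at the target percentile;
#' all other model enzymes are drawn from their fitted reference
#' distribution, so they should score as typical.
#'
#' @param spec a [simulation_spec()] whose \code{planted_effects} keys are
#'   all enzymes of \code{model}.
#' @param model an \code{ezs_reference} (see [build_reference()]).
#' @return a [count_table()] with \code{metagenome_id = "query"}.
#' @export
simulate_query <- function(spec, model) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(model, "ezs_reference"))
  planted <- spec$planted_effects
  missing <- setdiff(names(planted), names(model$distributions))
  if (length(missing)) {
    stop("planted enzymes absent from the model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(spec$seed)
  ecs <- names(model$distributions)
  rates <- vapply(ecs, function(ec) {
    fit <- model$distributions[[ec]]
    if (ec %in% names(planted)) {
      fit_quantile(fit, planted[[ec]])
    } else {
      max(1, fit_random(fit, 1L))
    }
  }, numeric(1))
  rates_to_table(rates, spec$totals[1], "query")
}

#' Generate synthetic KGML pathway files with ground truth
#'
#' Builds \code{n_pathways} well-formed KGML files in the dialect
#' [parse_kgml()] supports. Each pathway is a chain of reactions: enzyme
#' \eqn{j} converts compound \eqn{j} to compound \eqn{j+1}. A fraction of
#' each pathway's enzymes comes from a pool shared by all pathways;
#' compounds are pathway-specific, so pathways connect only through shared
#' enzymes. The returned ground truth makes the generator its own oracle
#' for parse/merge tests.
#'
#' @param n_pathways,ecs_per_pathway positive integers.
#' @param shared_fraction fraction of each pathway's enzymes drawn from the
#'   shared pool, in [0, 1].
#' @param seed integer seed (shuffles enzyme placement within pathways).
#' @return a list with \code{kgml} (character vector of XML documents) and
#'   \code{truth}: \code{membership} (named list EC -> pathway ids),
#'   \code{n_ec_nodes}, \code{n_compound_nodes} and \code{n_edges} expected
#'   after parse + merge.
#' @export
generate_kgml <- function(n_pathways, ecs_per_pathway, shared_fraction,
                          seed = 1L) {
  stopifnot(n_pathways >= 1, ecs_per_pathway >= 1,
            shared_fraction >= 0, shared_fraction <= 1)
  set.seed(seed)
  n_shared <- round(shared_fraction * ecs_per_pathway)
  shared_pool <- sprintf("1.1.1.%d", seq_len(n_shared))
  membership <- list()
  kgml <- character(n_pathways)
  for (p in seq_len(n_pathways)) {
    own <- sprintf("%d.2.1.%d", p, seq_len(ecs_per_pathway - n_shared))
    ecs <- sample(c(shared_pool, own))
    compounds <- sprintf("C%02d%03d", p, seq_len(ecs_per_pathway + 1L))
    pathway_id <- sprintf("ec%05d", p)
    for (ec in ecs) membership[[ec]] <- c(membership[[ec]], pathway_id)

    n_ec <- length(ecs)
    entry_lines <- c(
      sprintf('  <entry id="%d" name="ec:%s" type="enzyme"/>',
              seq_len(n_ec), ecs),
      sprintf('  <entry id="%d" name="cpd:%s" type="compound"/>',
              n_ec + seq_along(compounds), compounds))
    reaction_lines <- vapply(seq_len(n_ec), function(j) {
      type <- if (j %% 2L == 0L) "reversible" else "irreversible"
      paste0(sprintf('  <reaction id="%d" name="rn:R%02d%03d" type="%s">\n',
                     j, p, j, type),
             sprintf('    <substrate id="%d" name="cpd:%s"/>\n',
                     n_ec + j, compounds[j]),
             sprintf('    <product id="%d" name="cpd:%s"/>\n',
                     n_ec + j + 1L, compounds[j + 1L]),
             '  </reaction>')
    }, character(1))
    kgml[p] <- paste0(
      '<?xml version="1.0"?>\n',
      sprintf('<pathway name="path:%s" title="Synthetic pathway %d">\n',
              pathway_id, p),
      paste(c(entry_lines, reaction_lines), collapse = "\n"),
      "\n</pathway>\n")
  }
  list(kgml = kgml,
       truth = list(
         membership = membership,
         n_ec_nodes = length(membership),
         n_compound_nodes = n_pathways * (ecs_per_pathway + 1L),
         n_edges = n_pathways * ecs_per_pathway * 2L))
}

#' The packaged 19-reference worked example
#'
#' Ships the rates of four enzymes (EC 1.1.1.35, 1.14.13.7, 1.3.1.32,
#' 2.8.3.8) across 19 reference ocean-water metagenomes, together with the
#' expected fitted family and parameters per enzyme and, for documentation,
#' the published EZS values of the two Gulf of Mexico query samples (those
#' cannot be recomputed here because the query count tables are not part of
#' the fixture).
#'
#' @return a list with \code{rates} (19 x 4 numeric matrix, rows M1-M19),
#'   \code{expected} (data frame ec/family/p1/p2) and \code{printed_ezs}
#'   (data frame ec/ezs_d18_max/ezs_a04_aaiw).
#' @examples
#' fx <- load_reference_example()
#' fit_normal(fx$rates[, "1.1.1.35"])
#' @export
load_reference_example <- function() {
  rates_path <- system.file("extdata", "reference_rates_19x4.tsv",
                            package = "ezref", mustWork = TRUE)
  expected_path <- system.file("extdata", "reference_rates_expected.tsv",
                               package = "ezref", mustWork = TRUE)
  df <- utils::read.delim(rates_path, check.names = FALSE, comment.char = "#")
  rates <- as.matrix(df[, -1])
  rownames(rates) <- df[[1]]
  expected <- utils::read.delim(expected_path, comment.char = "#",
                                stringsAsFactors = FALSE)
  list(rates = rates,
       expected = expected[, c("ec", "family", "p1", "p2")],
       printed_ezs = expected[, c("ec", "ezs_d18_max", "ezs_a04_aaiw")])
}
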