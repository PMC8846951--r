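# Independent oracles and small fixture builders used across the suite.

# Brute-force grid maximization of the gamma log-likelihood over
# (shape, rate): coarse grid, then two rounds of local refinement.
# Deliberately independent of the package's Newton fitter.
grid_mle_gamma <- function(x, shape_range = c(1e-3, 20), rate_range = c(1e-3, 10)) {
  ll <- function(k, r) sum(dgamma(x, shape = k, rate = r, log = TRUE))
  best <- c(NA, NA)
  for (round in 1:4) {
    ks <- seq(shape_range[1], shape_range[2], length.out = 201)
    rs <- seq(rate_range[1], rate_range[2], length.out = 201)
    vals <- outer(ks, rs, Vectorize(ll))
    idx <- arrayInd(which.max(vals), dim(vals))
    best <- c(ks[idx[1]], rs[idx[2]])
    dk <- diff(shape_range) / 50; dr <- diff(rate_range) / 50
    shape_range <- c(max(1e-6, best[1] - dk), best[1] + dk)
    rate_range <- c(max(1e-6, best[2] - dr), best[2] + dr)
  }
  list(p1 = best[1], p2 = best[2])
}

grid_mle_weibull <- function(x, shape_range = c(1e-3, 20), scale_range = NULL) {
  if (is.null(scale_range)) scale_range <- c(min(x) / 2, max(x) * 2)
  ll <- function(k, s) sum(dweibull(x, shape = k, scale = s, log = TRUE))
  best <- c(NA, NA)
  for (round in 1:4) {
    ks <- seq(shape_range[1], shape_range[2], length.out = 201)
    ss <- seq(scale_range[1], scale_range[2], length.out = 201)
    vals <- outer(ks, ss, Vectorize(ll))
    idx <- arrayInd(which.max(vals), dim(vals))
    best <- c(ks[idx[1]], ss[idx[2]])
    dk <- diff(shape_range) / 50; ds <- diff(scale_range) / 50
    shape_range <- c(max(1e-6, best[1] - dk), best[1] + dk)
    scale_range <- c(max(1e-6, best[2] - ds), best[2] + ds)
  }
  list(p1 = best[1], p2 = best[2])
}

# Count tables whose rates reproduce the packaged 19x4 reference rates
# exactly: with a total of 1e12 and counts = rate * 1e6 every printed rate
# (at most 6 decimals) maps to an integer count.
reference_example_tables <- function() {
  fx <- load_reference_example()
  lapply(rownames(fx$rates), function(m) {
    counts <- round(fx$rates[m, ] * 1e6)
    filler <- 1e12 - sum(counts)
    count_table(c(counts, "9.9.9.9" = filler), m)
  })
}

# A mixed-family enzyme panel with magnitudes like real per-million rates.
enzyme_panel <- function(n) {
  fam <- rep(c("normal", "lognormal", "gamma", "weibull"), length.out = n)
  data.frame(
    ec = sprintf("%d.%d.%d.%d", 1 + (seq_len(n) - 1) %% 6,
                 1 + (seq_len(n) - 1) %% 9, 1, seq_len(n)),
    family = fam,
    p1 = c(normal = 2300, lognormal = 3.3, gamma = 2.7, weibull = 2.5)[fam],
    p2 = c(normal = 150, lognormal = 0.4, gamma = 0.09, weibull = 86)[fam],
    stringsAsFactors = FALSE)
}

# Minimal KGML document: two enzymes A and B sharing one compound C1
# (A --substrate--> C1 <--product-- B).
kgml_two_enzymes_one_compound <- function() {
  paste0(
    '<?xml version="1.0"?>\n',
    '<pathway name="path:ec99999" title="fixture">\n',
    '  <entry id="1" name="ec:1.1.1.1" type="enzyme"/>\n',
    '  <entry id="2" name="ec:2.2.2.2" type="enzyme"/>\n',
    '  <entry id="3" name="cpd:C00001" type="compound"/>\n',
    '  <entry id="4" name="unrelated" type="map"/>\n',
    '  <reaction id="1" name="rn:R00001" type="irreversible">\n',
    '    <substrate id="3" name="cpd:C00001"/>\n',
    '  </reaction>\n',
    '  <reaction id="2" name="rn:R00002" type="reversible">\n',
    '    <product id="3" name="cpd:C00001"/>\n',
    '  </reaction>\n',
    '</pathway>\n')
}

# One enzyme-compound biclique (n_enz enzymes x n_cpd compounds) as a
# kgml_pathway; block index b keeps labels disjoint across bicliques.
biclique_graph_for_test <- function(b, n_enz = 2, n_cpd = 2) {
  ecs <- sprintf("%d.1.1.%d", b, seq_len(n_enz))
  cpds <- sprintf("C%d%03d", b, seq_len(n_cpd))
  edges <- expand.grid(enzyme = ecs, compound = cpds,
                       stringsAsFactors = FALSE)
  edges$role <- "substrate"
  edges$reaction <- sprintf("R%d", b)
  edges$reversible <- FALSE
  structure(list(pathway_id = sprintf("ec%05d", b), name = "biclique",
                 nodes = data.frame(label = c(ecs, cpds),
                                    kind = rep(c("enzyme", "compound"),
                                               c(n_enz, n_cpd))),
                 edges = edges),
            class = "kgml_pathway")
}

# Disjoint bicliques merged into a metabolic_network; the component split
# is the clustering ground truth.
biclique_network <- function(n_enz = 2, n_cpd = 2, n_blocks = 2) {
  merge_networks(lapply(seq_len(n_blocks), biclique_graph_for_test,
                        n_enz = n_enz, n_cpd = n_cpd))
}

# Draw from a fitted reference distribution without touching the package's
# internal helpers.
fit_random_for_test <- function(fit, n) {
  switch(fit$family,
    normal    = rnorm(n, fit$p1, fit$p2),
    lognormal = rlnorm(n, fit$p1, fit$p2),
    gamma     = rgamma(n, shape = fit$p1, rate = fit$p2),
    weibull   = rweibull(n, shape = fit$p1, scale = fit$p2))
}

scores_from <- function(ec, ezs, id = "test") {
  structure(
    data.frame(ec = ec, lambda = NA_real_, p = NA_real_, ezs = ezs,
               category = classify(ezs), clamped = FALSE,
               stringsAsFactors = FALSE),
    class = c("ezs_scores", "data.frame"),
    metagenome_id = id, thresholds = c(over = 2, under = -1))
}
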