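test_that("drug-cancer network has one edge per approved association", {
  net <- build_drug_cancer_network(fixture_catalog())
  expect_equal(nrow(net$drugs), 150)
  expect_equal(nrow(net$cancers), 33)
  expect_equal(nrow(net$edges), 248)
  expect_equal(nrow(net$drugs) + nrow(net$cancers), 183)
  # edge endpoints belong to the node sets; no duplicates
  expect_true(all(net$edges$drug %in% net$drugs$name))
  expect_true(all(net$edges$cancer %in% net$cancers$name))
  expect_equal(anyDuplicated(net$edges), 0L)
})

test_that("a drug with two indications yields a 3-node, 2-edge network", {
  cat1 <- toy_catalog(list(list(name = "D1", indications = c("A", "B"),
                                targets = "G1")))
  net <- build_drug_cancer_network(cat1)
  expect_equal(nrow(net$drugs) + nrow(net$cancers), 3)
  expect_equal(nrow(net$edges), 2)
})

test_that("bipartite edge count equals the per-drug indication recount", {
  for (seed in 1:5) {
    cat_s <- generate_catalog(catalog_spec(n_drugs = 40, n_cancers = 8,
                                           seed = seed))
    net <- build_drug_cancer_network(cat_s)
    # brute-force recount over unique per-drug indications
    expect_equal(nrow(net$edges),
                 sum(vapply(cat_s$drugs$indications,
                            function(i) length(unique(i)), integer(1))))
  }
})

test_that("tripartite network restricts to targeted drugs and gene targets", {
  tri <- build_cancer_drug_target_network(fixture_catalog())
  expect_equal(nrow(tri$drugs), 89)
  expect_equal(nrow(tri$targets), 102)
  expect_equal(nrow(tri$cancers), 23)
  expect_equal(nrow(tri$drug_cancer), 118)
  expect_equal(nrow(tri$drug_target), 195)
  # every target node has at least one incident edge
  expect_setequal(tri$targets$name, unique(tri$drug_target$target))

  # drug-target edges equal the summed gene-target sets of targeted drugs
  drugs <- fixture_catalog()$drugs
  targeted <- drugs[drugs$category == "targeted", ]
  expect_equal(nrow(tri$drug_target),
               sum(vapply(targeted$target_tokens,
                          function(t) length(gene_targets(t)), integer(1))))
})

test_that("a catalog without targeted drugs gives an empty tripartite network", {
  cat0 <- toy_catalog(list(list(name = "D1", category = "cytotoxic",
                                indications = "A", targets = "DNA synthesis")))
  tri <- build_cancer_drug_target_network(cat0)
  expect_equal(nrow(tri$drugs), 0)
  expect_equal(nrow(tri$targets), 0)
  expect_equal(nrow(tri$drug_cancer) + nrow(tri$drug_target), 0)
})

test_that("degree summaries match the published drug and cancer statistics", {
  cat150 <- fixture_catalog()
  net <- build_drug_cancer_network(cat150)
  dd <- degree_summary(net, "drug")
  expect_equal(round(dd$mean, 2), 1.65)
  expect_equal(dd$min, 1L)
  expect_equal(dd$max, 11L)
  expect_gt(dd$skewness, 0)  # strongly right-skewed
  cd <- degree_summary(net, "cancer")
  expect_equal(round(cd$mean, 2), 7.52)
  expect_equal(cd$max, 40L)
  # the most widely indicated drug treats 11 cancer types
  expect_equal(names(which.max(dd$degrees)), "Doxorubicin hydrochloride")
})

test_that("tripartite drug nodes support per-edge-type degrees", {
  tri <- build_cancer_drug_target_network(fixture_catalog())
  tdeg <- degree_summary(tri, "drug", edge_type = "drug-target")
  expect_equal(round(tdeg$mean, 2), 2.19)
  expect_equal(tdeg$max, 18L)  # regorafenib
  cdeg <- degree_summary(tri, "drug", edge_type = "drug-cancer")
  expect_equal(round(cdeg$mean, 2), 1.33)
  expect_equal(cdeg$max, 4L)
  gdeg <- degree_summary(tri, "target")
  expect_equal(round(gdeg$mean, 2), 1.91)
  expect_equal(gdeg$max, 7L)  # EGFR and KDR
  expect_setequal(names(gdeg$degrees)[gdeg$degrees == 7], c("EGFR", "KDR"))
})

test_that("degrees behave on a star graph and ignore node order", {
  star <- toy_catalog(list(list(name = "Hub",
                                indications = paste0("C", 1:6),
                                targets = "G1")))
  net <- build_drug_cancer_network(star)
  expect_equal(unname(degree_summary(net, "drug")$degrees), 6L)
  expect_equal(unname(degree_summary(net, "cancer")$degrees), rep(1L, 6))

  cat150 <- fixture_catalog()
  net150 <- build_drug_cancer_network(cat150)
  perm <- cat150
  perm$drugs <- cat150$drugs[withr::with_seed(3, sample.int(150)), ]
  netp <- build_drug_cancer_network(perm)
  nm <- net150$drugs$name
  expect_equal(degree_summary(netp, "drug")$degrees[nm],
               degree_summary(net150, "drug")$degrees[nm])
  expect_error(degree_summary(net150, "drug", "NotADrug"), "not of class")
})

test_that("degree breakdown reproduces the published bins and checks partitions", {
  net <- build_drug_cancer_network(fixture_catalog())
  drug_bins <- degree_breakdown(net, "drug",
    list(`1` = function(d) d == 1, `2` = function(d) d == 2,
         `3+` = function(d) d >= 3))
  expect_equal(drug_bins$n, c(105, 24, 21))
  cancer_bins <- degree_breakdown(net, "cancer",
    list(`1` = function(d) d == 1,
         `2-9` = function(d) d >= 2 & d < 10,
         `10+` = function(d) d >= 10))
  expect_equal(cancer_bins$n, c(11, 12, 10))
  expect_error(
    degree_breakdown(net, "drug", list(a = function(d) d >= 1,
                                       b = function(d) d >= 2)),
    "overlapping")
  expect_error(
    degree_breakdown(net, "drug", list(a = function(d) d == 1)),
    "do not cover")
  # empty network gives zero counts
  empty <- structure(list(drugs = tibble::tibble(name = character(0),
                                                 category = character(0)),
                          cancers = tibble::tibble(name = character(0)),
                          edges = tibble::tibble(drug = character(0),
                                                 cancer = character(0))),
                     class = "od_bipartite")
  expect_equal(degree_breakdown(empty, "drug",
                                list(any = function(d) TRUE))$n, 0)
})

test_that("KS comparison equals the brute-force ECDF gap and handles ties", {
  expect_equal(compare_degree_distributions(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(compare_degree_distributions(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  withr::with_seed(11, {
    for (i in 1:20) {
      a <- sample(1:6, sample(3:50, 1), replace = TRUE)
      b <- sample(1:8, sample(3:50, 1), replace = TRUE)
      expect_equal(compare_degree_distributions(a, b)$statistic,
                   ks_stat_brute(a, b), tolerance = 1e-12)
    }
  })
  expect_error(compare_degree_distributions(numeric(0), 1), "non-empty")
})

test_that("cytotoxic drugs treat more cancers than targeted drugs", {
  cat150 <- fixture_catalog()
  net <- build_drug_cancer_network(cat150)
  cyt <- degree_summary(net, "drug",
    cat150$drugs$name[cat150$drugs$category == "cytotoxic"])
  tgt <- degree_summary(net, "drug",
    cat150$drugs$name[cat150$drugs$category == "targeted"])
  expect_equal(round(cyt$mean, 2), 2.13)
  expect_equal(round(tgt$mean, 2), 1.33)
  cmp <- compare_degree_distributions(cyt$degrees, tgt$degrees)
  expect_lt(cmp$p_value, 0.10)
  # the published one-sided tail of the same comparison
  one_sided <- compare_degree_distributions(cyt$degrees, tgt$degrees,
                                            alternative = "less")
  expect_equal(one_sided$p_value, 0.0378, tolerance = 0.01)
})

test_that("edge-TSV export round-trips and other formats are well-formed", {
  net <- build_drug_cancer_network(fixture_catalog())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "edge-tsv")
  back <- import_network_edges(tsv)
  expect_equal(nrow(back), 248)
  expect_setequal(paste(back$source, back$target),
                  paste(net$edges$drug, net$edges$cancer))
  expect_true(all(back$edge_type == "drug-cancer"))

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_length(readLines(sif), 248)

  gml <- withr::local_tempfile(fileext = ".graphml")
  tri <- build_cancer_drug_target_network(fixture_catalog())
  export_network(tri, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 214)
  expect_equal(igraph::ecount(g), 313)
  expect_setequal(unique(igraph::V(g)$class), c("drug", "target", "cancer"))

  expect_error(export_network(net, tsv, "dot"), "must be one of")
})
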