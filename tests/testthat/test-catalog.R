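test_that("packaged catalog loads with 150 validated drugs", {
  cat150 <- fixture_catalog()
  expect_s3_class(cat150, "od_catalog")
  expect_equal(nrow(cat150$drugs), 150)
  expect_equal(nrow(cat150$cancers), 33)
  expect_equal(nrow(cat150$annotations), 102)
  expect_true(all(cat150$drugs$approval_year >= 1949 &
                  cat150$drugs$approval_year <= 2014))
  expect_true(all(unlist(cat150$drugs$indications) %in% cat150$cancers$name))
})

test_that("a hand-written toy file round-trips field values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  cpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "name\tapproval_year\tcategory\tindications\ttargets\tdelivery",
    "DrugA\t1999\tcytotoxic\tLeukemia\tDNA synthesis\tsingle",
    "DrugB\t2005\ttargeted\tLeukemia; Lymphoma\tEGFR; KDR\tboth",
    "DrugC\t2010\ttargeted\tLymphoma\tEGFR\tcombination"), path)
  writeLines(c("name\tabbreviation", "Leukemia\tLEU", "Lymphoma\tLYM"), cpath)
  cat3 <- load_catalog(path, cpath)
  expect_equal(cat3$drugs$name, c("DrugA", "DrugB", "DrugC"))
  expect_equal(cat3$drugs$approval_year, c(1999L, 2005L, 2010L))
  expect_equal(cat3$drugs$indications[[2]], c("Leukemia", "Lymphoma"))
  expect_equal(cat3$drugs$target_tokens[[2]], c("EGFR", "KDR"))
  expect_equal(cat3$drugs$delivery, c("single", "both", "combination"))
})

test_that("validation names the offending row", {
  base <- list(name = "DrugA", year = 2000, category = "targeted",
               indications = "Leukemia", targets = "EGFR",
               delivery = "single")
  mk <- function(...) {
    upd <- list(...)
    d <- base
    for (nm in names(upd)) d[[nm]] <- upd[[nm]]
    toy_catalog(list(d), cancer_names = "Leukemia")
  }
  expect_error(mk(category = "cytotox"), "DrugA.*cytotox")
  expect_error(mk(delivery = "oral"), "DrugA.*oral")
  expect_error(mk(indications = "Gout"), "DrugA.*Gout")
  expect_error(mk(indications = character(0)), "no indication")
  expect_error(
    toy_catalog(list(base, base), cancer_names = "Leukemia"),
    "duplicate drug"
  )
  # missing column in the file loader
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("name\tapproval_year", path)
  expect_error(load_catalog(path, path), "missing column")
})

test_that("target token parsing preserves order, case and mechanism phrases", {
  expect_equal(parse_target_tokens("TUBA4A; TUBB"), c("TUBA4A", "TUBB"))
  expect_equal(parse_target_tokens("CD33; DNA synthesis"),
               c("CD33", "DNA synthesis"))
  expect_equal(parse_target_tokens(""), character(0))
  expect_equal(parse_target_tokens(NA_character_), character(0))
  expect_equal(parse_target_tokens(" EGFR ;  KDR "), c("EGFR", "KDR"))
})

test_that("gene targets drop mechanism tokens and deduplicate", {
  cat150 <- fixture_catalog()
  drugs <- cat150$drugs
  tok <- function(nm) drugs$target_tokens[[which(drugs$name == nm)]]
  expect_equal(gene_targets(tok("Gemtuzumab ozogamicin")), "CD33")
  expect_length(gene_targets(tok("Regorafenib")), 18)
  expect_equal(gene_targets(tok("Mitotane")), character(0))
  # case-insensitive mechanism matching, dedup
  expect_equal(gene_targets(c("EGFR", "dna synthesis", "EGFR")), "EGFR")
  # subset property: gene targets are always a subset of the raw tokens
  for (t in drugs$target_tokens) {
    expect_true(all(gene_targets(t) %in% t))
  }
  # the curated target universe of the targeted drugs
  expect_equal(dplyr::n_distinct(gene_targets(cat150)$gene), 102)
})

test_that("catalog summary counts drugs by category, year, delivery, period", {
  cat150 <- fixture_catalog()
  s <- summarize_catalog(cat150)
  expect_equal(s$n_total, 150)
  expect_equal(s$n_cytotoxic + s$n_targeted, s$n_total)
  expect_equal(unname(s$counts_by_delivery), c(96L, 22L, 32L))
  expect_equal(sum(s$counts_by_delivery), s$n_total)
  expect_equal(sum(s$counts_by_year$cytotoxic + s$counts_by_year$targeted),
               s$n_total)
  s2 <- summarize_catalog(cat150, periods = list(c(1991, 2014)))
  expect_equal(s2$counts_by_period$n, 116)
})

test_that("catalog summary is invariant to row order and handles empty input", {
  cat150 <- fixture_catalog()
  shuffled <- cat150
  perm <- withr::with_seed(7, sample.int(nrow(cat150$drugs)))
  shuffled$drugs <- cat150$drugs[perm, ]
  expect_equal(summarize_catalog(shuffled)$counts_by_delivery,
               summarize_catalog(cat150)$counts_by_delivery)
  expect_equal(summarize_catalog(shuffled)$counts_by_period,
               summarize_catalog(cat150)$counts_by_period)

  empty <- new_catalog(
    tibble::tibble(name = character(0), approval_year = integer(0),
                   category = character(0), indications = list(),
                   target_tokens = list(), delivery = character(0)),
    tibble::tibble(name = character(0), abbreviation = character(0)))
  se <- summarize_catalog(empty)
  expect_equal(se$n_total, 0)
  expect_equal(unname(se$counts_by_delivery), c(0L, 0L, 0L))
})

test_that("delivery correlation matches a direct Pearson evaluation", {
  # five-year toy catalog built by hand: annual targeted counts 2,0,1,3,1;
  # single-delivery counts 1,1,0,3,1
  spec <- list(
    c(2000, "targeted", "single"), c(2000, "targeted", "both"),
    c(2001, "cytotoxic", "single"),
    c(2002, "targeted", "combination"),
    c(2003, "targeted", "single"), c(2003, "targeted", "single"),
    c(2003, "targeted", "both"), c(2003, "cytotoxic", "single"),
    c(2004, "targeted", "single")
  )
  drugs <- lapply(seq_along(spec), function(i) {
    list(name = paste0("D", i), year = as.integer(spec[[i]][1]),
         category = spec[[i]][2], indications = list("Leukemia"),
         targets = "EGFR", delivery = spec[[i]][3])
  })
  cat9 <- toy_catalog(drugs, "Leukemia")
  got <- delivery_correlation(cat9, "targeted", "single")
  tser <- c(2, 0, 1, 3, 1)
  sser <- c(1, 1, 0, 3, 1)
  expect_equal(got$r, pearson_direct(tser, sser), tolerance = 1e-12)
  expect_equal(got$n_years, 5)
  expect_equal(delivery_correlation(cat9, "cytotoxic", "combination")$r,
               pearson_direct(c(0, 1, 0, 1, 0), c(0, 0, 1, 0, 0)),
               tolerance = 1e-12)
})

test_that("a constant annual series is a degenerate input", {
  drugs <- lapply(1:3, function(i) {
    list(name = paste0("D", i), year = 1999L + i, category = "targeted",
         indications = list("Leukemia"), targets = "EGFR",
         delivery = "single")
  })
  cat3 <- toy_catalog(drugs, "Leukemia")
  expect_error(delivery_correlation(cat3, "cytotoxic", "single"), "degenerate")
})

test_that("targeted drugs correlate with single-agent delivery on the fixture", {
  got <- delivery_correlation(fixture_catalog(), "targeted", "single")
  expect_equal(got$r, 0.92, tolerance = 0.02)
  expect_lt(got$p, 1e-20)
  expect_equal(got$n_years, 66)
})

test_that("annotation summary reproduces the location and family breakdown", {
  ann <- annotation_summary(fixture_catalog())
  loc <- ann$by_location
  expect_equal(loc$n[loc$location == "plasma membrane"], 45L)
  expect_equal(loc$pct[loc$location == "plasma membrane"], 44)
  expect_equal(sort(loc$n, decreasing = TRUE), c(45L, 27L, 23L, 7L))
  expect_equal(sum(loc$n), 102L)
  fam <- ann$by_family
  expect_equal(fam$n[fam$family == "Enzyme"], 58L)
  expect_equal(fam$pct[fam$family == "Enzyme"], 57)
  expect_equal(fam$n[fam$family == "Receptor"], 27L)
  # percentages round half away from zero (23/102 = 22.5% prints as 23%)
  expect_equal(loc$pct[loc$location == "nucleus"], 23)
})
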