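# shared fixtures: the packaged 1949-2014 catalog (loaded once per session)
# and small hand-built catalogs used across test files

fixture_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- load_catalog(od_example("drugs.tsv"), od_example("cancers.tsv"),
                             od_example("target_annotations.tsv"))
    }
    cache
  }
})

# minimal catalog builder: drugs is a list of lists with fields
# name/year/category/indications/targets/delivery
toy_catalog <- function(drugs, cancer_names = NULL) {
  cancer_names <- cancer_names %||%
    sort(unique(unlist(lapply(drugs, `[[`, "indications"))))
  new_catalog(
    drugs = tibble::tibble(
      name = vapply(drugs, `[[`, character(1), "name"),
      approval_year = vapply(drugs, function(d) as.integer(d$year %||% 2000L),
                             integer(1)),
      category = vapply(drugs, function(d) d$category %||% "targeted",
                        character(1)),
      indications = lapply(drugs, `[[`, "indications"),
      target_tokens = lapply(drugs, function(d) d$targets %||% character(0)),
      delivery = vapply(drugs, function(d) d$delivery %||% "single",
                        character(1))
    ),
    cancers = tibble::tibble(
      name = cancer_names,
      abbreviation = make.unique(toupper(substr(cancer_names, 1, 6)))
    )
  )
}

`%||%` <- rlang::`%||%`

# independent closed-form Pearson correlation (spreadsheet-style)
pearson_direct <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# independent brute-force two-sample KS statistic: max ECDF gap evaluated
# at every observed point
ks_stat_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# exhaustive upper-tail hypergeometric probability from the mass function,
# via choose() only
hyper_upper_brute <- function(k, n, K, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
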