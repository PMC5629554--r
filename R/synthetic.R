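#' Integer count distribution for the synthetic generators
#'
#' Two families are supported: `"geometric"` — a shifted geometric
#' `1 + Geom(prob)` (right-skewed, matching the observed degree
#' distributions), parameterised by its mean (`mean = 1/prob >= 1`); and
#' `"fixed"` — the constant `k`.
#'
#' @param name `"geometric"` or `"fixed"`.
#' @param mean Mean of the shifted geometric (>= 1).
#' @param k Constant for the fixed distribution.
#' @return A `count_dist` specification list.
#' @export
#' @examples
#' count_dist("geometric", mean = 1.65)
#' count_dist("fixed", k = 1)
count_dist <- function(name = c("geometric", "fixed"), mean = NULL, k = NULL) {
  name <- rlang::arg_match(name)
  if (name == "geometric") {
    if (is.null(mean) || mean < 1) abort("geometric count_dist needs mean >= 1")
    structure(list(name = name, mean = mean, prob = 1 / mean),
              class = "count_dist")
  } else {
    if (is.null(k) || k < 0) abort("fixed count_dist needs k >= 0")
    structure(list(name = name, k = as.integer(k)), class = "count_dist")
  }
}

draw_counts <- function(dist, n, max = Inf) {
  stopifnot(inherits(dist, "count_dist"))
  if (dist$name == "fixed") {
    if (dist$k > max) {
      abort(sprintf("infeasible spec: fixed count %d exceeds the available %d",
                    dist$k, max))
    }
    return(rep(dist$k, n))
  }
  pmin(1L + rgeom(n, dist$prob), max)
}

#' Specification for a synthetic drug catalog
#'
#' Defaults mirror the curated 1949-2014 catalog: 150 drugs of which a
#' fraction 89/150 are targeted, 102 candidate gene targets, 33 cancer
#' classes, shifted-geometric indications per drug with mean 1.65 and
#' targets per targeted drug with mean 2.19.
#'
#' @param n_drugs,n_targets,n_cancers Pool sizes.
#' @param p_targeted Probability that a drug is targeted.
#' @param targets_per_drug,indications_per_drug [count_dist()] specifications
#'   (indications must have support >= 1).
#' @param year_range Closed interval of approval years.
#' @param seed Integer seed driving all draws.
#' @return A `catalog_spec` list.
#' @export
catalog_spec <- function(n_drugs = 150, n_targets = 102, n_cancers = 33,
                         p_targeted = 89 / 150,
                         targets_per_drug = count_dist("geometric", mean = 2.19),
                         indications_per_drug = count_dist("geometric", mean = 1.65),
                         year_range = c(1949, 2014), seed = 1L) {
  if (p_targeted < 0 || p_targeted > 1) abort("p_targeted must be in [0, 1]")
  if (indications_per_drug$name == "fixed" && indications_per_drug$k < 1) {
    abort("indications_per_drug must have support >= 1")
  }
  structure(list(n_drugs = n_drugs, n_targets = n_targets,
                 n_cancers = n_cancers, p_targeted = p_targeted,
                 targets_per_drug = targets_per_drug,
                 indications_per_drug = indications_per_drug,
                 year_range = year_range, seed = as.integer(seed)),
            class = "catalog_spec")
}

#' Generate a synthetic catalog with known structure
#'
#' Produces a fully validated catalog with deterministic template names
#' (`DRUG0001`, `GENE0001`, `CANCER01`). Cytotoxic drugs receive a mechanism
#' token and occasionally a gene target; targeted drugs receive gene targets
#' only. Identical spec (including seed) gives an identical catalog.
#'
#' @param spec A [catalog_spec()].
#' @return An `od_catalog`.
#' @export
#' @examples
#' generate_catalog(catalog_spec(n_drugs = 10, n_cancers = 5, seed = 42))
generate_catalog <- function(spec) {
  stopifnot(inherits(spec, "catalog_spec"))
  withr::with_seed(spec$seed, {
    cancers <- tibble::tibble(
      name = sprintf("CANCER%02d", seq_len(spec$n_cancers)),
      abbreviation = sprintf("C%02d", seq_len(spec$n_cancers))
    )
    genes <- sprintf("GENE%04d", seq_len(spec$n_targets))
    n <- spec$n_drugs
    targeted <- runif(n) < spec$p_targeted
    n_ind <- draw_counts(spec$indications_per_drug, n, max = spec$n_cancers)
    n_tgt <- draw_counts(spec$targets_per_drug, n, max = spec$n_targets)
    drugs <- tibble::tibble(
      name = sprintf("DRUG%04d", seq_len(n)),
      approval_year = as.integer(
        sample(seq(spec$year_range[1], spec$year_range[2]), n, replace = TRUE)),
      category = ifelse(targeted, "targeted", "cytotoxic"),
      indications = lapply(n_ind, function(k) sample(cancers$name, k)),
      target_tokens = lapply(seq_len(n), function(i) {
        if (targeted[i]) {
          sample(genes, n_tgt[i])
        } else {
          tok <- sample(MECHANISM_TOKENS, 1)
          if (runif(1) < 0.3) c(tok, sample(genes, 1)) else tok
        }
      }),
      delivery = sample(DELIVERY_MODES, n, replace = TRUE)
    )
    new_catalog(drugs, cancers)
  })
}

#' Specification for a synthetic somatic-mutation table
#'
#' Emulates a Pan-Cancer style cohort: by default 3,268 profiled samples
#' across 12 cohorts, with per-sample per-gene Bernoulli mutation rates set
#' per gene set. The default rates plant the observed set means (2.41%,
#' 1.19%, 1.85%, 0.97%) as ground truth; the default set sizes follow the
#' four-way partition (32 / 70 / 537 / 20,308).
#'
#' @param n_samples Total profiled samples.
#' @param set_rates Named numeric vector of per-sample mutation
#'   probabilities per gene.
#' @param genes_per_set Named integer vector (same names as `set_rates`).
#' @param cohorts Cohort codes assigned round-robin to samples.
#' @param seed Integer seed.
#' @return A `mutation_spec` list.
#' @export
mutation_spec <- function(n_samples = 3268,
                          set_rates = c(target_cancer = 0.0241,
                                        target_only = 0.0119,
                                        cancer_only = 0.0185,
                                        other = 0.0097),
                          genes_per_set = c(target_cancer = 32,
                                            target_only = 70,
                                            cancer_only = 537,
                                            other = 20308),
                          cohorts = c("BLCA", "BRCA", "COAD", "READ", "GBM",
                                      "HNSC", "KIRC", "LAML", "LUAD", "LUSC",
                                      "OV", "UCEC"),
                          seed = 1L) {
  if (any(set_rates < 0 | set_rates > 1)) abort("rates must be in [0, 1]")
  if (!setequal(names(set_rates), names(genes_per_set))) {
    abort("set_rates and genes_per_set must share names")
  }
  structure(list(n_samples = as.integer(n_samples), set_rates = set_rates,
                 genes_per_set = genes_per_set, cohorts = cohorts,
                 seed = as.integer(seed)),
            class = "mutation_spec")
}

#' Generate a synthetic mutation table with known per-gene rates
#'
#' For every gene, the number of mutated samples is drawn as
#' Binomial(`n_samples`, rate of its set) and the mutated samples are chosen
#' uniformly; each record gets a variant class drawn uniformly from the
#' seven classes and the sample's (round-robin) cohort. The planted truth is
#' returned for recovery tests.
#'
#' @param spec A [mutation_spec()].
#' @return List with `table` (an `od_mutation_table`), `truth` (named
#'   gene -> rate vector) and `gene_sets` (named list of gene vectors).
#' @export
generate_mutation_table <- function(spec) {
  stopifnot(inherits(spec, "mutation_spec"))
  withr::with_seed(spec$seed, {
    sets <- names(spec$genes_per_set)
    gene_sets <- lapply(sets, function(s) {
      sprintf("%s_G%05d", toupper(s), seq_len(spec$genes_per_set[[s]]))
    })
    names(gene_sets) <- sets
    truth <- unlist(lapply(sets, function(s) {
      stats::setNames(rep(spec$set_rates[[s]], length(gene_sets[[s]])),
                      gene_sets[[s]])
    }))
    cohort_of <- rep_len(spec$cohorts, spec$n_samples)
    recs <- lapply(names(truth), function(g) {
      k <- rbinom(1, spec$n_samples, truth[[g]])
      if (k == 0) return(NULL)
      ids <- sample.int(spec$n_samples, k)
      tibble::tibble(
        sample_id = sprintf("S%05d", ids),
        gene_symbol = g,
        variant_class = sample(variant_classes(), k, replace = TRUE),
        cohort = cohort_of[ids]
      )
    })
    records <- dplyr::bind_rows(recs)
    if (nrow(records) == 0) {
      records <- tibble::tibble(sample_id = character(0),
                                gene_symbol = character(0),
                                variant_class = character(0),
                                cohort = character(0))
    }
    list(table = new_mutation_table(records, spec$n_samples),
         truth = truth, gene_sets = gene_sets)
  })
}

#' Generate a synthetic clinical-trial count table for predictions
#'
#' Each predicted pair receives zero trials with probability
#' `1 - p_supported`, otherwise a positive count drawn from
#' `count_distribution`. The default support probability plants the observed
#' supported fraction 116/133.
#'
#' @param predictions Tibble with `drug` and `cancer` columns.
#' @param p_supported Probability of at least one trial.
#' @param count_distribution [count_dist()] for positive counts.
#' @param seed Integer seed.
#' @param cancers Optional cancer-class tibble used to abbreviate cancer
#'   labels; by default the full label is written in the
#'   `cancer_abbreviation` column (which [evaluate_support()] resolves
#'   correctly either way).
#' @return Tibble with `drug`, `cancer_abbreviation`, `n_trials`.
#' @export
generate_trial_counts <- function(predictions, p_supported = 116 / 133,
                                  count_distribution = count_dist("geometric",
                                                                  mean = 10),
                                  seed = 1L, cancers = NULL) {
  if (p_supported < 0 || p_supported > 1) abort("p_supported must be in [0, 1]")
  label <- predictions$cancer
  if (!is.null(cancers)) {
    label <- cancers$abbreviation[match(label, cancers$name)]
  }
  withr::with_seed(seed, {
    n <- nrow(predictions)
    supported <- runif(n) < p_supported
    counts <- ifelse(supported, draw_counts(count_distribution, n), 0L)
    tibble::tibble(drug = predictions$drug, cancer_abbreviation = label,
                   n_trials = as.integer(counts))
  })
}
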