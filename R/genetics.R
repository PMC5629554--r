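#' Partition genes into target/cancer-gene sets
#'
#' The four-way partition used to contrast drug targets with cancer genes:
#' * `target_cancer` — targets that are also cancer genes;
#' * `target_only` — targets that are not cancer genes;
#' * `cancer_only` — cancer genes that are not targets, restricted to genes
#'   with mutation data;
#' * `other` — genes with mutation data in none of the above.
#'
#' @param targets Character vector of target gene symbols.
#' @param cancer_genes Character vector of cancer-gene symbols (e.g. a Cancer
#'   Gene Census list).
#' @param genes_with_data Character vector of genes observed in the mutation
#'   table.
#' @return An `od_gene_partition`: list of the four character vectors.
#' @export
#' @examples
#' partition_gene_sets(c("EGFR", "KDR"), c("EGFR", "TP53"),
#'                     c("EGFR", "KDR", "TP53", "GAPDH"))
partition_gene_sets <- function(targets, cancer_genes, genes_with_data) {
  targets <- unique(as.character(targets))
  cancer_genes <- unique(as.character(cancer_genes))
  genes_with_data <- unique(as.character(genes_with_data))
  target_cancer <- intersect(targets, cancer_genes)
  target_only <- setdiff(targets, cancer_genes)
  cancer_only <- intersect(setdiff(cancer_genes, targets), genes_with_data)
  other <- setdiff(genes_with_data, c(targets, cancer_genes))
  structure(list(target_cancer = sort(target_cancer),
                 target_only = sort(target_only),
                 cancer_only = sort(cancer_only),
                 other = sort(other)),
            class = "od_gene_partition")
}

#' @export
print.od_gene_partition <- function(x, ...) {
  cat(sprintf("<od_gene_partition> target_cancer %d, target_only %d, cancer_only %d, other %d\n",
              length(x$target_cancer), length(x$target_only),
              length(x$cancer_only), length(x$other)))
  invisible(x)
}

#' Upper-tail hypergeometric enrichment probability
#'
#' P(X >= k) where X counts category members among `n_sample` draws without
#' replacement from a population of `N_population` genes of which
#' `K_category` are in the category. Used to test whether drug targets are
#' enriched with cancer genes.
#'
#' @param k_overlap Observed overlap.
#' @param n_sample Number of draws (e.g. number of drug targets).
#' @param K_category Category size in the population (e.g. cancer genes).
#' @param N_population Population size (e.g. protein-coding genes).
#' @return The upper-tail probability.
#' @export
#' @examples
#' hypergeometric_enrichment(32, 102, 594, 20729)
hypergeometric_enrichment <- function(k_overlap, n_sample, K_category,
                                      N_population) {
  if (n_sample > N_population || K_category > N_population ||
      k_overlap > min(n_sample, K_category) || k_overlap < 0) {
    abort("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N")
  }
  phyper(k_overlap - 1, K_category, N_population - K_category, n_sample,
         lower.tail = FALSE)
}

#' Read a long-form somatic-mutation table
#'
#' MAF-like TSV with columns `sample_id`, `gene_symbol`, `variant_class`,
#' `cohort`. The total number of profiled samples (which may exceed the
#' number of samples carrying mutations) can be declared with a
#' `#n_samples=<int>` header directive; otherwise the distinct samples in the
#' records are used.
#'
#' @param path Path to the TSV.
#' @return An `od_mutation_table`: list with tibble `records` and `n_samples`.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readLines(path, n = 5L)
  n_samples <- NULL
  directive <- grep("^#n_samples=", header, value = TRUE)
  if (length(directive)) {
    n_samples <- as.integer(sub("^#n_samples=", "", directive[1]))
  }
  records <- read_tsv_checked(path, c("sample_id", "gene_symbol",
                                      "variant_class", "cohort"))
  new_mutation_table(records, n_samples)
}

#' Construct a mutation table from in-memory records
#'
#' @param records Tibble with columns `sample_id`, `gene_symbol`,
#'   `variant_class`, `cohort`.
#' @param n_samples Total profiled samples; defaults to the distinct samples
#'   present in `records`.
#' @return An `od_mutation_table`.
#' @export
new_mutation_table <- function(records, n_samples = NULL) {
  records <- tibble::as_tibble(records)
  bad <- !records$variant_class %in% variant_classes()
  if (any(bad)) {
    abort(sprintf("unknown variant class '%s' (expected one of: %s)",
                  records$variant_class[bad][1],
                  paste(variant_classes(), collapse = ", ")))
  }
  if (any(!nzchar(records$sample_id)) || any(!nzchar(records$gene_symbol))) {
    abort("sample_id and gene_symbol must be non-empty")
  }
  observed <- dplyr::n_distinct(records$sample_id)
  n_samples <- n_samples %||% observed
  if (n_samples < observed) {
    abort(sprintf("n_samples (%d) is below the %d distinct samples in the records",
                  n_samples, observed))
  }
  structure(list(records = records, n_samples = as.integer(n_samples)),
            class = "od_mutation_table")
}

#' @export
print.od_mutation_table <- function(x, ...) {
  cat(sprintf("<od_mutation_table> %d records, %d genes, %d/%d samples with mutations\n",
              nrow(x$records), dplyr::n_distinct(x$records$gene_symbol),
              dplyr::n_distinct(x$records$sample_id), x$n_samples))
  invisible(x)
}

#' Per-gene mutation frequency over a gene set
#'
#' The mutation frequency of a gene is the percentage of profiled samples
#' carrying at least one record of that gene in the included variant
#' classes; duplicated records of a (sample, gene) pair count once, and
#' genes absent from the table score 0. The denominator is the total number
#' of profiled samples, so genes unmutated in part of the cohort dilute
#' correctly.
#'
#' @param table An `od_mutation_table`.
#' @param genes Character vector of genes to profile.
#' @param include_classes Variant classes to count; defaults to all seven
#'   (silent included).
#' @return An `od_freq_profile`: list with tibble `per_gene` (`gene`, `pct`)
#'   and `set_mean`.
#' @export
mutation_frequency <- function(table, genes,
                               include_classes = variant_classes()) {
  stopifnot(inherits(table, "od_mutation_table"))
  if (length(include_classes) == 0) abort("include_classes must be non-empty")
  if (table$n_samples <= 0) abort("n_samples must be positive")
  genes <- unique(as.character(genes))
  counts <- table$records |>
    dplyr::filter(.data$variant_class %in% include_classes,
                  .data$gene_symbol %in% genes) |>
    dplyr::distinct(.data$sample_id, .data$gene_symbol) |>
    dplyr::count(.data$gene_symbol, name = "n_mut")
  per_gene <- tibble::tibble(gene = genes) |>
    dplyr::left_join(counts, by = c(gene = "gene_symbol")) |>
    dplyr::mutate(pct = 100 * dplyr::coalesce(.data$n_mut, 0L) / table$n_samples) |>
    dplyr::select("gene", "pct")
  structure(list(per_gene = per_gene, set_mean = mean(per_gene$pct)),
            class = "od_freq_profile")
}

#' @export
print.od_freq_profile <- function(x, ...) {
  cat(sprintf("<od_freq_profile> %d genes; mean mutation frequency %.2f%%\n",
              nrow(x$per_gene), x$set_mean))
  invisible(x)
}

freq_vector <- function(profile) {
  if (inherits(profile, "od_freq_profile")) profile$per_gene$pct
  else as.numeric(profile)
}

#' Pairwise comparison of mutation-frequency profiles
#'
#' For every pair of gene sets, reports the set means and the two-sample
#' two-sided Kolmogorov-Smirnov p-value (asymptotic) on the per-gene
#' frequency vectors.
#'
#' @param profiles Named list of `od_freq_profile` objects (or bare numeric
#'   frequency vectors); at least two, all non-empty.
#' @return Tibble with `set_a`, `set_b`, `mean_a`, `mean_b`, `ks_statistic`,
#'   `ks_p`.
#' @export
compare_frequency_sets <- function(profiles) {
  if (length(profiles) < 2 || is.null(names(profiles))) {
    abort("`profiles` must be a named list of at least two profiles")
  }
  vecs <- lapply(profiles, freq_vector)
  if (any(lengths(vecs) == 0)) abort("empty frequency profile")
  pairs <- utils::combn(names(profiles), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    kt <- suppressWarnings(ks.test(vecs[[a]], vecs[[b]], exact = FALSE))
    tibble::tibble(set_a = a, set_b = b,
                   mean_a = mean(vecs[[a]]), mean_b = mean(vecs[[b]]),
                   ks_statistic = unname(kt$statistic), ks_p = kt$p.value)
  })
}

#' Fraction of genes at or above a mutation-frequency threshold
#'
#' For each gene set, the fraction of genes whose mutation frequency is at
#' least `threshold_pct` percent, with pairwise 2x2 chi-squared tests
#' (gene above threshold yes/no by set membership). No continuity correction
#' by default.
#'
#' @param profiles Named list of profiles, as in [compare_frequency_sets()].
#' @param threshold_pct Threshold in percent, within \[0, 100\].
#' @param correct Apply the Yates continuity correction.
#' @return List with tibbles `fractions` (`set`, `n_genes`, `n_above`,
#'   `fraction`) and `tests` (`set_a`, `set_b`, `statistic`, `p`).
#' @export
threshold_fraction <- function(profiles, threshold_pct = 2, correct = FALSE) {
  if (threshold_pct < 0 || threshold_pct > 100) {
    abort("threshold_pct must be within [0, 100]")
  }
  vecs <- lapply(profiles, freq_vector)
  fractions <- tibble::tibble(
    set = names(profiles),
    n_genes = unname(lengths(vecs)),
    n_above = unname(vapply(vecs, function(v) sum(v >= threshold_pct),
                            integer(1))),
  ) |> dplyr::mutate(fraction = .data$n_above / .data$n_genes)
  pairs <- utils::combn(names(profiles), 2)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    m <- rbind(
      c(sum(vecs[[a]] >= threshold_pct), sum(vecs[[a]] < threshold_pct)),
      c(sum(vecs[[b]] >= threshold_pct), sum(vecs[[b]] < threshold_pct))
    )
    ct <- suppressWarnings(chisq.test(m, correct = correct))
    tibble::tibble(set_a = a, set_b = b,
                   statistic = unname(ct$statistic), p = ct$p.value)
  })
  list(fractions = fractions, tests = tests)
}

#' Correlation between mutation frequency and drug count over a gene set
#'
#' Pearson correlation (two-sided p) between each gene's mutation frequency
#' and the number of drugs targeting it.
#'
#' @param genes Character vector of at least three genes.
#' @param per_gene_frequency Named numeric vector of frequencies (percent).
#' @param drugs_per_gene Named numeric vector of drug counts.
#' @return List with `r`, `p`, `n`.
#' @export
drug_count_correlation <- function(genes, per_gene_frequency, drugs_per_gene) {
  genes <- unique(as.character(genes))
  if (length(genes) < 3) abort("need at least 3 genes")
  x <- as.numeric(per_gene_frequency[genes])
  y <- as.numeric(drugs_per_gene[genes])
  if (anyNA(x) || anyNA(y)) abort("frequency or drug count missing for some genes")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("degenerate input: constant vector, correlation undefined")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(genes))
}

#' Overlap of a gene set with a reference list
#'
#' @param genes Character vector.
#' @param reference Character vector (e.g. a high-confidence oncogene list).
#' @return List with the `overlap` set and its size `n`.
#' @export
list_overlap <- function(genes, reference) {
  overlap <- sort(intersect(unique(genes), unique(reference)))
  list(overlap = overlap, n = length(overlap))
}

#' Read a one-symbol-per-line gene list
#'
#' Lines starting with `#` are comments; blank lines are skipped.
#'
#' @param path Path to the list file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
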