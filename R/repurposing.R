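#' Index targeted drugs by shared gene target
#'
#' Maps every gene target of the targeted drugs to the set of drugs hitting
#' it, and reports which drugs share at least one gene target with another
#' drug — the population the common-target transfer operates on.
#'
#' @param catalog An `od_catalog`.
#' @return An `od_target_index`: list with `index` (named list gene ->
#'   character vector of drugs), `drugs_sharing` (character vector) and
#'   `n_drugs_sharing`.
#' @export
#' @examples
#' cat150 <- load_catalog(od_example("drugs.tsv"), od_example("cancers.tsv"))
#' shared_target_index(cat150)$n_drugs_sharing
shared_target_index <- function(catalog) {
  stopifnot(inherits(catalog, "od_catalog"))
  dt <- gene_targets(catalog, category = "targeted")
  index <- split(dt$drug, dt$gene)
  sharing <- sort(unique(unlist(index[lengths(index) >= 2], use.names = FALSE)))
  if (is.null(sharing)) sharing <- character(0)
  structure(list(index = index, drugs_sharing = sharing,
                 n_drugs_sharing = length(sharing)),
            class = "od_target_index")
}

#' @export
print.od_target_index <- function(x, ...) {
  cat(sprintf("<od_target_index> %d targets; %d drugs share >=1 target\n",
              length(x$index), x$n_drugs_sharing))
  invisible(x)
}

#' Predict novel drug-cancer associations by common-target transfer
#'
#' The guilt-by-association rule: if targeted drugs A and B share at least
#' one gene target and B is approved for cancer D, then (A, D) is proposed —
#' unless A is already approved for D. Every ordered pair of distinct
#' targeted drugs is considered, so transfers run symmetrically in both
#' directions. Proposals are deduplicated on (drug, cancer); the shared
#' targets and source drugs that support a pair are merged, not multiplied.
#' Cytotoxic drugs never take part: mechanism tokens are not targets, and the
#' transfer is defined on the targeted pharmacopoeia.
#'
#' @param catalog An `od_catalog`.
#' @return An `od_predictions` tibble: columns `drug`, `cancer`,
#'   `shared_targets` (list of character), `source_drugs` (list of
#'   character), ordered by drug then cancer.
#' @export
#' @examples
#' cat150 <- load_catalog(od_example("drugs.tsv"), od_example("cancers.tsv"))
#' nrow(predict_common_target(cat150))
predict_common_target <- function(catalog) {
  stopifnot(inherits(catalog, "od_catalog"))
  dt <- gene_targets(catalog, category = "targeted")
  targeted <- dplyr::filter(catalog$drugs, .data$category == "targeted")
  indications <- tibble::tibble(
    drug = rep(targeted$name, lengths(targeted$indications)),
    cancer = unlist(targeted$indications, use.names = FALSE) %||% character(0)
  )
  approved <- catalog$drugs |>
    (\(d) tibble::tibble(
      drug = rep(d$name, lengths(d$indications)),
      cancer = unlist(d$indications, use.names = FALSE) %||% character(0)))()
  pairs <- dplyr::inner_join(dt, dt, by = "gene",
                             suffix = c("", "_src"),
                             relationship = "many-to-many") |>
    dplyr::filter(.data$drug != .data$drug_src)
  proposals <- pairs |>
    dplyr::inner_join(indications, by = c(drug_src = "drug"),
                      relationship = "many-to-many") |>
    dplyr::anti_join(approved, by = c("drug", "cancer"))
  out <- proposals |>
    dplyr::group_by(.data$drug, .data$cancer) |>
    dplyr::summarise(
      shared_targets = list(sort(unique(.data$gene))),
      source_drugs = list(sort(unique(.data$drug_src))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$drug, .data$cancer)
  class(out) <- c("od_predictions", class(out))
  out
}

#' Exhaustive reference enumeration of common-target transfers
#'
#' Independent oracle for [predict_common_target()]: a literal triple loop
#' over ordered drug pairs and the partner's indications, with plain
#' set-membership checks and no joins or indexing. Intended for testing on
#' catalogs of up to a few hundred drugs.
#'
#' @param catalog An `od_catalog` with at most 200 drugs.
#' @return Tibble with columns `drug` and `cancer` (the deduplicated pairs).
#' @export
brute_force_predict <- function(catalog) {
  stopifnot(inherits(catalog, "od_catalog"))
  if (nrow(catalog$drugs) > 200) abort("brute force is limited to 200 drugs")
  drugs <- catalog$drugs
  approved <- paste(rep(drugs$name, lengths(drugs$indications)),
                    unlist(drugs$indications, use.names = FALSE) %||% character(0),
                    sep = "\r")
  targeted <- which(drugs$category == "targeted")
  tsets <- lapply(drugs$target_tokens, gene_targets)
  found_drug <- character(0)
  found_cancer <- character(0)
  for (i in targeted) {
    for (j in targeted) {
      if (i == j) next
      if (!any(tsets[[i]] %in% tsets[[j]])) next
      for (cancer in drugs$indications[[j]]) {
        key <- paste(drugs$name[i], cancer, sep = "\r")
        if (key %in% approved) next
        found_drug <- c(found_drug, drugs$name[i])
        found_cancer <- c(found_cancer, cancer)
      }
    }
  }
  dplyr::distinct(tibble::tibble(drug = found_drug, cancer = found_cancer)) |>
    dplyr::arrange(.data$drug, .data$cancer)
}

#' Read a clinical-trial count table
#'
#' @param path TSV with columns `drug`, `cancer_abbreviation`, `n_trials`.
#' @return Tibble with those columns.
#' @export
read_trial_counts <- function(path) {
  read_tsv_checked(path, c("drug", "cancer_abbreviation", "n_trials"))
}

#' Evaluate predictions against clinical-trial counts
#'
#' Attaches the number of registered trials to each predicted (drug, cancer)
#' pair and tallies how many predictions have at least one supporting trial.
#' Predictions absent from the trial table are counted as zero-trial (with a
#' warning) and reported in `unmatched_predictions`; trial-table rows that
#' match no prediction are reported in `unused_trials` — both views exist so
#' that a disagreement between the predictor and an external evaluation
#' table is surfaced rather than silently reconciled.
#'
#' @param predictions An `od_predictions` tibble (or any tibble with `drug`
#'   and `cancer` columns).
#' @param trials A trial-count tibble from [read_trial_counts()].
#' @param cancers Cancer-class tibble (`name`, `abbreviation`) used to
#'   resolve the trial table's abbreviations; typically `catalog$cancers`.
#' @return An `od_prediction_report`: list with the annotated `predictions`
#'   tibble (`n_trials` column added), counts `n_predictions`, `n_drugs`,
#'   `n_cancers`, `n_supported`, `n_unsupported`, the `top` association, and
#'   the two diagnostic tibbles described above.
#' @export
evaluate_support <- function(predictions, trials, cancers) {
  stopifnot(all(c("drug", "cancer") %in% names(predictions)))
  trials <- trials |>
    dplyr::left_join(cancers, by = c(cancer_abbreviation = "abbreviation")) |>
    dplyr::mutate(cancer = dplyr::coalesce(.data$name,
                                           .data$cancer_abbreviation)) |>
    dplyr::select("drug", "cancer", "n_trials")
  annotated <- predictions |>
    dplyr::left_join(trials, by = c("drug", "cancer"))
  unmatched <- annotated |>
    dplyr::filter(is.na(.data$n_trials)) |>
    dplyr::select("drug", "cancer")
  if (nrow(unmatched) > 0) {
    warn(sprintf("%d prediction(s) missing from the trial table; counted as 0 trials (see $unmatched_predictions)",
                 nrow(unmatched)))
  }
  annotated$n_trials[is.na(annotated$n_trials)] <- 0L
  unused <- dplyr::anti_join(trials, predictions, by = c("drug", "cancer"))
  top <- NULL
  if (nrow(annotated) > 0) {
    i <- which.max(annotated$n_trials)
    top <- list(drug = annotated$drug[i], cancer = annotated$cancer[i],
                n_trials = annotated$n_trials[i])
  }
  structure(list(
    predictions = annotated,
    n_predictions = nrow(annotated),
    n_drugs = dplyr::n_distinct(annotated$drug),
    n_cancers = dplyr::n_distinct(annotated$cancer),
    n_supported = sum(annotated$n_trials >= 1),
    n_unsupported = sum(annotated$n_trials == 0),
    top = top,
    unmatched_predictions = unmatched,
    unused_trials = unused
  ), class = "od_prediction_report")
}

#' @export
print.od_prediction_report <- function(x, ...) {
  cat(sprintf("<od_prediction_report> %d predictions over %d drugs and %d cancers\n",
              x$n_predictions, x$n_drugs, x$n_cancers))
  cat(sprintf("  supported by >=1 trial: %d; unsupported: %d\n",
              x$n_supported, x$n_unsupported))
  if (!is.null(x$top)) {
    cat(sprintf("  top association: %s - %s (%d trials)\n",
                x$top$drug, x$top$cancer, x$top$n_trials))
  }
  invisible(x)
}

#' Write predictions to TSV
#'
#' List columns are `;`-joined, matching the catalog cell convention.
#'
#' @param predictions An annotated or raw predictions tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions |>
    dplyr::mutate(dplyr::across(dplyr::where(is.list),
                                ~ vapply(.x, paste, character(1),
                                         collapse = "; ")))
  readr::write_tsv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}
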