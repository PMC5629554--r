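#' Load and validate a curated anticancer drug catalog
#'
#' Reads the three tab-separated tables that make up a curated catalog: the
#' drug table (one row per approved drug, with its approval year,
#' cytotoxic/targeted category, `;`-delimited cancer-class indications,
#' `;`-delimited target tokens and delivery mode), the cancer-class table
#' (full label plus short code) and, optionally, the target-annotation table
#' (subcellular location, family and subfamily per target gene).
#'
#' Every record is validated on load: categories and delivery modes must be
#' members of their enumerations, indications must be non-empty and resolve to
#' a cancer class, drug names and cancer labels must be unique. A violation
#' aborts with a message naming the offending row.
#'
#' @param catalog_path Path to the drug table (`name`, `approval_year`,
#'   `category`, `indications`, `targets`, `delivery`).
#' @param cancer_path Path to the cancer-class table (`name`, `abbreviation`).
#' @param annotation_path Optional path to the target-annotation table
#'   (`gene_symbol`, `location`, `family`, `subfamily`).
#' @return An object of class `od_catalog`: a list with tibbles `drugs`
#'   (list-columns `indications` and `target_tokens`), `cancers` and
#'   `annotations` (`NULL` when not supplied).
#' @export
#' @examples
#' cat150 <- load_catalog(od_example("drugs.tsv"), od_example("cancers.tsv"),
#'                        od_example("target_annotations.tsv"))
#' cat150
load_catalog <- function(catalog_path, cancer_path, annotation_path = NULL) {
  drugs_raw <- read_tsv_checked(catalog_path,
    c("name", "approval_year", "category", "indications", "targets", "delivery"))
  cancers <- read_tsv_checked(cancer_path, c("name", "abbreviation"))
  annotations <- NULL
  if (!is.null(annotation_path)) {
    annotations <- read_tsv_checked(annotation_path,
      c("gene_symbol", "location", "family", "subfamily"))
  }
  drugs <- tibble::tibble(
    name = as.character(drugs_raw$name),
    approval_year = as.integer(drugs_raw$approval_year),
    category = as.character(drugs_raw$category),
    indications = lapply(drugs_raw$indications, parse_target_tokens),
    target_tokens = lapply(drugs_raw$targets, parse_target_tokens),
    delivery = as.character(drugs_raw$delivery)
  )
  new_catalog(drugs, cancers, annotations)
}

#' Construct a catalog from in-memory tables
#'
#' Low-level constructor used by [load_catalog()] and [generate_catalog()];
#' validates all catalog invariants.
#'
#' @param drugs Tibble with columns `name`, `approval_year`, `category`,
#'   `indications` (list of character), `target_tokens` (list of character),
#'   `delivery`.
#' @param cancers Tibble with columns `name`, `abbreviation`.
#' @param annotations Optional tibble with columns `gene_symbol`, `location`,
#'   `family`, `subfamily`.
#' @return An `od_catalog` object.
#' @export
new_catalog <- function(drugs, cancers, annotations = NULL) {
  drugs <- tibble::as_tibble(drugs)
  cancers <- tibble::as_tibble(cancers)
  validate_catalog(drugs, cancers, annotations)
  structure(
    list(drugs = drugs, cancers = cancers, annotations = annotations),
    class = "od_catalog"
  )
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  x
}

validate_catalog <- function(drugs, cancers, annotations) {
  if (anyDuplicated(drugs$name)) {
    abort(sprintf("duplicate drug name(s): %s",
                  paste(unique(drugs$name[duplicated(drugs$name)]), collapse = ", ")))
  }
  if (anyDuplicated(cancers$name) || anyDuplicated(cancers$abbreviation)) {
    abort("cancer-class names and abbreviations must be unique")
  }
  bad <- !drugs$category %in% DRUG_CATEGORIES
  if (any(bad)) {
    abort(sprintf("drug '%s': unknown category '%s' (expected %s)",
                  drugs$name[bad][1], drugs$category[bad][1],
                  paste(DRUG_CATEGORIES, collapse = "/")))
  }
  bad <- !drugs$delivery %in% DELIVERY_MODES
  if (any(bad)) {
    abort(sprintf("drug '%s': unknown delivery '%s' (expected %s)",
                  drugs$name[bad][1], drugs$delivery[bad][1],
                  paste(DELIVERY_MODES, collapse = "/")))
  }
  n_ind <- lengths(drugs$indications)
  if (any(n_ind == 0)) {
    abort(sprintf("drug '%s': no indication", drugs$name[n_ind == 0][1]))
  }
  unknown <- setdiff(unique(unlist(drugs$indications)), cancers$name)
  if (length(unknown)) {
    offender <- drugs$name[vapply(drugs$indications,
                                  function(i) any(i %in% unknown), logical(1))][1]
    abort(sprintf("drug '%s': indication '%s' not in the cancer-class table",
                  offender, unknown[1]))
  }
  if (!is.null(annotations)) {
    if (anyDuplicated(annotations$gene_symbol)) {
      abort("duplicate gene_symbol in target annotations")
    }
    bad <- !annotations$location %in% TARGET_LOCATIONS
    if (any(bad)) {
      abort(sprintf("target '%s': unknown location '%s'",
                    annotations$gene_symbol[bad][1], annotations$location[bad][1]))
    }
  }
  invisible(TRUE)
}

#' @export
print.od_catalog <- function(x, ...) {
  n <- table(factor(x$drugs$category, levels = DRUG_CATEGORIES))
  cat(sprintf("<od_catalog> %d drugs (%d cytotoxic, %d targeted), %d cancer classes",
              nrow(x$drugs), n[["cytotoxic"]], n[["targeted"]], nrow(x$cancers)))
  if (!is.null(x$annotations)) {
    cat(sprintf(", %d annotated targets", nrow(x$annotations)))
  }
  cat("\n")
  invisible(x)
}

#' Split a printed target (or indication) cell into tokens
#'
#' Cells in the curated tables hold `;`-delimited lists, e.g.
#' `"TUBA4A; TUBB"`. Tokens are trimmed but otherwise kept verbatim: case and
#' order are preserved and mechanism phrases are retained (see
#' [gene_targets()] for their removal).
#'
#' @param raw A single string (may be empty or `NA`).
#' @return Character vector of tokens; empty input gives `character(0)`.
#' @export
#' @examples
#' parse_target_tokens("TUBA4A; TUBB")
#' parse_target_tokens("CD33; DNA synthesis")
parse_target_tokens <- function(raw) {
  if (length(raw) != 1) abort("`raw` must be a single string")
  if (is.na(raw) || !nzchar(trimws(raw))) return(character(0))
  tok <- trimws(strsplit(raw, ";", fixed = TRUE)[[1]])
  tok[nzchar(tok)]
}

#' Gene targets of a drug or of every drug in a catalog
#'
#' Reduces raw target tokens to the set of protein/gene targets by dropping
#' mechanism-of-action tokens (`"DNA synthesis"`, `"RNA synthesis"`,
#' `"Protein synthesis"`, `"Unknown"`, `"Biological"`, matched
#' case-insensitively) and deduplicating. Fusion targets such as `BCR-ABL`
#' are deliberately kept as single tokens: the curated tables print them as
#' one target.
#'
#' @param x A character vector of raw tokens, or an `od_catalog`.
#' @param ... Passed to methods.
#' @return For tokens, a character vector (a set). For a catalog, a tibble
#'   with columns `drug` and `gene`, one row per drug-target pair.
#' @export
#' @examples
#' gene_targets(c("CD33", "DNA synthesis"))
gene_targets <- function(x, ...) UseMethod("gene_targets")

#' @export
gene_targets.character <- function(x, ...) {
  unique(x[!tolower(x) %in% tolower(MECHANISM_TOKENS)])
}

#' @rdname gene_targets
#' @param category Restrict to `"targeted"` drugs (the default, matching how
#'   the curated target universe is defined) or use `"all"`.
#' @export
gene_targets.od_catalog <- function(x, category = c("targeted", "all"), ...) {
  category <- rlang::arg_match(category)
  drugs <- x$drugs
  if (category == "targeted") {
    drugs <- dplyr::filter(drugs, .data$category == "targeted")
  }
  genes <- lapply(drugs$target_tokens, gene_targets)
  tibble::tibble(
    drug = rep(drugs$name, lengths(genes)),
    gene = unlist(genes, use.names = FALSE) %||% character(0)
  )
}

#' Summarize a drug catalog
#'
#' Counts drugs in total, by category, by approval year and category, by
#' delivery mode, and within user-chosen approval periods (closed year
#' intervals). The default periods follow the catalog's historical framing:
#' 1941-1990, 1991-2000, 2001-2010 and 2011-2014.
#'
#' @param catalog An `od_catalog`.
#' @param periods List of length-2 integer vectors `c(start, end)`.
#' @return An `od_catalog_summary`: list with `n_total`, `n_cytotoxic`,
#'   `n_targeted`, `counts_by_year` (tibble `year`, `cytotoxic`, `targeted`),
#'   `counts_by_delivery` (named integer vector) and `counts_by_period`
#'   (tibble `start`, `end`, `n`).
#' @export
#' @examples
#' cat150 <- load_catalog(od_example("drugs.tsv"), od_example("cancers.tsv"))
#' summarize_catalog(cat150)$counts_by_delivery
summarize_catalog <- function(catalog,
                              periods = list(c(1941, 1990), c(1991, 2000),
                                             c(2001, 2010), c(2011, 2014))) {
  stopifnot(inherits(catalog, "od_catalog"))
  drugs <- catalog$drugs
  by_year <- drugs |>
    dplyr::count(.data$approval_year, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L) |>
    dplyr::rename(year = "approval_year") |>
    dplyr::arrange(.data$year)
  for (col in DRUG_CATEGORIES) {
    if (!col %in% names(by_year)) by_year[[col]] <- 0L
  }
  by_delivery <- vapply(DELIVERY_MODES,
                        function(m) sum(drugs$delivery == m), integer(1))
  by_period <- tibble::tibble(
    start = vapply(periods, `[`, numeric(1), 1),
    end = vapply(periods, `[`, numeric(1), 2),
    n = vapply(periods, function(p) {
      sum(drugs$approval_year >= p[1] & drugs$approval_year <= p[2])
    }, numeric(1))
  )
  structure(list(
    n_total = nrow(drugs),
    n_cytotoxic = sum(drugs$category == "cytotoxic"),
    n_targeted = sum(drugs$category == "targeted"),
    counts_by_year = by_year[, c("year", DRUG_CATEGORIES)],
    counts_by_delivery = by_delivery,
    counts_by_period = by_period
  ), class = "od_catalog_summary")
}

#' @export
print.od_catalog_summary <- function(x, ...) {
  cat(sprintf("<od_catalog_summary> %d drugs: %d cytotoxic, %d targeted\n",
              x$n_total, x$n_cytotoxic, x$n_targeted))
  cat("delivery:", paste(sprintf("%s %d", names(x$counts_by_delivery),
                                 x$counts_by_delivery), collapse = ", "), "\n")
  for (i in seq_len(nrow(x$counts_by_period))) {
    cat(sprintf("  %d-%d: %d drugs\n", x$counts_by_period$start[i],
                x$counts_by_period$end[i], x$counts_by_period$n[i]))
  }
  invisible(x)
}

#' Correlation between annual approvals of a drug category and delivery mode
#'
#' Builds two annual count series over every calendar year between the first
#' and last approval in the catalog (years without approvals count zero): the
#' number of drugs of `category` approved that year, and the number of drugs
#' with `delivery` approved that year. Returns the Pearson correlation and its
#' two-sided p-value from the t transform.
#'
#' @param catalog An `od_catalog` spanning at least three distinct years.
#' @param category `"cytotoxic"` or `"targeted"`.
#' @param delivery `"single"`, `"combination"` or `"both"`.
#' @return List with `r`, `p`, `n_years`, and the two series as a tibble.
#' @export
#' @examples
#' cat150 <- load_catalog(od_example("drugs.tsv"), od_example("cancers.tsv"))
#' delivery_correlation(cat150, "targeted", "single")$r
delivery_correlation <- function(catalog, category, delivery) {
  stopifnot(inherits(catalog, "od_catalog"))
  category <- rlang::arg_match(category, DRUG_CATEGORIES)
  delivery <- rlang::arg_match(delivery, DELIVERY_MODES)
  drugs <- catalog$drugs
  years <- seq(min(drugs$approval_year), max(drugs$approval_year))
  if (length(years) < 3) abort("catalog must span at least 3 calendar years")
  series <- function(sel) {
    tabulate(factor(drugs$approval_year[sel], levels = years), length(years))
  }
  a <- series(drugs$category == category)
  b <- series(drugs$delivery == delivery)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort("degenerate input: an annual series is constant, correlation undefined")
  }
  ct <- cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_years = length(years),
       series = tibble::tibble(year = years, category_count = a,
                               delivery_count = b))
}

#' Summarize target annotations by location, family and subfamily
#'
#' Counts annotated targets per subcellular location, per family and per
#' (location, family, subfamily) cell, with percentages of the annotated
#' total rounded half-up to whole percent (the convention of the source
#' tables).
#'
#' @param x An `od_catalog` carrying annotations, or the annotation tibble
#'   itself.
#' @return List of tibbles `by_location`, `by_family`, `by_subfamily`, each
#'   with `n` and `pct`, plus `n_total`.
#' @export
#' @examples
#' cat150 <- load_catalog(od_example("drugs.tsv"), od_example("cancers.tsv"),
#'                        od_example("target_annotations.tsv"))
#' annotation_summary(cat150)$by_location
annotation_summary <- function(x) {
  ann <- if (inherits(x, "od_catalog")) x$annotations else tibble::as_tibble(x)
  if (is.null(ann) || nrow(ann) == 0) abort("no target annotations available")
  n_total <- nrow(ann)
  tally <- function(...) {
    ann |>
      dplyr::count(..., name = "n") |>
      dplyr::mutate(pct = round_half_up(100 * .data$n / n_total)) |>
      dplyr::arrange(dplyr::desc(.data$n))
  }
  list(
    by_location = tally(.data$location),
    by_family = tally(.data$family),
    by_subfamily = tally(.data$location, .data$family, .data$subfamily),
    n_total = n_total
  )
}
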