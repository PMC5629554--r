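#' Validate a pipeline run configuration
#'
#' Collects input paths, analysis thresholds and the output directory for an
#' end-to-end run. All referenced paths must exist at validation time.
#'
#' @param catalog,cancers Paths to the drug and cancer-class tables
#'   (required).
#' @param annotations,trials,mutations,cancer_genes,ocg,tsg Optional paths:
#'   target annotations, clinical-trial counts, somatic-mutation table,
#'   cancer-gene list, high-confidence oncogene and tumor-suppressor lists.
#' @param out_dir Optional directory for per-stage TSV outputs (created if
#'   missing).
#' @param mutation_threshold Mutation-frequency threshold in percent for the
#'   gene-set fractions (default 2).
#' @param include_silent Count silent variants in mutation frequencies.
#' @param seed Integer seed recorded in the provenance (the pipeline itself
#'   is deterministic).
#' @return An `od_run_config` list.
#' @export
run_config <- function(catalog, cancers, annotations = NULL, trials = NULL,
                       mutations = NULL, cancer_genes = NULL, ocg = NULL,
                       tsg = NULL, out_dir = NULL, mutation_threshold = 2,
                       include_silent = TRUE, seed = 1L) {
  paths <- list(catalog = catalog, cancers = cancers,
                annotations = annotations, trials = trials,
                mutations = mutations, cancer_genes = cancer_genes,
                ocg = ocg, tsg = tsg)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("config input '%s': file not found: %s", nm, p))
    }
  }
  if (mutation_threshold < 0 || mutation_threshold > 100) {
    abort("mutation_threshold must be within [0, 100]")
  }
  structure(c(paths, list(out_dir = out_dir,
                          mutation_threshold = mutation_threshold,
                          include_silent = include_silent,
                          seed = as.integer(seed))),
            class = "od_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes catalog loading and summary, both network constructions with
#' degree statistics, the common-target prediction with trial-support
#' evaluation (when a trial table is configured), and the target-genetics
#' statistics (when mutation inputs are configured; otherwise that stage is
#' marked skipped). Per-stage TSVs are written when `out_dir` is set. The
#' result is deterministic for identical inputs, apart from the provenance
#' timestamp.
#'
#' @param config An [run_config()] object.
#' @param quiet Suppress progress messages (messages go to standard error).
#' @return An `od_report` nested list; see [render_report()].
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "od_run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  say("catalog: loading %s", config$catalog)
  catalog <- load_catalog(config$catalog, config$cancers, config$annotations)
  summary <- summarize_catalog(catalog)
  ann <- if (!is.null(catalog$annotations)) annotation_summary(catalog)

  say("networks: building drug-cancer and cancer-drug-target networks")
  bip <- build_drug_cancer_network(catalog)
  tri <- build_cancer_drug_target_network(catalog)
  drug_deg <- degree_summary(bip, "drug")
  cancer_deg <- degree_summary(bip, "cancer")
  cyt <- catalog$drugs$name[catalog$drugs$category == "cytotoxic"]
  tgt <- catalog$drugs$name[catalog$drugs$category == "targeted"]
  networks <- list(
    drug_cancer = list(
      n_drugs = nrow(bip$drugs), n_cancers = nrow(bip$cancers),
      n_edges = nrow(bip$edges),
      drug_degree = summarize_degrees(drug_deg),
      cancer_degree = summarize_degrees(cancer_deg),
      cytotoxic_mean_degree =
        if (length(cyt)) degree_summary(bip, "drug", cyt)$mean,
      targeted_mean_degree =
        if (length(tgt)) degree_summary(bip, "drug", tgt)$mean
    ),
    cancer_drug_target = list(
      n_drugs = nrow(tri$drugs), n_targets = nrow(tri$targets),
      n_cancers = nrow(tri$cancers),
      n_drug_cancer_edges = nrow(tri$drug_cancer),
      n_drug_target_edges = nrow(tri$drug_target),
      drug_target_degree = if (nrow(tri$drugs))
        summarize_degrees(degree_summary(tri, "drug",
                                         edge_type = "drug-target")),
      target_degree = if (nrow(tri$targets))
        summarize_degrees(degree_summary(tri, "target"))
    )
  )

  say("repurposing: common-target transfer over %d targeted drugs", length(tgt))
  predictions <- predict_common_target(catalog)
  index <- shared_target_index(catalog)
  if (!is.null(config$trials)) {
    trials <- read_trial_counts(config$trials)
    report <- evaluate_support(predictions, trials, catalog$cancers)
  } else {
    # no trial table configured: annotate with zeros, nothing to warn about
    report <- suppressWarnings(evaluate_support(
      predictions,
      tibble::tibble(drug = character(0), cancer_abbreviation = character(0),
                     n_trials = integer(0)),
      catalog$cancers))
  }
  repurposing <- list(
    n_drugs_sharing = index$n_drugs_sharing,
    n_predictions = report$n_predictions,
    n_drugs = report$n_drugs, n_cancers = report$n_cancers,
    n_supported = if (!is.null(config$trials)) report$n_supported,
    n_unsupported = if (!is.null(config$trials)) report$n_unsupported,
    top = report$top
  )

  genetics <- list(skipped = TRUE)
  if (!is.null(config$mutations) && !is.null(config$cancer_genes)) {
    say("genetics: mutation-frequency statistics")
    mut <- read_mutation_table(config$mutations)
    census <- read_gene_list(config$cancer_genes)
    targets <- unique(gene_targets(catalog)$gene)
    part <- partition_gene_sets(targets, census,
                                unique(mut$records$gene_symbol))
    classes <- variant_classes()
    if (!config$include_silent) classes <- setdiff(classes, "silent")
    profiles <- lapply(unclass(part)[lengths(part) > 0], function(g) {
      mutation_frequency(mut, g, include_classes = classes)
    })
    genetics <- list(
      skipped = FALSE,
      partition_sizes = lengths(part),
      enrichment_p = hypergeometric_enrichment(
        length(part$target_cancer), length(targets), length(census), 20729),
      set_means = vapply(profiles, function(p) p$set_mean, numeric(1)),
      ks_comparisons = compare_frequency_sets(profiles),
      threshold = threshold_fraction(profiles, config$mutation_threshold)
    )
    if (!is.null(config$ocg)) {
      genetics$ocg_overlap <- list_overlap(part$target_cancer,
                                           read_gene_list(config$ocg))$n
    }
    if (!is.null(config$tsg)) {
      genetics$tsg_overlap <- list_overlap(part$target_cancer,
                                           read_gene_list(config$tsg))$n
    }
  } else {
    say("genetics: skipped (no mutation table or cancer-gene list configured)")
  }

  out <- structure(list(
    catalog_summary = list(
      n_total = summary$n_total, n_cytotoxic = summary$n_cytotoxic,
      n_targeted = summary$n_targeted,
      counts_by_delivery = as.list(summary$counts_by_delivery),
      counts_by_period = summary$counts_by_period
    ),
    annotation_summary = ann,
    networks = networks,
    repurposing = repurposing,
    genetics = genetics,
    provenance = list(
      config = unclass(config)[!vapply(config, is.null, logical(1))],
      config_hash = rlang::hash(unclass(config)),
      package_version = as.character(utils::packageVersion("oncodrug")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
  ), class = "od_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    export_network(bip, file.path(config$out_dir, "drug_cancer_edges.tsv"))
    export_network(tri, file.path(config$out_dir, "cancer_drug_target_edges.tsv"))
    write_predictions(report$predictions,
                      file.path(config$out_dir, "predictions.tsv"))
    render_report(out, file.path(config$out_dir, "report.json"), "json")
    render_report(out, file.path(config$out_dir, "report.md"), "markdown")
  }
  out
}

summarize_degrees <- function(ds) {
  list(n = ds$n, mean = ds$mean, min = ds$min, max = ds$max,
       skewness = ds$skewness)
}

#' @export
print.od_report <- function(x, ...) {
  cat("<od_report>\n")
  cat(sprintf("  catalog: %d drugs (%d cytotoxic, %d targeted)\n",
              x$catalog_summary$n_total, x$catalog_summary$n_cytotoxic,
              x$catalog_summary$n_targeted))
  cat(sprintf("  drug-cancer network: %d + %d nodes, %d edges\n",
              x$networks$drug_cancer$n_drugs, x$networks$drug_cancer$n_cancers,
              x$networks$drug_cancer$n_edges))
  cat(sprintf("  cancer-drug-target network: %d/%d/%d nodes, %d + %d edges\n",
              x$networks$cancer_drug_target$n_drugs,
              x$networks$cancer_drug_target$n_targets,
              x$networks$cancer_drug_target$n_cancers,
              x$networks$cancer_drug_target$n_drug_cancer_edges,
              x$networks$cancer_drug_target$n_drug_target_edges))
  cat(sprintf("  repurposing: %d predictions over %d drugs, %d cancers\n",
              x$repurposing$n_predictions, x$repurposing$n_drugs,
              x$repurposing$n_cancers))
  cat(sprintf("  genetics: %s\n",
              if (isTRUE(x$genetics$skipped)) "skipped" else "computed"))
  invisible(x)
}

#' Render a results report to JSON or markdown
#'
#' JSON preserves the full nested structure with stable key order and
#' re-parses to equal values; markdown renders the headline tables. The
#' timestamp lives only in the provenance block, so everything else is
#' diffable across runs.
#'
#' @param report An `od_report` from [run_pipeline()].
#' @param path Output file path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("json", "markdown")) {
  format <- rlang::arg_match(format)
  stopifnot(inherits(report, "od_report"))
  if (format == "json") {
    jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  } else {
    writeLines(render_markdown_report(report), path)
  }
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.data.frame(x)) {
    as.data.frame(x)
  } else {
    x
  }
}

render_markdown_report <- function(x) {
  lines <- c("# Anticancer drug catalog analysis", "")
  cs <- x$catalog_summary
  lines <- c(lines, "## Catalog", "",
    sprintf("- %d drugs: %d cytotoxic, %d targeted", cs$n_total,
            cs$n_cytotoxic, cs$n_targeted),
    sprintf("- delivery: %s",
            paste(sprintf("%s %d", names(cs$counts_by_delivery),
                          unlist(cs$counts_by_delivery)), collapse = ", ")),
    "")
  nc <- x$networks$drug_cancer
  lines <- c(lines, "## Drug-cancer network", "",
    sprintf("- %d drug and %d cancer nodes, %d edges", nc$n_drugs,
            nc$n_cancers, nc$n_edges),
    sprintf("- drug degree: mean %.2f, max %d", nc$drug_degree$mean,
            nc$drug_degree$max),
    sprintf("- cancer degree: mean %.2f, max %d", nc$cancer_degree$mean,
            nc$cancer_degree$max),
    "")
  nt <- x$networks$cancer_drug_target
  lines <- c(lines, "## Cancer-drug-target network", "",
    sprintf("- %d drugs, %d targets, %d cancers; %d drug-cancer + %d drug-target edges",
            nt$n_drugs, nt$n_targets, nt$n_cancers, nt$n_drug_cancer_edges,
            nt$n_drug_target_edges),
    "")
  rp <- x$repurposing
  lines <- c(lines, "## Common-target predictions", "",
    sprintf("- %d drugs share at least one target", rp$n_drugs_sharing),
    sprintf("- %d novel associations over %d drugs and %d cancer types",
            rp$n_predictions, rp$n_drugs, rp$n_cancers))
  if (!is.null(rp$n_supported)) {
    lines <- c(lines,
      sprintf("- %d supported by at least one clinical trial, %d unsupported",
              rp$n_supported, rp$n_unsupported))
  }
  if (!is.null(rp$top)) {
    lines <- c(lines, sprintf("- top association: %s - %s (%d trials)",
                              rp$top$drug, rp$top$cancer, rp$top$n_trials))
  }
  lines <- c(lines, "", "## Target genetics", "")
  if (isTRUE(x$genetics$skipped)) {
    lines <- c(lines, "- skipped (no mutation inputs configured)")
  } else {
    g <- x$genetics
    lines <- c(lines,
      sprintf("- partition sizes: %s",
              paste(sprintf("%s %d", names(g$partition_sizes),
                            g$partition_sizes), collapse = ", ")),
      sprintf("- cancer-gene enrichment p = %.3g", g$enrichment_p),
      sprintf("- set mean mutation frequencies: %s",
              paste(sprintf("%s %.2f%%", names(g$set_means), g$set_means),
                    collapse = ", ")))
  }
  c(lines, "", "## Provenance", "",
    sprintf("- config hash: %s", x$provenance$config_hash),
    sprintf("- oncodrug %s, %s", x$provenance$package_version,
            x$provenance$r_version),
    sprintf("- generated: %s", x$provenance$timestamp))
}
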