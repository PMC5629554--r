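#' Build the drug-cancer bipartite network
#'
#' One node per drug and per cancer class with at least one approved drug;
#' one undirected edge per approved (drug, cancer) association. Duplicate
#' associations collapse to a single edge.
#'
#' @param catalog An `od_catalog`.
#' @return An `od_bipartite`: list with tibbles `drugs` (`name`, `category`),
#'   `cancers` (`name`) and `edges` (`drug`, `cancer`).
#' @export
#' @examples
#' cat150 <- load_catalog(od_example("drugs.tsv"), od_example("cancers.tsv"))
#' build_drug_cancer_network(cat150)
build_drug_cancer_network <- function(catalog) {
  stopifnot(inherits(catalog, "od_catalog"))
  drugs <- catalog$drugs
  edges <- tibble::tibble(
    drug = rep(drugs$name, lengths(drugs$indications)),
    cancer = unlist(drugs$indications, use.names = FALSE) %||% character(0)
  ) |> dplyr::distinct()
  structure(list(
    drugs = tibble::tibble(name = drugs$name, category = drugs$category),
    cancers = tibble::tibble(name = sort(unique(edges$cancer))),
    edges = dplyr::arrange(edges, .data$drug, .data$cancer)
  ), class = "od_bipartite")
}

#' @export
print.od_bipartite <- function(x, ...) {
  cat(sprintf("<od_bipartite> %d nodes (%d drugs, %d cancers), %d edges\n",
              nrow(x$drugs) + nrow(x$cancers), nrow(x$drugs), nrow(x$cancers),
              nrow(x$edges)))
  invisible(x)
}

#' Build the cancer-drug-target tripartite network
#'
#' Restricted to targeted drugs. Drug-target edges come from
#' [gene_targets()] (mechanism tokens excluded); drug-cancer edges from the
#' approved indications of the targeted drugs. Target nodes are exactly the
#' genes with at least one incident edge.
#'
#' @param catalog An `od_catalog`.
#' @return An `od_tripartite`: list with tibbles `drugs`, `targets`, `cancers`
#'   and edge tibbles `drug_cancer` (`drug`, `cancer`) and `drug_target`
#'   (`drug`, `target`).
#' @export
#' @examples
#' cat150 <- load_catalog(od_example("drugs.tsv"), od_example("cancers.tsv"))
#' build_cancer_drug_target_network(cat150)
build_cancer_drug_target_network <- function(catalog) {
  stopifnot(inherits(catalog, "od_catalog"))
  drugs <- dplyr::filter(catalog$drugs, .data$category == "targeted")
  drug_cancer <- tibble::tibble(
    drug = rep(drugs$name, lengths(drugs$indications)),
    cancer = unlist(drugs$indications, use.names = FALSE) %||% character(0)
  ) |> dplyr::distinct()
  drug_target <- gene_targets(catalog, category = "targeted") |>
    dplyr::distinct() |>
    dplyr::rename(target = "gene")
  structure(list(
    drugs = tibble::tibble(name = drugs$name),
    targets = tibble::tibble(name = sort(unique(drug_target$target))),
    cancers = tibble::tibble(name = sort(unique(drug_cancer$cancer))),
    drug_cancer = dplyr::arrange(drug_cancer, .data$drug, .data$cancer),
    drug_target = dplyr::arrange(drug_target, .data$drug, .data$target)
  ), class = "od_tripartite")
}

#' @export
print.od_tripartite <- function(x, ...) {
  cat(sprintf(
    "<od_tripartite> %d nodes (%d drugs, %d targets, %d cancers), %d edges (%d drug-cancer + %d drug-target)\n",
    nrow(x$drugs) + nrow(x$targets) + nrow(x$cancers),
    nrow(x$drugs), nrow(x$targets), nrow(x$cancers),
    nrow(x$drug_cancer) + nrow(x$drug_target),
    nrow(x$drug_cancer), nrow(x$drug_target)))
  invisible(x)
}

network_edge_table <- function(network) {
  if (inherits(network, "od_bipartite")) {
    tibble::tibble(source = network$edges$drug, source_class = "drug",
                   target = network$edges$cancer, target_class = "cancer",
                   edge_type = "drug-cancer")
  } else if (inherits(network, "od_tripartite")) {
    dplyr::bind_rows(
      tibble::tibble(source = network$drug_cancer$drug, source_class = "drug",
                     target = network$drug_cancer$cancer,
                     target_class = "cancer", edge_type = "drug-cancer"),
      tibble::tibble(source = network$drug_target$drug, source_class = "drug",
                     target = network$drug_target$target,
                     target_class = "target", edge_type = "drug-target")
    )
  } else {
    abort("`network` must be an od_bipartite or od_tripartite")
  }
}

network_node_classes <- function(network) {
  if (inherits(network, "od_bipartite")) {
    c(stats::setNames(rep("drug", nrow(network$drugs)), network$drugs$name),
      stats::setNames(rep("cancer", nrow(network$cancers)), network$cancers$name))
  } else {
    c(stats::setNames(rep("drug", nrow(network$drugs)), network$drugs$name),
      stats::setNames(rep("target", nrow(network$targets)), network$targets$name),
      stats::setNames(rep("cancer", nrow(network$cancers)), network$cancers$name))
  }
}

#' Degree summary of one node class
#'
#' Node degree is the number of incident edges, regardless of the partner
#' class. For tripartite drug nodes the two edge types can be summarized
#' separately via `edge_type` (the convention used when reporting a drug's
#' "target degree" and "cancer degree").
#'
#' @param network An `od_bipartite` or `od_tripartite`.
#' @param node_class `"drug"`, `"cancer"` or (tripartite only) `"target"`.
#' @param node_subset Optional character vector restricting the summarized
#'   nodes (e.g. the cytotoxic drugs). Nodes outside the class are an error.
#' @param edge_type For tripartite networks: `"all"`, `"drug-cancer"` or
#'   `"drug-target"`.
#' @return An `od_degree_summary`: list with the named integer vector
#'   `degrees` plus `n`, `mean`, `min`, `max` and sample skewness `skewness`
#'   (g1).
#' @export
#' @examples
#' cat150 <- load_catalog(od_example("drugs.tsv"), od_example("cancers.tsv"))
#' net <- build_drug_cancer_network(cat150)
#' degree_summary(net, "drug")
degree_summary <- function(network, node_class, node_subset = NULL,
                           edge_type = c("all", "drug-cancer", "drug-target")) {
  edge_type <- rlang::arg_match(edge_type)
  classes <- network_node_classes(network)
  node_class <- rlang::arg_match(node_class, unique(classes))
  nodes <- names(classes)[classes == node_class]
  if (!is.null(node_subset)) {
    bad <- setdiff(node_subset, nodes)
    if (length(bad)) {
      abort(sprintf("node(s) not of class '%s': %s", node_class,
                    paste(head(bad, 3), collapse = ", ")))
    }
    nodes <- intersect(nodes, node_subset)
  }
  if (length(nodes) == 0) abort("empty node class")
  edges <- network_edge_table(network)
  if (edge_type != "all") {
    edges <- dplyr::filter(edges, .data$edge_type == !!edge_type)
  }
  incident <- c(edges$source, edges$target)
  degrees <- stats::setNames(
    tabulate(factor(incident, levels = nodes), length(nodes)), nodes)
  structure(list(
    degrees = degrees, n = length(degrees),
    mean = mean(degrees), min = min(degrees), max = max(degrees),
    skewness = skewness_g1(degrees)
  ), class = "od_degree_summary")
}

#' @export
print.od_degree_summary <- function(x, ...) {
  cat(sprintf("<od_degree_summary> %d nodes; degree mean %.2f, range %d-%d, skewness %.2f\n",
              x$n, x$mean, x$min, x$max, x$skewness))
  invisible(x)
}

#' Count nodes per degree bin
#'
#' Bins are predicates on the degree (e.g. `function(d) d == 1`). They must
#' partition the observed degrees: a degree matching zero or several bins is
#' an error.
#'
#' @param network A network object, or an `od_degree_summary`.
#' @param node_class Node class to bin (ignored when a degree summary is
#'   given).
#' @param bins Named list of predicate functions.
#' @param node_subset Optional node restriction, as in [degree_summary()].
#' @return Tibble with `bin` and `n`.
#' @export
#' @examples
#' cat150 <- load_catalog(od_example("drugs.tsv"), od_example("cancers.tsv"))
#' net <- build_drug_cancer_network(cat150)
#' degree_breakdown(net, "drug", list(`1` = function(d) d == 1,
#'                                    `2` = function(d) d == 2,
#'                                    `3+` = function(d) d >= 3))
degree_breakdown <- function(network, node_class = "drug", bins,
                             node_subset = NULL) {
  if (is.null(names(bins)) || any(!nzchar(names(bins)))) {
    abort("`bins` must be a named list of predicates")
  }
  if (!inherits(network, "od_degree_summary") &&
      length(network_node_classes(network)) == 0) {
    return(tibble::tibble(bin = names(bins), n = 0))
  }
  ds <- if (inherits(network, "od_degree_summary")) network
        else degree_summary(network, node_class, node_subset)
  hits <- vapply(bins, function(f) vapply(ds$degrees, f, logical(1)),
                 logical(length(ds$degrees)))
  hits <- matrix(hits, nrow = length(ds$degrees))
  n_hit <- rowSums(hits)
  if (any(n_hit > 1)) abort("overlapping bins: a degree matches several predicates")
  if (any(n_hit == 0)) {
    abort(sprintf("bins do not cover observed degree %d",
                  ds$degrees[n_hit == 0][1]))
  }
  tibble::tibble(bin = names(bins), n = colSums(hits))
}

#' Two-sample Kolmogorov-Smirnov comparison of degree distributions
#'
#' Wraps the two-sample K-S test with the asymptotic p-value (the observed
#' degrees are heavily tied integers, so the exact small-sample p is not
#' defined; tie warnings are suppressed by design).
#'
#' @param degrees_a,degrees_b Non-empty numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`, as in
#'   [stats::ks.test()]. One-sided alternatives compare the ECDF of
#'   `degrees_a` against that of `degrees_b`.
#' @return List with `statistic`, `p_value`, `mean_a`, `mean_b`.
#' @export
#' @examples
#' compare_degree_distributions(c(1, 2, 3, 5), c(1, 1, 2, 2))
compare_degree_distributions <- function(degrees_a, degrees_b,
                                         alternative = "two.sided") {
  if (length(degrees_a) == 0 || length(degrees_b) == 0) {
    abort("both degree samples must be non-empty")
  }
  kt <- suppressWarnings(
    ks.test(degrees_a, degrees_b, alternative = alternative, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       mean_a = mean(degrees_a), mean_b = mean(degrees_b))
}

#' Export a network to edge-TSV, SIF or GraphML
#'
#' The edge-TSV format (`source, source_class, target, target_class,
#' edge_type`) round-trips losslessly through [import_network_edges()]. SIF
#' and GraphML target external viewers; GraphML carries a `class` node
#' attribute.
#'
#' @param network An `od_bipartite` or `od_tripartite`.
#' @param path Output file path.
#' @param format `"edge-tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("edge-tsv", "sif", "graphml")) {
  format <- rlang::arg_match(format)
  edges <- network_edge_table(network)
  if (format == "edge-tsv") {
    readr::write_tsv(edges, path, progress = FALSE)
  } else if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", edges$source, edges$edge_type,
                       edges$target), path)
  } else {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Re-import an edge-TSV written by [export_network()]
#'
#' @param path Path to an edge-TSV file.
#' @return Tibble with the five edge-TSV columns.
#' @export
import_network_edges <- function(path) {
  read_tsv_checked(path, c("source", "source_class", "target", "target_class",
                           "edge_type"))
}

#' Convert a network to an igraph object
#'
#' Nodes carry a `class` attribute (`drug`/`cancer`/`target`); edges carry
#' `edge_type`.
#'
#' @param network An `od_bipartite` or `od_tripartite`.
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(network) {
  classes <- network_node_classes(network)
  edges <- network_edge_table(network)
  igraph::graph_from_data_frame(
    edges[, c("source", "target", "edge_type")], directed = FALSE,
    vertices = data.frame(name = names(classes), class = unname(classes),
                          stringsAsFactors = FALSE)
  )
}
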