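#' Assemble a domain-centered interactome network
#'
#' Bundles a screen's confirmed interactions with the domain catalog and
#' the set of auto-activating baits (baits excluded from screening because
#' they drive reporters without any prey). Auto-activator edges are
#' rejected; (domain, prey) pairs must be unique within a library.
#'
#' @param interactions Data.frame from [aggregate_interactions()] (at
#'   minimum `bait_domain_id`, `prey_protein_id`; `library` and `n_hits`
#'   are filled with defaults when missing).
#' @param catalog Domain catalog rows (`domain_id`, `protein_id`).
#' @param auto_activators Character vector of auto-activator domain ids.
#' @param library Library label when `interactions` lacks one.
#' @return A `pdz_network` object.
#' @export
assemble_network <- function(interactions, catalog,
                             auto_activators = character(),
                             library = "cDNA") {
  edges <- interactions
  if (is.null(edges$library)) edges$library <- library
  if (is.null(edges$n_hits)) edges$n_hits <- 1L
  stopifnot(all(c("bait_domain_id", "prey_protein_id") %in% names(edges)))
  if (nrow(edges) > 0) {
    bad <- edges$bait_domain_id %in% auto_activators
    if (any(bad))
      stop("edges involve auto-activator bait(s): ",
           paste(unique(edges$bait_domain_id[bad]), collapse = ", "))
    key <- paste(edges$bait_domain_id, edges$prey_protein_id, edges$library)
    if (anyDuplicated(key))
      stop("duplicate (domain, prey) edge within a library")
    unknown <- !(edges$bait_domain_id %in% catalog$domain_id)
    if (any(unknown))
      stop("edges reference domains absent from the catalog: ",
           paste(unique(edges$bait_domain_id[unknown]), collapse = ", "))
  }
  structure(list(edges = edges, catalog = catalog,
                 auto_activators = auto_activators,
                 library = library),
            class = "pdz_network")
}

#' @export
print.pdz_network <- function(x, ...) {
  cat(sprintf("pdz_network (%s): %d edges, %d/%d productive domains, %d preys\n",
              x$library, nrow(x$edges),
              length(unique(x$edges$bait_domain_id)),
              nrow(x$catalog),
              length(unique(x$edges$prey_protein_id))))
  invisible(x)
}

#' Degree and coverage statistics of a network
#'
#' Promiscuity statistics on both sides of the bipartite network. The mean
#' degree is interactions per productive domain (domains with at least one
#' edge); coverage is productive domains over the full catalog, with
#' auto-activators counted in the denominator. Medians are computed over
#' productive domains (respectively observed preys). Display values use
#' half-away-from-zero rounding: coverage as an integer percentage, the
#' domain mean to `mean_digits` decimals.
#'
#' @param network A `pdz_network`.
#' @param mean_digits Decimals of the displayed mean degree (screens of a
#'   non-normalized library are conventionally reported as integers,
#'   normalized ones at one decimal).
#' @return List: `domain_degrees`, `prey_degrees` (data.frames),
#'   `n_edges`, `n_domains_productive`, `n_catalog`, `mean_degree`,
#'   `median_degree`, `coverage`, `prey_mean_degree`, `prey_median_degree`,
#'   and display-rounded `mean_degree_display`, `coverage_pct`.
#' @export
degree_stats <- function(network, mean_digits = 0) {
  stopifnot(inherits(network, "pdz_network"))
  if (nrow(network$catalog) == 0) stop("empty domain catalog")
  edges <- network$edges
  dom_tab <- table(edges$bait_domain_id)
  prey_tab <- table(edges$prey_protein_id)
  n_edges <- nrow(edges)
  n_prod <- length(dom_tab)
  n_cat <- nrow(network$catalog)
  mean_deg <- if (n_prod > 0) n_edges / n_prod else NA_real_
  prey_mean <- if (length(prey_tab) > 0) n_edges / length(prey_tab) else NA_real_
  list(
    domain_degrees = data.frame(domain_id = names(dom_tab),
                                degree = as.integer(dom_tab),
                                stringsAsFactors = FALSE),
    prey_degrees = data.frame(prey_protein_id = names(prey_tab),
                              degree = as.integer(prey_tab),
                              stringsAsFactors = FALSE),
    n_edges = n_edges,
    n_domains_productive = n_prod,
    n_catalog = n_cat,
    mean_degree = mean_deg,
    median_degree = if (n_prod > 0) stats::median(as.integer(dom_tab)) else NA_real_,
    coverage = n_prod / n_cat,
    prey_mean_degree = prey_mean,
    prey_median_degree = if (length(prey_tab) > 0)
      stats::median(as.integer(prey_tab)) else NA_real_,
    mean_degree_display = round_half_away(mean_deg, mean_digits),
    coverage_pct = percent_of(n_prod, n_cat)
  )
}

#' Consensus-class composition of interacting proteins
#'
#' Builds the two rows of a class-proportion table for a screen: the
#' redundant row counts each interaction once (a promiscuous prey
#' contributes once per partner domain), the nonredundant row counts each
#' distinct prey once. A proteome background row can be appended for
#' comparison.
#'
#' @param network A `pdz_network`.
#' @param consensus_calls Data.frame from [classify_proteome()] (uses
#'   `cls_gene`, the class after the conservative splice-form rule).
#' @param proteome_table Optional output of [proteome_class_table()] for
#'   the background row.
#' @return Data.frame with rows `redundant`, `nonredundant` (and
#'   `proteome`): integer percentage columns `class1`, `class2`, `class3`,
#'   `total_consensus`, `total_nonconsensus`, plus `n`.
#' @export
class_proportion_table <- function(network, consensus_calls,
                                   proteome_table = NULL) {
  stopifnot(inherits(network, "pdz_network"))
  edges <- network$edges
  cls_of <- stats::setNames(consensus_calls$cls_gene,
                            consensus_calls$protein_id)
  missing <- setdiff(edges$prey_protein_id, names(cls_of))
  if (length(missing) > 0)
    stop("unclassified prey protein(s): ", paste(missing, collapse = ", "))
  row_of <- function(cls_vec) {
    n <- length(cls_vec)
    counts <- table(factor(cls_vec, levels = c("1", "2", "3", "none")))
    cons <- sum(counts[c("1", "2", "3")])
    data.frame(class1 = percent_of(counts[["1"]], n),
               class2 = percent_of(counts[["2"]], n),
               class3 = percent_of(counts[["3"]], n),
               total_consensus = percent_of(cons, n),
               total_nonconsensus = percent_of(n - cons, n),
               n = n)
  }
  red <- row_of(cls_of[edges$prey_protein_id])
  nr <- row_of(cls_of[unique(edges$prey_protein_id)])
  out <- rbind(redundant = red, nonredundant = nr)
  if (!is.null(proteome_table)) {
    pt <- proteome_table
    bg <- data.frame(
      class1 = round_half_away(100 * pt$proportions[["1"]]),
      class2 = round_half_away(100 * pt$proportions[["2"]]),
      class3 = round_half_away(100 * pt$proportions[["3"]]),
      total_consensus = round_half_away(100 * pt$total_consensus[["proportion"]]),
      total_nonconsensus = round_half_away(
        100 * (1 - pt$total_consensus[["proportion"]])),
      n = pt$n)
    rownames(bg) <- "proteome"
    out <- rbind(out, bg)
  }
  out
}

#' Overlap between two screens
#'
#' Shared (domain, prey) pairs between two networks over the same catalog,
#' with the percentage expressed relative to the smaller screen's edge
#' count and rounded to the nearest integer.
#'
#' @param network_a,network_b `pdz_network` objects.
#' @return List: `shared` (count), `shared_edges` (data.frame),
#'   `percent`.
#' @export
network_overlap <- function(network_a, network_b) {
  a <- network_a$edges; b <- network_b$edges
  key_a <- paste(a$bait_domain_id, a$prey_protein_id)
  key_b <- paste(b$bait_domain_id, b$prey_protein_id)
  shared_keys <- intersect(key_a, key_b)
  shared <- length(shared_keys)
  pct <- if (min(nrow(a), nrow(b)) == 0) 0 else
    percent_of(shared, min(nrow(a), nrow(b)))
  list(shared = shared,
       shared_edges = a[key_a %in% shared_keys,
                        c("bait_domain_id", "prey_protein_id"), drop = FALSE],
       percent = pct)
}

#' Pool screens from several libraries
#'
#' Concatenates per-library edge sets, keeping library provenance:
#' the pooled interaction count is the plain sum over libraries
#' (cross-library duplicate pairs are not merged), while distinct-prey and
#' distinct-domain counts are computed over the union.
#'
#' @param networks List of `pdz_network` objects sharing a catalog.
#' @return List: `network` (pooled `pdz_network` with library label
#'   `"pooled"`), `n_interactions`, `n_preys`, `n_domains`.
#' @export
pool_networks <- function(networks) {
  stopifnot(length(networks) >= 1,
            all(vapply(networks, inherits, logical(1), "pdz_network")))
  edges <- do.call(rbind, lapply(networks, function(nw) nw$edges))
  pooled <- structure(list(edges = edges, catalog = networks[[1]]$catalog,
                           auto_activators = unique(unlist(
                             lapply(networks, `[[`, "auto_activators"))),
                           library = "pooled"),
                      class = "pdz_network")
  list(network = pooled,
       n_interactions = nrow(edges),
       n_preys = length(unique(edges$prey_protein_id)),
       n_domains = length(unique(edges$bait_domain_id)))
}

#' Export a network as GraphML and/or SIF
#'
#' Writes the bipartite graph with node attributes `node_kind`
#' (`domain`/`prey`) and `consensus_class`, and edge attributes `library`
#' and `n_hits`. Only domains with at least one edge become nodes.
#'
#' @param network A `pdz_network`.
#' @param consensus_calls Optional [classify_proteome()] output for prey
#'   class attributes.
#' @param graphml_path,sif_path Output paths (either may be `NULL`).
#' @return Invisibly, the igraph object.
#' @export
export_graph <- function(network, consensus_calls = NULL,
                         graphml_path = NULL, sif_path = NULL) {
  edges <- network$edges
  # domain nodes are namespaced: a prey protein may share its id with a
  # single-domain bait protein, yet is a distinct node of the bipartite graph
  doms <- unique(paste0("PDZ:", edges$bait_domain_id))
  preys <- unique(edges$prey_protein_id)
  el <- data.frame(from = paste0("PDZ:", edges$bait_domain_id),
                   to = edges$prey_protein_id,
                   library = edges$library, n_hits = edges$n_hits,
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(
      name = c(doms, preys),
      node_kind = c(rep("domain", length(doms)), rep("prey", length(preys))),
      stringsAsFactors = FALSE))
  cls <- rep("", igraph::vcount(g))
  if (!is.null(consensus_calls)) {
    idx <- match(igraph::V(g)$name, consensus_calls$protein_id)
    cls <- ifelse(is.na(idx) | igraph::V(g)$node_kind == "domain", "",
                  consensus_calls$cls_gene[idx])
  }
  g <- igraph::set_vertex_attr(g, "consensus_class", value = cls)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(sif_path)) {
    sif <- paste(paste0("PDZ:", edges$bait_domain_id), "pd",
                 edges$prey_protein_id)
    writeLines(sif, sif_path)
  }
  invisible(g)
}
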