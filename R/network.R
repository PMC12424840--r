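#' Build the species-compound bipartite network
#'
#' One node per species and per compound, one edge per distinct
#' (species, compound) link. Compound nodes carry their chemical-class bin
#' for styling exports; species nodes carry genus and the focal-genus
#' flag. Only compounds with at least one edge become nodes.
#'
#' @param dataset A `formula_dataset`.
#' @param genus Optional genus restricting the species side.
#' @param class_map Class map used to bin compound nodes.
#' @return A `bipartite_network`: list of `species_nodes`,
#'   `compound_nodes` and `edges` tibbles.
#' @export
build_bipartite <- function(dataset, genus = NULL,
                            class_map = default_class_map()) {
  stopifnot(inherits(dataset, "formula_dataset"))
  sp <- dataset$species
  if (!is.null(genus)) sp <- filter(sp, .data$genus == !!genus)
  edges <- dataset$species_compounds |>
    filter(.data$species %in% sp$species) |>
    distinct(.data$species, .data$compound_key) |>
    arrange(.data$species, .data$compound_key)
  compound_nodes <- dataset$compounds |>
    filter(.data$compound_key %in% edges$compound_key) |>
    classify_compounds(class_map) |>
    select("compound_key", "bin") |>
    arrange(.data$compound_key)
  species_nodes <- sp |>
    filter(.data$species %in% edges$species) |>
    arrange(.data$species)
  structure(list(species_nodes = species_nodes,
                 compound_nodes = compound_nodes, edges = edges),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %d species, %d compounds, %d edges\n",
              nrow(x$species_nodes), nrow(x$compound_nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Project the bipartite network onto species
#'
#' Weighted species-species edges quantifying metabolome sharedness: for
#' each pair, `shared` is the number of compounds present in both species
#' and `jaccard = shared / (deg_a + deg_b - shared)` the normalized
#' overlap. Symmetric by construction; pairs below `min_shared` are
#' dropped, and raising `min_shared` never adds edges.
#'
#' @param network A `bipartite_network`.
#' @param min_shared Minimum shared-compound count for an edge (default 1).
#' @return A tibble with class `"species_projection"`: `species_a` <
#'   `species_b` lexicographically, `shared`, `jaccard`, sorted by the
#'   pair.
#' @export
project_species <- function(network, min_shared = 1) {
  stopifnot(inherits(network, "bipartite_network"))
  e <- network$edges
  deg <- count(e, .data$species, name = "degree")
  pairs <- e |>
    inner_join(e, by = "compound_key", relationship = "many-to-many",
               suffix = c("_a", "_b")) |>
    filter(.data$species_a < .data$species_b) |>
    count(.data$species_a, .data$species_b, name = "shared") |>
    filter(.data$shared >= min_shared) |>
    left_join(deg, by = c(species_a = "species")) |>
    left_join(deg, by = c(species_b = "species"),
              suffix = c("_a", "_b")) |>
    mutate(jaccard = .data$shared /
             (.data$degree_a + .data$degree_b - .data$shared)) |>
    select("species_a", "species_b", "shared", "jaccard") |>
    arrange(.data$species_a, .data$species_b)
  structure(pairs, class = c("species_projection", class(pairs)))
}

as_igraph_network <- function(x) {
  if (inherits(x, "bipartite_network")) {
    vertices <- bind_rows(
      tibble(name = x$species_nodes$species, side = "species",
             bin = NA_character_, genus = x$species_nodes$genus,
             is_target_genus = x$species_nodes$is_target_genus),
      tibble(name = x$compound_nodes$compound_key, side = "compound",
             bin = x$compound_nodes$bin, genus = NA_character_,
             is_target_genus = NA)
    )
    igraph::graph_from_data_frame(
      d = x$edges, directed = FALSE, vertices = vertices)
  } else if (inherits(x, "species_projection")) {
    vertices <- tibble(name = sort(unique(c(x$species_a, x$species_b))))
    igraph::graph_from_data_frame(
      d = as_tibble(x), directed = FALSE, vertices = vertices)
  } else {
    abort("export_network: unknown object type")
  }
}

#' Export a network as an edge list and/or GraphML
#'
#' Writes a tab-delimited edge list and/or a GraphML XML file with node
#' attributes (bipartite side, class bin, genus flag; edge weights for
#' projections). Output is byte-stable for a fixed input: node and edge
#' order are deterministic.
#'
#' @param x A `bipartite_network` or `species_projection`.
#' @param edgelist_path Optional path for the TSV edge list.
#' @param graphml_path Optional path for the GraphML file.
#' @return Invisible character vector of the files written.
#' @export
export_network <- function(x, edgelist_path = NULL, graphml_path = NULL) {
  written <- character(0)
  if (!is.null(edgelist_path)) {
    df <- if (inherits(x, "bipartite_network")) x$edges else as_tibble(x)
    readr::write_tsv(df, edgelist_path, eol = "\n", progress = FALSE)
    written <- c(written, edgelist_path)
  }
  if (!is.null(graphml_path)) {
    g <- as_igraph_network(x)
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}

#' Read back an exported edge list
#'
#' @param path Path to a TSV written by [export_network()].
#' @return A tibble of the edges.
#' @export
read_edgelist <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}
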