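# Merged directed pathway graphs, all-pairs shortest-path distances with the
# unreachable-equals-N convention, and the distance-based SNP-DEG p-value.
#
# With d the N x N matrix of shortest directed path lengths (diagonal 0,
# unreachable entries set to N), the association p-value of a (gSNP, gDEG)
# pair is the fraction of all N^2 ordered gene pairs (diagonal included)
# whose distance is <= d[gSNP, gDEG]. A cis pair (same gene, distance 0) is
# therefore always the most significant.

#' Merge directed pathway graphs
#'
#' Node set is the union of all endpoints (plus `nodes`); duplicate edges
#' collapse to one; direction is preserved.
#'
#' @param graphs List of edge-list tibbles with columns `source`, `target`.
#' @param nodes Optional character vector of extra (possibly isolated) genes.
#' @return A directed `igraph` graph.
#' @export
merge_pathways <- function(graphs, nodes = NULL) {
  if (length(graphs) == 0) abort("at least one pathway graph is required")
  edges <- bind_rows(graphs) |>
    distinct(.data$source, .data$target)
  all_nodes <- unique(c(edges$source, edges$target, nodes))
  if (length(all_nodes) == 0) abort("merged pathway graph has no genes")
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = tibble(name = all_nodes))
}

#' All-pairs shortest-path distance matrix
#'
#' Shortest directed path lengths between every ordered gene pair (unit edge
#' weights). Pairs with no connecting path get distance N, the number of
#' genes in the merged graph; the diagonal is 0.
#'
#' @param g A directed `igraph` graph from [merge_pathways()].
#' @return Integer N x N matrix with gene names as dimnames and
#'   `attr(, "n_genes")` = N.
#' @export
all_pairs_distances <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g, mode = "out", algorithm = "unweighted")
  d[is.infinite(d)] <- n
  storage.mode(d) <- "integer"
  diag(d) <- 0L
  attr(d, "n_genes") <- n
  d
}

#' Pathway-distance SNP-DEG association p-value
#'
#' @param gsnp Gene harbouring the SNP.
#' @param gdeg Differentially expressed gene.
#' @param d Distance matrix from [all_pairs_distances()].
#' @return Tibble with `gsnp`, `gdeg`, `distance`, `pvalue` where
#'   `pvalue = #\{(i,j): d[i,j] <= d[gsnp,gdeg]\} / N^2`.
#' @export
snp_deg_pvalue <- function(gsnp, gdeg, d) {
  for (g in c(gsnp, gdeg)) {
    if (!g %in% rownames(d)) abort(sprintf("gene '%s' is not in the pathway graph", g))
  }
  n <- nrow(d)
  dist <- d[gsnp, gdeg]
  tibble(gsnp = gsnp, gdeg = gdeg, distance = as.integer(dist),
         pvalue = sum(d <= dist) / n^2)
}

#' Read a two-column edge list
#'
#' @param path TSV with columns `source<TAB>target` (no header).
#' @return Edge tibble suitable for [merge_pathways()].
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, col_names = c("source", "target"), col_types = "cc")
}

#' Parse a KGML pathway file into a directed edge list
#'
#' Reduces KGML to gene -> gene edges: `entry` elements of type `gene`
#' contribute their (space-separated) gene names; each `relation` element
#' yields all edges from the genes of `entry1` to the genes of `entry2`.
#' Relation subtypes (activation, inhibition, ...) are ignored.
#'
#' @param path Path to a KGML (.xml) file.
#' @return Edge tibble with `source`, `target`.
#' @export
read_kgml <- function(path) {
  doc <- xml2::read_xml(path)
  entries <- xml2::xml_find_all(doc, ".//entry[@type='gene']")
  genes_by_id <- setNames(
    strsplit(xml2::xml_attr(entries, "name"), "\\s+"),
    xml2::xml_attr(entries, "id"))
  relations <- xml2::xml_find_all(doc, ".//relation")
  edges <- purrr::map(relations, function(rel) {
    src <- genes_by_id[[xml2::xml_attr(rel, "entry1")]]
    tgt <- genes_by_id[[xml2::xml_attr(rel, "entry2")]]
    if (is.null(src) || is.null(tgt)) return(NULL)
    tidyr::crossing(source = src, target = tgt)
  }) |> bind_rows()
  if (nrow(edges) == 0) tibble(source = character(), target = character())
  else distinct(edges)
}
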