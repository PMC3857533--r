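## Per-disease miRNA-mediated post-transcriptional interaction networks:
## bipartite miRNA -> {circRNA, mRNA, lncRNA} graphs restricted to the
## miRNAs of one disease, exported in formats a graph viewer (e.g.
## Cytoscape) loads directly.

#' Build the miRNA interaction network of one disease
#'
#' Nodes are the disease's miRNAs (after the optional curation filter) plus
#' every target any of them interacts with; edges are exactly the
#' interaction rows restricted to those miRNAs. Disease miRNAs without any
#' target are kept as isolated nodes. Target node identity is the pair
#' (id, class): an mRNA and a lncRNA sharing a symbol remain distinct nodes.
#'
#' @param disease disease name present in `diseases`.
#' @param diseases a [disease_mirna_map()].
#' @param interactions an [interaction_table()].
#' @param curated_only restrict to the curated miRNA subset; if the subset is
#'   undefined or empty the network is empty and a warning is raised.
#' @return object of class `disease_network`: list with `disease`, `nodes`
#'   (data.frame `id`, `class`) and `edges` (data.frame `mirna_id`,
#'   `target_id`, `target_class`), both lexicographically sorted.
#' @export
build_disease_network <- function(disease, diseases, interactions,
                                  curated_only = FALSE) {
  stopifnot(inherits(diseases, "disease_mirna_map"),
            inherits(interactions, "interaction_table"))
  if (!disease %in% names(diseases$map))
    stop("unknown disease: ", disease, " (available: ",
         paste(names(diseases$map), collapse = ", "), ")")
  mirnas <- disease_mirnas(diseases, disease, curated_only)
  if (!length(mirnas))
    warning("disease '", disease, "' has an empty miRNA set",
            if (curated_only) " after curation filter" else "", call. = FALSE)
  ed <- interactions$edges
  ed <- ed[ed$mirna_id %in% mirnas, , drop = FALSE]
  ed <- ed[order(ed$mirna_id, ed$target_class, ed$target_id), , drop = FALSE]
  rownames(ed) <- NULL
  mirna_nodes <- sort(unique(mirnas))
  nodes <- rbind(
    data.frame(id = mirna_nodes, class = rep("miRNA", length(mirna_nodes)),
               stringsAsFactors = FALSE),
    unique(data.frame(id = ed$target_id, class = ed$target_class,
                      stringsAsFactors = FALSE))
  )
  nodes <- nodes[order(nodes$class, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  net <- structure(list(disease = disease, nodes = nodes, edges = ed),
                   class = "disease_network")
  assert_bipartite(net)
  net
}

# invariant: edges only run miRNA -> target, no self-loops, no duplicates
assert_bipartite <- function(net) {
  ed <- net$edges
  mirnas <- net$nodes$id[net$nodes$class == "miRNA"]
  targets_in_mirnas <- ed$target_id %in% mirnas &
    ed$target_class %in% "miRNA"  # target classes never include miRNA
  if (any(ed$mirna_id == ed$target_id & ed$target_class == "miRNA") ||
      any(targets_in_mirnas))
    stop("network is not bipartite")
  if (anyDuplicated(ed)) stop("duplicate edges in network")
  invisible(net)
}

#' @export
print.disease_network <- function(x, ...) {
  cat("disease_network '", x$disease, "': ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Export a network as SIF (Simple Interaction Format)
#'
#' One line per edge: `mirna_id<TAB>targets_<class><TAB>target_id`, in
#' deterministic lexicographic order, so re-export of the same network is
#' byte-identical regardless of input ordering.
#'
#' @param net a `disease_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_sif <- function(net, path) {
  stopifnot(inherits(net, "disease_network"))
  ed <- net$edges
  lines <- sprintf("%s\ttargets_%s\t%s", ed$mirna_id, ed$target_class,
                   ed$target_id)
  writeLines(sort(lines), path, sep = "\n")
  invisible(path)
}

#' Read a SIF file written by [export_sif()]
#' @param path path to the SIF file.
#' @return data.frame `mirna_id`, `target_id`, `target_class`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(mirna_id = character(), target_id = character(),
                      target_class = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3)) stop("malformed SIF line")
  mat <- do.call(rbind, parts)
  cls <- sub("^targets_", "", mat[, 2])
  data.frame(mirna_id = mat[, 1], target_id = mat[, 3], target_class = cls,
             stringsAsFactors = FALSE)
}

#' Export a network as GraphML with node-class attributes
#'
#' Vertex names are node ids; when the same symbol occurs in more than one
#' class the clashing ids are disambiguated as `id|class`. The `class`
#' vertex attribute always carries the node class.
#'
#' @inheritParams export_sif
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  stopifnot(inherits(net, "disease_network"))
  nodes <- net$nodes
  vname <- nodes$id
  clash <- nodes$id %in% nodes$id[duplicated(nodes$id)]
  vname[clash] <- paste(nodes$id[clash], nodes$class[clash], sep = "|")
  key <- setNames(vname, paste(nodes$id, nodes$class, sep = "\r"))
  ed <- net$edges
  edf <- data.frame(
    from = unname(key[paste(ed$mirna_id, "miRNA", sep = "\r")]),
    to = unname(key[paste(ed$target_id, ed$target_class, sep = "\r")]),
    stringsAsFactors = FALSE
  )
  vdf <- data.frame(name = vname, class = nodes$class, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the node attribute table accompanying a SIF export
#' @inheritParams export_sif
#' @return `path`, invisibly.
#' @export
export_node_table <- function(net, path) {
  stopifnot(inherits(net, "disease_network"))
  df <- net$nodes
  names(df) <- c("node_id", "class")
  write_tsv_lf(df, path)
}

#' Degrees and node-class counts of a disease network
#'
#' The class counts are the per-disease bar heights of a
#' "targets-per-disease" summary: the numbers of distinct mRNA, lncRNA and
#' circRNA nodes interacting with the disease's miRNAs.
#'
#' @param net a `disease_network`.
#' @return list with `class_counts` (named integer: miRNA, circRNA, mRNA,
#'   lncRNA) and `degrees` (data.frame `id`, `class`, `degree`). The sum of
#'   miRNA out-degrees equals the edge count.
#' @export
network_degree_summary <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  nodes <- net$nodes
  cc <- table(factor(nodes$class, levels = c("miRNA", TARGET_CLASSES)))
  key <- paste(nodes$id, nodes$class, sep = "\r")
  deg <- setNames(integer(nrow(nodes)), key)
  ed <- net$edges
  if (nrow(ed)) {
    up <- table(paste(ed$mirna_id, "miRNA", sep = "\r"))
    deg[names(up)] <- deg[names(up)] + as.integer(up)
    dn <- table(paste(ed$target_id, ed$target_class, sep = "\r"))
    deg[names(dn)] <- deg[names(dn)] + as.integer(dn)
  }
  list(
    class_counts = setNames(as.integer(cc), names(cc)),
    degrees = data.frame(id = nodes$id, class = nodes$class,
                         degree = as.integer(deg), row.names = NULL,
                         stringsAsFactors = FALSE)
  )
}
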