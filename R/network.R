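#' Construct a LayeredNetwork
#'
#' @param layers named list of character node-id vectors, in layer order.
#' @param edges data.frame with `from` (earlier layer) and `to` (adjacent
#'   later layer) character columns; duplicates are collapsed.
#' @param nodeLabels named character display names; defaults to the ids.
#' @return A validated [LayeredNetwork-class].
#' @export
LayeredNetwork <- function(layers, edges, nodeLabels = NULL) {
  layers <- lapply(layers, as.character)
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  rownames(edges) <- NULL
  ids <- unlist(layers, use.names = FALSE)
  if (is.null(nodeLabels)) nodeLabels <- stats::setNames(ids, ids)
  new("LayeredNetwork", layers = layers, edges = edges,
      nodeLabels = nodeLabels)
}

#' Build the bipartite compound-target (C-T) network
#'
#' One edge per distinct (compound, target) interaction. Compounds without
#' surviving interactions are retained as isolated nodes (they were
#' screened); targets appear only when connected.
#'
#' @param compounds a [CompoundSet-class]; every interaction's compound
#'   must appear here.
#' @param interactions interaction data.frame with `compound_id` and
#'   `target_id` columns.
#' @return A two-layer [LayeredNetwork-class] with layers `compound` and
#'   `target`.
#' @export
buildCTNetwork <- function(compounds, interactions) {
  stopifnot(is(compounds, "CompoundSet"))
  unknown <- setdiff(interactions$compound_id, compounds@ids)
  if (length(unknown))
    stop("interactions reference unknown compound(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  targets <- sort(unique(as.character(interactions$target_id)))
  edges <- data.frame(from = as.character(interactions$compound_id),
                      to = as.character(interactions$target_id),
                      stringsAsFactors = FALSE)
  labels <- c(stats::setNames(compounds@names, compounds@ids),
              stats::setNames(targets, targets))
  LayeredNetwork(list(compound = compounds@ids, target = targets),
                 edges, labels)
}

#' Build the tripartite compound-target-pathway (C-T-P) network
#'
#' Compounds are restricted to `pairCompounds` (typically the compounds
#' appearing in the top-ranked synergistic pairs); their targets come from
#' `interactions`; a target-pathway edge is placed whenever the pathway
#' set contains the target. Pathways with no such target are omitted.
#' Compound-target edges are kept even for targets in no pathway.
#'
#' @param pairCompounds character vector of compound ids.
#' @param interactions interaction data.frame (`compound_id`, `target_id`).
#' @param pathwaySets a [GeneSets-class] of pathway memberships.
#' @return A three-layer [LayeredNetwork-class] (`compound`, `target`,
#'   `pathway`).
#' @export
buildCTPNetwork <- function(pairCompounds, interactions, pathwaySets) {
  stopifnot(is(pathwaySets, "GeneSets"))
  pairCompounds <- sort(unique(as.character(pairCompounds)))
  sub <- interactions[interactions$compound_id %in% pairCompounds, , drop = FALSE]
  targets <- sort(unique(as.character(sub$target_id)))
  ctEdges <- data.frame(from = as.character(sub$compound_id),
                        to = as.character(sub$target_id),
                        stringsAsFactors = FALSE)
  tpEdges <- do.call(rbind, lapply(names(pathwaySets@sets), function(pw) {
    hit <- intersect(pathwaySets@sets[[pw]], targets)
    if (length(hit) == 0L) return(NULL)
    data.frame(from = hit, to = pw, stringsAsFactors = FALSE)
  }))
  pathways <- if (is.null(tpEdges)) character(0) else sort(unique(tpEdges$to))
  edges <- rbind(ctEdges, tpEdges)
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character())
  labels <- c(stats::setNames(pairCompounds, pairCompounds),
              stats::setNames(targets, targets),
              stats::setNames(unname(pathwaySets@termNames[pathways]), pathways))
  LayeredNetwork(list(compound = pairCompounds, target = targets,
                      pathway = pathways),
                 edges, labels)
}

#' Degree statistics of a layered network
#'
#' Per-node degrees and, per layer, the mean number of edge endpoints per
#' node: (edges incident to the layer) / (layer size), computed exactly
#' before any rounding. For a two-layer network every edge touches both
#' layers, so each partition mean is simply |E| / |layer|.
#'
#' @param net a [LayeredNetwork-class] (any number of layers); at least one
#'   node per layer.
#' @return A [DegreeReport-class].
#' @rdname degreeStatistics
#' @export
setMethod("degreeStatistics", "LayeredNetwork", function(net) {
  if (any(lengths(net@layers) == 0L))
    stop("degenerate network: empty partition")
  ids <- unlist(net@layers, use.names = FALSE)
  deg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(c(net@edges$from, net@edges$to))
  deg[names(tab)] <- as.integer(tab)
  nodeLayer <- stats::setNames(
    rep(names(net@layers), lengths(net@layers)), ids)
  means <- vapply(names(net@layers), function(ln) {
    members <- net@layers[[ln]]
    sum(deg[members]) / length(members)
  }, numeric(1))
  new("DegreeReport", perNode = deg, nodeLayer = nodeLayer,
      partitionMeans = means, nEdges = nrow(net@edges))
})

#' Hub nodes of one partition
#'
#' Nodes whose degree strictly exceeds a threshold: by default the mean
#' degree of their own partition. Results are sorted by degree descending,
#' ties broken by node id.
#'
#' @param report a [DegreeReport-class].
#' @param layer partition name.
#' @param threshold `"partition_mean"` (default) or a numeric cutoff.
#' @return Character vector of hub node ids.
#' @rdname hubNodes
#' @export
setMethod("hubNodes", "DegreeReport", function(report, layer,
                                               threshold = "partition_mean") {
  if (!layer %in% unique(report@nodeLayer))
    stop("unknown layer: ", layer)
  cut <- if (identical(threshold, "partition_mean"))
    report@partitionMeans[[layer]] else as.numeric(threshold)
  members <- names(report@nodeLayer)[report@nodeLayer == layer]
  deg <- report@perNode[members]
  hubs <- deg[deg > cut]
  names(hubs)[order(-hubs, names(hubs))]
})

#' Export a layered network to standard graph formats
#'
#' * `sif`: one line per edge, `source<TAB>relation<TAB>target`, relation
#'   being the adjacent-layer pair name (e.g. `compound-target`).
#' * `graphml`: GraphML via igraph, with `layer` and `label` node
#'   attributes.
#' * `tsv`: two tables, `<file>.nodes.tsv` (id, layer, label) and
#'   `<file>.edges.tsv` (from, to, relation); [importNetworkTSV()] on the
#'   same stem reproduces the network.
#'
#' @param net a [LayeredNetwork-class].
#' @param file output path (for `tsv`, the stem of the two files).
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return The path(s) written, invisibly.
#' @rdname exportNetwork
#' @export
setMethod("exportNetwork", "LayeredNetwork",
  function(net, file, format = c("sif", "graphml", "tsv")) {
    format <- match.arg(format)
    rel <- edgeRelations(net)
    if (format == "sif") {
      writeLines(paste(net@edges$from, rel, net@edges$to, sep = "\t"), file)
      return(invisible(file))
    }
    if (format == "graphml") {
      g <- asIgraph(net)
      igraph::write_graph(g, file, format = "graphml")
      return(invisible(file))
    }
    nodesPath <- paste0(file, ".nodes.tsv")
    edgesPath <- paste0(file, ".edges.tsv")
    ids <- unlist(net@layers, use.names = FALSE)
    nodes <- data.frame(
      id = ids,
      layer = rep(names(net@layers), lengths(net@layers)),
      label = unname(net@nodeLabels[ids]),
      stringsAsFactors = FALSE)
    utils::write.table(nodes, nodesPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    edges <- data.frame(from = net@edges$from, to = net@edges$to,
                        relation = rel, stringsAsFactors = FALSE)
    utils::write.table(edges, edgesPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(nodesPath, edgesPath))
  })

#' Re-import a network written as TSV node/edge tables
#'
#' @param file the stem passed to `exportNetwork(..., format = "tsv")`.
#' @return A [LayeredNetwork-class] isomorphic to the exported one.
#' @export
importNetworkTSV <- function(file) {
  nodes <- utils::read.table(paste0(file, ".nodes.tsv"), sep = "\t",
                             header = TRUE, colClasses = "character",
                             quote = "")
  edges <- utils::read.table(paste0(file, ".edges.tsv"), sep = "\t",
                             header = TRUE, colClasses = "character",
                             quote = "")
  layerNames <- unique(nodes$layer)
  layers <- lapply(layerNames, function(ln) nodes$id[nodes$layer == ln])
  names(layers) <- layerNames
  LayeredNetwork(layers, edges[, c("from", "to")],
                 stats::setNames(nodes$label, nodes$id))
}

#' Convert a LayeredNetwork to an igraph graph
#'
#' @param net a [LayeredNetwork-class].
#' @return An undirected [igraph::igraph] with `layer` and `label` vertex
#'   attributes.
#' @export
asIgraph <- function(net) {
  ids <- unlist(net@layers, use.names = FALSE)
  vertices <- data.frame(
    name = ids,
    layer = rep(names(net@layers), lengths(net@layers)),
    label = unname(net@nodeLabels[ids]),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                vertices = vertices)
}

edgeRelations <- function(net) {
  if (nrow(net@edges) == 0L) return(character(0))
  layerOf <- stats::setNames(
    rep(names(net@layers), lengths(net@layers)),
    unlist(net@layers, use.names = FALSE))
  paste(layerOf[net@edges$from], layerOf[net@edges$to], sep = "-")
}
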