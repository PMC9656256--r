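#' Assemble the specific network for one cluster sign
#'
#' The "specific network" joins the nodes of the significant clusters of a
#' given sign with the edges between them that the edge-wise FDR analysis
#' flagged significant: node set = union of member nodes of the selected
#' clusters; edge list = upper-triangle pairs internal to that node set
#' where the mask is 1. Hubs are the member nodes ranked by descending
#' within-network degree, ties broken by atlas index.
#'
#' @param clusters data.frame with columns `sign`, `start`, `end` (as
#'   produced by [significant_clusters()]), or a `node_cluster_result`.
#' @param sign `"positive"` (control > depression) or `"negative"`.
#' @param edge_mask symmetric 0/1 matrix of FDR-significant edges.
#' @param alpha cluster significance level when a `node_cluster_result`
#'   is supplied.
#' @return object of class `specific_network`: `nodes` (sorted atlas
#'   indices), `edges` data.frame (i, j), `degree` (named by node),
#'   `hubs` (node indices in rank order), `sign`.
#' @export
build_specific_network <- function(clusters, sign = c("positive", "negative"),
                                   edge_mask, alpha = 0.05) {
  sign <- match.arg(sign)
  if (inherits(clusters, "node_cluster_result")) {
    clusters <- significant_clusters(clusters, alpha)
  }
  stopifnot(is.matrix(edge_mask), nrow(edge_mask) == ncol(edge_mask))
  if (max(abs(edge_mask - t(edge_mask))) > 0) {
    stop("edge mask must be symmetric", call. = FALSE)
  }
  sel <- clusters[clusters$sign == sign, , drop = FALSE]
  nodes <- as.integer(sort(unique(unlist(
    lapply(seq_len(nrow(sel)), function(k) sel$start[k]:sel$end[k])
  ))))
  if (length(nodes) > 0 && max(nodes) > nrow(edge_mask)) {
    stop("cluster node index exceeds edge-mask dimension", call. = FALSE)
  }
  if (length(nodes) >= 2L) {
    p <- upper_pairs(length(nodes))
    gi <- nodes[p[, 1L]]; gj <- nodes[p[, 2L]]
    keep <- edge_mask[cbind(gi, gj)] != 0
    edges <- data.frame(i = gi[keep], j = gj[keep])
  } else {
    edges <- data.frame(i = integer(0), j = integer(0))
  }
  degree <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges) > 0) {
    tab <- table(factor(c(edges$i, edges$j), levels = nodes))
    degree[] <- as.integer(tab)
  }
  hubs <- nodes[order(-degree, nodes)]
  structure(list(nodes = nodes, edges = edges, degree = degree,
                 hubs = hubs, sign = sign),
            class = "specific_network")
}

#' @export
print.specific_network <- function(x, ...) {
  cat(sprintf("specific_network (%s): %d nodes, %d edges\n",
              x$sign, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a specific network in BrainNet Viewer formats
#'
#' Writes the `.node` file (six whitespace-separated columns: MNI x, y, z,
#' color code, size, label) and the `.edge` file (dense symmetric matrix
#' over the network's nodes, tab-separated, 0 for absent edges). The color
#' code is 1 for positive networks and 2 for negative ones; node size is
#' the within-network degree. An empty network writes two empty files.
#'
#' @param net a [build_specific_network()] result.
#' @param regions region table with columns `index`, `label`, `x`, `y`,
#'   `z` covering every member node.
#' @param node_path,edge_path output file paths.
#' @return invisibly, the two paths.
#' @export
export_brainnet <- function(net, regions, node_path, edge_path) {
  stopifnot(inherits(net, "specific_network"))
  validate_region_table(regions)
  missing <- setdiff(net$nodes, regions$index)
  if (length(missing) > 0) {
    stop(sprintf("missing coordinates for node(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  color <- if (net$sign == "positive") 1 else 2
  if (length(net$nodes) == 0L) {
    writeLines(character(0), node_path)
    writeLines(character(0), edge_path)
    return(invisible(c(node = node_path, edge = edge_path)))
  }
  ri <- match(net$nodes, regions$index)
  node_lines <- sprintf("%g %g %g %d %d %s",
                        regions$x[ri], regions$y[ri], regions$z[ri],
                        color, as.integer(net$degree), regions$label[ri])
  writeLines(node_lines, node_path)
  k <- length(net$nodes)
  adj <- matrix(0, k, k)
  if (nrow(net$edges) > 0) {
    a <- match(net$edges$i, net$nodes); b <- match(net$edges$j, net$nodes)
    adj[cbind(a, b)] <- 1
    adj[cbind(b, a)] <- 1
  }
  utils::write.table(adj, edge_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(c(node = node_path, edge = edge_path))
}

#' Read back a BrainNet Viewer node/edge pair
#'
#' Reconstructs a `specific_network` from files written by
#' [export_brainnet()]; mainly a round-trip check.
#'
#' @param node_path,edge_path file paths.
#' @param regions the region table used at export time.
#' @return a `specific_network` (sign inferred from the color code).
#' @export
read_brainnet <- function(node_path, edge_path, regions) {
  validate_region_table(regions)
  lines <- readLines(node_path)
  if (length(lines) == 0L) {
    return(structure(list(nodes = integer(0),
                          edges = data.frame(i = integer(0), j = integer(0)),
                          degree = setNames(integer(0), character(0)),
                          hubs = integer(0), sign = "positive"),
                     class = "specific_network"))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  labels <- vapply(parts, function(p) p[[6L]], "")
  color <- as.integer(vapply(parts, function(p) p[[4L]], ""))
  nodes <- regions$index[match(labels, regions$label)]
  ord <- order(nodes)
  nodes <- nodes[ord]
  adj <- as.matrix(utils::read.table(edge_path, sep = "\t"))
  adj <- adj[ord, ord, drop = FALSE]
  p <- if (length(nodes) >= 2L) upper_pairs(length(nodes)) else
    cbind(i = integer(0), j = integer(0))
  keep <- adj[p] != 0
  edges <- data.frame(i = nodes[p[keep, 1L]], j = nodes[p[keep, 2L]])
  degree <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges) > 0) {
    tab <- table(factor(c(edges$i, edges$j), levels = nodes))
    degree[] <- as.integer(tab)
  }
  structure(list(nodes = nodes, edges = edges, degree = degree,
                 hubs = nodes[order(-degree, nodes)],
                 sign = if (color[1L] == 2L) "negative" else "positive"),
            class = "specific_network")
}
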