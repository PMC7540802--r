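# Differential-network view: the top-k most regulated links, decomposed into
# size-ordered connected subnetworks and coloured green-white-red by
# regulation, exportable to GraphML for external viewers.

.round_half_up <- function(x) floor(x + 0.5)

#' Green-white-red regulation colour map
#'
#' Linear interpolation in RGB between pure green (down-regulation) at
#' `center - halfwidth`, white (no change) at `center`, and pure red
#' (up-regulation) at `center + halfwidth`; values beyond the bounds clamp.
#' The defaults place the green/red anchors at LinkScores of -0.5 and +0.5.
#'
#' @param value numeric vector of scores.
#' @param center score mapping to white.
#' @param halfwidth positive distance from `center` to the saturated anchors.
#' @return integer matrix with columns `r`, `g`, `b` in 0..255 (a plain
#'   length-3 vector for a single value); channels rounded half-up.
#' @export
colour_map <- function(value, center = 0, halfwidth = 0.5) {
  if (halfwidth <= 0) stop("halfwidth must be positive")
  if (any(!is.finite(value))) stop("colour_map requires finite values")
  t <- pmin(pmax((value - center) / halfwidth, -1), 1)
  r <- ifelse(t <= 0, 255 * (1 + t), 255)
  g <- ifelse(t <= 0, 255, 255 * (1 - t))
  b <- 255 * (1 - abs(t))
  out <- cbind(
    r = .round_half_up(r),
    g = .round_half_up(g),
    b = .round_half_up(b)
  )
  storage.mode(out) <- "integer"
  if (length(value) == 1) out[1, ] else out
}

#' Hex string for colour-map output
#'
#' @param rgb integer matrix/vector as returned by [colour_map()].
#' @return character vector of `#RRGGBB` strings.
#' @export
colour_hex <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  sprintf("#%02X%02X%02X", rgb[, 1], rgb[, 2], rgb[, 3])
}

#' Data-driven node colours
#'
#' Applies [colour_map()] per gene with the white centre at the mean of the
#' supplied values and the halfwidth reaching the more distant of the
#' minimum and maximum, so the mean maps to white and at least one extreme
#' saturates. All-identical values map to all-white.
#'
#' @param values named numeric vector, gene -> expression value (one
#'   condition) or log-fold change.
#' @return integer matrix gene x `(r, g, b)` with attribute `center` and
#'   `halfwidth`.
#' @export
node_colour_map <- function(values) {
  if (length(values) == 0) stop("node_colour_map needs at least one value")
  center <- mean(values)
  halfwidth <- max(max(values) - center, center - min(values))
  out <- if (halfwidth == 0) {
    matrix(
      255L,
      nrow = length(values), ncol = 3,
      dimnames = list(names(values), c("r", "g", "b"))
    )
  } else {
    m <- colour_map(values, center, halfwidth)
    if (is.null(dim(m))) m <- matrix(m, ncol = 3, dimnames = list(NULL, c("r", "g", "b")))
    rownames(m) <- names(values)
    m
  }
  attr(out, "center") <- center
  attr(out, "halfwidth") <- halfwidth
  out
}

#' The k links most regulated by absolute LinkScore
#'
#' @param scored data.frame of scored links as produced by [score_links()]
#'   (needs `link_score` and `link_id` columns).
#' @param k number of links to keep; the published figures use 47.
#' @return the `k` rows with largest `|link_score|`, sorted by absolute score
#'   descending; boundary ties broken by lexicographic link identity.
#' @export
top_k_links <- function(scored, k = 47) {
  if (k > nrow(scored)) {
    stop("k = ", k, " exceeds the ", nrow(scored), " scored links available")
  }
  if (k < 1) stop("k must be at least 1")
  ord <- order(-abs(scored$link_score), scored$link_id)
  out <- scored[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Connected subnetworks of a link set, largest first
#'
#' @param links data.frame of links (`gene_a`, `gene_b`, plus any score
#'   columns, which are carried through).
#' @return list of subnetworks, each a list with `genes` (sorted), `links`
#'   (rows of the input) and `n_links`; ordered by link count descending,
#'   then gene count descending, then smallest gene id.
#' @export
components_by_size <- function(links) {
  if (nrow(links) == 0) return(list())
  g <- igraph::graph_from_data_frame(
    links[, c("gene_a", "gene_b")],
    directed = FALSE
  )
  comp <- igraph::components(g)
  membership <- comp$membership
  subs <- lapply(seq_len(comp$no), function(i) {
    genes <- sort(names(membership)[membership == i])
    rows <- links[links$gene_a %in% genes & links$gene_b %in% genes, ,
      drop = FALSE
    ]
    list(genes = genes, links = rows, n_links = nrow(rows))
  })
  ord <- order(
    -vapply(subs, `[[`, numeric(1), "n_links"),
    -vapply(subs, function(s) length(s$genes), numeric(1)),
    vapply(subs, function(s) s$genes[1], character(1))
  )
  subs[ord]
}

#' Assemble a differential-network view
#'
#' Extracts the top-`k` links by absolute LinkScore, decomposes them into
#' size-ordered connected subnetworks, and attaches green-white-red colours:
#' edges coloured by LinkScore around a fixed centre (default white at 0,
#' saturation at +/-0.5), nodes coloured around the mean of `node_values`.
#'
#' @param scored scored-link data.frame ([score_links()]).
#' @param node_values named numeric vector of per-gene values to colour nodes
#'   by (e.g. one condition's expression, or log-fold change); defaults to
#'   the log-fold changes carried by `scored`.
#' @param k number of top links (default 47).
#' @param edge_center,edge_halfwidth colour anchors for LinkScores.
#' @return a `differential_network_view`: list with `links`, `subnetworks`,
#'   `node_values`, `edge_colours` (hex, named by link_id), `node_colours`
#'   (hex, named by gene), `colour_center`, `colour_halfwidth`.
#' @export
build_view <- function(scored, node_values = NULL, k = 47,
                       edge_center = 0, edge_halfwidth = 0.5) {
  top <- top_k_links(scored, k)
  genes <- sort(unique(c(top$gene_a, top$gene_b)))
  if (is.null(node_values)) {
    lfc <- c(
      stats::setNames(top$logfc_a, top$gene_a),
      stats::setNames(top$logfc_b, top$gene_b)
    )
    node_values <- lfc[genes]
  } else {
    node_values <- node_values[genes]
    if (anyNA(node_values)) stop("node_values missing for some view genes")
  }
  edge_rgb <- colour_map(top$link_score, edge_center, edge_halfwidth)
  if (is.null(dim(edge_rgb))) edge_rgb <- matrix(edge_rgb, ncol = 3)
  node_rgb <- node_colour_map(node_values)
  structure(
    list(
      links = top,
      subnetworks = components_by_size(top),
      node_values = node_values,
      edge_colours = stats::setNames(colour_hex(edge_rgb), top$link_id),
      node_colours = stats::setNames(colour_hex(node_rgb), genes),
      colour_center = edge_center,
      colour_halfwidth = edge_halfwidth
    ),
    class = "differential_network_view"
  )
}

#' Head-to-head view: another experiment's changes on the same link set
#'
#' Keeps the link set of an existing view (typically the disease's top-k)
#' and recomputes every LinkScore, log-fold change and colour from a second
#' experiment's log-fold changes - the side-by-side comparison of what the
#' disease does versus what the drug does to the very same interactions.
#'
#' @param view a `differential_network_view`.
#' @param profile an [experiment_profile()] (e.g. the candidate drug); must
#'   cover every gene in the view.
#' @return a `differential_network_view` over the identical link set.
#' @export
head_to_head_view <- function(view, profile) {
  lfc <- profile$logfc
  genes <- names(view$node_values)
  missing <- setdiff(genes, names(lfc))
  if (length(missing) > 0) {
    stop(
      "profile ", profile$experiment_id, " lacks log-fold changes for ",
      length(missing), " view gene(s), e.g. ", missing[1]
    )
  }
  links <- view$links
  links$logfc_a <- unname(lfc[links$gene_a])
  links$logfc_b <- unname(lfc[links$gene_b])
  links$link_score <- ifelse(
    links$interaction_type == "inhibition",
    links$logfc_a - links$logfc_b,
    links$logfc_a + links$logfc_b
  )
  out <- view
  out$links <- links
  out$subnetworks <- components_by_size(links)
  out$node_values <- lfc[genes]
  edge_rgb <- colour_map(
    links$link_score, view$colour_center, view$colour_halfwidth
  )
  if (is.null(dim(edge_rgb))) edge_rgb <- matrix(edge_rgb, ncol = 3)
  out$edge_colours <- stats::setNames(colour_hex(edge_rgb), links$link_id)
  out$node_colours <- stats::setNames(
    colour_hex(node_colour_map(out$node_values)), genes
  )
  out
}

#' @export
print.differential_network_view <- function(x, ...) {
  sizes <- vapply(x$subnetworks, `[[`, numeric(1), "n_links")
  cat(
    "differential_network_view:", nrow(x$links), "links,",
    length(x$node_values), "genes,", length(x$subnetworks),
    "subnetwork(s) with link counts", paste(sizes, collapse = ", "), "\n"
  )
  invisible(x)
}

#' Export a view as GraphML plus attribute tables
#'
#' Writes `<prefix>.graphml` (node attributes: value, hex colour; edge
#' attributes: LinkScore, interaction type, hex colour) and two TSVs,
#' `<prefix>_nodes.tsv` and `<prefix>_edges.tsv`. The GraphML round-trips
#' through [read_view_graph()].
#'
#' @param view a `differential_network_view`.
#' @param prefix output path prefix (directories must exist).
#' @return invisibly, the GraphML path.
#' @export
export_view <- function(view, prefix) {
  if (nrow(view$links) == 0) warning("exporting an empty view")
  nodes <- data.frame(
    name = names(view$node_values),
    value = unname(view$node_values),
    colour = unname(view$node_colours),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    from = view$links$gene_a,
    to = view$links$gene_b,
    link_score = view$links$link_score,
    interaction_type = view$links$interaction_type,
    colour = unname(view$edge_colours),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  graphml <- paste0(prefix, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  utils::write.table(
    nodes, paste0(prefix, "_nodes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  utils::write.table(
    edges, paste0(prefix, "_edges.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(graphml)
}

#' Read back an exported GraphML view
#'
#' @param path GraphML file written by [export_view()].
#' @return list with `nodes` and `edges` data.frames carrying the exported
#'   attributes; edge rows keyed by [link_identity()].
#' @export
read_view_graph <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(
    name = igraph::V(g)$name,
    value = igraph::V(g)$value,
    colour = igraph::V(g)$colour,
    stringsAsFactors = FALSE
  )
  el <- igraph::as_edgelist(g)
  edges <- data.frame(
    from = el[, 1],
    to = el[, 2],
    link_score = igraph::E(g)$link_score,
    interaction_type = igraph::E(g)$interaction_type,
    colour = igraph::E(g)$colour,
    stringsAsFactors = FALSE
  )
  edges$link_id <- link_identity(edges$from, edges$to, edges$interaction_type)
  list(nodes = nodes, edges = edges)
}
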