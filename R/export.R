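#' Export a connectivity map
#'
#' Three machine-readable renderings of the map:
#' \describe{
#'   \item{`graphml`}{GraphML with node attributes `polarity` and `degree`
#'     and edge attributes `ls` and `distance`, all at full precision;
#'     [read_graphml()] reproduces the map exactly.}
#'   \item{`dot`}{Graphviz DOT; edge labels carry the link strength in the
#'     two-decimal truncated display form (see [display_value()]).}
#'   \item{`edge-tsv`}{Tab-separated edge list, full precision.}
#' }
#'
#' @param map A `connectivity_map`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"dot"`, `"edge-tsv"`.
#' @return The path, invisibly.
#' @export
export_graph <- function(map, path, format = c("graphml", "dot", "edge-tsv")) {
  stopifnot(inherits(map, "connectivity_map"))
  if (length(format) != 1 || !format %in% c("graphml", "dot", "edge-tsv")) {
    stop("unknown export format '", paste(format, collapse = ","),
         "'; options: graphml, dot, edge-tsv", call. = FALSE)
  }
  switch(format,
         "graphml" = write_graphml(map, path),
         "dot" = write_dot(map, path),
         "edge-tsv" = write_edge_tsv(map, path))
  invisible(path)
}

num_chr <- function(x) sprintf("%.17g", x)

write_graphml <- function(map, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(
    c(id = "polarity", `for` = "node", attr.name = "polarity", attr.type = "string"),
    c(id = "degree",   `for` = "node", attr.name = "degree",   attr.type = "int"),
    c(id = "ls",       `for` = "edge", attr.name = "ls",       attr.type = "double"),
    c(id = "distance", `for` = "edge", attr.name = "distance", attr.type = "double"))
  for (k in keys) {
    kn <- xml2::xml_add_child(doc, "key")
    xml2::xml_set_attrs(kn, c(id = k[["id"]], "for" = k[["for"]],
                              "attr.name" = k[["attr.name"]],
                              "attr.type" = k[["attr.type"]]))
  }
  g <- xml2::xml_add_child(doc, "graph", id = "connectivity_map",
                           edgedefault = "undirected")
  for (i in seq_len(nrow(map$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = map$nodes$name[i])
    d1 <- xml2::xml_add_child(nd, "data", key = "polarity")
    xml2::xml_set_text(d1, map$nodes$polarity[i])
    d2 <- xml2::xml_add_child(nd, "data", key = "degree")
    xml2::xml_set_text(d2, as.character(map$nodes$degree[i]))
  }
  for (i in seq_len(nrow(map$edges))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = map$edges$node_a[i],
                              target = map$edges$node_b[i])
    d1 <- xml2::xml_add_child(ed, "data", key = "ls")
    xml2::xml_set_text(d1, num_chr(map$edges$ls[i]))
    d2 <- xml2::xml_add_child(ed, "data", key = "distance")
    xml2::xml_set_text(d2, num_chr(map$edges$distance[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a connectivity map back from GraphML
#'
#' Inverse of `export_graph(format = "graphml")`.
#'
#' @param path GraphML file written by [export_graph()].
#' @return A `connectivity_map`.
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  node_xml <- xml2::xml_find_all(doc, ".//graph/node")
  get_data <- function(x, key) {
    xml2::xml_text(xml2::xml_find_first(x, paste0("./data[@key='", key, "']")))
  }
  nodes <- data.frame(
    name = xml2::xml_attr(node_xml, "id"),
    polarity = vapply(node_xml, get_data, "", key = "polarity"),
    degree = as.integer(vapply(node_xml, get_data, "", key = "degree")),
    stringsAsFactors = FALSE)
  edge_xml <- xml2::xml_find_all(doc, ".//graph/edge")
  edges <- data.frame(
    node_a = xml2::xml_attr(edge_xml, "source"),
    node_b = xml2::xml_attr(edge_xml, "target"),
    ls = as.numeric(vapply(edge_xml, get_data, "", key = "ls")),
    distance = as.numeric(vapply(edge_xml, get_data, "", key = "distance")),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "connectivity_map")
}

write_dot <- function(map, path) {
  quote_id <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("graph connectivity_map {")
  lines <- c(lines, sprintf("  %s [polarity=%s, degree=%d];",
                            quote_id(map$nodes$name),
                            quote_id(map$nodes$polarity),
                            map$nodes$degree))
  lines <- c(lines, sprintf('  %s -- %s [label="%s"];',
                            quote_id(map$edges$node_a),
                            quote_id(map$edges$node_b),
                            display_value(pmin(pmax(map$edges$ls, 0), 1))))
  lines <- c(lines, "}")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

write_edge_tsv <- function(map, path) {
  df <- map$edges
  df$ls <- num_chr(df$ls)
  df$distance <- num_chr(df$distance)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
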