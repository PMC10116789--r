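#' Export a ranked edge list for Cytoscape
#'
#' Writes either SIF (\code{source<TAB>relation<TAB>target}, relation
#' \code{influences_pos} or \code{influences_neg} by edge sign, plus a
#' sidecar \code{*_edges.csv} with weight and dispersion attributes) or
#' GraphML with \code{weight}, \code{sign} and \code{dispersion} edge
#' attributes. Both formats load in Cytoscape.
#'
#' @param edges data.frame from [rankInteractions()] (columns
#'   \code{source}, \code{target}, \code{weight}, \code{dispersion}).
#' @param file output path.
#' @param format \code{"sif"} or \code{"graphml"}.
#' @return the main output path, invisibly.
#' @export
exportNetwork <- function(edges, file, format = c("sif", "graphml")) {
  format <- tolower(format[1])
  if (!format %in% c("sif", "graphml"))
    stop("unknown format '", format, "': use 'sif' or 'graphml'")
  if (!nrow(edges)) stop("edge list is empty")
  rel <- ifelse(edges$weight >= 0, "influences_pos", "influences_neg")
  if (format == "sif") {
    writeLines(paste(edges$source, rel, edges$target, sep = "\t"), file)
    sidecar <- sub("\\.sif$", "", file)
    sidecar <- paste0(sidecar, "_edges.csv")
    write.csv(
      data.frame(source = edges$source, target = edges$target,
                 relation = rel, weight = edges$weight,
                 dispersion = edges$dispersion),
      sidecar, row.names = FALSE)
    return(invisible(file))
  }
  nodes <- sort(unique(c(edges$source, edges$target)))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(v) sprintf("%.17g", v)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\" ",
           "xmlns:xsi=\"http://www.w3.org/2001/XMLSchema-instance\" ",
           "xsi:schemaLocation=\"http://graphml.graphdrawing.org/xmlns ",
           "http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd\">"),
    paste0("  <key id=\"w\" for=\"edge\" attr.name=\"weight\" ",
           "attr.type=\"double\"/>"),
    paste0("  <key id=\"s\" for=\"edge\" attr.name=\"sign\" ",
           "attr.type=\"double\"/>"),
    paste0("  <key id=\"d\" for=\"edge\" attr.name=\"dispersion\" ",
           "attr.type=\"double\"/>"),
    "  <graph id=\"anni\" edgedefault=\"directed\">",
    sprintf("    <node id=\"%s\"/>", esc(nodes)),
    unlist(lapply(seq_len(nrow(edges)), function(i) c(
      sprintf("    <edge source=\"%s\" target=\"%s\">",
              esc(edges$source[i]), esc(edges$target[i])),
      sprintf("      <data key=\"w\">%s</data>", num(edges$weight[i])),
      sprintf("      <data key=\"s\">%s</data>",
              num(sign(edges$weight[i]))),
      sprintf("      <data key=\"d\">%s</data>",
              num(edges$dispersion[i])),
      "    </edge>"))),
    "  </graph>",
    "</graphml>")
  writeLines(lines, file)
  invisible(file)
}

#' Read a GraphML network back into an edge list
#'
#' Parses the GraphML files written by [exportNetwork()]; attribute keys
#' are matched by \code{attr.name}.
#'
#' @param file GraphML path.
#' @return data.frame with \code{source}, \code{target}, \code{weight},
#'   \code{sign}, \code{dispersion}.
#' @export
readNetworkGraphML <- function(file) {
  doc <- xml2::read_xml(file)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  keys <- xml2::xml_find_all(doc, ".//g:key", ns)
  keyMap <- setNames(xml2::xml_attr(keys, "attr.name"),
                     xml2::xml_attr(keys, "id"))
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  getAttr <- function(e, name) {
    data <- xml2::xml_find_all(e, "./g:data", ns)
    ids <- xml2::xml_attr(data, "key")
    vals <- as.numeric(xml2::xml_text(data))
    v <- vals[keyMap[ids] == name]
    if (length(v)) v[1] else NA_real_
  }
  data.frame(
    source = xml2::xml_attr(edges, "source"),
    target = xml2::xml_attr(edges, "target"),
    weight = vapply(edges, getAttr, 1, "weight"),
    sign = vapply(edges, getAttr, 1, "sign"),
    dispersion = vapply(edges, getAttr, 1, "dispersion"),
    stringsAsFactors = FALSE)
}

#' Write an interaction matrix and influence summary as CSV
#'
#' @param im an [InteractionMatrix-class].
#' @param matrixFile,influenceFile output CSV paths (either may be
#'   \code{NULL} to skip).
#' @return invisible list of the paths written.
#' @export
writeInteractionCsv <- function(im, matrixFile = NULL,
                                influenceFile = NULL) {
  if (!is.null(matrixFile)) {
    df <- data.frame(gene = im@genes, im@W, check.names = FALSE)
    write.csv(df, matrixFile, row.names = FALSE)
  }
  if (!is.null(influenceFile))
    write.csv(collapseInfluence(im), influenceFile, row.names = FALSE)
  invisible(list(matrix = matrixFile, influence = influenceFile))
}
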