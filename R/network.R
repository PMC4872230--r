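#' Build the bipartite miRNA-target regulatory network
#'
#' One directed edge per distinct (miRNA, gene) pair supported by at
#' least one target site. An edge is annotated translational_inhibition
#' when any supporting site carries that mode, otherwise cleavage.
#' Bipartiteness (no miRNA-miRNA or gene-gene edge) is asserted on
#' every build.
#'
#' @param sites A `target_sites` data.frame.
#' @return A list of class `regulatory_network`: `nodes` (data.frame
#'   `name`, `type`) and `edges` (data.frame `mirna`, `gene`, `mode`).
#' @export
build_network <- function(sites) {
  if (nrow(sites) == 0) {
    net <- list(nodes = data.frame(name = character(0), type = character(0),
                                   stringsAsFactors = FALSE),
                edges = data.frame(mirna = character(0), gene = character(0),
                                   mode = character(0),
                                   stringsAsFactors = FALSE))
    class(net) <- "regulatory_network"
    return(net)
  }
  key <- paste(sites$mirna_id, sites$transcript_id, sep = "\r")
  ti <- tapply(sites$mode == "translational_inhibition", key, any)
  pairs <- do.call(rbind, strsplit(names(ti), "\r", fixed = TRUE))
  edges <- data.frame(mirna = pairs[, 1], gene = pairs[, 2],
                      mode = ifelse(ti, "translational_inhibition",
                                    "cleavage"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  mirnas <- unique(edges$mirna)
  genes <- unique(edges$gene)
  both <- intersect(mirnas, genes)
  if (length(both) > 0) {
    stop("network is not bipartite; ids on both sides: ",
         paste(utils::head(both, 3), collapse = ", "))
  }
  net <- list(nodes = data.frame(name = c(mirnas, genes),
                                 type = c(rep("miRNA", length(mirnas)),
                                          rep("gene", length(genes))),
                                 stringsAsFactors = FALSE),
              edges = edges)
  class(net) <- "regulatory_network"
  net
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("mirna", "gene", "mode")],
    directed = TRUE, vertices = net$nodes)
  g
}

#' Degree, hubs and connected components of a regulatory network
#'
#' @param net A `regulatory_network`.
#' @return A list: `degree` (data.frame `name`, `type`, `degree`,
#'   sorted by decreasing degree then name), `hub` (the miRNA of
#'   maximum out-degree), `components` (membership data.frame),
#'   `n_components`, `largest_component_size`.
#' @export
network_stats <- function(net) {
  if (nrow(net$nodes) == 0) {
    return(list(degree = data.frame(name = character(0), type = character(0),
                                    degree = integer(0)),
                hub = NA_character_, components = data.frame(
                  name = character(0), component = integer(0)),
                n_components = 0L, largest_component_size = 0L))
  }
  g <- as_igraph(net)
  deg <- igraph::degree(g, mode = "all")
  dd <- data.frame(name = names(deg), type = net$nodes$type,
                   degree = as.integer(deg), stringsAsFactors = FALSE)
  dd <- dd[order(-dd$degree, dd$name), , drop = FALSE]
  rownames(dd) <- NULL
  mir_deg <- dd[dd$type == "miRNA", , drop = FALSE]
  comp <- igraph::components(g, mode = "weak")
  list(degree = dd,
       hub = if (nrow(mir_deg)) mir_deg$name[1] else NA_character_,
       components = data.frame(name = names(comp$membership),
                               component = as.integer(comp$membership),
                               stringsAsFactors = FALSE),
       n_components = comp$no,
       largest_component_size = if (comp$no) max(comp$csize) else 0L)
}

#' Export a regulatory network
#'
#' SIF: one line per edge, `<miRNA> targets <gene>` (tab-separated).
#' GraphML: via igraph, with node `type` and edge `mode` attributes.
#' Both round-trip through [import_network()].
#'
#' @param net A `regulatory_network`.
#' @param path Output file path.
#' @param format "sif" or "graphml".
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    writeLines(sprintf("%s\ttargets\t%s", net$edges$mirna, net$edges$gene),
               path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Import a regulatory network written by [export_network()]
#'
#' @param path File path.
#' @param format "sif" or "graphml".
#' @return A `regulatory_network`. SIF carries no mode attribute, so
#'   modes come back as "cleavage".
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    f <- strsplit(lines, "\t")
    edges <- data.frame(
      mirna = vapply(f, `[[`, "", 1),
      gene = vapply(f, `[[`, "", 3),
      mode = "cleavage", stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(mirna = el$from, gene = el$to,
                        mode = if ("mode" %in% names(el)) el$mode
                               else "cleavage",
                        stringsAsFactors = FALSE)
  }
  sites <- data.frame(mirna_id = edges$mirna, transcript_id = edges$gene,
                      mode = edges$mode, stringsAsFactors = FALSE)
  build_network(sites)
}
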