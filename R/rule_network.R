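#' Build a rule co-occurrence network
#'
#' Nodes are rule conditions (attribute = category); an edge connects two
#' conditions that co-occur in at least one rule. Edge weight is the summed
#' support of the contributing rules (the number of correctly classified
#' children they account for); the edge score is the best contributing
#' rule's -log10 Bonferroni-adjusted hypergeometric p, binned into
#' high/mid/low tertiles.
#'
#' @param model an [induce_rules()] result (or a plain list of [rule()]s).
#' @param target_class `"affected"` or `"unaffected"`; only rules of that
#'   class enter the network.
#' @param phenotype phenotype name stored as metadata.
#' @param stats optional [rule_statistics()] data.frame supplying `p_adj`
#'   per rule id; without it all scores are 0.
#' @param attributes optional attribute metadata for display codes (an
#'   attribute's `short_code` plus the category, e.g. `"V1"`).
#' @return an object of class `"rule_network"`: list with `phenotype`,
#'   `target_class`, `nodes` (condition, code, support) and `edges`
#'   (condition_a, condition_b, n_rules, weight, score, score_bin), plus
#'   the tertile boundaries in `score_breaks`.
#' @export
build_network <- function(model, target_class = "affected",
                          phenotype = NULL, stats = NULL,
                          attributes = NULL) {
  rules <- if (inherits(model, "rule_model")) model$rules else model
  rules <- Filter(function(r) r$decision == target_class, rules)
  empty <- list(
    phenotype = phenotype, target_class = target_class,
    nodes = data.frame(condition = character(0), code = character(0),
                       support = numeric(0)),
    edges = data.frame(condition_a = character(0), condition_b = character(0),
                       n_rules = integer(0), weight = numeric(0),
                       score = numeric(0), score_bin = character(0)),
    score_breaks = numeric(0))
  if (length(rules) == 0L) return(structure(empty, class = "rule_network"))

  score_of <- function(r) {
    if (is.null(stats) || is.na(r$id)) return(0)
    row <- stats[stats$id == r$id, , drop = FALSE]
    if (nrow(row) == 0L || is.na(row$p_adj[1])) return(0)
    -log10(row$p_adj[1])
  }
  cond_str <- function(conds) paste0(names(conds), "=", conds)

  node_support <- list()
  edge_map <- new.env(parent = emptyenv())
  for (r in rules) {
    cs <- sort(cond_str(r$conditions))
    sc <- score_of(r)
    for (cd in cs)
      node_support[[cd]] <- (node_support[[cd]] %||% 0) + r$support
    if (length(cs) >= 2L) {
      pairs <- utils::combn(cs, 2L, simplify = FALSE)
      for (p in pairs) {
        key <- paste(p, collapse = "\x1f")
        prev <- edge_map[[key]] %||%
          list(a = p[1], b = p[2], n_rules = 0L, weight = 0, score = -Inf)
        prev$n_rules <- prev$n_rules + 1L
        prev$weight <- prev$weight + r$support
        prev$score <- max(prev$score, sc)
        edge_map[[key]] <- prev
      }
    }
  }
  code_of <- function(cd) {
    parts <- strsplit(cd, "=", fixed = TRUE)[[1]]
    sc <- attributes[[parts[1]]]$short_code
    if (is.null(sc)) cd else paste0(sc, parts[2])
  }
  nodes <- data.frame(condition = names(node_support),
                      code = vapply(names(node_support), code_of,
                                    character(1)),
                      support = unlist(node_support, use.names = FALSE),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$code, nodes$condition), ]
  rownames(nodes) <- NULL
  ekeys <- ls(edge_map)
  if (length(ekeys) == 0L) {
    out <- empty
    out$nodes <- nodes
    return(structure(out, class = "rule_network"))
  }
  el <- mget(ekeys, envir = edge_map)
  edges <- data.frame(
    condition_a = vapply(el, `[[`, character(1), "a"),
    condition_b = vapply(el, `[[`, character(1), "b"),
    n_rules = vapply(el, `[[`, integer(1), "n_rules"),
    weight = vapply(el, `[[`, numeric(1), "weight"),
    score = vapply(el, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  breaks <- unique(quantile(edges$score, c(1 / 3, 2 / 3), names = FALSE))
  bin <- function(s) {
    if (length(breaks) < 2L) return(rep("high", length(s)))
    ifelse(s <= breaks[1], "low", ifelse(s <= breaks[2], "mid", "high"))
  }
  edges$score_bin <- bin(edges$score)
  edges <- edges[order(-edges$weight, edges$condition_a, edges$condition_b), ]
  rownames(edges) <- NULL
  structure(list(phenotype = phenotype, target_class = target_class,
                 nodes = nodes, edges = edges, score_breaks = breaks),
            class = "rule_network")
}

#' @exportS3Method print rule_network
print.rule_network <- function(x, ...) {
  cat(sprintf("<rule_network> %s/%s: %d nodes, %d edges\n",
              x$phenotype %||% "?", x$target_class, nrow(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

network_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    if (nrow(net$edges)) net$edges else
      data.frame(condition_a = character(0), condition_b = character(0)),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$condition, code = net$nodes$code,
                          support = net$nodes$support))
  g
}

#' Export a rule network
#'
#' Lossless for nodes, edges, weights and score bins. GraphML files load in
#' standard graph tools (igraph, Cytoscape); JSON carries the phenotype and
#' class metadata; the edge TSV is a flat edge list with a node table
#' written alongside (suffix `.nodes.tsv`).
#'
#' @param net a [build_network()] result.
#' @param path output file path.
#' @param format `"graphml"`, `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network_igraph(net), path, format = "graphml")
  } else if (format == "json") {
    jsonlite::write_json(
      list(phenotype = net$phenotype, target_class = net$target_class,
           score_breaks = net$score_breaks, nodes = net$nodes,
           edges = net$edges),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    write.table(net$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(net$nodes, sub("(\\.tsv)?$", ".nodes.tsv", path, perl = TRUE),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Deterministic circular layout of a rule network
#'
#' Places nodes on the unit circle sorted by display code (then condition),
#' and assigns each edge a width proportional to its weight and a color by
#' score bin (high = red, mid = orange, low = grey).
#'
#' @param net a [build_network()] result.
#' @param max_width line width of the heaviest edge.
#' @return list with `nodes` (condition, code, angle, x, y) and `edges`
#'   (endpoints, width, color).
#' @export
network_layout <- function(net, max_width = 8) {
  nodes <- net$nodes
  n <- nrow(nodes)
  angle <- if (n > 0) 2 * pi * (seq_len(n) - 1) / n else numeric(0)
  nodes$angle <- angle
  nodes$x <- cos(angle)
  nodes$y <- sin(angle)
  edges <- net$edges
  if (nrow(edges)) {
    edges$width <- max_width * edges$weight / max(edges$weight)
    edges$color <- c(high = "#d73027", mid = "#fc8d59",
                     low = "#bdbdbd")[edges$score_bin]
  }
  list(nodes = nodes, edges = edges)
}

#' Render a rule network as a circular chord plot
#'
#' @param net a [build_network()] result with at least one node.
#' @param path output image path; the extension selects the device
#'   (`.png` or `.svg`).
#' @param ... passed to [network_layout()].
#' @return `path`, invisibly.
#' @export
render_circular <- function(net, path, ...) {
  if (nrow(net$nodes) == 0L) stop("cannot render an empty network")
  lay <- network_layout(net, ...)
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 7, height = 7)
  else grDevices::png(path, width = 900, height = 900, res = 120)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%s (%s)", net$phenotype %||% "",
                                net$target_class))
  if (nrow(lay$edges)) {
    idx <- function(cond) match(cond, lay$nodes$condition)
    for (i in seq_len(nrow(lay$edges))) {
      a <- idx(lay$edges$condition_a[i]); b <- idx(lay$edges$condition_b[i])
      graphics::segments(lay$nodes$x[a], lay$nodes$y[a],
                         lay$nodes$x[b], lay$nodes$y[b],
                         lwd = lay$edges$width[i], col = lay$edges$color[i])
    }
  }
  graphics::points(lay$nodes$x, lay$nodes$y, pch = 19, cex = 1.2)
  graphics::text(lay$nodes$x * 1.15, lay$nodes$y * 1.15, lay$nodes$code,
                 cex = 0.7)
  invisible(path)
}
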