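# Cohort-level aggregation: integer scores of neighborhood relations and
# directed preference networks.

# round half away from zero, matching the published integer percentages
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Aggregate significance matrices into a cohort score matrix
#'
#' For each class combination, counts the images of the group in which the
#' combination was called `sh` and `sl`; the integer score is
#' `n_sh - n_sl` and the percent normalization
#' `round(100 * score / n_images)` (half away from zero).  A high positive
#' (negative) percent means the combination is significantly high (low) in
#' the majority of the group's images.
#'
#' @param matrices list of [significance_matrix()] objects, or of plain
#'   8 x 8 character call matrices (entries `"sh"`, `"sl"`, `"ns"`/blank,
#'   rows PC, columns NPC, e.g. from [read_matrix()]).
#' @param group label for the cohort (e.g. a diagnosis, or `"all"`).
#' @return object of class `score_matrix`: list with `group`, `n_images`,
#'   and 8 x 8 matrices `n_sh`, `n_sl`, `score`, `percent` (rows PC,
#'   columns NPC).
#' @export
score_matrix <- function(matrices, group = "all") {
  if (length(matrices) == 0L) stop("empty group", call. = FALSE)
  calls_of <- function(m) {
    if (inherits(m, "significance_matrix")) return(m$calls)
    if (is.matrix(m) && all(dim(m) == c(8L, 8L))) {
      m[is.na(m) | m == ""] <- "ns"  # published layout leaves ns blank
      return(m)
    }
    stop("expected significance_matrix objects or 8 x 8 call matrices",
         call. = FALSE)
  }
  dn <- list(paste0("PC", 0:7), paste0("NPC", 0:7))
  n_sh <- n_sl <- matrix(0L, 8L, 8L, dimnames = dn)
  for (m in matrices) {
    calls <- calls_of(m)
    n_sh <- n_sh + (calls == "sh")
    n_sl <- n_sl + (calls == "sl")
  }
  n_images <- length(matrices)
  score <- n_sh - n_sl
  percent <- .round_half_up(100 * score / n_images)
  structure(list(group = group, n_images = n_images,
                 n_sh = n_sh, n_sl = n_sl,
                 score = score, percent = percent),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix>", x$group, "-", x$n_images, "images; percent:\n")
  print(x$percent)
  invisible(x)
}

#' Build a preference network from a score matrix
#'
#' Nodes are the eight profile classes; a directed edge `pc -> npc` is
#' drawn when the absolute percent-normalized score strictly *exceeds*
#' `100 * edge_fraction` (default: 50% of the maximally possible value).
#' Edge sign follows the score (favored green / unfavored red);
#' self-loops are allowed.  `(i -> j)` and `(j -> i)` are independent —
#' preferences need not be mutual.
#'
#' @param sm a [score_matrix()].
#' @param edge_fraction fraction of the maximal score in (0, 1\]
#'   (default 0.5).
#' @return object of class `preference_network`: list with `nodes` (0:7),
#'   `edges` data frame (`from`, `to`, `sign`, `weight` = |percent|), and
#'   `group`.
#' @export
build_network <- function(sm, edge_fraction = 0.5) {
  stopifnot(inherits(sm, "score_matrix"),
            edge_fraction > 0, edge_fraction <= 1)
  hits <- which(abs(sm$percent) > 100 * edge_fraction, arr.ind = TRUE)
  edges <- data.frame(from = integer(0), to = integer(0),
                      sign = integer(0), weight = numeric(0))
  if (nrow(hits) > 0L) {
    edges <- data.frame(from = hits[, 1] - 1L,
                        to = hits[, 2] - 1L,
                        sign = sign(sm$score[hits]),
                        weight = abs(sm$percent[hits]))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = 0:7, edges = edges, group = sm$group),
            class = "preference_network")
}

#' @export
print.preference_network <- function(x, ...) {
  cat("<preference_network>", x$group, "-", nrow(x$edges), "edge(s)\n")
  if (nrow(x$edges) > 0L) print(x$edges)
  invisible(x)
}

#' Convert a preference network to an igraph graph
#'
#' @param network a `preference_network`.
#' @return an `igraph` directed graph with vertex attribute `name`
#'   (`"0"`..`"7"`) and edge attributes `sign` and `weight`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "preference_network"))
  g <- igraph::make_empty_graph(n = 8, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(0:7))
  if (nrow(network$edges) > 0L) {
    g <- igraph::add_edges(
      g, rbind(network$edges$from + 1L, network$edges$to + 1L),
      sign = network$edges$sign, weight = network$edges$weight)
  }
  g
}

#' Export a preference network
#'
#' `"graphml"` goes through igraph (round-trippable with attributes);
#' `"dot"` writes Graphviz source with green/red edges and pen width
#' proportional to the percent weight; `"csv"` writes the edge list.
#'
#' @param network a `preference_network`.
#' @param path output file path.
#' @param format one of `"dot"`, `"graphml"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("dot", "graphml",
                                                     "csv")) {
  stopifnot(inherits(network, "preference_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else if (format == "csv") {
    utils::write.csv(network$edges, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- c("digraph preference_network {",
               "  layout=circo;",
               sprintf("  %d [label=\"PC%d\"];", 0:7, 0:7))
    e <- network$edges
    if (nrow(e) > 0L) {
      lines <- c(lines, sprintf(
        "  %d -> %d [color=%s, penwidth=%.2f, weight=%g];",
        e$from, e$to, ifelse(e$sign > 0, "green", "red"),
        0.5 + 3 * e$weight / 100, e$weight))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read back a GraphML preference network
#'
#' @param path GraphML file written by [export_network()].
#' @return a `preference_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(from = as.integer(el[, 1]),
                      to = as.integer(el[, 2]),
                      sign = if (igraph::ecount(g) > 0)
                        as.integer(igraph::E(g)$sign) else integer(0),
                      weight = if (igraph::ecount(g) > 0)
                        as.numeric(igraph::E(g)$weight) else numeric(0))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = 0:7, edges = edges, group = "imported"),
            class = "preference_network")
}
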