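#' Construct a signaling network
#'
#' Builds a directed signaling network from an edge table. Each edge carries a
#' typed interaction (see [interaction_vocabulary()]); terms outside the
#' vocabulary are replaced by `"activates"` and reported with a warning.
#' Nodes referenced only in edges are auto-declared (edge-list formats rarely
#' carry a separate node manifest). Parallel edges between the same ordered
#' pair and self-loops (feedback) are retained; each edge contributes
#' independently to a node's net input. Different forms of the same protein
#' (splice variants, phospho-forms) should be separate nodes.
#'
#' @param edges A data frame with columns `source`, `interaction`, `target`
#'   (extra columns ignored; three unnamed columns are taken in that order),
#'   or `NULL` for an edgeless network.
#' @param nodes Optional character vector of declared node names; nodes found
#'   only in edges are appended in order of first appearance.
#' @param quiet If `TRUE`, suppress the substitution/auto-declaration
#'   warnings (they remain available via [validate_network()]).
#' @return An object of class `signaling_network` with components `nodes`
#'   (character vector of unique names) and `edges` (data frame with columns
#'   `source`, `target`, `original_term`, `term`, `effect`, `strength`,
#'   `weight`, `substituted`).
#' @seealso [read_network()], [validate_network()], [simulate.signaling_network()]
#' @export
#' @examples
#' net <- signaling_network(data.frame(
#'   source = "A", interaction = c("activates", "weakly inhibits"),
#'   target = c("B", "C")
#' ))
#' net
signaling_network <- function(edges = NULL, nodes = NULL, quiet = FALSE) {
  declared <- as.character(nodes %||% character())
  dup <- unique(declared[duplicated(declared)])
  declared <- unique(declared)

  if (is.null(edges) || NROW(edges) == 0L) {
    edge_df <- empty_edge_table()
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    cols <- tolower(names(edges))
    need <- c("source", "interaction", "target")
    if (all(need %in% cols)) {
      edges <- edges[, match(need, cols), drop = FALSE]
    } else if (ncol(edges) >= 3L) {
      edges <- edges[, 1:3, drop = FALSE]
    } else {
      stop("edge table needs columns source, interaction, target")
    }
    names(edges) <- need
    edges$source <- trimws(as.character(edges$source))
    edges$target <- trimws(as.character(edges$target))
    if (any(!nzchar(edges$source)) || any(!nzchar(edges$target))) {
      stop("edge table contains empty node names")
    }
    spec <- normalize_interaction(edges$interaction)
    edge_df <- data.frame(
      source = edges$source, target = edges$target,
      original_term = spec$original_term, term = spec$term,
      effect = spec$effect, strength = spec$strength,
      weight = spec$weight, substituted = spec$substituted,
      stringsAsFactors = FALSE
    )
  }

  referenced <- unique(c(rbind(edge_df$source, edge_df$target)))
  auto <- setdiff(referenced, declared)
  net <- structure(
    list(nodes = c(declared, auto), edges = edge_df),
    class = "signaling_network",
    duplicated_nodes = dup,
    auto_declared = if (length(declared)) auto else character()
  )
  if (length(net$nodes) == 0L) stop("network has no nodes")

  if (!quiet) {
    if (any(edge_df$substituted)) {
      subs <- unique(edge_df$original_term[edge_df$substituted])
      warning(
        "interaction term(s) outside the controlled vocabulary replaced ",
        "with 'activates': ", paste(sQuote(subs), collapse = ", "),
        call. = FALSE
      )
    }
    if (length(attr(net, "auto_declared"))) {
      warning(
        "node(s) referenced in edges but not declared were auto-added: ",
        paste(attr(net, "auto_declared"), collapse = ", "),
        call. = FALSE
      )
    }
  }
  net
}

empty_edge_table <- function() {
  data.frame(
    source = character(), target = character(),
    original_term = character(), term = character(),
    effect = character(), strength = character(),
    weight = numeric(), substituted = logical(),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a signaling network
#'
#' Collects the diagnostics a user should see before simulating: duplicate
#' declared node names, nodes that were auto-declared because they appeared
#' only in edges, and every vocabulary substitution made while normalizing
#' interaction terms. Edges are never silently dropped by the constructor, so
#' the report is complete.
#'
#' @param net A [signaling_network()].
#' @return An object of class `network_validation`: a list with `n_nodes`,
#'   `n_edges`, `duplicated_nodes`, `auto_declared` and a `substitutions`
#'   data frame (`source`, `target`, `original_term`, `replacement`).
#' @export
#' @examples
#' net <- suppressWarnings(signaling_network(
#'   data.frame(source = "A", interaction = "cleaves", target = "B")
#' ))
#' validate_network(net)
validate_network <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  if (length(net$nodes) == 0L) stop("network has no nodes")
  sub <- net$edges[net$edges$substituted, c("source", "target", "original_term")]
  sub$replacement <- rep("activates", nrow(sub))
  rownames(sub) <- NULL
  structure(
    list(
      n_nodes = length(net$nodes),
      n_edges = nrow(net$edges),
      duplicated_nodes = attr(net, "duplicated_nodes") %||% character(),
      auto_declared = attr(net, "auto_declared") %||% character(),
      substitutions = sub
    ),
    class = "network_validation"
  )
}

#' @export
print.network_validation <- function(x, ...) {
  cat("Network validation:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  if (length(x$duplicated_nodes)) {
    cat("  duplicate declared node names:",
        paste(x$duplicated_nodes, collapse = ", "), "\n")
  }
  if (length(x$auto_declared)) {
    cat("  auto-declared nodes:", paste(x$auto_declared, collapse = ", "), "\n")
  }
  if (nrow(x$substitutions)) {
    cat("  vocabulary substitutions (replaced with 'activates'):\n")
    for (i in seq_len(nrow(x$substitutions))) {
      cat(sprintf("    %s -> %s: %s\n", x$substitutions$source[i],
                  x$substitutions$target[i],
                  sQuote(x$substitutions$original_term[i])))
    }
  }
  if (!length(x$duplicated_nodes) && !length(x$auto_declared) &&
      !nrow(x$substitutions)) {
    cat("  no issues\n")
  }
  invisible(x)
}

#' Signed weight matrix of a network
#'
#' Returns the n-by-n matrix `W` with `W[i, j]` the summed signed weight of
#' all edges from node `i` to node `j` (parallel edges add; `binds` edges
#' contribute zero).
#'
#' @param net A [signaling_network()].
#' @return A numeric matrix with node names on both dimensions.
#' @export
weight_matrix <- function(net) {
  n <- length(net$nodes)
  W <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$source, net$nodes)
    j <- match(net$edges$target, net$nodes)
    for (k in seq_along(i)) W[i[k], j[k]] <- W[i[k], j[k]] + net$edges$weight[k]
  }
  W
}

#' @export
print.signaling_network <- function(x, ...) {
  cat("Signaling network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  nodes:", paste(utils::head(x$nodes, 10L), collapse = ", "),
      if (length(x$nodes) > 10L) "..." else "", "\n")
  if (nrow(x$edges)) {
    shown <- utils::head(x$edges, 10L)
    for (i in seq_len(nrow(shown))) {
      cat(sprintf("  %s %s %s (w = %+.1f)\n", shown$source[i], shown$term[i],
                  shown$target[i], shown$weight[i]))
    }
    if (nrow(x$edges) > 10L) cat("  ...", nrow(x$edges) - 10L, "more edges\n")
  }
  invisible(x)
}

#' @export
summary.signaling_network <- function(object, ...) {
  v <- validate_network(object)
  print(object)
  cat("  effects:", paste(names(table(object$edges$effect)),
                          table(object$edges$effect),
                          sep = "=", collapse = ", "), "\n")
  if (nrow(v$substitutions)) {
    cat("  ", nrow(v$substitutions), "vocabulary substitution(s); see validate_network()\n")
  }
  invisible(v)
}

#' @export
as.data.frame.signaling_network <- function(x, ...) x$edges

#' Plot a signaling network
#'
#' A simple base-graphics layout: nodes on a circle, activating edges drawn
#' solid, inhibitory edges dashed, `binds` edges dotted; line width scales
#' with the strength class.
#'
#' @param x A [signaling_network()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.signaling_network <- function(x, ...) {
  n <- length(x$nodes)
  theta <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  px <- cos(theta); py <- sin(theta)
  graphics::plot(px, py, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1, ...)
  if (nrow(x$edges)) {
    i <- match(x$edges$source, x$nodes)
    j <- match(x$edges$target, x$nodes)
    lty <- ifelse(x$edges$effect == "activation", 1L,
                  ifelse(x$edges$effect == "inhibition", 2L, 3L))
    for (k in seq_along(i)) {
      if (i[k] == j[k]) next  # self-loops not drawn
      graphics::arrows(px[i[k]], py[i[k]], px[j[k]] * 0.92, py[j[k]] * 0.92,
                       length = 0.08, lty = lty[k],
                       lwd = 0.5 + abs(x$edges$weight[k]))
    }
  }
  graphics::text(px * 1.15, py * 1.15, x$nodes)
  invisible(x)
}
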