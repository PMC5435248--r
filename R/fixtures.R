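#' Strength-demonstration network
#'
#' A seven-node star used to show graded responses: a central source A
#' weakly inhibits B, inhibits C, strongly inhibits D, weakly activates E,
#' activates F and strongly activates G. Simulated at zero noise this yields
#' the canonical ordering G > F > E > baseline > B > C > D, with the weak
#' activation/inhibition pair (E, B) mirroring about the 50% baseline.
#'
#' @return A [signaling_network()] with 7 nodes and 6 edges.
#' @export
#' @examples
#' strength_demo_network()
strength_demo_network <- function() {
  signaling_network(data.frame(
    source = "A",
    interaction = c("weakly inhibits", "inhibits", "strongly inhibits",
                    "weakly activates", "activates", "strongly activates"),
    target = c("B", "C", "D", "E", "F", "G"),
    stringsAsFactors = FALSE
  ), nodes = c("A", "B", "C", "D", "E", "F", "G"))
}

#' Perturbation-demonstration network pair
#'
#' Two three-node activation chains with identical structure: ABC
#' (A activates B, B activates C) and DEF (D activates E, E activates F).
#' The ABC copy carries an external inhibition of A that is released after
#' time point 1, so the pair demonstrates how a perturbation propagates
#' downstream and how the network recovers towards its unperturbed twin once
#' the clamp is lifted.
#'
#' @return A list with components `abc` and `def`, each a list of `network`
#'   and `perturbations` (empty for DEF).
#' @export
#' @examples
#' demo <- perturbation_demo_networks()
#' demo$abc$perturbations[[1]]
perturbation_demo_networks <- function() {
  chain <- function(nodes) {
    signaling_network(data.frame(
      source = nodes[1:2], interaction = "activates", target = nodes[2:3],
      stringsAsFactors = FALSE
    ), nodes = nodes)
  }
  list(
    abc = list(
      network = chain(c("A", "B", "C")),
      perturbations = list(perturbation("A", "inhibit", release_step = 1))
    ),
    def = list(
      network = chain(c("D", "E", "F")),
      perturbations = list()
    )
  )
}

#' EGFR signaling example network
#'
#' A small EGF-receptor network inspired by published phosphoproteomics of
#' EGF-treated cells: EGFR weakly activates STAM2 (its activity rises
#' slowly after stimulation) and strongly activates Shc1 (rapid rise), with
#' further downstream edges whose strengths are illustrative defaults rather
#' than measured values. The topology is shipped as an editable SIF file
#' (`egfr_demo_synthetic.sif` under `inst/extdata`) so that users holding
#' their own time-course data can adjust strengths and baselines.
#'
#' @return A [signaling_network()].
#' @export
egfr_demo_network <- function() {
  path <- system.file("extdata", "egfr_demo_synthetic.sif",
                      package = "signalsim", mustWork = TRUE)
  read_network(path, dialect = "sif", quiet = TRUE)
}

#' Random signaling network generator
#'
#' Draws a seeded, reproducible directed network for stress-testing and
#' benchmarking: each ordered node pair (self-loops excluded by default —
#' feedback loops are better added explicitly) receives an edge with
#' probability `edge_density`, and each edge's interaction term is drawn
#' from `strength_mix`, a probability distribution over the seven vocabulary
#' terms. No duplicate (source, target, term) triples are generated.
#'
#' @param n_nodes Number of nodes (`>= 2`); named `N1`, `N2`, ...
#' @param edge_density Probability in (0, 1\] that an ordered pair carries an
#'   edge; 1 gives the complete directed graph (`n_nodes * (n_nodes - 1)`
#'   edges).
#' @param strength_mix Named numeric vector of nonnegative sampling weights
#'   over vocabulary terms (default: uniform over all seven). Names must be
#'   vocabulary terms; weights are normalized internally.
#' @param seed Integer seed.
#' @param allow_self_loops Include self-edges (default `FALSE`).
#' @return A [signaling_network()].
#' @export
#' @examples
#' random_signaling_network(5, 1, c(activates = 1), seed = 1)
random_signaling_network <- function(n_nodes, edge_density,
                                     strength_mix = NULL, seed = 1L,
                                     allow_self_loops = FALSE) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1L, n_nodes >= 2)
  if (!is.numeric(edge_density) || length(edge_density) != 1L ||
      edge_density <= 0 || edge_density > 1) {
    stop("edge_density must lie in (0, 1]")
  }
  vocab <- interaction_vocabulary()$term
  if (is.null(strength_mix)) {
    strength_mix <- stats::setNames(rep(1, length(vocab)), vocab)
  }
  if (is.null(names(strength_mix)) ||
      !all(canonical_term(names(strength_mix)) %in% vocab) ||
      any(strength_mix < 0) || sum(strength_mix) <= 0) {
    stop("strength_mix must be nonnegative weights named by vocabulary terms")
  }
  names(strength_mix) <- canonical_term(names(strength_mix))

  nodes <- paste0("N", seq_len(n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  if (!allow_self_loops) pairs <- pairs[pairs$source != pairs$target, ]

  set.seed(as.integer(seed))
  keep <- stats::runif(nrow(pairs)) <= edge_density
  pairs <- pairs[keep, , drop = FALSE]
  terms <- sample(names(strength_mix), nrow(pairs), replace = TRUE,
                  prob = strength_mix / sum(strength_mix))
  edges <- if (nrow(pairs)) {
    data.frame(source = pairs$source, interaction = terms,
               target = pairs$target, stringsAsFactors = FALSE)
  } else NULL
  signaling_network(edges, nodes = nodes, quiet = TRUE)
}
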