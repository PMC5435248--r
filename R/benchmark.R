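#' Pearson correlation with explicit validation
#'
#' Standard product-moment correlation between two equal-length series, used
#' to compare simulated and reference time courses. A series with zero
#' variance has no defined correlation and raises an error rather than
#' silently returning 0.
#'
#' @param a,b Numeric vectors of equal length `>= 3`.
#' @return The correlation coefficient, in \[-1, 1\].
#' @export
#' @examples
#' pearson(c(1, 2, 3, 5), c(2, 4, 6, 9))
pearson <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) stop("inputs must be numeric")
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 3L) stop("need at least 3 paired observations")
  if (anyNA(a) || anyNA(b)) stop("series contain missing values")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: a series has zero variance")
  }
  stats::cor(a, b)
}

#' Score predicted edges against a ground-truth network
#'
#' Benchmarks an inferred edge list against the structure of the network the
#' data were simulated from. Counts are computed over unique edges (duplicate
#' predictions collapse; order is irrelevant). In `directed` mode an edge
#' matches on its ordered (source, target) pair, except that `binds` edges in
#' the truth — which record undirected physical association — match either
#' orientation. In `undirected` mode all matching ignores direction. With
#' `strict = TRUE` a predicted edge must also carry an interaction term whose
#' effect sign (activation/inhibition/neutral) matches the truth edge.
#' Predicted edges naming nodes absent from the truth network count as false
#' positives, with a warning.
#'
#' @param truth A [signaling_network()] (the ground truth).
#' @param predicted A data frame with columns `source`, `target` and, for
#'   `strict` scoring, `interaction`; or a `signaling_network`.
#' @param mode `"directed"` (default) or `"undirected"`.
#' @param strict Require the effect sign to match as well (default `FALSE`).
#' @return An object of class `edge_metrics`: a list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `sensitivity` (synonym of recall) and `f1`.
#'   `precision` is `NaN` (with a warning) when nothing was predicted.
#' @export
#' @examples
#' truth <- signaling_network(data.frame(
#'   source = c("A", "B"), interaction = "activates", target = c("B", "C")
#' ))
#' edge_confusion(truth, data.frame(source = c("A", "A"), target = c("B", "C")))
edge_confusion <- function(truth, predicted,
                           mode = c("directed", "undirected"),
                           strict = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "signaling_network"))
  if (inherits(predicted, "signaling_network")) {
    predicted <- data.frame(source = predicted$edges$source,
                            target = predicted$edges$target,
                            interaction = predicted$edges$term,
                            stringsAsFactors = FALSE)
  }
  predicted <- as.data.frame(predicted, stringsAsFactors = FALSE)
  names(predicted) <- tolower(names(predicted))
  if (!all(c("source", "target") %in% names(predicted))) {
    stop("predicted edges need columns source, target")
  }
  has_term <- "interaction" %in% names(predicted)
  if (strict && !has_term) {
    stop("strict scoring needs an interaction column in the predictions")
  }

  unknown <- setdiff(unique(c(predicted$source, predicted$target)), truth$nodes)
  if (length(unknown) && nrow(predicted)) {
    warning("predicted edges reference node(s) not in the truth network ",
            "(counted as false positives): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }

  pred_eff <- if (has_term) normalize_interaction2(predicted$interaction)
              else rep(NA_character_, nrow(predicted))

  # keys for matching; truth 'binds' edges (and everything in undirected
  # mode) are keyed on the unordered pair
  key <- function(s, t, undirected) {
    und <- rep_len(undirected, length(s))
    ifelse(und, paste(pmin(s, t), pmax(s, t), sep = "\r"),
           paste(s, t, sep = "\r"))
  }
  te <- truth$edges
  # 'binds' records undirected association: keyed on the unordered pair even
  # in directed mode
  t_undir <- if (nrow(te)) (mode == "undirected" | te$effect == "neutral")
             else logical()
  truth_keys <- if (nrow(te)) key(te$source, te$target, t_undir) else character()
  truth_eff <- te$effect
  keep <- !duplicated(if (strict) paste(truth_keys, truth_eff) else truth_keys)
  truth_keys <- truth_keys[keep]
  truth_eff <- truth_eff[keep]
  truth_undir <- t_undir[keep]

  if (nrow(predicted)) {
    pk_dir <- key(predicted$source, predicted$target, FALSE)
    pk_und <- key(predicted$source, predicted$target, TRUE)
    pkey <- if (strict) paste(if (mode == "directed") pk_dir else pk_und,
                              pred_eff)
            else if (mode == "directed") pk_dir else pk_und
    dedup <- !duplicated(pkey)
    pk_dir <- pk_dir[dedup]; pk_und <- pk_und[dedup]
    pred_eff <- pred_eff[dedup]
  } else {
    pk_dir <- pk_und <- character(); pred_eff <- character()
  }

  matched_truth <- rep(FALSE, length(truth_keys))
  tp <- 0L
  for (i in seq_along(pk_dir)) {
    hits <- ifelse(truth_undir, truth_keys == pk_und[i],
                   truth_keys == pk_dir[i])
    if (strict) hits <- hits & truth_eff == pred_eff[i]
    if (any(hits)) {
      tp <- tp + 1L
      matched_truth[hits] <- TRUE
    }
  }
  fp <- length(pk_dir) - tp
  fn <- sum(!matched_truth)

  precision <- if (tp + fp > 0L) tp / (tp + fp) else {
    warning("no edges predicted: precision undefined", call. = FALSE)
    NaN
  }
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NaN
  f1 <- if (!is.nan(precision) && !is.nan(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NaN

  structure(
    list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         sensitivity = recall, f1 = f1, mode = mode, strict = strict),
    class = "edge_metrics"
  )
}

# effect class of arbitrary predicted terms, without the substitution warning
normalize_interaction2 <- function(term) {
  if (!length(term)) return(character())
  normalize_interaction(term)$effect
}

#' @export
print.edge_metrics <- function(x, ...) {
  cat(sprintf("Edge prediction metrics (%s%s):\n", x$mode,
              if (x$strict) ", strict sign matching" else ""))
  cat(sprintf("  TP = %d, FP = %d, FN = %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision = %.4f\n", x$precision))
  cat(sprintf("  recall (sensitivity) = %.4f\n", x$recall))
  cat(sprintf("  F1 = %.4f\n", x$f1))
  invisible(x)
}

#' Correlate simulated trajectories with reference data
#'
#' Compares replicate-mean simulated trajectories with an experimental (or
#' other reference) time course. Simulated time point `t` is mapped to
#' reference time `t * time_scale` (e.g. `time_scale = 0.5` when one
#' simulation step corresponds to half a minute), and only matched times are
#' scored. Per-node correlations are Pearson coefficients over the matched
#' pairs of that node; the overall score pools the matched pairs of all
#' nodes into one Pearson coefficient (not the mean of the per-node values).
#'
#' @param ts A `trajectory_set`.
#' @param reference A data frame with columns `time`, `node`, `value` (a
#'   long-format reference table), or a path to such a CSV.
#' @param time_scale Reference time units per simulation step (default 1).
#' @return A list with `per_node` (named vector of correlations), `overall`
#'   (pooled Pearson) and `n_pairs` (matched pairs per node).
#' @export
score_against_reference <- function(ts, reference, time_scale = 1) {
  stopifnot(inherits(ts, "trajectory_set"))
  if (is.character(reference) && length(reference) == 1L) {
    reference <- utils::read.csv(reference, comment.char = "#",
                                 stringsAsFactors = FALSE)
  }
  reference <- as.data.frame(reference, stringsAsFactors = FALSE)
  names(reference) <- tolower(names(reference))
  if (!all(c("time", "node", "value") %in% names(reference))) {
    stop("reference table needs columns time, node, value")
  }
  m <- replicate_means(ts)
  nodes <- colnames(m)
  miss <- setdiff(unique(reference$node), nodes)
  if (length(miss)) {
    stop("reference node(s) absent from the trajectories: ",
         paste(miss, collapse = ", "))
  }
  sim_time <- as.numeric(rownames(m)) * time_scale

  sim_vals <- ref_vals <- numeric()
  per_node <- stats::setNames(rep(NA_real_, length(unique(reference$node))),
                              unique(reference$node))
  n_pairs <- per_node
  for (nd in names(per_node)) {
    rf <- reference[reference$node == nd, , drop = FALSE]
    idx <- match_times(rf$time, sim_time)
    ok <- !is.na(idx)
    n_pairs[nd] <- sum(ok)
    if (sum(ok) >= 3L) {
      s <- m[idx[ok], nd]
      per_node[nd] <- pearson(s, rf$value[ok])
      sim_vals <- c(sim_vals, s)
      ref_vals <- c(ref_vals, rf$value[ok])
    }
  }
  if (!length(sim_vals)) {
    stop("no overlapping time points between simulation and reference ",
         "after alignment")
  }
  list(per_node = per_node, overall = pearson(sim_vals, ref_vals),
       n_pairs = n_pairs)
}

match_times <- function(ref_time, sim_time, tol = 1e-8) {
  vapply(ref_time, function(t) {
    i <- which(abs(sim_time - t) <= tol)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
}
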