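#' Simulation configuration
#'
#' Bundles everything that defines one simulated experiment: the number of
#' experimental repeats (replicates), the number of time points, the noise
#' level on the input-output relationship, the sigmoid exponent shared by the
#' response and decay curves, whether stochastic decay is active, external
#' perturbations, an optional baseline activity profile, and the master seed.
#'
#' @param n_replicates Number of independent simulated repeats (default 10).
#' @param n_timepoints Number of update steps (default 10); the initial state
#'   is recorded as time point 0 in addition.
#' @param noise_pct Noise level in percent (default 0); see [apply_noise()].
#' @param exponent Sigmoid steepness (default 0.15).
#' @param decay Enable the stochastic decay function (default `FALSE`);
#'   requires `n_timepoints >= 2` and acts only on the second half of the
#'   time series.
#' @param perturbations A list of [perturbation()] objects.
#' @param baseline Optional named numeric vector mapping nodes to initial
#'   activity in \[0, 100\]; unlisted nodes start near the 50% homeostatic
#'   baseline.
#' @param seed Integer master seed; each replicate derives its own stream
#'   from it, so results are reproducible and adding replicates never
#'   reshuffles earlier ones.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' sim_config(n_replicates = 10, n_timepoints = 20, noise_pct = 5, seed = 1)
sim_config <- function(n_replicates = 10L, n_timepoints = 10L, noise_pct = 0,
                       exponent = 0.15, decay = FALSE,
                       perturbations = list(), baseline = NULL, seed = 1L) {
  stopifnot(
    is.numeric(n_replicates), length(n_replicates) == 1L, n_replicates >= 1,
    is.numeric(n_timepoints), length(n_timepoints) == 1L, n_timepoints >= 1,
    is.numeric(noise_pct), length(noise_pct) == 1L, noise_pct >= 0,
    is.numeric(exponent), length(exponent) == 1L, exponent > 0,
    is.logical(decay), length(decay) == 1L,
    is.list(perturbations),
    is.numeric(seed), length(seed) == 1L
  )
  if (decay && n_timepoints < 2) {
    stop("the decay function can only be used for simulations with time ",
         "series of two or more time points")
  }
  if (!is.null(baseline)) {
    if (!is.numeric(baseline) || is.null(names(baseline)) ||
        any(!nzchar(names(baseline)))) {
      stop("baseline must be a named numeric vector")
    }
  }
  if (length(perturbations) && inherits(perturbations, "perturbation")) {
    perturbations <- list(perturbations)
  }
  structure(
    list(
      n_replicates = as.integer(n_replicates),
      n_timepoints = as.integer(n_timepoints),
      noise_pct = as.numeric(noise_pct), exponent = as.numeric(exponent),
      decay = decay,
      perturbations = perturbations, baseline = baseline,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d replicates x %d time points, noise %g%%, exponent %g, decay %s, seed %d\n",
    x$n_replicates, x$n_timepoints, x$noise_pct, x$exponent,
    if (x$decay) "on" else "off", x$seed
  ))
  for (p in x$perturbations) {
    cat(sprintf("  perturbation: %s %s%s\n", p$mode, p$node,
                if (is.null(p$release_step)) ""
                else paste0(", released after step ", p$release_step)))
  }
  if (length(x$baseline)) {
    cat("  baseline profile for", length(x$baseline), "node(s)\n")
  }
  invisible(x)
}

#' External perturbation of a node
#'
#' Mimics experimental targeting of a protein, e.g. by a drug: an inhibited
#' node is clamped at 0% activity, an activated node at 100%. When
#' `release_step` is given the clamp is lifted after that time point — the
#' node's activity is restored to its baseline and it then responds freely to
#' its inputs.
#'
#' @param node Node name.
#' @param mode `"inhibit"` or `"activate"`.
#' @param release_step Optional time point after which the perturbation is
#'   removed (must be smaller than `n_timepoints`); `NULL` means the clamp
#'   lasts the whole simulation.
#' @return An object of class `perturbation`.
#' @export
#' @examples
#' perturbation("A", "inhibit", release_step = 1)
perturbation <- function(node, mode = c("inhibit", "activate"),
                         release_step = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.character(node), length(node) == 1L, nzchar(node))
  if (!is.null(release_step)) {
    stopifnot(is.numeric(release_step), length(release_step) == 1L,
              release_step >= 0)
    release_step <- as.integer(release_step)
  }
  structure(list(node = node, mode = mode, release_step = release_step),
            class = "perturbation")
}

# Deterministic per-replicate substream seed: arithmetic in doubles, reduced
# below 2^31 so set.seed() accepts it; adding replicates keeps earlier ones.
replicate_seed <- function(seed, replicate) {
  as.integer((as.numeric(seed) + as.numeric(replicate) * 1000003) %% 2147483647)
}

#' Simulate activity time-series from a signaling network
#'
#' Generates `nsim` replicate trajectories of per-node percentage activity
#' under the sigmoidal signal-response dynamics, with optional noise, decay
#' and perturbations taken from `config`. Each replicate runs on its own RNG
#' stream derived deterministically from the master seed, so the same
#' seed and configuration always reproduce the same trajectories bit for bit.
#'
#' @param object A [signaling_network()].
#' @param nsim Number of replicates; defaults to `config$n_replicates`.
#' @param seed Master seed; defaults to `config$seed`.
#' @param config A [sim_config()].
#' @param ... Unused.
#' @return An object of class `trajectory_set`: a 3-d array indexed
#'   (replicate, time point, node) of activities in \[0, 100\], with time
#'   points `0:n_timepoints` (0 is the initial state). Attributes carry the
#'   network, the config and the per-replicate decay rates.
#' @seealso [replicate_means()], [as.data.frame.trajectory_set()],
#'   [write_trajectories()]
#' @export
#' @examples
#' net <- strength_demo_network()
#' ts <- simulate(net, config = sim_config(n_replicates = 3, n_timepoints = 5))
#' summary(ts)
simulate.signaling_network <- function(object, nsim = NULL, seed = NULL,
                                       config = sim_config(), ...) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(nsim)) config$n_replicates <- as.integer(nsim)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  check_perturbations(config$perturbations, object, config$n_timepoints)

  nodes <- object$nodes
  R <- config$n_replicates
  T <- config$n_timepoints
  out <- array(
    NA_real_, dim = c(R, T + 1L, length(nodes)),
    dimnames = list(NULL, as.character(0:T), nodes)
  )
  rates <- matrix(NA_real_, R, length(nodes), dimnames = list(NULL, nodes))
  W <- weight_matrix(object)

  for (r in seq_len(R)) {
    set.seed(replicate_seed(config$seed, r))
    state <- initialize_state(object, config)
    attr(state, "W") <- W
    rates[r, ] <- state$decay_rates
    out[r, 1L, ] <- state$activities
    for (t in seq_len(T)) {
      state <- advance_state(state, object, config)
      out[r, t + 1L, ] <- state$activities
    }
  }

  structure(out, class = "trajectory_set", network = object, config = config,
            decay_rates = rates)
}

#' Replicate-mean trajectories
#'
#' @param ts A `trajectory_set`.
#' @return A (time point x node) matrix of activities averaged over
#'   replicates, with time points `0:n_timepoints` as row names.
#' @export
replicate_means <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  apply(unclass(ts), c(2L, 3L), mean)
}

#' @export
print.trajectory_set <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "Trajectory set: %d replicates x %d time points (incl. initial) x %d nodes\n",
    d[1], d[2], d[3]
  ))
  cat("  activity range: [", sprintf("%.2f", min(x)), ",",
      sprintf("%.2f", max(x)), "] %\n")
  invisible(x)
}

#' @export
summary.trajectory_set <- function(object, ...) {
  print(object)
  m <- replicate_means(object)
  cat("  replicate-mean final activities:\n")
  fin <- m[nrow(m), ]
  for (n in names(fin)) cat(sprintf("    %s: %.2f%%\n", n, fin[n]))
  invisible(m)
}

#' Long-format view of a trajectory set
#'
#' @param x A `trajectory_set`.
#' @param ... Unused.
#' @return A data frame with columns `replicate` (1-based), `timepoint`
#'   (0-based; 0 is the initial state), `node`, `activity`.
#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  d <- dim(x)
  nodes <- dimnames(x)[[3]]
  df <- data.frame(
    replicate = rep(seq_len(d[1]), times = d[2] * d[3]),
    timepoint = rep(rep(0:(d[2] - 1L), each = d[1]), times = d[3]),
    node = rep(nodes, each = d[1] * d[2]),
    activity = as.vector(unclass(x)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$replicate, df$timepoint, df$node), ]
  rownames(df) <- NULL
  df
}

#' Plot replicate-mean trajectories
#'
#' One line per node, activity (%) against time point.
#'
#' @param x A `trajectory_set`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.trajectory_set <- function(x, ...) {
  m <- replicate_means(x)
  graphics::matplot(as.numeric(rownames(m)), m, type = "l", lty = 1,
                    xlab = "time point", ylab = "activity (%)",
                    ylim = c(0, 100), ...)
  graphics::legend("topleft", legend = colnames(m), lty = 1,
                   col = seq_len(ncol(m)), cex = 0.8, bty = "n")
  invisible(x)
}
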