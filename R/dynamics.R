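#' Sigmoidal signal-response curve
#'
#' Maps the net input ("signal") into a node onto the change in that node's
#' activity per time step: `100 / (1 + exp(-exponent * x)) - 50`. The curve
#' is the general case for graded, reversible signaling (multistep cascades,
#' zero-order ultrasensitivity, positive feedback all produce sigmoidal
#' stimulus-response relationships). It is odd in `x`, strictly increasing,
#' and bounded in (-50, +50) percent activity per step.
#'
#' @param x Numeric vector of net inputs (finite).
#' @param exponent Positive steepness; default 0.15.
#' @return Activity change per step, in percent.
#' @export
#' @examples
#' response(0)            # 0: no signal, no change
#' response(c(0.5, 1, 1.5))  # graded weak/standard/strong single-edge inputs
response <- function(x, exponent = 0.15) {
  if (!is.numeric(exponent) || length(exponent) != 1L || !is.finite(exponent) ||
      exponent <= 0) {
    stop("exponent must be a single positive number")
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("net input must be finite numeric")
  }
  100 / (1 + exp(-exponent * x)) - 50
}

#' Stochastic decay step
#'
#' The per-step loss of activity from unregulated protein turnover:
#' `100 / (1 + exp(exponent * x)) - 50`, with `x` a per-protein decay rate
#' drawn once from U(0, 5). The delta is non-positive (zero at `x = 0`) and
#' strictly decreasing in `x`, so different proteins decay at different
#' constant rates and the system can return to homeostasis after stimulation.
#'
#' @param x_decay Numeric vector of decay rates in \[0, 5\].
#' @param exponent Positive steepness; default 0.15 (shared with [response()]).
#' @return Activity change per step (non-positive), in percent.
#' @export
#' @examples
#' decay_delta(c(0, 2.5, 5))
decay_delta <- function(x_decay, exponent = 0.15) {
  if (!is.numeric(x_decay) || anyNA(x_decay) ||
      any(x_decay < 0 | x_decay > 5)) {
    stop("decay rate must lie in [0, 5]")
  }
  response(-x_decay, exponent)
}

#' Net input into a node
#'
#' The signed signal arriving at a node at one time step: the sum over its
#' incoming edges of `weight * source_activity / 50`. Activating edges
#' contribute positively and inhibitory edges negatively (the sign lives in
#' the weight); `binds` edges contribute exactly zero. The scaling by the
#' 50% homeostatic baseline means a single edge whose source sits at baseline
#' contributes exactly its class weight (0.5 / 1.0 / 1.5), and a fully
#' inhibited source contributes nothing — which is what lets perturbations
#' propagate downstream.
#'
#' @param node A node name.
#' @param state A simulation state (see [initialize_state()]), or any list
#'   with an `activities` component named by node.
#' @param net The [signaling_network()].
#' @return A single signed signal value.
#' @export
net_input <- function(node, state, net) {
  if (!node %in% net$nodes) stop("unknown node: ", node)
  e <- net$edges[net$edges$target == node, , drop = FALSE]
  if (!nrow(e)) return(0)
  sum(e$weight * state$activities[e$source] / 50)
}

#' Add user-specified noise to an activity change
#'
#' Models stochasticity in the input-output relationship of a node: at
#' `noise_pct = 0` (the default) the delta is returned unchanged; otherwise a
#' zero-mean Gaussian deviate with standard deviation
#' `(noise_pct / 100) * 50` is added, scaling the noise level against the
#' +/-50 half-range of the response curve. Deviates are consumed from the
#' current RNG stream (one per element), so replicate streams stay
#' reproducible.
#'
#' @param delta Numeric vector of activity changes.
#' @param noise_pct Noise level in percent, `>= 0`.
#' @return `delta`, perturbed when `noise_pct > 0`.
#' @export
apply_noise <- function(delta, noise_pct) {
  if (!is.numeric(noise_pct) || length(noise_pct) != 1L || is.na(noise_pct) ||
      noise_pct < 0) {
    stop("noise_pct must be a single number >= 0")
  }
  if (noise_pct == 0) return(delta)
  delta + stats::rnorm(length(delta), mean = 0, sd = noise_pct / 100 * 50)
}

clip01 <- function(x) pmin(pmax(x, 0), 100)

#' Initialize the simulation state for one replicate
#'
#' Every node is assigned a baseline activity: the user-supplied baseline
#' profile value where one exists, otherwise approximately 50% — the
#' homeostatic steady state — realized as 50 plus a U(-2.5, +2.5) jitter.
#' Nodes under an external perturbation start pinned (inhibited at 0,
#' activated at 100); their baseline is remembered so activity can be
#' restored when the perturbation is released. A decay rate is drawn from
#' U(0, 5) once per node (per replicate); it only acts when decay is enabled,
#' but the draw is always made so that decay-on and decay-off runs, and runs
#' that differ only in perturbations or profiles, share identical random
#' streams.
#'
#' @param net A [signaling_network()].
#' @param config A [sim_config()].
#' @return An object of class `simulation_state`: a list with `activities`
#'   (named, in \[0, 100\]), `baseline`, `decay_rates` and `step = 0`.
#' @export
initialize_state <- function(net, config) {
  stopifnot(inherits(net, "signaling_network"), inherits(config, "sim_config"))
  nodes <- net$nodes
  check_perturbations(config$perturbations, net, config$n_timepoints)

  jitter <- stats::runif(length(nodes), -2.5, 2.5)
  baseline <- stats::setNames(50 + jitter, nodes)
  if (length(config$baseline)) {
    prof <- config$baseline
    bad <- setdiff(names(prof), nodes)
    if (length(bad)) stop("baseline profile names unknown node(s): ",
                          paste(bad, collapse = ", "))
    if (any(!is.finite(prof)) || any(prof < 0 | prof > 100)) {
      bad <- names(prof)[!is.finite(prof) | prof < 0 | prof > 100]
      stop("baseline activity outside [0, 100] for node(s): ",
           paste(bad, collapse = ", "))
    }
    baseline[names(prof)] <- prof
  }

  activities <- baseline
  for (p in config$perturbations) {
    activities[p$node] <- if (p$mode == "inhibit") 0 else 100
  }

  # rates are drawn whether or not decay is active (and simply ignored when
  # it is off) so decay-on and decay-off runs share identical noise streams
  decay_rates <- stats::setNames(stats::runif(length(nodes), 0, 5), nodes)

  structure(
    list(activities = clip01(activities), baseline = clip01(baseline),
         decay_rates = decay_rates, step = 0L),
    class = "simulation_state"
  )
}

check_perturbations <- function(perturbations, net, n_timepoints) {
  for (p in perturbations) {
    if (!inherits(p, "perturbation")) stop("perturbations must be perturbation() objects")
    if (!p$node %in% net$nodes) stop("perturbed node not in network: ", p$node)
    if (!is.null(p$release_step) && p$release_step >= n_timepoints) {
      stop("release_step must be smaller than n_timepoints")
    }
  }
  invisible(TRUE)
}

#' Advance the simulation by one synchronous step
#'
#' All nodes update together (Jacobi scheme) from the previous step's
#' activities: each node's net input is computed from the previous state, fed
#' through [response()], noise is added via [apply_noise()], and — when decay
#' is enabled and the new step index lies in the second half of the time
#' series (index > floor(n_timepoints / 2)) — the node's [decay_delta()] is
#' added. The new activity is the previous activity plus the delta, clipped
#' to \[0, 100\]. Nodes under an unreleased perturbation are held at their
#' pinned value (0 or 100); at the first step after `release_step` a node's
#' activity is restored to its recorded baseline, after which it updates
#' freely. One noise deviate per node is consumed whenever `noise_pct > 0`
#' (discarded for pinned nodes), keeping streams aligned across perturbation
#' variants.
#'
#' @param state A `simulation_state` (see [initialize_state()]).
#' @param net The [signaling_network()].
#' @param config The [sim_config()].
#' @return The updated `simulation_state` with `step` incremented.
#' @export
advance_state <- function(state, net, config) {
  stopifnot(inherits(state, "simulation_state"))
  if (state$step >= config$n_timepoints) {
    stop("simulation already at its final time point")
  }
  step <- state$step + 1L
  prev <- state$activities
  W <- attr(state, "W") %||% weight_matrix(net)

  x <- as.vector(crossprod(W, prev / 50))      # net input per node
  delta <- apply_noise(response(x, config$exponent), config$noise_pct)
  if (config$decay && step > config$n_timepoints %/% 2L) {
    delta <- delta + decay_delta(state$decay_rates, config$exponent)
  }
  new <- clip01(prev + delta)
  names(new) <- names(prev)

  for (p in config$perturbations) {
    if (is.null(p$release_step) || step <= p$release_step) {
      new[p$node] <- if (p$mode == "inhibit") 0 else 100
    } else if (step == p$release_step + 1L) {
      new[p$node] <- state$baseline[p$node]
    }
  }

  state$activities <- new
  state$step <- step
  state
}
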