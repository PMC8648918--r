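# Particle swarm optimisation: configuration object plus a generic R
# maximiser for arbitrary objectives. Neuron fitting uses a compiled
# implementation of the same canonical update (see src/pso_neuron.cpp).

#' PSO configuration
#'
#' Canonical particle swarm settings: velocity update
#' `v <- inertia * v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with
#' positions clipped to `range`. Defaults are the standard
#' constriction-equivalent choice.
#'
#' @param swarm Number of particles (>= 2).
#' @param iterations Update sweeps after the initial evaluation.
#' @param inertia Inertia weight, in \[0, 1\].
#' @param c1,c2 Cognitive and social acceleration coefficients (> 0).
#' @param range Length-2 numeric search box applied to every coordinate.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return Object of class `pso_config`.
#' @export
pso_config <- function(swarm = 30L, iterations = 100L, inertia = 0.72,
                       c1 = 1.49, c2 = 1.49, range = c(-10, 10), seed = 1L) {
  if (swarm < 2L) abort("swarm size must be >= 2")
  if (inertia < 0 || inertia > 1) abort("inertia must be in [0, 1]")
  if (c1 <= 0 || c2 <= 0) abort("c1 and c2 must be positive")
  if (length(range) != 2L || !all(is.finite(range)) || range[1] >= range[2]) {
    abort("range must be a finite (lo, hi) pair")
  }
  structure(list(swarm = as.integer(swarm), iterations = as.integer(iterations),
                 inertia = inertia, c1 = c1, c2 = c2,
                 range = as.numeric(range), seed = as.integer(seed)),
            class = "pso_config")
}

#' Maximise an objective by particle swarm
#'
#' Reference R implementation for arbitrary objectives (the GMDH neuron
#' fitter uses a compiled kernel with the same update rule).
#'
#' @param objective Function of a numeric vector returning a scalar to
#'   maximise.
#' @param dim Dimension of the search space.
#' @param config A [pso_config()].
#' @return List with `par`, `value` and the best-value trace per iteration.
#' @export
#' @examples
#' pso_optimize(function(x) -sum(x^2), dim = 2,
#'              config = pso_config(iterations = 50, seed = 1))$value
pso_optimize <- function(objective, dim, config = pso_config()) {
  lo <- config$range[1]; hi <- config$range[2]
  with_local_seed(config$seed, {
    x <- matrix(runif(config$swarm * dim, lo, hi), nrow = config$swarm)
    vel <- matrix(0, nrow = config$swarm, ncol = dim)
    fit <- apply(x, 1L, objective)
    pbest <- x; pbest_fit <- fit
    g <- which.max(fit)
    gbest <- x[g, ]; gbest_fit <- fit[g]
    trace <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      r1 <- matrix(runif(config$swarm * dim), nrow = config$swarm)
      r2 <- matrix(runif(config$swarm * dim), nrow = config$swarm)
      gmat <- matrix(gbest, config$swarm, dim, byrow = TRUE)
      vel <- config$inertia * vel + config$c1 * r1 * (pbest - x) +
        config$c2 * r2 * (gmat - x)
      x <- pmin(pmax(x + vel, lo), hi)
      fit <- apply(x, 1L, objective)
      better <- fit > pbest_fit
      pbest[better, ] <- x[better, , drop = FALSE]
      pbest_fit[better] <- fit[better]
      if (max(fit) > gbest_fit) {
        g <- which.max(fit)
        gbest <- x[g, ]; gbest_fit <- fit[g]
      }
      trace[it] <- gbest_fit
    }
    list(par = gbest, value = gbest_fit, trace = trace)
  })
}
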