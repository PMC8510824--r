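## Particle swarm optimization of flattened tree parameters.

#' Particle swarm optimization settings
#'
#' Defaults are the standard constriction-equivalent values (inertia 0.729,
#' c1 = c2 = 1.49445), swarm of 30, 50 iterations, velocity clamp 4.
#'
#' @param swarm_size number of particles (>= 2).
#' @param iterations number of update sweeps; 0 is allowed (no optimization).
#' @param inertia inertia factor applied to the previous velocity.
#' @param c1,c2 cognitive (p_best) and social (g_best) learning factors.
#' @param v_max positive velocity clamp; every velocity component is
#'   restricted to \[-v_max, v_max\] after each update.
#' @param per_dimension draw the random factors r1, r2 independently per
#'   dimension (canonical PSO, the default) or once per particle update
#'   (scalar convention; set `FALSE`). Scalar draws couple all coordinates of
#'   a velocity update and noticeably slow convergence in higher dimensions.
#' @return a list of class `pso_control`.
#' @export
pso_control <- function(swarm_size = 30, iterations = 50, inertia = 0.729,
                        c1 = 1.49445, c2 = 1.49445, v_max = 4,
                        per_dimension = TRUE) {
  stopifnot(swarm_size >= 2, iterations >= 0, v_max > 0)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 inertia = inertia, c1 = c1, c2 = c2, v_max = v_max,
                 per_dimension = isTRUE(per_dimension)),
            class = "pso_control")
}

#' Particle velocity update
#'
#' Computes `inertia * v + c1 * r1 * (p_best - x) + c2 * r2 * (g_best - x)`
#' with r1, r2 ~ U(0, 1) drawn per dimension (or once per update when
#' `control$per_dimension` is `FALSE`), then clamps each component to
#' \[-v_max, v_max\].
#'
#' @param velocity,position,p_best,g_best numeric vectors of equal length.
#' @param control a [pso_control()].
#' @param r1,r2 optionally injected random factors (for deterministic checks);
#'   drawn from the RNG when `NULL`.
#' @return the new, clamped velocity vector.
#' @export
update_velocity <- function(velocity, position, p_best, g_best,
                            control = pso_control(), r1 = NULL, r2 = NULL) {
  d <- length(position)
  if (length(velocity) != d || length(p_best) != d || length(g_best) != d)
    stop("velocity, position, p_best and g_best must have equal length")
  n <- if (control$per_dimension) d else 1L
  if (is.null(r1)) r1 <- stats::runif(n)
  if (is.null(r2)) r2 <- stats::runif(n)
  v <- control$inertia * velocity +
    control$c1 * r1 * (p_best - position) +
    control$c2 * r2 * (g_best - position)
  pmin(pmax(v, -control$v_max), control$v_max)
}

#' Particle position update
#'
#' `x + v`, componentwise; positions are not clamped.
#'
#' @param position,velocity numeric vectors of equal length.
#' @return the new position.
#' @export
update_position <- function(position, velocity) {
  if (length(position) != length(velocity))
    stop("position and velocity must have equal length")
  position + velocity
}

#' Minimize an objective with particle swarm optimization
#'
#' The swarm is initialized around `init`: one particle sits exactly at
#' `init`, the rest at `init` plus U(-1, 1) perturbations; initial velocities
#' are zero. The global best is tracked across all evaluations, so its fitness
#' trace is monotone non-increasing.
#'
#' @param objective function mapping a numeric vector to a scalar to minimize.
#' @param init numeric starting vector (search dimension = its length).
#' @param control a [pso_control()].
#' @param seed optional integer seed for reproducibility.
#' @return list with `par` (best position), `value` (best objective) and
#'   `trace` (best-so-far value after initialization and each iteration).
#' @export
pso_optimize <- function(objective, init, control = pso_control(),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(init)
  if (d < 1L) stop("init must have positive length")
  S <- control$swarm_size
  pos <- matrix(rep(init, each = S), nrow = S)
  for (s in seq_len(S)[-1L]) pos[s, ] <- init + stats::runif(d, -1, 1)
  vel <- matrix(0, nrow = S, ncol = d)
  fit <- apply(pos, 1L, objective)
  pbest <- pos
  pbest_f <- fit
  g <- which.min(fit)
  gbest <- pos[g, ]
  gbest_f <- fit[g]
  trace <- numeric(control$iterations + 1L)
  trace[1L] <- gbest_f
  for (it in seq_len(control$iterations)) {
    for (s in seq_len(S)) {
      vel[s, ] <- update_velocity(vel[s, ], pos[s, ], pbest[s, ], gbest,
                                  control)
      pos[s, ] <- update_position(pos[s, ], vel[s, ])
      f <- objective(pos[s, ])
      if (f < pbest_f[s]) {
        pbest_f[s] <- f
        pbest[s, ] <- pos[s, ]
      }
      if (f < gbest_f) {
        gbest_f <- f
        gbest <- pos[s, ]
      }
    }
    trace[it + 1L] <- gbest_f
  }
  list(par = gbest, value = gbest_f, trace = trace)
}

#' Optimize the parameters of a flexible neural tree by PSO
#'
#' Runs [pso_optimize()] on the tree's flattened parameter vector with the
#' RMSE fitness [fnt_fitness()] as objective. The swarm is seeded at the
#' incumbent parameters so PSO refines rather than restarts; the returned
#' fitness is never worse than the incumbent's. A tree with no parameters
#' (single leaf) is returned unchanged with a notice. With `iterations = 0`
#' the tree is returned with its original parameters.
#'
#' @param tree an `fnt` to refine.
#' @param X,y training matrix and coded targets (see [fnt_fitness()]).
#' @param control a [pso_control()].
#' @param seed optional integer seed.
#' @return list with `tree` (parameters installed), `fitness` and `trace`.
#' @export
optimize_params <- function(tree, X, y, control = pso_control(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_params(tree) == 0L) {
    message("tree has no tunable parameters (single leaf); returned unchanged")
    f <- fnt_fitness(tree, X, y)
    return(list(tree = tree, fitness = f, trace = f))
  }
  v0 <- flatten_params(tree)
  if (control$iterations == 0L) {
    f <- fnt_fitness(tree, X, y)
    return(list(tree = tree, fitness = f, trace = f))
  }
  res <- pso_optimize(function(p) fnt_fitness(set_params(tree, p), X, y),
                      v0, control)
  list(tree = set_params(tree, res$par), fitness = res$value,
       trace = res$trace)
}
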