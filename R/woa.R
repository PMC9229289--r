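#' Whale optimization algorithm configuration
#'
#' @param bounds Search box: numeric `c(low, high)` for one dimension or a
#'   2-row matrix (`rbind(low, high)`) for several.
#' @param pop_size Number of whales (>= 2).
#' @param t_max Number of iterations (>= 1).
#' @param b Spiral shape constant.
#' @param seed Optional RNG seed; with a fixed seed the full trajectory is
#'   reproducible.
#' @return Object of class `woa_config`.
#' @export
woa_config <- function(bounds, pop_size = 10L, t_max = 100L, b = 1,
                       seed = NULL) {
  if (is.null(dim(bounds))) bounds <- matrix(bounds, nrow = 2L)
  if (nrow(bounds) != 2L) stop("bounds must have rows (low, high)")
  if (any(!is.finite(bounds))) stop("bounds must be finite")
  if (any(bounds[1L, ] >= bounds[2L, ])) {
    stop("each dimension needs low < high bounds")
  }
  if (pop_size < 2L) stop("pop_size must be >= 2")
  if (t_max < 1L) stop("t_max must be >= 1")
  structure(list(bounds = bounds, pop_size = as.integer(pop_size),
                 t_max = as.integer(t_max), b = b, seed = seed),
            class = "woa_config")
}

#' Convergence factor schedule
#'
#' The control factor `a = 2 - 2 t / t_max` decreases linearly from 2 (at
#' `t = 0`) to 0 (at `t = t_max`), shrinking the expected magnitude of the
#' coefficient `A = 2 a r1 - a` and thereby moving the swarm from
#' exploration to exploitation.
#'
#' @param t Iteration counter (0..`t_max`).
#' @param t_max Maximum number of iterations.
#' @return Numeric value in `[0, 2]`.
#' @export
woa_convergence_factor <- function(t, t_max) 2 - 2 * t / t_max

# One position update for a single whale. Branches per dimension: spiral
# around the best when p >= 0.5; otherwise encircle (|A| < 1) or random
# search around xrand (|A| >= 1). The spiral uses D' = |best - x|; the
# encircling and random moves use |C * ref - x|.
woa_move <- function(x, best, xrand, a_coef, c_coef, p, l, b) {
  if (p >= 0.5) {
    best + abs(best - x) * exp(b * l) * cos(2 * pi * l)
  } else {
    enc <- best - a_coef * abs(c_coef * best - x)
    rnd <- xrand - a_coef * abs(c_coef * xrand - x)
    ifelse(abs(a_coef) < 1, enc, rnd)
  }
}

.check_fitness <- function(value, position) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("fitness function returned a non-finite value at position (",
         paste(signif(position, 6), collapse = ", "), ")")
  }
  value
}

#' Minimise a function with the whale optimization algorithm
#'
#' Population metaheuristic alternating three moves: encircling the best
#' position found so far, a logarithmic-spiral approach to it, and a
#' randomized search around another whale, with the branch chosen by a coin
#' flip `p` and the magnitude of the coefficient `A = 2 a r1 - a` whose
#' scale `a` decays linearly from 2 to 0 over the run. Positions are clipped
#' to the search box after every move; the best-so-far position is elitist,
#' so the fitness history is non-increasing.
#'
#' @param fitness_fn Function of a position vector returning a finite scalar
#'   to minimise.
#' @param cfg A [woa_config()].
#' @return List with `position`, `fitness`, `history` (best fitness after
#'   each iteration).
#' @examples
#' cfg <- woa_config(bounds = c(0, 10), pop_size = 10, t_max = 50, seed = 1)
#' woa_optimize(function(x) (x - 3)^2, cfg)$position
#' @export
woa_optimize <- function(fitness_fn, cfg) {
  stopifnot(inherits(cfg, "woa_config"))
  if (!is.null(cfg$seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(cfg$seed)
  }
  lo <- cfg$bounds[1L, ]
  hi <- cfg$bounds[2L, ]
  d <- length(lo)
  pop <- cfg$pop_size

  positions <- matrix(stats::runif(pop * d, rep(lo, each = pop),
                                   rep(hi, each = pop)), nrow = pop)
  fit <- apply(positions, 1L, function(xx) .check_fitness(fitness_fn(xx), xx))
  best_i <- which.min(fit)
  best <- positions[best_i, ]
  best_fit <- fit[best_i]

  history <- numeric(cfg$t_max)
  for (t in seq_len(cfg$t_max)) {
    a <- woa_convergence_factor(t, cfg$t_max)
    for (i in seq_len(pop)) {
      p <- stats::runif(1)
      r1 <- stats::runif(d)
      r2 <- stats::runif(d)
      l <- stats::runif(1, -1, 1)
      a_coef <- 2 * a * r1 - a
      c_coef <- 2 * r2
      xrand <- positions[sample.int(pop, 1L), ]
      xnew <- woa_move(positions[i, ], best, xrand, a_coef, c_coef, p, l,
                       cfg$b)
      positions[i, ] <- pmin(pmax(xnew, lo), hi)
      fit[i] <- .check_fitness(fitness_fn(positions[i, ]), positions[i, ])
      if (fit[i] < best_fit) {
        best_fit <- fit[i]
        best <- positions[i, ]
      }
    }
    history[t] <- best_fit
  }
  list(position = best, fitness = best_fit, history = history)
}
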