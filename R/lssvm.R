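# ---------------------------------------------------------------------------
# Least-squares support vector machine (RBF kernel) and a real-coded genetic
# algorithm for tuning its two hyperparameters.
#
# LS-SVM replaces the SVM quadratic program with one linear system
#   [ 0   1'      ] [ b     ]   [ 0 ]
#   [ 1   K + I/g ] [ alpha ] = [ y ]
# with K_ij = exp(-||x_i - x_j||^2 / sigma2); every training point keeps a
# coefficient.  Training is an exact solve and therefore deterministic.
# ---------------------------------------------------------------------------

rbf_kernel <- function(x1, x2, sigma2) {
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), `+`) - 2 * tcrossprod(x1, x2)
  exp(-pmax(d2, 0) / sigma2)
}

#' Train an LS-SVM classifier
#'
#' @param x n x d numeric feature matrix.
#' @param y labels in {-1, +1}.
#' @param sigma2 RBF kernel width parameter (> 0).
#' @param gamma regularization parameter (> 0); larger fits training data
#'   harder.
#' @return `lssvm_model` with the dual coefficients `alpha`, bias `b` and the
#'   support (= training) matrix.
#' @export
lssvm_train <- function(x, y, sigma2, gamma) {
  stopifnot(sigma2 > 0, gamma > 0, nrow(x) == length(y),
            all(y %in% c(-1, 1)), length(unique(y)) == 2)
  n <- nrow(x)
  K <- rbf_kernel(x, x, sigma2)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  sol <- tryCatch(solve(A, c(0, y)),
                  error = function(e)
                    abort("fascicle3d_degenerate_training",
                          paste("singular LS-SVM system:", conditionMessage(e))))
  structure(list(alpha = sol[-1], b = sol[1], x = x,
                 sigma2 = sigma2, gamma = gamma,
                 normalization = "per-window min-max (see window_features)"),
            class = "lssvm_model")
}

#' LS-SVM decision values
#' @param model `lssvm_model`.
#' @param xnew m x d matrix.
#' @return numeric vector of decision values (positive = class +1).
#' @export
lssvm_decision <- function(model, xnew) {
  as.vector(rbf_kernel(rbind(xnew), model$x, model$sigma2) %*% model$alpha +
              model$b)
}

#' LS-SVM class predictions in {-1, +1}
#' @inheritParams lssvm_decision
#' @export
lssvm_predict <- function(model, xnew) {
  ifelse(lssvm_decision(model, xnew) >= 0, 1, -1)
}

#' Misclassification rate on a labelled set
#' @param model `lssvm_model`.
#' @param x feature matrix; `y` labels in {-1, +1}.
#' @return fraction misclassified.
#' @export
lssvm_error <- function(model, x, y) mean(lssvm_predict(model, x) != y)

# ---------------------------------------------------------------------------
# Real-coded GA: tournament selection, arithmetic crossover, Gaussian
# mutation, elitism of one.  Minimizes `fn` over a box.
# ---------------------------------------------------------------------------

#' Real-coded genetic algorithm minimizer
#'
#' @param fn objective taking a numeric parameter vector, returning a scalar
#'   to minimize.
#' @param lower,upper box bounds.
#' @param pop_size population size.
#' @param generations number of generations.
#' @param seed integer seed (the search is fully reproducible).
#' @param seed_points optional matrix of individuals injected into the
#'   initial population (clamped to bounds) -- used to warm-start from a
#'   known baseline.
#' @param p_mut per-gene mutation probability.
#' @return list with `par`, `value` and `history` (best value per generation).
#' @export
ga_minimize <- function(fn, lower, upper, pop_size = 30L, generations = 50L,
                        seed = 1L, seed_points = NULL, p_mut = 0.25) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower), pop_size >= 2)
  clamp <- function(m) {
    for (j in seq_len(d)) m[, j] <- pmin(pmax(m[, j], lower[j]), upper[j])
    m
  }
  with_seed(seed, {
    pop <- matrix(runif(pop_size * d, rep(lower, each = pop_size),
                        rep(upper, each = pop_size)), pop_size, d)
    if (!is.null(seed_points)) {
      sp <- clamp(rbind(seed_points))
      pop[seq_len(min(nrow(sp), pop_size)), ] <- sp[seq_len(min(nrow(sp),
                                                                pop_size)), ]
    }
    fit <- apply(pop, 1, fn)
    history <- numeric(generations)
    sdv <- (upper - lower) * 0.1
    for (g in seq_len(generations)) {
      newpop <- matrix(0, pop_size, d)
      best <- which.min(fit)
      newpop[1, ] <- pop[best, ]             # elitism
      for (i in seq(2, pop_size)) {
        pick <- function() {
          cand <- sample.int(pop_size, 3)
          cand[which.min(fit[cand])]
        }
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        w <- runif(d)
        child <- w * p1 + (1 - w) * p2       # arithmetic crossover
        mut <- runif(d) < p_mut
        child[mut] <- child[mut] + rnorm(sum(mut), 0, sdv[mut])
        newpop[i, ] <- child
      }
      pop <- clamp(newpop)
      fit <- apply(pop, 1, fn)
      history[g] <- min(fit)
    }
    best <- which.min(fit)
    list(par = pop[best, ], value = fit[best], history = history)
  })
}
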