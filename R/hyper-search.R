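#' Hyperparameter search space
#'
#' Bounds and budget for selecting the smoothing parameter `alpha`
#' (log-scaled) and the candidate-filter threshold `minidp_min` (decibans)
#' by maximising the cross-validated support-weighted total F1.
#'
#' @param alpha_bounds Positive interval for `alpha`, searched on a log
#'   scale.
#' @param minidp_bounds Interval for `minidp_min` in decibans.
#' @param budget Maximum number of cross-validation evaluations.
#' @param strategy `"grid"` (reference strategy) or `"bayesian"`
#'   (sequential model-based search with expected improvement).
#' @param seed Seed for the search's own randomness.
#' @return A `search_space` list.
#' @export
search_space <- function(alpha_bounds = c(1e-3, 10), minidp_bounds = c(0, 5),
                         budget = 10L, strategy = c("grid", "bayesian"),
                         seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(length(alpha_bounds) == 2, all(alpha_bounds > 0),
            diff(alpha_bounds) >= 0, length(minidp_bounds) == 2,
            diff(minidp_bounds) >= 0, budget >= 1)
  structure(list(alpha_bounds = alpha_bounds, minidp_bounds = minidp_bounds,
                 budget = as.integer(budget), strategy = strategy,
                 seed = as.integer(seed)),
            class = "search_space")
}

# minimal GP surrogate on the unit square: RBF kernel, fixed length-scale,
# expected improvement acquisition over a random candidate cloud
gp_expected_improvement <- function(X, y, cand, lengthscale = 0.3) {
  sf2 <- stats::var(y)
  if (!is.finite(sf2) || sf2 <= 0) sf2 <- 1
  sqdist <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  }
  K <- sf2 * exp(-sqdist(X, X) / (2 * lengthscale^2)) +
    diag(1e-6 * sf2, nrow(X))
  Ks <- sf2 * exp(-sqdist(cand, X) / (2 * lengthscale^2))
  Kinv_y <- solve(K, y - mean(y))
  mu <- mean(y) + Ks %*% Kinv_y
  v <- Ks %*% solve(K, t(Ks))
  s2 <- pmax(sf2 - diag(v), 1e-12)
  s <- sqrt(s2)
  best <- max(y)
  z <- (mu - best) / s
  as.vector((mu - best) * stats::pnorm(z) + s * stats::dnorm(z))
}

#' Tune alpha and the minIDP threshold
#'
#' Runs the chosen search strategy over the [search_space()], scoring each
#' configuration with [cross_validate()] on the full mining + model
#' pipeline, and returns the argmax configuration with the full evaluation
#' history. The grid strategy spreads the budget over a log-spaced `alpha`
#' x linear `minidp_min` lattice; the Bayesian strategy seeds a few random
#' evaluations and then proposes points by expected improvement under a
#' Gaussian-process surrogate. Both are deterministic given the space's
#' seed.
#'
#' @inheritParams cross_validate
#' @param space A [search_space()].
#' @param ... Further arguments passed to [cross_validate()]
#'   (e.g. `min_per_fold`, `cap`, `targets`).
#' @return A list of class `hyper_search`: `alpha`, `minidp_min`,
#'   `best_f1`, and `history` (tibble: iteration, alpha, minidp_min,
#'   mean_f1, per-fold F1 list-column).
#' @export
tune_hyperparameters <- function(X0, Y, space, model_order, support_min = 30,
                                 k = 5, seed = 1L, ...) {
  stopifnot(inherits(space, "search_space"))
  la <- log(space$alpha_bounds)
  mb <- space$minidp_bounds
  evaluate <- function(alpha, minidp) {
    tryCatch(
      cross_validate(X0, Y, model_order = model_order, alpha = alpha,
                     support_min = support_min, minidp_min = minidp,
                     k = k, seed = seed, ...),
      error = function(e) NULL
    )
  }
  history <- tibble::tibble(iteration = integer(0), alpha = numeric(0),
                            minidp_min = numeric(0), mean_f1 = numeric(0),
                            fold_f1 = list())
  record <- function(i, alpha, minidp, cv) {
    history <<- dplyr::bind_rows(history, tibble::tibble(
      iteration = i, alpha = alpha, minidp_min = minidp,
      mean_f1 = if (is.null(cv)) NA_real_ else cv$mean_f1,
      fold_f1 = list(if (is.null(cv)) numeric(0) else cv$fold_f1)))
  }
  if (space$strategy == "grid") {
    n_a <- max(1L, ceiling(sqrt(space$budget)))
    n_m <- max(1L, floor(space$budget / n_a))
    alphas <- if (n_a == 1) exp(mean(la)) else exp(seq(la[1], la[2], length.out = n_a))
    minidps <- if (n_m == 1) mean(mb) else seq(mb[1], mb[2], length.out = n_m)
    grid <- expand.grid(alpha = alphas, minidp = minidps)
    grid <- utils::head(grid, space$budget)
    for (i in seq_len(nrow(grid)))
      record(i, grid$alpha[i], grid$minidp[i], evaluate(grid$alpha[i], grid$minidp[i]))
  } else {
    set.seed(space$seed)
    n_init <- min(max(3L, 2L), space$budget)
    # unit-square coordinates: u1 -> log alpha, u2 -> minidp
    U <- matrix(stats::runif(2 * n_init), ncol = 2)
    to_par <- function(u) c(exp(la[1] + u[1] * diff(la)),
                            mb[1] + u[2] * diff(mb))
    for (i in seq_len(n_init)) {
      p <- to_par(U[i, ])
      record(i, p[1], p[2], evaluate(p[1], p[2]))
    }
    i <- n_init
    while (i < space$budget) {
      i <- i + 1L
      done <- !is.na(history$mean_f1)
      if (sum(done) >= 2) {
        cand <- matrix(stats::runif(1000), ncol = 2)
        ei <- gp_expected_improvement(U[done, , drop = FALSE],
                                      history$mean_f1[done], cand)
        u_next <- cand[which.max(ei), ]
      } else {
        u_next <- stats::runif(2)
      }
      U <- rbind(U, u_next)
      p <- to_par(u_next)
      record(i, p[1], p[2], evaluate(p[1], p[2]))
    }
  }
  if (all(is.na(history$mean_f1)))
    stop("all hyperparameter evaluations failed")
  best <- which.max(history$mean_f1)
  structure(list(alpha = history$alpha[best],
                 minidp_min = history$minidp_min[best],
                 best_f1 = history$mean_f1[best], history = history),
            class = "hyper_search")
}

#' @export
print.hyper_search <- function(x, ...) {
  cat("Hyperparameter search:", nrow(x$history), "evaluations\n")
  cat("  best: alpha =", signif(x$alpha, 4), ", minIDP_min =",
      signif(x$minidp_min, 4), "db, mean F1 =", round(x$best_f1, 4), "\n")
  invisible(x)
}

#' Write a hyperparameter-search history as CSV
#'
#' @param search A `hyper_search` result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_search_history <- function(search, path) {
  h <- search$history
  h$fold_f1 <- vapply(h$fold_f1, paste, character(1), collapse = ";")
  readr::write_csv(h, path, progress = FALSE)
  invisible(path)
}
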