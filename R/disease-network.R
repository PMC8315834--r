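#' Coefficient-similarity matrix of the generalized disease network
#'
#' Two features are similar when they predict similar targets across the
#' whole diagnostic spectrum: the similarity is the Gaussian approximation
#' to the mutual information of their coefficient rows,
#' `Phi(f1, f2) = -1/2 * log(1 - rho^2)` (natural log, nats), where `rho`
#' is the Pearson correlation of the rows `C(f1, .)` and `C(f2, .)`.
#' Constant rows get `rho = 0`; `rho = +/-1` is clipped
#' (`rho^2 <= 1 - 1e-12`). The diagonal (self-loops) is set to 0. `Phi` is
#' symmetric, non-negative and invariant under affine rescaling of the
#' coefficient rows.
#'
#' @param model A fitted [mnb_fit()] model with at least two features and
#'   two targets.
#' @return A symmetric non-negative features x features matrix.
#' @export
coefficient_similarity <- function(model) {
  C <- model$C
  if (nrow(C) < 2) stop("need at least two features")
  if (ncol(C) < 2) stop("need at least two targets to correlate over")
  sds <- apply(C, 1, stats::sd)
  rho <- suppressWarnings(stats::cor(t(C)))
  rho[is.na(rho)] <- 0
  rho[sds == 0, ] <- 0
  rho[, sds == 0] <- 0
  phi <- -0.5 * log(pmax(1 - rho^2, 1e-12))  # clip rho = +/-1
  diag(phi) <- 0
  dimnames(phi) <- list(rownames(C), rownames(C))
  phi
}

#' Discretize a similarity matrix into integer weights
#'
#' Bins every positive off-diagonal entry of `Phi` into one of `n_bins`
#' equal-width bins spanning the off-diagonal range, mapping the maximum to
#' bin `n_bins`. Self-loops and exact zeros stay 0, so absent similarity
#' contributes no mass to the null model. The bin count balances the
#' resolution of the discretization against the cost of the subsequent
#' null-model filter.
#'
#' @param phi Similarity matrix from [coefficient_similarity()].
#' @param n_bins Number of bins (default 30).
#' @return Integer weight matrix of the same shape.
#' @export
discretize_weights <- function(phi, n_bins = 30) {
  stopifnot(all(is.finite(phi)))
  W <- phi
  diag(W) <- 0
  off <- W[row(W) != col(W)]
  lo <- min(off); hi <- max(off)
  if (hi == lo) {
    warning("degenerate similarity range: all positive entries map to bin 1")
    W[W > 0] <- 1L
    storage.mode(W) <- "integer"
    return(W)
  }
  width <- (hi - lo) / n_bins
  pos <- W > 0
  W[pos] <- pmin(n_bins, pmax(1, ceiling((W[pos] - lo) / width)))
  W[!pos] <- 0
  storage.mode(W) <- "integer"
  W
}

#' Fit the weighted configuration model
#'
#' The weighted configuration model (WCM) is the maximum-entropy ensemble
#' of weighted networks with the observed node strengths
#' `s_i = sum_j w_ij` fixed. Its parameters `y* in [0, 1)^N` solve
#' `sum_{j != i} y_i y_j / (1 - y_i y_j) = s_i` for every node; they are
#' found by Levenberg-Marquardt least squares on the strength residuals,
#' parametrized on the logit scale to keep `y` strictly inside `[0, 1)`
#' and initialized with seeded random numbers in `[0, 1)`. Isolated nodes
#' (`s_i = 0`) get `y_i = 0` exactly.
#'
#' @param W Integer weight matrix from [discretize_weights()].
#' @param seed Seed for the random initialization.
#' @param tol Convergence requirement: maximum absolute strength residual.
#' @param maxit Maximum optimizer iterations.
#' @return Named numeric vector `y*` (one entry per node).
#' @export
fit_wcm <- function(W, seed = 1L, tol = 1e-6, maxit = 500L) {
  s <- rowSums(W)
  n <- length(s)
  y <- stats::setNames(numeric(n), rownames(W))
  active <- s > 0
  if (!any(active)) return(y)
  sa <- s[active]
  resid_fn <- function(ya) {
    P <- outer(ya, ya)
    M <- P / (1 - P)
    diag(M) <- 0
    rowSums(M) - sa
  }
  # Fit on the logit scale: y = plogis(z) keeps y strictly inside [0, 1)
  # without box constraints (the boundary y = 1 is a singular attractor of
  # the raw parametrization).  The strength equations can be degenerate --
  # an isolated dyad constrains only the product y_i y_j -- so a tiny
  # ridge on z selects the minimum-norm (symmetric) solution; its
  # perturbation of the strength residuals is far below the tolerance.
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxit, ftol = 1e-15,
                                     ptol = 1e-15)
  best <- NULL
  for (attempt in seq_len(5L)) {
    set.seed(seed + attempt - 1L)
    z0 <- stats::qlogis(pmin(pmax(stats::runif(sum(active)), 1e-3), 1 - 1e-3))
    # ridge continuation: start with a strong pull along any degenerate
    # direction and relax it, finishing with a pure strength-residual polish
    par <- z0
    for (mu in c(0.3, 0.03, 0.003, 3e-4, 0)) {
      fitm <- minpack.lm::nls.lm(par = par, control = ctrl,
                                 fn = function(z)
                                   c(resid_fn(stats::plogis(z)), mu * z))
      par <- fitm$par
    }
    res <- max(abs(resid_fn(stats::plogis(par))))
    if (is.null(best) || res < best$res) best <- list(par = par, res = res)
    if (best$res < tol) break
  }
  if (best$res >= tol)
    stop("WCM fit did not converge: max |strength residual| = ",
         format(best$res, digits = 4))
  y[active] <- stats::plogis(best$par)
  y
}

#' Extract the maximum-entropy backbone
#'
#' For every positive-weight pair, the probability under the WCM null
#' model of generating a link at least as heavy as observed is
#' `gamma_ij = (y*_i * y*_j)^w_ij`; an edge enters the backbone iff
#' `gamma_ij < alpha` (strictly). The local, strength-conditioned filter
#' adjusts for multiple testing and for the wide strength imbalance across
#' nodes. Retained edges carry the attributes `phi`, `w` and `gamma`.
#'
#' @param phi Similarity matrix.
#' @param W Integer weight matrix.
#' @param ystar Fitted WCM parameters ([fit_wcm()]).
#' @param alpha Significance threshold (default 0.05).
#' @return An undirected [igraph::graph] over all features, with the
#'   backbone edges.
#' @export
extract_backbone <- function(phi, W, ystar, alpha = 0.05) {
  nodes <- rownames(phi)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  gamma <- (ystar[idx[, 1]] * ystar[idx[, 2]])^W[idx]
  keep <- gamma < alpha
  edges <- tibble::tibble(
    from = nodes[idx[keep, 1]],
    to = nodes[idx[keep, 2]],
    phi = phi[idx[keep, , drop = FALSE]],
    w = W[idx[keep, , drop = FALSE]],
    gamma = gamma[keep]
  )
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = tibble::tibble(name = nodes))
}

#' Cluster the backbone and keep its giant component
#'
#' Applies seeded Louvain modularity optimisation (edge weights: `phi`,
#' resolution 1 by default) to the backbone and restricts the result to
#' the largest connected component, which is presented as the generalized
#' disease network.
#'
#' @param graph Backbone graph from [extract_backbone()].
#' @param seed Seed for the Louvain heuristic.
#' @param resolution Louvain resolution parameter.
#' @return An object of class `disease_network`: `nodes` (tibble: feature,
#'   cluster, degree, in_giant) covering every non-isolated backbone node,
#'   and `graph`, the giant connected component with a `cluster` vertex
#'   attribute — the network as presented. Cluster ids and cohort
#'   construction use the full backbone clustering; the giant component is
#'   the displayed subgraph.
#' @export
cluster_network <- function(graph, seed = 1L, resolution = 1) {
  if (igraph::ecount(graph) == 0) stop("empty backbone: nothing to cluster")
  # drop fully isolated nodes before clustering; they carry no retained
  # association
  deg <- igraph::degree(graph)
  g <- igraph::induced_subgraph(graph, which(deg > 0))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, weights = igraph::E(g)$phi,
                                  resolution = resolution)
  memb <- igraph::membership(comm)
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  in_giant <- comp$membership == giant
  sub <- igraph::induced_subgraph(g, which(in_giant))
  igraph::V(sub)$cluster <- memb[in_giant]
  nodes <- tibble::tibble(feature = igraph::V(g)$name,
                          cluster = as.integer(memb),
                          degree = as.integer(igraph::degree(g)),
                          in_giant = unname(in_giant))
  structure(list(graph = sub, nodes = nodes, n_components = comp$no),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat("Generalized disease network:", nrow(x$nodes), "connected features in",
      length(unique(x$nodes$cluster)), "clusters;",
      "giant component:", sum(x$nodes$in_giant), "features,",
      igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

#' Build the generalized disease network from a fitted model
#'
#' Convenience pipeline: [coefficient_similarity()] ->
#' [discretize_weights()] -> [fit_wcm()] -> [extract_backbone()] ->
#' [cluster_network()].
#'
#' @param model A fitted [mnb_fit()] model.
#' @param n_bins Discretization bins.
#' @param alpha Backbone significance threshold.
#' @param seed Seed for the WCM initialization and Louvain.
#' @param resolution Louvain resolution.
#' @return A `disease_network` (see [cluster_network()]); the similarity
#'   and weight matrices are attached as attributes `phi` and `W`.
#' @export
build_disease_network <- function(model, n_bins = 30, alpha = 0.05,
                                  seed = 1L, resolution = 1) {
  phi <- coefficient_similarity(model)
  W <- discretize_weights(phi, n_bins)
  ystar <- fit_wcm(W, seed = seed)
  bb <- extract_backbone(phi, W, ystar, alpha)
  net <- cluster_network(bb, seed = seed, resolution = resolution)
  attr(net, "phi") <- phi
  attr(net, "W") <- W
  attr(net, "ystar") <- ystar
  net
}

feature_contains_code <- function(keys, icd3) {
  targets <- paste0(icd3, c("p", "s"))
  vapply(strsplit(keys, " ", fixed = TRUE),
         function(cs) any(cs %in% targets), logical(1))
}

#' Distribution of an index disease over network clusters
#'
#' Counts, per cluster, the features whose code set contains the index
#' code in either diagnostic role (primary or secondary). An index disease
#' whose features are spread over several clusters is a candidate for
#' multiple distinct phenotypes.
#'
#' @param network A `disease_network`.
#' @param icd3 Bare 3-character index code, e.g. `"E66"`.
#' @return Tibble with `cluster`, `n_features` and `fraction` (of all
#'   index-code features in the network), sorted by count descending.
#' @export
index_disease_view <- function(network, icd3) {
  hit <- feature_contains_code(network$nodes$feature, icd3)
  if (!any(hit)) {
    warning("no feature in the network contains code ", icd3)
    return(tibble::tibble(cluster = integer(0), n_features = integer(0),
                          fraction = numeric(0)))
  }
  network$nodes[hit, ] |>
    dplyr::count(.data$cluster, name = "n_features") |>
    dplyr::mutate(fraction = .data$n_features / sum(.data$n_features)) |>
    dplyr::arrange(dplyr::desc(.data$n_features), .data$cluster)
}

#' Export the disease network
#'
#' Writes the giant component as GraphML (vertex attributes: feature key,
#' cluster; edge attributes: phi, w, gamma) or the edge list as TSV.
#'
#' @param network A `disease_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edgelist <- function(network, path) {
  e <- igraph::as_data_frame(network$graph, what = "edges")
  readr::write_tsv(tibble::as_tibble(e), path, progress = FALSE)
  invisible(path)
}
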