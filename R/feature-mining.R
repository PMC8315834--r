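feature_key <- function(codes) paste(sort(codes), collapse = " ")

key_codes <- function(key) strsplit(key, " ", fixed = TRUE)

# dense logical view of a sparse patient x code indicator
dense_logical <- function(X0) {
  m <- as.matrix(X0) != 0
  dimnames(m) <- dimnames(X0)
  m
}

#' Minimum information difference to prior (minIDP)
#'
#' For a set of role-suffixed diagnosis codes, minIDP is the minimum over
#' member codes `d` of `10 * log10( P(d | rest of the set present) / P(d) )`
#' in decibans, with Laplace-smoothed probability estimates (add 1 to the
#' numerator count and 2 to the denominator count). A set of diagnoses that
#' co-occur more often than chance has a positive minIDP for *every* member;
#' any member occurring independently of the rest pulls the minimum towards
#' 0, and mutual exclusivity makes it strongly negative. Used to filter
#' candidate features so that only genuinely associated code sets survive.
#'
#' @param codes Character vector of two or more column names of `X0`.
#' @param X0 Patient x code indicator matrix ([build_matrices()]).
#' @return minIDP in decibans (a single number).
#' @examples
#' X0 <- Matrix::sparseMatrix(i = c(1:10, 1:10), j = rep(1:2, each = 10),
#'                            x = 1, dims = c(100, 2),
#'                            dimnames = list(NULL, c("E11s", "E66s")))
#' min_idp(c("E11s", "E66s"), X0)  # perfectly co-occurring: strongly positive
#' @export
min_idp <- function(codes, X0) {
  stopifnot(length(codes) >= 2)
  miss <- setdiff(codes, colnames(X0))
  if (length(miss)) stop("codes absent from X0: ", paste(miss, collapse = ", "))
  n <- nrow(X0)
  sub <- dense_logical(X0[, codes, drop = FALSE])
  n_all <- sum(rowSums(sub) == length(codes))
  vals <- vapply(seq_along(codes), function(i) {
    rest <- sub[, -i, drop = FALSE]
    n_rest <- sum(rowSums(rest) == ncol(rest))
    p_cond <- (n_all + 1) / (n_rest + 2)
    p_marg <- (sum(sub[, i]) + 1) / (n + 2)
    10 * log10(p_cond / p_marg)
  }, numeric(1))
  min(vals)
}

order_feature_tbl <- function(tbl) {
  ord <- order(-tbl$cardinality, -tbl$minidp, -tbl$support, tbl$key,
               method = "radix")
  tbl <- tbl[ord, , drop = FALSE]
  tbl$rank <- seq_len(nrow(tbl))
  dplyr::relocate(tbl, "rank")
}

new_feature_set <- function(tbl) {
  class(tbl) <- c("feature_set", class(tbl))
  tbl
}

#' Construct a feature set from explicit code sets
#'
#' Builds an ordered feature tibble from a given list of code sets,
#' computing support (raw co-occurrence count) and minIDP from `X0` and
#' applying the canonical ordering: cardinality descending, then minIDP
#' descending, then support descending, then lexicographic code string.
#' Useful for designed feature sets in simulation studies; [mine_candidates()]
#' produces the same structure from the data itself.
#'
#' @param codes_list List of character vectors of role-suffixed codes.
#' @param X0 Patient x code indicator matrix.
#' @return An ordered `feature_set` tibble with columns `rank`, `key`,
#'   `codes` (list), `cardinality`, `minidp`, `support`.
#' @export
feature_set <- function(codes_list, X0) {
  X0d <- dense_logical(X0)
  keys <- vapply(codes_list, feature_key, character(1))
  if (anyDuplicated(keys)) stop("duplicate code sets in feature set")
  tbl <- tibble::tibble(
    key = keys,
    codes = lapply(codes_list, sort),
    cardinality = lengths(codes_list),
    minidp = vapply(codes_list, function(cs) {
      if (length(cs) < 2) 0 else min_idp(cs, X0)
    }, numeric(1)),
    support = vapply(codes_list, function(cs) {
      sum(rowSums(X0d[, cs, drop = FALSE]) == length(cs))
    }, numeric(1))
  )
  new_feature_set(order_feature_tbl(tbl))
}

#' Mine candidate higher-order diagnosis features
#'
#' Level-wise (apriori-style) enumeration of all code sets of size 1 to
#' `model_order` whose co-occurrence support is at least `support_min`,
#' keeping, for sets of two or more codes, only those with
#' [min_idp()] at or above `minidp_min` — i.e. sets whose members occur
#' together more often than expected by chance. Singletons bypass the
#' minIDP filter (their conditional and marginal probabilities coincide, so
#' the measure is identically 0). Extension at each level uses support
#' frequency only (support is anti-monotone; minIDP is not), so a set may
#' qualify even when a subset was filtered by minIDP.
#'
#' @param X0 Patient x code indicator matrix ([build_matrices()]).
#' @param model_order Maximum number of codes per feature (>= 1). Orders
#'   above 4 are permitted but warned about (combinatorial growth).
#' @param support_min Minimum number of carriers (default 30).
#' @param minidp_min minIDP threshold in decibans for sets of size >= 2.
#' @return An ordered `feature_set` tibble (see [feature_set()]).
#' @export
mine_candidates <- function(X0, model_order, support_min = 30, minidp_min = 0) {
  stopifnot(model_order >= 1, support_min >= 1)
  if (model_order > 4)
    warning("model_order > 4: candidate enumeration may be very large")
  X0d <- dense_logical(X0)
  n <- nrow(X0d)
  codes <- colnames(X0d)
  supp1 <- colSums(X0d)
  freq1 <- sort(codes[supp1 >= support_min])
  out <- list()
  if (length(freq1)) {
    out[[1]] <- tibble::tibble(
      key = freq1, codes = as.list(freq1), cardinality = 1L,
      minidp = 0, support = as.numeric(supp1[freq1])
    )
  }
  # frequent-set registry per level: named support vectors + indicator lists
  prev_keys <- freq1
  prev_codes <- as.list(freq1)
  prev_supp <- stats::setNames(as.numeric(supp1[freq1]), freq1)
  prev_ind <- lapply(freq1, function(cd) X0d[, cd])
  names(prev_ind) <- freq1
  supp_by_level <- list(prev_supp)
  level <- 1L
  while (level < model_order && length(prev_keys) > 0) {
    level <- level + 1L
    keys <- character(0); codes_l <- list(); supp <- numeric(0)
    ind <- list(); midp <- numeric(0)
    for (i in seq_along(prev_keys)) {
      base_codes <- prev_codes[[i]]
      last <- base_codes[length(base_codes)]
      ext <- freq1[freq1 > last]
      if (!length(ext)) next
      base_ind <- prev_ind[[i]]
      for (cd in ext) {
        cand <- c(base_codes, cd)
        # apriori prune: every (level-1)-subset must be support-frequent
        subs <- vapply(seq_along(cand), function(j)
          feature_key(cand[-j]), character(1))
        if (!all(subs %in% prev_keys)) next
        v <- base_ind & X0d[, cd]
        s <- sum(v)
        if (s < support_min) next
        # minIDP from the registered subset supports: subs[j] is the set
        # without cand[j], so p_cond[j] = P(cand[j] | rest) pairs with
        # p_marg[j] = P(cand[j])
        p_marg <- (supp1[cand] + 1) / (n + 2)
        p_cond <- (s + 1) / (prev_supp[subs] + 2)
        m <- min(10 * log10(p_cond / p_marg))
        k <- feature_key(cand)
        keys <- c(keys, k); codes_l <- c(codes_l, list(cand))
        supp <- c(supp, s); ind <- c(ind, list(v)); midp <- c(midp, m)
      }
    }
    if (length(keys)) {
      names(supp) <- keys
      names(ind) <- keys
      keep <- midp >= minidp_min
      if (any(keep)) {
        out[[level]] <- tibble::tibble(
          key = keys[keep], codes = codes_l[keep],
          cardinality = level, minidp = unname(midp[keep]),
          support = unname(supp[keep])
        )
      }
      prev_keys <- keys; prev_codes <- codes_l
      prev_supp <- supp; prev_ind <- ind
    } else {
      prev_keys <- character(0)
    }
  }
  tbl <- dplyr::bind_rows(out)
  if (nrow(tbl) == 0) {
    tbl <- tibble::tibble(key = character(0), codes = list(),
                          cardinality = integer(0), minidp = numeric(0),
                          support = numeric(0))
  }
  new_feature_set(order_feature_tbl(tbl))
}

#' Greedily assign features to patients
#'
#' Walks the ordered feature set from top (highest cardinality / minIDP /
#' support) to bottom. A feature is assigned to a patient iff all its codes
#' are present in the patient's feature-period diagnoses *and* none of them
#' has already been covered by a previously assigned feature; on assignment
#' the feature's codes are marked covered. Each diagnosis code of a patient
#' is therefore covered by at most one feature, and the assigned features
#' of a patient have pairwise-disjoint code sets. Codes for which no
#' feature survives remain uncovered.
#'
#' @param X0 Patient x code indicator matrix.
#' @param features Ordered `feature_set` tibble.
#' @return Sparse patients x features indicator matrix (columns in feature
#'   order, named by feature key).
#' @export
assign_features <- function(X0, features) {
  X0d <- dense_logical(X0)
  n <- nrow(X0d)
  covered <- matrix(FALSE, n, ncol(X0d), dimnames = dimnames(X0d))
  ii <- integer(0); jj <- integer(0)
  for (f in seq_len(nrow(features))) {
    cs <- features$codes[[f]]
    if (!all(cs %in% colnames(X0d))) next
    k <- length(cs)
    if (k == 1L) {
      ok <- X0d[, cs] & !covered[, cs]
    } else {
      ok <- rowSums(X0d[, cs, drop = FALSE]) == k &
        rowSums(covered[, cs, drop = FALSE]) == 0
    }
    if (any(ok)) {
      covered[ok, cs] <- TRUE
      w <- which(ok)
      ii <- c(ii, w); jj <- c(jj, rep.int(f, length(w)))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(n, nrow(features)),
                       dimnames = list(rownames(X0d), features$key))
}

#' Prune weakly supported features to the final feature set
#'
#' Iterates greedy assignment and pruning: after [assign_features()], if
#' any feature's *assigned* support falls below `support_min`, only the
#' first such feature in the ordering is removed and the assignment is
#' repeated — removing one at a time lets later weak features regain
#' support from the remapped patients. Terminates when every remaining
#' feature is supported by at least `support_min` patients (each round
#' removes exactly one feature, so termination is guaranteed).
#'
#' @inheritParams assign_features
#' @param support_min Minimum assigned support.
#' @return A list with `features` (the final ordered feature set, `support`
#'   updated to the assigned support) and `X` (the final patients x
#'   features matrix).
#' @export
prune_to_final <- function(X0, features, support_min = 30) {
  repeat {
    X <- assign_features(X0, features)
    supp <- Matrix::colSums(X)
    weak <- which(supp < support_min)
    if (!length(weak)) {
      features$support <- as.numeric(supp)
      features$rank <- seq_len(nrow(features))
      return(list(features = features, X = X))
    }
    features <- features[-weak[1], , drop = FALSE]
    if (nrow(features) == 0) {
      return(list(features = features,
                  X = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0),
                                           dims = c(nrow(X0), 0),
                                           dimnames = list(rownames(X0), NULL))))
    }
  }
}

#' Serialize a feature set as TSV
#'
#' Columns: rank, codes (space-joined), cardinality, minIDP (db), support.
#'
#' @param features `feature_set` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(features, path) {
  out <- tibble::tibble(rank = features$rank, codes = features$key,
                        cardinality = features$cardinality,
                        minidp = features$minidp, support = features$support)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
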