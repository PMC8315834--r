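#' Decompose a feature into lower-order constituents
#'
#' Walks the ordered feature set downwards starting immediately after
#' feature `f` and collects every feature whose code set is contained in
#' the not-yet-collected remainder of `f`'s codes, stopping when the union
#' of the collected code sets equals `f`'s codes. The ordering (cardinality
#' descending first) guarantees the collected sets are pairwise disjoint,
#' so they form a partition of `f`'s diagnosis set.
#'
#' @param key Feature key (space-joined sorted codes) present in `features`.
#' @param features Ordered `feature_set` tibble.
#' @return Character vector of constituent feature keys, in collection
#'   order. Errors if no complete partition exists (some remainder code has
#'   no feature), in which case the lift of `f` is undefined.
#' @export
build_partition <- function(key, features) {
  pos <- match(key, features$key)
  if (is.na(pos)) stop("feature not in the feature set: ", key)
  target_codes <- features$codes[[pos]]
  if (length(target_codes) == 1)
    stop("singleton features have no lower-order decomposition")
  remaining <- target_codes
  collected <- character(0)
  f <- pos
  while (length(remaining) > 0) {
    f <- f + 1L
    if (f > nrow(features))
      stop("incomplete partition for feature ", key,
           ": no feature covers codes ", paste(remaining, collapse = " "))
    cs <- features$codes[[f]]
    if (all(cs %in% remaining)) {
      collected <- c(collected, features$key[f])
      remaining <- setdiff(remaining, cs)
    }
  }
  collected
}

#' Fit the family of per-order models
#'
#' Lift compares the coefficient of a higher-order feature with the
#' coefficients of its constituents taken from *lower-order* models, so
#' one model per order `1..model_order` is fitted. By default each order
#' gets its own mined and pruned feature set; alternatively an explicit
#' (designed) feature set can be supplied, in which case the order-`m`
#' model uses its features of cardinality at most `m` without pruning.
#'
#' @inheritParams cross_validate
#' @param features Optional `feature_set` tibble overriding mining.
#' @param targets,event_model Passed to [mnb_fit()].
#' @return A list of class `order_models`: `models` (one `mnb_model` per
#'   order), `X` (per-order feature matrices) and `model_order`.
#' @export
fit_order_models <- function(X0, Y, model_order, alpha = 1, support_min = 30,
                             minidp_min = 0, targets = NULL,
                             event_model = "multinomial", features = NULL) {
  models <- vector("list", model_order)
  Xs <- vector("list", model_order)
  for (m in seq_len(model_order)) {
    if (is.null(features)) {
      cand <- mine_candidates(X0, m, support_min, minidp_min)
      fin <- prune_to_final(X0, cand, support_min)
      feats_m <- fin$features
      X_m <- fin$X
    } else {
      feats_m <- features[features$cardinality <= m, , drop = FALSE]
      feats_m$rank <- seq_len(nrow(feats_m))
      X_m <- assign_features(X0, feats_m)
    }
    models[[m]] <- mnb_fit(X_m, Y, alpha = alpha, targets = targets,
                           event_model = event_model, features = feats_m,
                           order = m)
    Xs[[m]] <- X_m
  }
  structure(list(models = models, X = Xs, model_order = model_order),
            class = "order_models")
}

#' Lift of a feature-target combination
#'
#' The lift `L(f, t) = C(f, t) - Cbar(f, t)` measures the interaction of
#' the diagnoses making up feature `f` with respect to target `t`:
#' `C(f, t)` is the coefficient from the model whose order equals `f`'s
#' cardinality, and the expected coefficient `Cbar(f, t)` is the sum of the
#' constituents' coefficients, each taken from the model of order equal to
#' that constituent's cardinality ([build_partition()]). For
#' non-interacting diagnoses the model is additive and the lift is about
#' zero; positive lift means synergy, negative redundancy. Singletons have
#' no lower-order decomposition and lift 0 by convention.
#'
#' @param om An [fit_order_models()] object.
#' @param Y Patients x codes target matrix (row order matching the
#'   matrices in `om`), used for the joint-occurrence count.
#' @param pairs Optional tibble with columns `key`, `target` restricting
#'   the computation; default: every feature of cardinality >= 2 in the
#'   top-order model crossed with every model target.
#' @return A tibble of lift records: `key`, `target`, `cardinality`,
#'   `c_db`, `c_expected_db`, `lift_db`, `partition` (pipe-joined
#'   constituent keys), `n_joint` (patients positive in both feature and
#'   target) and `trivial` (target code contained in the feature's codes).
#'   Features whose partition is incomplete get `NA` lift and are flagged
#'   in `partition_complete`.
#' @export
lift_table <- function(om, Y, pairs = NULL) {
  stopifnot(inherits(om, "order_models"))
  top <- om$models[[om$model_order]]
  feats <- top$features
  X_top <- om$X[[om$model_order]]
  if (is.null(pairs)) {
    keys <- feats$key[feats$cardinality >= 2]
    pairs <- tidyr::expand_grid(key = keys, target = colnames(top$C))
  }
  part_cache <- new.env(parent = emptyenv())
  get_partition <- function(key) {
    if (!is.null(part_cache[[key]])) return(part_cache[[key]])
    p <- tryCatch(build_partition(key, feats), error = function(e) NA_character_)
    part_cache[[key]] <- list(p)
    list(p)
  }
  records <- purrr::pmap_dfr(pairs, function(key, target) {
    row <- match(key, feats$key)
    card <- feats$cardinality[row]
    codes <- feats$codes[[row]]
    c_db <- top$C[key, target]
    n_joint <- sum((X_top[, key] != 0) & (Y[, target] != 0))
    trivial <- target %in% codes
    if (card == 1) {
      return(tibble::tibble(key = key, target = target, cardinality = card,
                            c_db = c_db, c_expected_db = c_db, lift_db = 0,
                            partition = key, partition_complete = TRUE,
                            n_joint = n_joint, trivial = trivial))
    }
    part <- get_partition(key)[[1]]
    if (length(part) == 1 && is.na(part)) {
      return(tibble::tibble(key = key, target = target, cardinality = card,
                            c_db = c_db, c_expected_db = NA_real_,
                            lift_db = NA_real_, partition = NA_character_,
                            partition_complete = FALSE, n_joint = n_joint,
                            trivial = trivial))
    }
    c_exp <- sum(vapply(part, function(g) {
      g_card <- length(key_codes(g)[[1]])
      mod <- om$models[[g_card]]
      if (!g %in% rownames(mod$C))
        stop("constituent ", g, " missing from the order-", g_card, " model")
      mod$C[g, target]
    }, numeric(1)))
    tibble::tibble(key = key, target = target, cardinality = card,
                   c_db = c_db, c_expected_db = c_exp,
                   lift_db = c_db - c_exp,
                   partition = paste(part, collapse = " | "),
                   partition_complete = TRUE, n_joint = n_joint,
                   trivial = trivial)
  })
  records
}

#' Rank features by median lift
#'
#' Filters lift records to reliably estimated, non-trivial higher-order
#' combinations — joint occurrence in at least `min_joint` patients
#' (damping coefficient fluctuations) and a coefficient of at least
#' `min_c_db` decibans (a relatively large effect) — then groups by
#' feature, reports the median lift over the qualifying targets of each
#' feature, and sorts descending.
#'
#' @param records Lift-record tibble from [lift_table()].
#' @param min_joint Minimum joint feature-and-target patient count.
#' @param min_c_db Minimum coefficient in decibans.
#' @return A tibble with `key`, `partition`, `median_lift_db`, `targets`
#'   (comma-joined) and `n_targets`, sorted by median lift descending.
#' @export
rank_lifts <- function(records, min_joint = 50, min_c_db = 8) {
  qual <- records |>
    dplyr::filter(.data$n_joint >= min_joint, .data$c_db >= min_c_db,
                  !.data$trivial, .data$cardinality >= 2,
                  .data$partition_complete)
  if (nrow(qual) == 0) {
    return(tibble::tibble(key = character(0), partition = character(0),
                          median_lift_db = numeric(0), targets = character(0),
                          n_targets = integer(0)))
  }
  qual |>
    dplyr::group_by(.data$key, .data$partition) |>
    dplyr::summarise(median_lift_db = stats::median(.data$lift_db),
                     targets = paste(.data$target, collapse = ", "),
                     n_targets = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$median_lift_db))
}

#' Write a ranked lift table as TSV
#'
#' @param ranked Output of [rank_lifts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lift_table <- function(ranked, path) {
  readr::write_tsv(ranked, path, progress = FALSE)
  invisible(path)
}
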