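test_that("minIDP matches hand-computed smoothed estimates", {
  # perfectly co-occurring pair at rate 0.1, n = 1000:
  # P(d | other) = 101/102, P(d) = 101/1002 -> 10 log10(1002/102) = 9.92 db
  X <- toy_matrix(1000, list(A00s = 1:100, B00s = 1:100))
  expect_equal(min_idp(c("A00s", "B00s"), X), 10 * log10(1002 / 102),
               tolerance = 1e-12)
  # independent pair: about 0
  Xi <- toy_matrix(1000, list(A00s = 1:500, B00s = c(1:250, 501:750)))
  expect_lt(abs(min_idp(c("A00s", "B00s"), Xi)), 0.1)
  # mutually exclusive pair: strongly negative
  Xm <- toy_matrix(1000, list(A00s = 1:100, B00s = 101:200))
  expect_lt(min_idp(c("A00s", "B00s"), Xm), -10)
  expect_error(min_idp(c("A00s", "Z99s"), X), "absent")
  expect_error(min_idp("A00s", X))
})

test_that("candidate mining filters by support and minIDP", {
  # A, B always together in 100 of 1000 patients, support_min 30:
  # both singletons and the pair qualify
  X <- toy_matrix(1000, list(A00s = 1:100, B00s = 1:100))
  f <- mine_candidates(X, 2, support_min = 30, minidp_min = 1)
  expect_setequal(f$key, c("A00s", "B00s", "A00s B00s"))
  expect_equal(f$key[1], "A00s B00s")  # higher cardinality first
  # independent at 0.5: the pair misses the 1 db minIDP bar
  Xi <- toy_matrix(1000, list(A00s = 1:500, B00s = c(1:250, 501:750)))
  fi <- mine_candidates(Xi, 2, support_min = 30, minidp_min = 1)
  expect_setequal(fi$key, c("A00s", "B00s"))
  # support below the floor excludes the code everywhere
  Xs <- toy_matrix(1000, list(A00s = 1:29, B00s = 1:100))
  fs <- mine_candidates(Xs, 2, support_min = 30, minidp_min = 0)
  expect_false(any(grepl("A00s", fs$key)))
  expect_warning(mine_candidates(X, 5, 30, 0), "model_order")
})

test_that("mined candidates match a brute-force enumerator on 12 codes", {
  set.seed(20)
  n <- 400
  codes <- sprintf("D%02ds", 1:12)
  # correlated blocks + noise so some but not all sets pass the filters
  base <- matrix(stats::runif(n * 12) < 0.15, n, 12)
  block <- stats::runif(n) < 0.25
  base[block, 1:4] <- matrix(stats::runif(sum(block) * 4) < 0.7, ncol = 4)
  base[block, 5:6] <- matrix(stats::runif(sum(block) * 2) < 0.5, ncol = 2)
  X <- Matrix::Matrix(base * 1, sparse = TRUE,
                      dimnames = list(sprintf("P%04d", 1:n), codes))
  support_min <- 20; minidp_min <- 0.5; max_ord <- 3
  got <- mine_candidates(X, max_ord, support_min, minidp_min)
  # brute force: enumerate every subset up to the order, count directly
  dense <- base
  colnames(dense) <- codes
  brute <- list()
  for (k in 1:max_ord) {
    cmb <- utils::combn(codes, k, simplify = FALSE)
    for (cs in cmb) {
      supp <- sum(rowSums(dense[, cs, drop = FALSE]) == k)
      if (supp < support_min) next
      mi <- if (k == 1) 0 else min_idp(cs, X)
      if (k >= 2 && mi < minidp_min) next
      brute[[length(brute) + 1]] <- tibble::tibble(
        key = paste(sort(cs), collapse = " "), cardinality = k,
        minidp = mi, support = supp)
    }
  }
  brute <- dplyr::bind_rows(brute)
  brute <- brute[order(-brute$cardinality, -brute$minidp, -brute$support,
                       brute$key, method = "radix"), ]
  expect_equal(got$key, brute$key)
  expect_equal(got$support, brute$support)
  expect_equal(got$minidp, brute$minidp, tolerance = 1e-12)
})

test_that("greedy assignment covers each code at most once, in feature order", {
  # patient with {A,B}: the pair wins, the singletons are blocked
  X <- toy_matrix(3, list(A00s = c(1, 2), B00s = 1))
  F1 <- toy_features(list(c("A00s", "B00s"), "A00s", "B00s"))
  M <- assign_features(X, F1)
  expect_equal(as.numeric(M[1, ]), c(1, 0, 0))
  # patient with {A} only: the pair's subset test fails
  expect_equal(as.numeric(M[2, ]), c(0, 1, 0))
  # patient with nothing
  expect_equal(sum(M[3, ]), 0)
})

test_that("assigned features have disjoint code sets within the patient's codes", {
  cfg <- two_phenotype_fixture(seed = 15, n_patients = 1500)
  sim <- simulate_claims(cfg)
  m <- build_matrices(sim$stays,
                      select_study_population(sim$stays, cfg$periods),
                      cfg$periods)
  fin <- prune_to_final(m$X0, mine_candidates(m$X0, 2, 20, 0.5), 20)
  X0d <- as.matrix(m$X0) != 0
  Xf <- fin$X
  for (p in sample.int(nrow(Xf), 50)) {
    keys <- colnames(Xf)[Xf[p, ] != 0]
    codes <- unlist(strsplit(keys, " ", fixed = TRUE))
    expect_false(anyDuplicated(codes) > 0)
    expect_true(all(X0d[p, codes]))
  }
})

test_that("pruning removes one weak feature at a time and re-supports the rest", {
  # 10 patients with {A,B}, 22 with A only, 22 with B only; support_min 30:
  # the pair (support 10) is removed first, after which both singletons
  # reach 32 -- one-at-a-time pruning must keep them
  X <- toy_matrix(60, list(A00s = 1:32, B00s = c(1:10, 33:54)))
  F1 <- toy_features(list(c("A00s", "B00s"), "A00s", "B00s"))
  out <- prune_to_final(X, F1, support_min = 30)
  expect_setequal(out$features$key, c("A00s", "B00s"))
  expect_equal(sort(out$features$support), c(32, 32))
  # well-supported input is a fixed point, and pruning is idempotent
  again <- prune_to_final(X, out$features, support_min = 30)
  expect_equal(again$features$key, out$features$key)
  expect_equal(as.matrix(again$X), as.matrix(out$X))
})

test_that("independent codes collapse to supported singletons at any order", {
  set.seed(8)
  n <- 2000
  dense <- matrix(stats::runif(n * 6) < 0.2, n, 6)
  colnames(dense) <- sprintf("N%02ds", 1:6)
  X <- Matrix::Matrix(dense * 1, sparse = TRUE,
                      dimnames = list(sprintf("P%04d", 1:n), colnames(dense)))
  for (ord in c(2, 3)) {
    fin <- prune_to_final(X, mine_candidates(X, ord, 30, 1), 30)
    expect_true(all(fin$features$cardinality == 1))
    expect_setequal(fin$features$key, colnames(dense))
  }
})

test_that("feature sets serialize to TSV with their ordering", {
  X <- toy_matrix(100, list(A00s = 1:50, B00s = 1:40))
  fs <- feature_set(list("A00s", "B00s", c("A00s", "B00s")), X)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_set(fs, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$rank, 1:3)
  expect_equal(back$codes[1], "A00s B00s")
})
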