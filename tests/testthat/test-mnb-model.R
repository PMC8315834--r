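test_that("deciban conversions follow the Jeffreys scheme", {
  expect_equal(db_to_odds(10), 10)
  expect_equal(db_to_odds(20), 100)
  expect_equal(odds_to_db(db_to_odds(7.3)), 7.3)
  expect_equal(db_to_odds(5), 10^0.5)
})

test_that("coefficients match the stated estimator on a hand example", {
  # 20 patients, one feature present in 9/10 target-positives and 1/10
  # negatives, alpha = 1.  Bernoulli estimator: (9+1)/(10+2) over
  # (1+1)/(10+2) -> 10 log10(5) = 6.99 db
  X <- toy_matrix(20, list(F01s = c(1:9, 11)))
  Y <- toy_matrix(20, list(T01s = 1:10))
  fit_b <- mnb_fit(X, Y, alpha = 1, event_model = "bernoulli")
  expect_equal(unname(fit_b$C["F01s", "T01s"]), 10 * log10(5),
               tolerance = 1e-12)
  expect_equal(unname(fit_b$prior[["T01s"]]), 0)  # balanced classes
  # feature equally frequent in both classes -> C about 0 for small alpha
  Xe <- toy_matrix(20, list(F01s = c(1:5, 11:15)))
  fit_e <- mnb_fit(Xe, Y, alpha = 1e-6, event_model = "bernoulli")
  expect_lt(abs(fit_e$C["F01s", "T01s"]), 1e-4)
  fit_m <- mnb_fit(Xe, Y, alpha = 1e-6, event_model = "multinomial")
  expect_lt(abs(fit_m$C["F01s", "T01s"]), 1e-4)
})

test_that("multinomial class-conditional probabilities are normalized", {
  set.seed(4)
  X <- toy_matrix(200, list(A00s = sample(200, 80), B00s = sample(200, 50),
                            C00s = sample(200, 120)))
  Y <- toy_matrix(200, list(T00s = sample(200, 90)))
  fit <- mnb_fit(X, Y, alpha = 0.7)
  expect_equal(unname(colSums(fit$theta1)), 1, tolerance = 1e-12)
  expect_equal(unname(colSums(fit$theta0)), 1, tolerance = 1e-12)
})

test_that("coefficients are antisymmetric under class swap", {
  set.seed(5)
  X <- toy_matrix(300, list(A00s = sample(300, 120), B00s = sample(300, 60)))
  y <- sample(300, 140)
  Y <- toy_matrix(300, list(T00s = y))
  Yswap <- toy_matrix(300, list(T00s = setdiff(1:300, y)))
  for (em in c("multinomial", "bernoulli")) {
    f1 <- mnb_fit(X, Y, alpha = 1, event_model = em)
    f2 <- mnb_fit(X, Yswap, alpha = 1, event_model = em)
    expect_equal(f1$C, -f2$C, tolerance = 1e-12)
    expect_equal(f1$prior, -f2$prior, tolerance = 1e-12)
  }
})

test_that("coefficients match a brute-force per-target computation", {
  set.seed(6)
  n <- 150
  X <- toy_matrix(n, list(A00s = sample(n, 60), B00s = sample(n, 40),
                          C00s = sample(n, 90)))
  Y <- toy_matrix(n, list(T00s = sample(n, 70), T01s = sample(n, 30)))
  alpha <- 0.5
  fit <- mnb_fit(X, Y, alpha = alpha)
  Xd <- as.matrix(X) != 0; Yd <- as.matrix(Y) != 0
  for (t in colnames(Yd)) {
    pos <- Yd[, t]
    for (f in colnames(Xd)) {
      n1f <- sum(Xd[pos, f]); n0f <- sum(Xd[!pos, f])
      N1 <- sum(Xd[pos, ]); N0 <- sum(Xd[!pos, ])
      theta1 <- (n1f + alpha) / (N1 + alpha * ncol(Xd))
      theta0 <- (n0f + alpha) / (N0 + alpha * ncol(Xd))
      expect_equal(unname(fit$C[f, t]), 10 * log10(theta1 / theta0),
                   tolerance = 1e-12)
    }
    expect_equal(unname(fit$prior[[t]]), 10 * log10(sum(pos) / sum(!pos)),
                 tolerance = 1e-12)
  }
})

test_that("prediction thresholds the decision function strictly at zero", {
  model <- structure(list(
    C = matrix(c(30, -5), 1, 2, dimnames = list("F01s", c("T01s", "T02s"))),
    prior = c(T01s = -10, T02s = 5),
    alpha = 1, event_model = "multinomial", order = 1, features = NULL),
    class = "mnb_model")
  X <- toy_matrix(2, list(F01s = 1))  # patient 2 has no features
  d <- predict(model, X, type = "decision")
  expect_equal(unname(d[1, ]), c(20, 0))
  p <- predict(model, X)
  expect_true(p[1, "T01s"])        # Delta = +20
  expect_false(p[1, "T02s"])       # Delta = 0 exactly -> absent
  expect_false(p[2, "T01s"])       # empty sum: majority class, pi < 0
  expect_true(p[2, "T02s"])        # pi > 0
  colnames(X) <- "other"
  expect_error(predict(model, X), "align")
})

test_that("scores follow the stated zero conventions and weighting", {
  yt <- toy_matrix(200, list(T01s = 1:50, T02s = 1:100))
  # T01s: TP=50, FP=50, FN=0 -> precision .5, recall 1, F1 = 2/3
  yp <- toy_matrix(200, list(T01s = 1:100, T02s = 1:100))
  sc <- mnb_score(yt, yp)
  t1 <- sc$per_target[sc$per_target$target == "T01s", ]
  expect_equal(t1$precision, 0.5)
  expect_equal(t1$recall, 1)
  expect_equal(t1$f1, 2 / 3)
  expect_equal(t1$support, 50)
  # perfect predictions -> all F1 = 1
  expect_equal(mnb_score(yt, yt)$total_f1, 1)
  # support weighting: F1 0.2 with support 10 and 0.8 with support 90 -> 0.74
  expect_equal((10 * 0.2 + 90 * 0.8) / 100, 0.74)
  w <- sum(sc$per_target$support * sc$per_target$f1) / sum(sc$per_target$support)
  expect_equal(sc$total_f1, w)
  expect_gte(sc$total_f1, min(sc$per_target$f1))
  expect_lte(sc$total_f1, max(sc$per_target$f1))
  # nothing predicted and nothing true -> all metrics 0 by convention
  z <- mnb_score(toy_matrix(10, list(T01s = integer(0))),
                 toy_matrix(10, list(T01s = integer(0))))
  expect_equal(z$per_target$f1, 0)
  expect_equal(z$total_f1, 0)
})

test_that("target selection applies the per-fold floor, ranking and cap", {
  set.seed(9)
  n <- 1000
  folds <- make_folds(n, 5, seed = 1)
  # T01s: 400 positives spread evenly (>= 200/5 = 80 per fold at floor 50)
  # T02s: 300 positives, T03s: concentrated in one fold
  one_fold <- which(folds == 1)
  Y <- toy_matrix(n, list(T01s = 1:400, T02s = 401:700,
                          T03s = one_fold[1:60]))
  sel <- select_targets(Y, folds, min_per_fold = 50, cap = 10)
  expect_equal(sel, c("T01s", "T02s"))  # T03s misses the floor in 4 folds
  expect_equal(select_targets(Y, folds, min_per_fold = 50, cap = 1), "T01s")
  # boundary: a target 1 short of the floor in a single fold is excluded
  cnt <- min(table(folds[1:400]))
  expect_true("T01s" %in% select_targets(Y, folds, min_per_fold = cnt, cap = 10))
  expect_false("T01s" %in% select_targets(Y, folds, min_per_fold = cnt + 1,
                                          cap = 10))
})

test_that("fold assignment is balanced and seeded", {
  f <- make_folds(1000, 5, seed = 3)
  expect_equal(as.vector(table(f)), rep(200L, 5))
  expect_identical(f, make_folds(1000, 5, seed = 3))
  expect_false(identical(f, make_folds(1000, 5, seed = 4)))
})

test_that("cross-validation is deterministic and reports per-fold scores", {
  cfg <- two_phenotype_fixture(seed = 21, n_patients = 2500)
  sim <- simulate_claims(cfg)
  m <- build_matrices(sim$stays,
                      select_study_population(sim$stays, cfg$periods),
                      cfg$periods)
  cv <- suppressWarnings(
    cross_validate(m$X0, m$Y, model_order = 2, alpha = 1, support_min = 20,
                   minidp_min = 1, k = 5, seed = 2, min_per_fold = 25))
  expect_length(cv$fold_f1, 5)
  expect_equal(cv$mean_f1, mean(cv$fold_f1))
  expect_true(all(cv$fold_f1 > 0 & cv$fold_f1 < 1))
  cv2 <- suppressWarnings(
    cross_validate(m$X0, m$Y, model_order = 2, alpha = 1, support_min = 20,
                   minidp_min = 1, k = 5, seed = 2, min_per_fold = 25))
  expect_identical(cv$fold_f1, cv2$fold_f1)
})

test_that("tidy and glance methods return the expected shapes", {
  X <- toy_matrix(50, list(A00s = 1:20, B00s = 10:30))
  Y <- toy_matrix(50, list(T00s = 1:25, T01s = 20:40))
  fit <- mnb_fit(X, Y, alpha = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_named(td, c("feature", "target", "estimate", "prior"))
  expect_equal(td$estimate[td$feature == "A00s" & td$target == "T00s"],
               unname(fit$C["A00s", "T00s"]))
  gl <- glance(fit)
  expect_equal(gl$n_features, 2)
  sc <- mnb_score(Y, Y)
  expect_equal(glance(sc)$total_f1, 1)
  expect_equal(nrow(tidy(sc)), 2)
})
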