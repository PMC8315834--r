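test_that("effect sizes reproduce printed two-group comparisons", {
  # diabetes prevalence, women, 45/684 vs 650/2052 -> 6.8 db
  expect_equal(round(effect_size(45 / 684, 650 / 2052), 1), 6.8)
  # hypertensive diseases, women, controls 1818/6840 vs 411/684 -> 3.5 db
  expect_equal(round(effect_size(1818 / 6840, 411 / 684), 1), 3.5)
  expect_equal(effect_size(0.2, 0.2), 0)
  # antisymmetry and scale invariance
  expect_equal(effect_size(0.1, 0.4), -effect_size(0.4, 0.1))
  expect_equal(effect_size(10, 40), effect_size(0.1, 0.4))
  expect_true(is.na(effect_size(0, 0.4)))
})

test_that("G statistic matches an entropy-based oracle and scales linearly", {
  g <- g_test(10, 90, 20, 80)
  # independent oracle: G = 2 N x mutual information from entropies
  O <- matrix(c(10, 90, 20, 80), 2, byrow = TRUE)
  N <- sum(O)
  H <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log(p)) }
  mi <- H(rowSums(O)) + H(colSums(O)) - H(as.vector(O))
  expect_equal(unname(g$statistic), 2 * N * mi, tolerance = 1e-10)
  expect_equal(g$p.value, stats::pchisq(2 * N * mi, 1, lower.tail = FALSE))
  # doubling all cells doubles G (likelihood-ratio scaling)
  g2 <- g_test(20, 180, 40, 160)
  expect_equal(unname(g2$statistic), 2 * unname(g$statistic),
               tolerance = 1e-10)
  # identical proportions -> G = 0, p = 1
  g0 <- g_test(10, 90, 30, 270)
  expect_equal(unname(g0$statistic), 0, tolerance = 1e-12)
  expect_equal(g0$p.value, 1)
  expect_error(g_test(0, 0, 5, 5), "margin")
})

test_that("cohort assignment uses the two largest index clusters exclusively", {
  net <- list(nodes = tibble::tibble(
    feature = c("E11s E66s", "E66s", "E66s M54s", "E66s M17s", "E11s"),
    cluster = c(1L, 1L, 2L, 2L, 3L),
    degree = 1L, in_giant = TRUE))
  class(net) <- "disease_network"
  X <- toy_matrix(8, list(`E11s E66s` = 1, `E66s` = 2, `E66s M54s` = c(3, 5),
                          `E66s M17s` = 4, `E11s` = c(6, 8)))
  X0 <- toy_matrix(8, list(E66s = 1:5, E11s = c(1, 6, 8), M54s = c(3, 5),
                           M17s = c(4, 7)))
  asn <- assign_cohorts(net, X, X0, "E66")
  lab <- as.character(asn$label)
  expect_equal(lab[1], "cohort_1")  # cluster-1 index feature
  expect_equal(lab[2], "cohort_1")
  expect_equal(lab[3], "cohort_2")
  expect_equal(lab[4], "cohort_2")
  expect_equal(lab[6], "control")   # no E66 anywhere in the feature period
  expect_equal(lab[7], "control")
  # patient 5: positive in features of... only cluster 2 -> cohort_2
  expect_equal(lab[5], "cohort_2")
  # a patient positive in both clusters' index features is excluded
  Xb <- toy_matrix(8, list(`E11s E66s` = c(1, 4), `E66s` = 2,
                           `E66s M54s` = c(3, 5), `E66s M17s` = 4,
                           `E11s` = c(6, 8)))
  asnb <- assign_cohorts(net, Xb, X0, "E66")
  expect_equal(as.character(asnb$label)[4], "excluded")
  expect_gte(attr(asnb, "n_excluded"), 1)
  # with the alternative rule the tie goes to the larger feature count
  asnc <- assign_cohorts(net, Xb, X0, "E66",
                         both_rule = "larger_feature_count")
  expect_equal(as.character(asnc$label)[4], "excluded")  # 1 vs 1 tie stays out
  expect_error(assign_cohorts(
    structure(list(nodes = tibble::tibble(feature = "E66s", cluster = 1L,
                                          degree = 1L, in_giant = TRUE)),
              class = "disease_network"), X, X0, "E66"),
    "fewer than two")
})

test_that("matched blocks respect sex, region and the age window exactly", {
  set.seed(30)
  n <- 900
  demo <- tibble::tibble(
    patient_id = sprintf("P%04d", 1:n),
    sex = sample(c("f", "m"), n, replace = TRUE),
    region = sample(c("R1", "R2"), n, replace = TRUE),
    birth_year = sample(1940:1960, n, replace = TRUE)
  )
  label <- rep("control", n)
  label[1:60] <- "cohort_2"           # anchors (smaller)
  label[61:360] <- "cohort_1"
  asn <- tibble::tibble(patient_id = demo$patient_id,
                        label = factor(label, levels = c("control", "cohort_1",
                                                         "cohort_2",
                                                         "excluded")))
  ms <- match_cohorts(asn, demo, k_large = 2, k_control = 4,
                      max_age_diff = 2, seed = 9)
  expect_equal(ms$anchor_cohort, "cohort_2")
  blocks <- dplyr::left_join(ms$blocks, demo, by = "patient_id")
  for (b in unique(blocks$block)) {
    bl <- blocks[blocks$block == b, ]
    anchor <- bl[bl$group == "cohort_2", ]
    expect_equal(nrow(anchor), 1)
    expect_equal(sum(bl$group == "cohort_1"), 2)
    expect_equal(sum(bl$group == "control"), 4)
    expect_true(all(bl$sex == anchor$sex))
    expect_true(all(bl$region == anchor$region))
    expect_true(all(abs(bl$birth_year - anchor$birth_year) <= 2))
  }
  # no patient reused across blocks; group sizes follow the k pattern
  expect_equal(anyDuplicated(ms$blocks$patient_id), 0)
  expect_equal(sum(ms$blocks$group == "cohort_1"), 2 * ms$n_anchors)
  expect_equal(sum(ms$blocks$group == "control"), 4 * ms$n_anchors)
  expect_equal(ms$n_anchors + ms$excluded_anchors, 60)
})

test_that("anchors without a full matching pool are excluded", {
  demo <- tibble::tibble(
    patient_id = c("A1", "L1", "L2", "C1", "C2", "C3"),
    sex = c("f", "f", "m", "f", "f", "f"),
    region = "R1",
    birth_year = c(1950, 1951, 1950, 1949, 1952, 1956)  # C3: diff 6
  )
  asn <- tibble::tibble(
    patient_id = demo$patient_id,
    label = factor(c("cohort_2", "cohort_1", "cohort_1", "control", "control",
                     "control"),
                   levels = c("control", "cohort_1", "cohort_2", "excluded")))
  # needs 1 large + 3 controls; only L1 matches sex, and only 2 controls
  # are inside the age window -> anchor excluded
  ms <- match_cohorts(asn, demo, k_large = 1, k_control = 3, seed = 1)
  expect_equal(ms$n_anchors, 0)
  expect_equal(ms$excluded_anchors, 1)
  # with a tolerant window the same anchor matches
  ms2 <- match_cohorts(asn, demo, k_large = 1, k_control = 3,
                       max_age_diff = 10, seed = 1)
  expect_equal(ms2$n_anchors, 1)
})

test_that("prevalence, incidence and mortality are computed per block and group", {
  per <- default_study_periods()
  mk_stay <- function(id, date, primary, sec = character(0), death = FALSE,
                      sex = "f") {
    tibble::tibble(patient_id = id, entry_date = as.Date(date),
                   exit_date = as.Date(date) + 1, primary_dx = primary,
                   secondary_dx = list(sec), region = "R1", sex = sex,
                   birth_year = 1950, death = death)
  }
  stays <- dplyr::bind_rows(
    mk_stay("A1", "2004-01-01", "E66", "E11"),   # anchor: prevalent diabetes
    mk_stay("A1", "2007-01-01", "Z03"),
    mk_stay("L1", "2004-01-01", "E66"),
    mk_stay("L1", "2007-01-01", "E14"),          # larger: incident diabetes
    mk_stay("L1", "2010-01-01", "Z03", death = TRUE),
    mk_stay("C1", "2004-01-01", "J06"),
    mk_stay("C1", "2007-01-01", "K29")
  )
  matched <- structure(list(
    blocks = tibble::tibble(block = 1,
                            patient_id = c("A1", "L1", "C1"),
                            group = c("cohort_2", "cohort_1", "control")),
    anchor_cohort = "cohort_2", larger_cohort = "cohort_1",
    n_anchors = 1, excluded_anchors = 0, k_large = 1, k_control = 1,
    max_age_diff = 2), class = "matched_set")
  cmp <- compare_cohorts(matched, stays, per,
                         blocks = list("diabetes (E10-E14)" = c("E10", "E14")))
  r <- cmp$rates
  prev <- r[r$measure == "prevalence", ]
  expect_equal(prev$rate_anchor, 1)    # E11 secondary in the feature period
  expect_equal(prev$rate_larger, 0)
  expect_equal(prev$rate_control, 0)
  inc <- r[r$measure == "incidence", ]
  expect_equal(inc$rate_anchor, 0)     # prevalent cases are not incident
  expect_equal(inc$rate_larger, 1)     # first E14 in the target period
  expect_equal(inc$rate_control, 0)
  s <- cmp$summary
  expect_equal(s$mortality[s$group == "cohort_1"], 1)  # death in follow-up
  expect_equal(s$mortality[s$group == "control"], 0)
  # feature+target hospital days: two 2-day stays
  expect_equal(s$hospital_days_per_patient[s$group == "cohort_2"], 4)
})

test_that("significance stars and evidence bands follow the caption scheme", {
  expect_equal(phenonet:::p_stars(c(0.5, 9e-3, 9e-5, 9e-7, NA)),
               c("", "*", "**", "***", ""))
  expect_equal(phenonet:::evidence_band(c(3, 6, 11, 16, 21)),
               c("", "substantial", "strong", "very strong", "decisive"))
})
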