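#' Assign patients to index-disease phenotype cohorts
#'
#' Takes the two clusters of the disease network containing the most
#' index-code features. A patient joins a cluster's cohort iff they are
#' positive in at least one of that cluster's index-code-containing
#' features; `cohort_1` is the cluster with more such features. Controls
#' are the patients with no index-code diagnosis (either role) in the
#' feature period. Patients positive in index features of *both* clusters
#' — or carrying the index code without being positive in either cluster's
#' index features — are excluded (and counted), keeping the labels
#' mutually exclusive.
#'
#' @param network A `disease_network` ([cluster_network()]).
#' @param X Patients x features matrix ([assign_features()]) whose columns
#'   are the network's feature keys.
#' @param X0 Patients x codes feature-period matrix (for the control
#'   definition).
#' @param icd3 Bare 3-character index code.
#' @param both_rule `"exclude"` (default) drops patients qualifying for
#'   both cohorts; `"larger_feature_count"` assigns them to the cohort
#'   whose index features they carry more of (ties excluded).
#' @return A tibble `patient_id`, `label` (factor: control, cohort_1,
#'   cohort_2, excluded), with the chosen clusters and exclusion count in
#'   attributes `clusters` and `n_excluded`.
#' @export
assign_cohorts <- function(network, X, X0, icd3,
                           both_rule = c("exclude", "larger_feature_count")) {
  both_rule <- match.arg(both_rule)
  view <- index_disease_view(network, icd3)
  if (nrow(view) < 2)
    stop("fewer than two network clusters contain features of ", icd3)
  cl1 <- view$cluster[1]
  cl2 <- view$cluster[2]
  keys_in <- function(cl) {
    keys <- network$nodes$feature[network$nodes$cluster == cl]
    keys[feature_contains_code(keys, icd3)]
  }
  k1 <- intersect(keys_in(cl1), colnames(X))
  k2 <- intersect(keys_in(cl2), colnames(X))
  n1 <- Matrix::rowSums(X[, k1, drop = FALSE] != 0)
  n2 <- Matrix::rowSums(X[, k2, drop = FALSE] != 0)
  icd_cols <- intersect(paste0(icd3, c("p", "s")), colnames(X0))
  has_index <- Matrix::rowSums(X0[, icd_cols, drop = FALSE] != 0) > 0
  label <- rep("excluded", nrow(X))
  label[n1 > 0 & n2 == 0] <- "cohort_1"
  label[n2 > 0 & n1 == 0] <- "cohort_2"
  if (both_rule == "larger_feature_count") {
    label[n1 > 0 & n2 > 0 & n1 > n2] <- "cohort_1"
    label[n1 > 0 & n2 > 0 & n2 > n1] <- "cohort_2"
  }
  label[!has_index] <- "control"
  out <- tibble::tibble(
    patient_id = rownames(X),
    label = factor(label, levels = c("control", "cohort_1", "cohort_2",
                                     "excluded"))
  )
  attr(out, "clusters") <- c(cohort_1 = cl1, cohort_2 = cl2)
  attr(out, "n_excluded") <- sum(label == "excluded")
  out
}

#' Match phenotype cohorts to the larger cohort and to controls
#'
#' Takes the smaller of the two cohorts as anchors. In seeded random
#' order, each anchor is matched without replacement to `k_large` patients
#' from the larger cohort and `k_control` controls with identical sex and
#' region and a birth-year difference of at most `max_age_diff` years.
#' Anchors whose remaining pools are too small are excluded (and counted);
#' every patient is used at most once. With `A` matched anchors the group
#' sizes are `A`, `3 A` and `10 A` under the defaults.
#'
#' @param assignment Cohort assignment tibble ([assign_cohorts()]).
#' @param demographics Tibble `patient_id`, `sex`, `region`, `birth_year`
#'   ([patient_demographics()]).
#' @param k_large Matches drawn from the larger cohort per anchor.
#' @param k_control Matches drawn from the controls per anchor.
#' @param max_age_diff Maximum absolute birth-year difference.
#' @param seed Seed for the anchor order and the sampling.
#' @return An object of class `matched_set`: `blocks` (tibble: block,
#'   patient_id, group with levels control / anchor cohort / larger
#'   cohort), `anchor_cohort`, `larger_cohort`, `n_anchors`,
#'   `excluded_anchors`.
#' @export
match_cohorts <- function(assignment, demographics, k_large = 3,
                          k_control = 10, max_age_diff = 2, seed = 1L) {
  df <- dplyr::inner_join(assignment, demographics, by = "patient_id")
  sizes <- table(df$label)
  anchor_cohort <- if (sizes[["cohort_1"]] <= sizes[["cohort_2"]])
    "cohort_1" else "cohort_2"
  larger_cohort <- setdiff(c("cohort_1", "cohort_2"), anchor_cohort)
  df$stratum <- paste(df$sex, df$region, sep = "|")
  pool_of <- function(lab) {
    p <- df[df$label == lab, c("patient_id", "stratum", "birth_year")]
    split(p[c("patient_id", "birth_year")], p$stratum)
  }
  pool_l <- pool_of(larger_cohort)
  pool_c <- pool_of("control")
  avail_l <- lapply(pool_l, function(p) rep(TRUE, nrow(p)))
  avail_c <- lapply(pool_c, function(p) rep(TRUE, nrow(p)))
  anchors <- df[df$label == anchor_cohort, ]
  set.seed(seed)
  anchors <- anchors[sample.int(nrow(anchors)), ]
  blocks <- vector("list", nrow(anchors))
  excluded <- 0L
  bno <- 0L
  for (i in seq_len(nrow(anchors))) {
    st <- anchors$stratum[i]
    by <- anchors$birth_year[i]
    pl <- pool_l[[st]]
    pc <- pool_c[[st]]
    cand_l <- if (is.null(pl)) integer(0) else
      which(avail_l[[st]] & abs(pl$birth_year - by) <= max_age_diff)
    cand_c <- if (is.null(pc)) integer(0) else
      which(avail_c[[st]] & abs(pc$birth_year - by) <= max_age_diff)
    if (length(cand_l) < k_large || length(cand_c) < k_control) {
      excluded <- excluded + 1L
      next
    }
    take_l <- cand_l[sample.int(length(cand_l), k_large)]
    take_c <- cand_c[sample.int(length(cand_c), k_control)]
    avail_l[[st]][take_l] <- FALSE
    avail_c[[st]][take_c] <- FALSE
    bno <- bno + 1L
    blocks[[i]] <- tibble::tibble(
      block = bno,
      patient_id = c(anchors$patient_id[i], pl$patient_id[take_l],
                     pc$patient_id[take_c]),
      group = c(anchor_cohort, rep(larger_cohort, k_large),
                rep("control", k_control))
    )
  }
  blocks <- dplyr::bind_rows(blocks)
  structure(list(blocks = blocks, anchor_cohort = anchor_cohort,
                 larger_cohort = larger_cohort, n_anchors = bno,
                 excluded_anchors = excluded,
                 k_large = k_large, k_control = k_control,
                 max_age_diff = max_age_diff),
            class = "matched_set")
}

#' @export
print.matched_set <- function(x, ...) {
  cat("Matched set:", x$n_anchors, "anchors (", x$anchor_cohort, ") x (1 +",
      x$k_large, "from", x$larger_cohort, "+", x$k_control, "controls );",
      x$excluded_anchors, "anchors excluded\n")
  invisible(x)
}

#' Effect size in decibans between two relative frequencies
#'
#' `ES_{i,j} = 10 * (log10(n_j) - log10(n_i))` db, where `n_i`, `n_j` are
#' the relative frequencies in groups `i` and `j`. The measure is
#' antisymmetric and scale-invariant (percentages and proportions give the
#' same value). Above 5 db the difference can be considered substantial
#' evidence, above 10 strong, above 15 very strong and above 20 decisive.
#' Zero frequencies make the effect size undefined (`NA`).
#'
#' @param n_i,n_j Relative frequencies (or counts on the same scale).
#' @return Effect size(s) in decibans.
#' @examples
#' effect_size(45 / 684, 650 / 2052)  # ~6.8 db
#' @export
effect_size <- function(n_i, n_j) {
  ifelse(n_i > 0 & n_j > 0, 10 * (log10(n_j) - log10(n_i)), NA_real_)
}

#' G-test of independence for a 2x2 table
#'
#' Likelihood-ratio test: `G = 2 * sum O * ln(O / E)` over the four cells,
#' with expected counts from the independence model; cells with `O = 0`
#' contribute 0. `G` is asymptotically chi-square with one degree of
#' freedom; no continuity correction is applied.
#'
#' @param a,b First row of the table (e.g. events / non-events in group 1).
#' @param c,d Second row (group 2).
#' @return An `htest`-style list with `statistic` (G), `parameter` (df)
#'   and `p.value`.
#' @export
g_test <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(O < 0)) stop("counts must be non-negative")
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("G-test undefined: a table margin is zero")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  terms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms)
  structure(list(statistic = c(G = G), parameter = c(df = 1),
                 p.value = stats::pchisq(G, df = 1, lower.tail = FALSE),
                 method = "G-test of independence (2x2)",
                 data.name = "2x2 contingency table"),
            class = "htest")
}

p_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 1e-6 ~ "***", p < 1e-4 ~ "**",
                   p < 1e-2 ~ "*", TRUE ~ "")
}

evidence_band <- function(es) {
  a <- abs(es)
  dplyr::case_when(is.na(a) ~ "", a > 20 ~ "decisive", a > 15 ~ "very strong",
                   a > 10 ~ "strong", a > 5 ~ "substantial", TRUE ~ "")
}

# bare 3-character codes per patient and period from stays
patient_period_codes <- function(stays, periods, attribute = "exit") {
  long <- stay_codes_long(stays, periods, attribute)
  long$icd3 <- substr(long$code, 1, 3)
  dplyr::distinct(long, .data$patient_id, .data$icd3, .data$period)
}

#' Compare matched cohorts on diagnosis blocks
#'
#' For every diagnosis block (an inclusive range of bare 3-character
#' codes, both roles) and sex, computes per matched group the prevalence
#' (at least one block diagnosis in the feature period) and the incidence
#' (first-ever block diagnosis in the target period, i.e. none in the
#' feature period), with pairwise deciban effect sizes ([effect_size()])
#' control -> anchor cohort and anchor -> larger cohort, [g_test()]
#' p-values, significance stars (`*` p < 1e-2, `**` p < 1e-4, `***`
#' p < 1e-6) and Jeffreys evidence bands. A per-group summary reports
#' hospitalization days (feature + target periods), primary/secondary
#' diagnoses per patient (feature period) and in-hospital mortality over
#' the follow-up period.
#'
#' @param matched A `matched_set` ([match_cohorts()]).
#' @param stays Stay tibble covering the matched patients.
#' @param periods A [study_periods()].
#' @param blocks Named list of inclusive code ranges,
#'   e.g. `list("diabetes mellitus (E10-E14)" = c("E10", "E14"))`.
#' @param attribute Stay-to-period attribution rule.
#' @return An object of class `cohort_comparison`: `rates` (tibble: block,
#'   sex, measure, per-group n / count / rate, effect sizes, p-values,
#'   stars, evidence) and `summary` (per-group utilisation and mortality).
#' @export
compare_cohorts <- function(matched, stays, periods, blocks,
                            attribute = c("exit", "entry")) {
  attribute <- match.arg(attribute)
  members <- matched$blocks[, c("patient_id", "group")]
  groups <- c("control", matched$anchor_cohort, matched$larger_cohort)
  demo <- patient_demographics(stays)
  members <- dplyr::left_join(members, demo, by = "patient_id")
  stays_m <- stays[stays$patient_id %in% members$patient_id, , drop = FALSE]
  codes <- patient_period_codes(stays_m, periods, attribute)

  rate_rows <- list()
  for (bn in names(blocks)) {
    rng <- blocks[[bn]]
    in_block <- codes$icd3 >= rng[1] & codes$icd3 <= rng[2]
    prev_ids <- unique(codes$patient_id[in_block & codes$period == 2L])
    targ_ids <- unique(codes$patient_id[in_block & codes$period == 3L])
    inc_ids <- setdiff(targ_ids, prev_ids)
    for (sx in sort(unique(members$sex))) {
      msex <- members[members$sex == sx, ]
      for (measure in c("prevalence", "incidence")) {
        ids <- if (measure == "prevalence") prev_ids else inc_ids
        stat <- lapply(groups, function(g) {
          gm <- msex$patient_id[msex$group == g]
          n <- length(gm)
          cnt <- sum(gm %in% ids)
          list(n = n, count = cnt, rate = if (n > 0) cnt / n else NA_real_)
        })
        names(stat) <- c("g0", "g1", "g2")
        es01 <- effect_size(stat$g0$rate, stat$g1$rate)
        es12 <- effect_size(stat$g1$rate, stat$g2$rate)
        p01 <- tryCatch(g_test(stat$g0$count, stat$g0$n - stat$g0$count,
                               stat$g1$count, stat$g1$n - stat$g1$count)$p.value,
                        error = function(e) NA_real_)
        p12 <- tryCatch(g_test(stat$g1$count, stat$g1$n - stat$g1$count,
                               stat$g2$count, stat$g2$n - stat$g2$count)$p.value,
                        error = function(e) NA_real_)
        rate_rows[[length(rate_rows) + 1L]] <- tibble::tibble(
          block = bn, sex = sx, measure = measure,
          n_control = stat$g0$n, count_control = stat$g0$count,
          rate_control = stat$g0$rate,
          n_anchor = stat$g1$n, count_anchor = stat$g1$count,
          rate_anchor = stat$g1$rate,
          n_larger = stat$g2$n, count_larger = stat$g2$count,
          rate_larger = stat$g2$rate,
          es_control_anchor = es01, p_control_anchor = p01,
          stars_control_anchor = p_stars(p01),
          evidence_control_anchor = evidence_band(es01),
          es_anchor_larger = es12, p_anchor_larger = p12,
          stars_anchor_larger = p_stars(p12),
          evidence_anchor_larger = evidence_band(es12)
        )
      }
    }
  }
  rates <- dplyr::bind_rows(rate_rows)

  per <- stay_period(stays_m, periods, attribute)
  days <- as.numeric(stays_m$exit_date - stays_m$entry_date) + 1
  in_ft <- per %in% c(2L, 3L)
  util <- tibble::tibble(patient_id = stays_m$patient_id,
                         days = ifelse(in_ft, days, 0),
                         primary_ft = as.integer(per == 2L),
                         secondary_ft = ifelse(per == 2L,
                                               lengths(stays_m$secondary_dx), 0L),
                         death_fu = stays_m$death & per == 4L) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(days = sum(.data$days),
                     primary_ft = sum(.data$primary_ft),
                     secondary_ft = sum(.data$secondary_ft),
                     died = any(.data$death_fu), .groups = "drop")
  summary <- dplyr::left_join(members, util, by = "patient_id") |>
    dplyr::mutate(days = dplyr::coalesce(.data$days, 0),
                  primary_ft = dplyr::coalesce(.data$primary_ft, 0L),
                  secondary_ft = dplyr::coalesce(.data$secondary_ft, 0),
                  died = dplyr::coalesce(.data$died, FALSE)) |>
    dplyr::group_by(group = factor(.data$group, levels = groups)) |>
    dplyr::summarise(n = dplyr::n(),
                     hospital_days_per_patient = mean(.data$days),
                     primary_dx_per_patient = mean(.data$primary_ft),
                     secondary_dx_per_patient = mean(.data$secondary_ft),
                     mortality = mean(.data$died),
                     deaths = sum(.data$died), .groups = "drop")
  structure(list(rates = rates, summary = summary, groups = groups),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("Cohort comparison — groups:", paste(x$groups, collapse = ", "), "\n\n")
  print(x$summary)
  cat("\n")
  print(dplyr::select(x$rates, "block", "sex", "measure",
                      dplyr::starts_with("rate"),
                      dplyr::starts_with("es_"),
                      dplyr::starts_with("stars")), n = 50)
  invisible(x)
}

#' Write a cohort comparison as TSV
#'
#' @param comparison A `cohort_comparison`.
#' @param rates_path,summary_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_comparison <- function(comparison, rates_path = NULL, summary_path = NULL) {
  if (!is.null(rates_path))
    readr::write_tsv(comparison$rates, rates_path, progress = FALSE)
  if (!is.null(summary_path))
    readr::write_tsv(comparison$summary, summary_path, progress = FALSE)
  invisible(c(rates_path, summary_path))
}
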