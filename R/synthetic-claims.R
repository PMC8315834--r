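#' Phenotype specification for the synthetic-claims generator
#'
#' A latent phenotype is a patient subgroup with elevated probabilities for
#' a set of feature-period *core* diagnoses and for a set of target-period
#' diagnoses. Phenotypes sharing an *index code* (e.g. `"E66"`) but with
#' disjoint comorbidity sets are the ground truth against which phenotype
#' recovery is judged.
#'
#' @param label Phenotype name.
#' @param weight Mixing weight (probability that a patient belongs to this
#'   phenotype); weights over all phenotypes must sum to at most 1.
#' @param core_codes Named numeric vector: feature-period occurrence
#'   probability per 3-character code.
#' @param target_codes Named numeric vector: target-period occurrence
#'   probability per code.
#' @param index_code Optional shared index code; must be among `core_codes`.
#' @param sex_weights,region_weights Optional named sampling weights.
#' @param birth_year_range Optional integer range `c(lo, hi)`.
#' @param death_rate Probability of an in-hospital death during follow-up.
#' @return A `phenotype_spec` list.
#' @export
phenotype_spec <- function(label, weight, core_codes, target_codes = numeric(0),
                           index_code = NULL, sex_weights = NULL,
                           region_weights = NULL, birth_year_range = NULL,
                           death_rate = NULL) {
  stopifnot(is.numeric(weight), weight >= 0, weight <= 1)
  check_probs <- function(p, what) {
    if (length(p) && (is.null(names(p)) || any(!nzchar(names(p)))))
      stop(what, " must be a named numeric vector")
    if (any(p < 0 | p > 1)) stop(what, " probabilities must be in [0, 1]")
  }
  check_probs(core_codes, "core_codes")
  check_probs(target_codes, "target_codes")
  if (!is.null(index_code) && !index_code %in% names(core_codes))
    stop("index_code must be one of the core_codes")
  structure(list(label = label, weight = weight, core_codes = core_codes,
                 target_codes = target_codes, index_code = index_code,
                 sex_weights = sex_weights, region_weights = region_weights,
                 birth_year_range = birth_year_range, death_rate = death_rate),
            class = "phenotype_spec")
}

#' Beyond-pairwise synergy specification
#'
#' Plants a dependency of a target-period diagnosis on the *joint* presence
#' of a set of feature-period diagnoses: the odds of `target_code` in the
#' target period are multiplied by `boost` only for patients carrying *all*
#' of `feature_codes` during the feature period. With three or more feature
#' codes this is a strictly beyond-pairwise dependency. `boost > 1` plants
#' synergy, `boost < 1` redundancy, `boost = 1` the null.
#'
#' @param feature_codes Character vector of 2-3 bare 3-character codes.
#' @param target_code Single bare 3-character code.
#' @param boost Positive multiplicative odds boost.
#' @return A `synergy_spec` list.
#' @export
synergy_spec <- function(feature_codes, target_code, boost) {
  stopifnot(length(feature_codes) >= 2, length(target_code) == 1,
            is.numeric(boost), boost > 0)
  structure(list(feature_codes = sort(feature_codes), target_code = target_code,
                 boost = boost),
            class = "synergy_spec")
}

#' Synthetic-claims configuration
#'
#' Bundles everything [simulate_claims()] needs: the patient count, the
#' diagnosis code universe, latent phenotypes, per-code background rates,
#' planted synergies, the study timeline and the seed. The generator model
#' is independent Bernoulli per code given phenotype membership, with
#' multiplicative odds boosts on targets for planted synergies — simple
#' enough that pairwise and triple-wise structure is analytically
#' controllable.
#'
#' @param n_patients Number of patients.
#' @param code_universe Character vector of bare 3-character codes.
#' @param phenotypes List of [phenotype_spec()] objects.
#' @param background_rate Scalar or named numeric vector of per-code
#'   occurrence probabilities per period (unnamed scalar applies to every
#'   code).
#' @param synergy List of [synergy_spec()] objects.
#' @param periods A [study_periods()] object.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param regions,sexes Category labels for the demographic fields.
#' @param birth_year_range Integer range for birth years.
#' @param death_rate Baseline probability of in-hospital death during
#'   follow-up for patients outside any phenotype.
#' @param filler_code Administrative code used as the primary diagnosis of
#'   a stay when a patient drew no diagnosis for that period (every stay
#'   record carries exactly one primary diagnosis).
#' @param role_rule How drawn codes are mapped to diagnostic roles on a
#'   stay: `"first_primary"` promotes the first drawn code to the primary
#'   diagnosis (the rest become secondary), mimicking the admission-reason
#'   convention of real claims; `"all_secondary"` records every drawn code
#'   as secondary with the filler code as primary, so each planted
#'   comorbidity maps to exactly one role-suffixed code.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_patients, code_universe, phenotypes = list(),
                       background_rate = 0.02, synergy = list(),
                       periods = default_study_periods(), seed = 1L,
                       regions = c("R1", "R2"), sexes = c("f", "m"),
                       birth_year_range = c(1930L, 1979L), death_rate = 0.02,
                       filler_code = "Z00",
                       role_rule = c("first_primary", "all_secondary")) {
  role_rule <- match.arg(role_rule)
  if (length(code_universe) == 0) stop("code_universe must not be empty")
  if (!all(grepl(ICD3_PATTERN, code_universe)))
    stop("code_universe entries must match letter + two digits")
  code_universe <- sort(unique(code_universe))
  if (is.null(names(background_rate))) {
    stopifnot(length(background_rate) == 1)
    background_rate <- stats::setNames(rep(background_rate, length(code_universe)),
                                       code_universe)
  } else {
    base <- stats::setNames(rep(0, length(code_universe)), code_universe)
    base[names(background_rate)] <- background_rate
    background_rate <- base
  }
  if (any(background_rate < 0 | background_rate > 1))
    stop("background rates must be probabilities")
  w <- vapply(phenotypes, function(p) p$weight, numeric(1))
  if (sum(w) > 1 + 1e-12) stop("phenotype mixing weights must sum to at most 1")
  for (p in phenotypes) {
    miss <- setdiff(c(names(p$core_codes), names(p$target_codes)), code_universe)
    if (length(miss)) stop("phenotype ", p$label, " uses codes outside the universe: ",
                           paste(miss, collapse = ", "))
    low <- p$core_codes <= background_rate[names(p$core_codes)]
    if (any(low)) stop("phenotype ", p$label,
                       " core probabilities must exceed the background rate")
  }
  for (s in synergy) {
    miss <- setdiff(c(s$feature_codes, s$target_code), code_universe)
    if (length(miss)) stop("synergy uses codes outside the universe: ",
                           paste(miss, collapse = ", "))
  }
  structure(list(n_patients = as.integer(n_patients),
                 code_universe = code_universe, phenotypes = phenotypes,
                 background_rate = background_rate, synergy = synergy,
                 periods = periods, seed = as.integer(seed), regions = regions,
                 sexes = sexes, birth_year_range = as.integer(birth_year_range),
                 death_rate = death_rate, filler_code = filler_code,
                 role_rule = role_rule),
            class = "sim_config")
}

# uniform stay dates within [from, to): entry + short length of stay
draw_stay_dates <- function(n, from, to, max_los = 7L) {
  span <- as.integer(to - from) - 1L
  los <- sample.int(max_los + 1L, n, replace = TRUE) - 1L
  entry <- from + floor(stats::runif(n) * pmax(span - los, 1L))
  list(entry = entry, exit = entry + los)
}

# one stay per patient for a period: under "first_primary" the first drawn
# code becomes the primary diagnosis and the rest secondary; under
# "all_secondary" every drawn code is secondary and the filler is primary
compose_stays <- function(patient_id, code_mat, dates, demo, filler_code,
                          role_rule = "first_primary",
                          death = rep(FALSE, length(patient_id))) {
  codes_per_patient <- apply(code_mat, 1L, function(z) colnames(code_mat)[z],
                             simplify = FALSE)
  shuffled <- lapply(codes_per_patient, function(cs) {
    if (length(cs) > 1) sample(cs) else cs
  })
  if (role_rule == "all_secondary") {
    primary <- rep(filler_code, length(patient_id))
    secondary <- shuffled
  } else {
    primary <- vapply(shuffled, function(cs) if (length(cs)) cs[1] else filler_code,
                      character(1))
    secondary <- lapply(shuffled, function(cs) if (length(cs) > 1) cs[-1] else character(0))
  }
  tibble::tibble(
    patient_id = patient_id,
    entry_date = dates$entry,
    exit_date = dates$exit,
    primary_dx = primary,
    secondary_dx = secondary,
    region = demo$region,
    sex = demo$sex,
    birth_year = demo$birth_year,
    death = death
  )
}

#' Simulate hospital-stay records with planted structure
#'
#' Generates one feature-period and one target-period stay per patient (no
#' stays in the no-admission period, so by construction every simulated
#' patient passes [select_study_population()]), plus a terminal follow-up
#' stay for patients who die in hospital. Feature-period diagnoses are
#' drawn independently per code from the background rates, overridden by
#' the phenotype core probabilities for phenotype members; target-period
#' diagnoses likewise from background/phenotype target probabilities, with
#' planted [synergy_spec()] odds boosts applied only to patients carrying
#' the full feature-code set. Within a stay the first drawn code becomes
#' the primary diagnosis and the rest secondary.
#'
#' @param config A [sim_config()].
#' @return A list with `stays` (tibble in the [read_stays()] layout) and
#'   `truth` (ground truth: per-patient phenotype assignment, the planted
#'   synergies and the config).
#' @examples
#' cfg <- sim_config(50, c("E66", "E11", "I10"), seed = 7)
#' sim <- simulate_claims(cfg)
#' nrow(sim$stays)
#' @export
simulate_claims <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  codes <- config$code_universe
  D <- length(codes)
  ph <- config$phenotypes
  labels <- vapply(ph, function(p) p$label, character(1))
  w <- vapply(ph, function(p) p$weight, numeric(1))
  assign_idx <- sample.int(length(ph) + 1L, n, replace = TRUE,
                           prob = c(w, max(0, 1 - sum(w))))
  phenotype <- c(labels, NA_character_)[assign_idx]

  # demographics
  pick <- function(weights_field, default_values) {
    out <- character(n)
    for (k in seq_len(length(ph) + 1L)) {
      idx <- which(assign_idx == k)
      if (!length(idx)) next
      wts <- if (k <= length(ph)) ph[[k]][[weights_field]] else NULL
      if (is.null(wts)) {
        out[idx] <- sample(default_values, length(idx), replace = TRUE)
      } else {
        out[idx] <- sample(names(wts), length(idx), replace = TRUE, prob = wts)
      }
    }
    out
  }
  sex <- pick("sex_weights", config$sexes)
  region <- pick("region_weights", config$regions)
  birth_year <- integer(n)
  for (k in seq_len(length(ph) + 1L)) {
    idx <- which(assign_idx == k)
    if (!length(idx)) next
    rng <- if (k <= length(ph) && !is.null(ph[[k]]$birth_year_range))
      ph[[k]]$birth_year_range else config$birth_year_range
    birth_year[idx] <- sample(seq(rng[1], rng[2]), length(idx), replace = TRUE)
  }
  demo <- tibble::tibble(patient_id = sprintf("P%06d", seq_len(n)),
                         sex = sex, region = region, birth_year = birth_year)

  # per-patient x code probability matrices (feature and target period)
  p_feat <- matrix(config$background_rate, n, D, byrow = TRUE,
                   dimnames = list(NULL, codes))
  p_targ <- p_feat
  for (k in seq_along(ph)) {
    idx <- which(assign_idx == k)
    if (!length(idx)) next
    cc <- ph[[k]]$core_codes
    if (length(cc)) p_feat[idx, names(cc)] <-
      matrix(pmax(cc, config$background_rate[names(cc)]), length(idx),
             length(cc), byrow = TRUE)
    tc <- ph[[k]]$target_codes
    if (length(tc)) p_targ[idx, names(tc)] <-
      matrix(pmax(tc, config$background_rate[names(tc)]), length(idx),
             length(tc), byrow = TRUE)
  }
  feat <- matrix(stats::runif(n * D), n, D) < p_feat
  colnames(feat) <- codes

  # synergy boosts act on the odds of the target code, only for patients
  # carrying the complete feature-code set in the feature period
  for (s in config$synergy) {
    carrier <- rowSums(feat[, s$feature_codes, drop = FALSE]) == length(s$feature_codes)
    if (any(carrier)) {
      p0 <- p_targ[carrier, s$target_code]
      odds <- p0 / (1 - p0) * s$boost
      p_targ[carrier, s$target_code] <- odds / (1 + odds)
    }
  }
  targ <- matrix(stats::runif(n * D), n, D) < p_targ
  colnames(targ) <- codes

  per <- config$periods
  stays_feat <- compose_stays(demo$patient_id, feat,
                              draw_stay_dates(n, per$t1, per$t2),
                              demo, config$filler_code, config$role_rule)
  stays_targ <- compose_stays(demo$patient_id, targ,
                              draw_stay_dates(n, per$t2, per$t3),
                              demo, config$filler_code, config$role_rule)

  dr <- rep(config$death_rate, n)
  for (k in seq_along(ph)) {
    if (!is.null(ph[[k]]$death_rate)) dr[assign_idx == k] <- ph[[k]]$death_rate
  }
  dies <- stats::runif(n) < dr
  stays_fu <- NULL
  if (any(dies)) {
    idx <- which(dies)
    dates <- draw_stay_dates(length(idx), per$t3, per$t4)
    stays_fu <- tibble::tibble(
      patient_id = demo$patient_id[idx],
      entry_date = dates$entry,
      exit_date = dates$exit,
      primary_dx = config$filler_code,
      secondary_dx = rep(list(character(0)), length(idx)),
      region = demo$region[idx],
      sex = demo$sex[idx],
      birth_year = demo$birth_year[idx],
      death = TRUE
    )
  }
  stays <- dplyr::bind_rows(stays_feat, stays_targ, stays_fu) |>
    dplyr::arrange(.data$patient_id, .data$entry_date)

  truth <- list(
    assignments = tibble::tibble(patient_id = demo$patient_id,
                                 phenotype = phenotype),
    synergy = purrr::map_dfr(config$synergy, function(s) tibble::tibble(
      feature_codes = paste(s$feature_codes, collapse = " "),
      target_code = s$target_code, boost = s$boost)),
    config = config
  )
  list(stays = stays, truth = truth)
}

#' Write the generator ground truth as JSON
#'
#' @param truth The `truth` element returned by [simulate_claims()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(assignments = truth$assignments, synergy = truth$synergy),
    path, dataframe = "rows", na = "null", auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Canned two-phenotype fixture configuration
#'
#' Returns a [sim_config()] with two latent phenotypes sharing the index
#' code `"E66"` (overweight/obesity) but with disjoint core comorbidity
#' sets: a metabolic-like phenotype (core E11, E78, I10; elevated metabolic
#' and cardiovascular target-period incidence) and a musculoskeletal-like
#' phenotype (core M54, M17, M81; musculoskeletal targets, plus milder
#' cardiometabolic target rates — obesity raises cardiometabolic risk in
#' both phenotypes, which also ties the two feature groups together in the
#' coefficient-similarity network). The metabolic phenotype is six times
#' larger, so cohort matching can draw three same-stratum matches per
#' anchor from it, plus ten controls. Background codes at 3% provide
#' sparse noise; all diagnoses are coded as secondary so each planted
#' comorbidity maps to a single role-suffixed code.
#'
#' @param seed Integer seed stored in the config.
#' @param n_patients Number of patients (default 20000).
#' @return A `sim_config`.
#' @export
two_phenotype_fixture <- function(seed = 1L, n_patients = 20000L) {
  bg_codes <- c("J06", "K29", "R10", "Z03", "A09", "B34", "H10", "J18",
                "K52", "L30", "N39", "R07")
  metabolic <- phenotype_spec(
    label = "metabolic", weight = 0.30,
    core_codes = c(E66 = 0.85, E11 = 0.55, E78 = 0.35),
    target_codes = c(E14 = 0.35, I21 = 0.20, I25 = 0.30, E87 = 0.15),
    index_code = "E66", death_rate = 0.10
  )
  musculoskeletal <- phenotype_spec(
    label = "musculoskeletal", weight = 0.05,
    core_codes = c(E66 = 0.85, M54 = 0.55, M17 = 0.35),
    target_codes = c(M16 = 0.30, M48 = 0.25, S72 = 0.10,
                     E14 = 0.10, I21 = 0.08, I25 = 0.12),
    index_code = "E66", death_rate = 0.06
  )
  universe <- c("E66", "E11", "E78", "M54", "M17",
                "E14", "I21", "I25", "E87", "M16", "M48", "S72", bg_codes)
  sim_config(
    n_patients = n_patients, code_universe = universe,
    phenotypes = list(metabolic, musculoskeletal),
    background_rate = 0.03, seed = seed, death_rate = 0.03,
    role_rule = "all_secondary"
  )
}

#' Planted-triple synergy fixture configuration
#'
#' A designed benchmark for the interaction-lift estimator: `n_triples`
#' disjoint code triples `{Axx, Bxx, Cxx}`, each independently present at
#' rate `code_rate` in the feature period, and one target code `Txx` per
#' triple at background rate `target_rate` in the target period whose odds
#' are multiplied by `boost` exactly when the full triple is present.
#' Averaging the recovered lift over many planted triples controls the
#' sampling noise of the per-triple coefficient estimates; the rates were
#' chosen so that triple carriers are frequent enough to estimate a
#' coefficient (about `n * code_rate^3` carriers per triple) while the
#' marginal leakage of the conditional boost into the pairwise models stays
#' small (see the methods vignette).
#'
#' @param seed Integer seed.
#' @param boost Planted odds boost (1 = null).
#' @param n_triples Number of disjoint planted triples (max 100).
#' @param n_patients Number of patients.
#' @param code_rate Feature-code occurrence probability.
#' @param target_rate Target-code background occurrence probability.
#' @return A `sim_config` whose single bulk phenotype carries the feature
#'   and target rates; the synergies are in `$synergy`.
#' @export
synergy_fixture <- function(seed = 1L, boost = 2, n_triples = 60L,
                            n_patients = 20000L, code_rate = 0.12,
                            target_rate = 0.30) {
  stopifnot(n_triples >= 1, n_triples <= 100)
  k <- seq_len(n_triples) - 1L
  a <- sprintf("A%02d", k); b <- sprintf("B%02d", k); c3 <- sprintf("C%02d", k)
  tg <- sprintf("T%02d", k)
  core <- stats::setNames(rep(code_rate, 3L * n_triples), c(a, b, c3))
  targ <- stats::setNames(rep(target_rate, n_triples), tg)
  bulk <- phenotype_spec(label = "bulk", weight = 1, core_codes = core,
                         target_codes = targ)
  synergies <- purrr::pmap(list(a, b, c3, tg), function(x, y, z, t)
    synergy_spec(c(x, y, z), t, boost))
  sim_config(
    n_patients = n_patients, code_universe = c(a, b, c3, tg),
    phenotypes = list(bulk), background_rate = 0.005,
    synergy = synergies, seed = seed, role_rule = "all_secondary"
  )
}
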