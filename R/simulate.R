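# Cohort simulator for property-based testing.
#
# Emulates the screening setting: a high-risk HNSCC cohort with ~26 %
# distant-metastasis and ~11 % second-primary prevalence, pulmonary lesion
# sizes straddling the 5-mm PET detection limit (two-component lognormal
# mixture), size-dependent PET detection (near zero below the limit),
# CT detection of lung lesions only, rare CT false positives at
# supra-limit sizes, ordinal Likert emission per truth class, and an
# independent locoregional-control flag.  What it deliberately does not
# emulate: reader correlation between modalities, time-to-event structure,
# lesion multiplicity beyond a flag, or site-specific metastatic patterns.

#' Simulation parameters
#'
#' Defaults emulate the validation study's operating point: marginal CT and
#' PET sensitivity 0.50 each (CT detects only pulmonary lesions at rate
#' `ct_sensitivity_lung`; PET detection is zero below the 5-mm limit), CT
#' specificity 0.97, PET specificity 1.00, distant-metastasis prevalence
#' 0.26, second-primary prevalence 0.11, locoregional failure rate 5/47.
#'
#' @param n_patients cohort size.
#' @param dm_prevalence,spt_prevalence probabilities of a
#'   distant-metastasis / second-primary truth (independent draws).
#' @param extra_pulmonary_rate fraction of metastatic index lesions outside
#'   the chest CT field (visible to whole-body PET only).
#' @param size_mixture two-component lognormal mixture for pulmonary lesion
#'   diameters: `weight_sub5` is the mass truncated below 5 mm, the
#'   remainder truncated above; `meanlog`/`sdlog` per component.
#' @param ct_sensitivity_lung probability CT detects a pulmonary metastatic
#'   lesion (any size).
#' @param pet_sensitivity_by_size named vector `c(sub5 = , supra5 = )`:
#'   PET detection probability by size band; extra-pulmonary lesions use the
#'   `supra5` band.
#' @param ct_specificity,pet_specificity per-patient probability of a
#'   negative call in truth-negative patients.
#' @param likert_emission list of two probability vectors over scores 0--5,
#'   `detected` (truth-positive, detected lesions) and `false_positive`.
#' @param locoregional_failure_rate probability of losing locoregional
#'   control (independent of everything else).
#' @param spt_at_screening_rate fraction of second primaries found at
#'   screening (rest during follow-up).
#' @param seed integer RNG seed; the same seed reproduces the same cohort.
#' @return A validated list of class `dm_sim_params`.
#' @export
simulation_params <- function(n_patients = 200,
                              dm_prevalence = 0.26,
                              spt_prevalence = 0.11,
                              extra_pulmonary_rate = 0.1,
                              size_mixture = list(weight_sub5 = 0.3,
                                                  meanlog_sub5 = log(3.5),
                                                  sdlog_sub5 = 0.25,
                                                  meanlog_supra5 = log(12),
                                                  sdlog_supra5 = 0.45),
                              ct_sensitivity_lung = 0.5 / 0.9,
                              pet_sensitivity_by_size = c(sub5 = 0,
                                                          supra5 = 0.5 / 0.73),
                              ct_specificity = 0.97,
                              pet_specificity = 1.0,
                              likert_emission = list(
                                detected = c(0, 0.05, 0.05, 0.15, 0.30, 0.45),
                                false_positive = c(0, 0.30, 0.30, 0.25, 0.10, 0.05)),
                              locoregional_failure_rate = 5 / 47,
                              spt_at_screening_rate = 0.6,
                              seed = 1L) {
  p <- list(n_patients = as.integer(n_patients),
            dm_prevalence = dm_prevalence, spt_prevalence = spt_prevalence,
            extra_pulmonary_rate = extra_pulmonary_rate,
            size_mixture = size_mixture,
            ct_sensitivity_lung = ct_sensitivity_lung,
            pet_sensitivity_by_size = pet_sensitivity_by_size,
            ct_specificity = ct_specificity,
            pet_specificity = pet_specificity,
            likert_emission = likert_emission,
            locoregional_failure_rate = locoregional_failure_rate,
            spt_at_screening_rate = spt_at_screening_rate,
            seed = as.integer(seed))
  probs <- c(p$dm_prevalence, p$spt_prevalence, p$extra_pulmonary_rate,
             p$size_mixture$weight_sub5, p$ct_sensitivity_lung,
             p$pet_sensitivity_by_size, p$ct_specificity, p$pet_specificity,
             p$locoregional_failure_rate, p$spt_at_screening_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("simulation_params: probabilities must lie in [0, 1]", call. = FALSE)
  if (p$n_patients < 1) stop("simulation_params: n_patients >= 1", call. = FALSE)
  for (e in p$likert_emission)
    if (length(e) != 6L || any(e < 0) || abs(sum(e) - 1) > 1e-8)
      stop("simulation_params: likert_emission entries must be probability ",
           "vectors over scores 0-5", call. = FALSE)
  structure(p, class = "dm_sim_params")
}

#' Marginal operating characteristics implied by simulation parameters
#'
#' The configuration is stated structurally (per-site CT detection, per-band
#' PET detection, size mixture); this returns the exact marginal per-patient
#' sensitivity and specificity those choices imply, which large-sample
#' empirical estimates from [simulate_cohort()] must recover.  The combined
#' reading's implied sensitivity accounts for the sub-5-mm CT branch.
#'
#' @param params a [simulation_params()] object.
#' @return Named vector: `ct_sensitivity`, `ct_specificity`,
#'   `pet_sensitivity`, `pet_specificity`, `combined_sensitivity`,
#'   `combined_specificity`.
#' @export
implied_accuracy <- function(params) {
  w_sub <- params$size_mixture$weight_sub5
  p_ep <- params$extra_pulmonary_rate
  ct_s <- (1 - p_ep) * params$ct_sensitivity_lung
  pet_band <- params$pet_sensitivity_by_size
  pet_s <- p_ep * pet_band[["supra5"]] +
    (1 - p_ep) * (w_sub * pet_band[["sub5"]] +
                    (1 - w_sub) * pet_band[["supra5"]])
  # combined: positive if PET detects, or CT detects a sub-5-mm lesion
  comb_lung <- w_sub * (pet_band[["sub5"]] +
                          (1 - pet_band[["sub5"]]) * params$ct_sensitivity_lung) +
    (1 - w_sub) * pet_band[["supra5"]]
  comb_s <- p_ep * pet_band[["supra5"]] + (1 - p_ep) * comb_lung
  # false-positive CT lesions are drawn at supra-limit sizes, so a negative
  # PET discounts them; combined specificity is driven by PET alone
  comb_spec <- params$pet_specificity
  c(ct_sensitivity = ct_s, ct_specificity = params$ct_specificity,
    pet_sensitivity = unname(pet_s), pet_specificity = params$pet_specificity,
    combined_sensitivity = unname(comb_s), combined_specificity = comb_spec)
}

# inverse-CDF draw from one lognormal component truncated at the 5-mm limit
.rsize <- function(n, sub5, mix) {
  u <- stats::runif(n)
  if (sub5) {
    p5 <- stats::plnorm(5, mix$meanlog_sub5, mix$sdlog_sub5)
    stats::qlnorm(u * p5, mix$meanlog_sub5, mix$sdlog_sub5)
  } else {
    p5 <- stats::plnorm(5, mix$meanlog_supra5, mix$sdlog_supra5)
    stats::qlnorm(p5 + u * (1 - p5), mix$meanlog_supra5, mix$sdlog_supra5)
  }
}

.rlikert <- function(n, probs) sample(0:5, n, replace = TRUE, prob = probs)

#' Simulate a screening cohort
#'
#' Reproducible given `params$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param params a [simulation_params()] object.
#' @return A `dm_cohort` of `params$n_patients` patients.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "dm_sim_params"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  n <- params$n_patients
  mix <- params$size_mixture
  pet_band <- params$pet_sensitivity_by_size
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dm <- stats::runif(1) < params$dm_prevalence
    spt <- stats::runif(1) < params$spt_prevalence
    ct_les <- no_lesions(); pet_les <- no_lesions()
    ct_call <- "negative"; pet_call <- "negative"
    if (dm) {
      extra <- stats::runif(1) < params$extra_pulmonary_rate
      if (extra) {
        size <- NA_real_
        pet_det <- stats::runif(1) < pet_band[["supra5"]]
        ct_det <- FALSE
      } else {
        sub5 <- stats::runif(1) < mix$weight_sub5
        size <- round(.rsize(1, sub5, mix), 1)
        # rounding to 0.1 mm must not cross the detection limit
        if (sub5 && size >= 5) size <- 4.9
        if (!sub5 && size < 5) size <- 5.0
        pet_det <- stats::runif(1) <
          (if (sub5) pet_band[["sub5"]] else pet_band[["supra5"]])
        ct_det <- stats::runif(1) < params$ct_sensitivity_lung
      }
      multiple <- stats::runif(1) < 0.3
      if (ct_det) {
        ct_call <- "positive"
        ct_les <- lesion_set("lung", size, multiple,
                             .rlikert(1, params$likert_emission$detected))
      }
      if (pet_det) {
        pet_call <- "positive"
        pet_les <- lesion_set(if (extra) "extra_pulmonary" else "lung",
                              NA, multiple,
                              .rlikert(1, params$likert_emission$detected))
      }
    } else {
      if (stats::runif(1) > params$ct_specificity) {
        ct_call <- "positive"
        ct_les <- lesion_set("lung", round(.rsize(1, FALSE, mix), 1), FALSE,
                             .rlikert(1, params$likert_emission$false_positive))
      }
      if (stats::runif(1) > params$pet_specificity) {
        pet_call <- "positive"
        pet_les <- lesion_set("lung", NA, FALSE,
                              .rlikert(1, params$likert_emission$false_positive))
      }
    }
    screen_pos <- ct_call == "positive" || pet_call == "positive"
    dm_at <- dm && screen_pos
    spt_at <- spt && stats::runif(1) < params$spt_at_screening_rate
    rows[[i]] <- patient_record(
      patient_id = sprintf("S%05d", i),
      risk_factors = "bilateral_nodes",
      primary_site = "oropharynx",
      ct = modality_reading(ct_call, ct_les, "ct"),
      pet = modality_reading(pet_call, pet_les, "pet"),
      dm_at_screening = dm_at,
      spt_at_screening = spt_at,
      dm_within_12mo = dm && !dm_at,
      spt_within_12mo = spt && !spt_at,
      locoregional_control =
        stats::runif(1) >= params$locoregional_failure_rate,
      confirmation = if (dm_at) "histopathology"
                     else if (dm) "progression" else "none")
  }
  as_cohort(rows)
}

# ---------------------------------------------------------------------------
# Paired ordinal score generator with a known AUC, for parameter-recovery
# tests of the ROC machinery.

# exact AUC (ties counted half) of ordinal scores obtained by cutting
# latent N(mu,1) positives and N(0,1) negatives at `cuts`
.ordinal_auc <- function(mu, cuts) {
  edges <- c(-Inf, cuts, Inf)
  p_pos <- diff(stats::pnorm(edges, mean = mu))
  p_neg <- diff(stats::pnorm(edges))
  k <- length(p_pos)
  auc <- 0
  for (i in seq_len(k))
    for (j in seq_len(k))
      auc <- auc + p_pos[i] * p_neg[j] *
        (as.numeric(i > j) + 0.5 * as.numeric(i == j))
  auc
}

# latent separation whose discretised AUC equals `target`
.calibrate_mu <- function(target, cuts) {
  stats::uniroot(function(m) .ordinal_auc(m, cuts) - target,
                 lower = 0, upper = 6, tol = 1e-10)$root
}

#' Simulate paired ordinal scores with known true AUCs
#'
#' Two modalities score the same patients on the 0--5 ordinal scale.  Latent
#' reader signals are correlated bivariate normal; the latent separation of
#' each modality is calibrated (by root-finding on the exact discretised
#' pair-probability) so that the true AUC of the *emitted ordinal scores*,
#' with ties counted half, equals the requested value.
#'
#' @param n number of patients.
#' @param prevalence probability a patient is truth-positive.
#' @param auc_a,auc_b target true AUCs of the two modalities.
#' @param rho correlation of the two modalities' latent signals.
#' @param cuts latent cutpoints producing the six ordinal levels.
#' @param seed RNG seed.
#' @return data.frame: `score_a`, `score_b` (ordinal 0--5), `truth`.
#' @export
simulate_paired_scores <- function(n, prevalence = 0.26,
                                   auc_a = 0.84, auc_b = 0.78,
                                   rho = 0.5,
                                   cuts = c(-1.2, -0.4, 0.4, 1.2, 2.0),
                                   seed = 1L) {
  stopifnot(auc_a >= 0.5, auc_b >= 0.5, rho >= 0, rho < 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  mu_a <- .calibrate_mu(auc_a, cuts)
  mu_b <- .calibrate_mu(auc_b, cuts)
  truth <- ifelse(stats::runif(n) < prevalence, "positive", "negative")
  d <- as.numeric(truth == "positive")
  common <- stats::rnorm(n)
  lat_a <- mu_a * d + sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(n)
  lat_b <- mu_b * d + sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(n)
  cut_scores <- function(x) findInterval(x, cuts)
  data.frame(score_a = cut_scores(lat_a), score_b = cut_scores(lat_b),
             truth = truth, stringsAsFactors = FALSE)
}
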