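# Synthetic emergency-department infection cohort. A single latent severity
# factor drives gas exchange, oxygen therapy, PaO2 measurement (sicker
# patients get arterial blood gases more often), non-respiratory organ
# dysfunction, and in-hospital mortality.

#' Default synthetic cohort configuration
#'
#' Returns the calibrated generator defaults. Structural targets emulate a
#' large single-center ED infection cohort: about 4.9% in-hospital
#' mortality, about 56% missing PaO2, and substantially higher mortality in
#' the measured-PaO2 subgroup (severity-dependent missingness). Logistic
#' intercepts were calibrated by Gaussian quadrature against those marginal
#' rates given the unit-normal latent severity; remaining constants
#' (physiologic clamps, organ loadings, device cutpoints) are realistic
#' round numbers documented in the package vignette.
#'
#' @param n Cohort size (default 15000, the scale of the motivating study
#'   population).
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_config` (a named list).
#' @export
default_config <- function(n = 15000, seed = 20230925) {
  structure(list(
    n = n,
    seed = seed,
    # logistic coefficients on latent severity z ~ N(0,1)
    mortality_intercept = -3.869,   # marginal mortality ~ 4.9%
    mortality_slope = 1.5,
    miss_intercept = -0.341,        # P(PaO2 measured) ~ 44% => 56% missing
    miss_slope = 1.5,               # > 0: sicker patients measured more
    # room-air gas exchange: true PaO2 =
    #   clamp(base - sat_drop*plogis(z)
    #         - det_drop*plogis(det_rate*(z - det_center)) + noise, lo, hi)
    pao2_base = 100,
    pao2_sat_drop = 30,
    pao2_det_drop = 40,
    pao2_det_rate = 1.5,
    pao2_det_center = 0.8,
    pao2_noise_sd = 6,
    pao2_clamp = c(35, 110),
    # supplemental oxygen raises the arterial tension the blood gas sees by
    # support_boost * (FiO2 - 0.21); the oximetry nadir reflects only a
    # fraction of that support (continuous monitoring catches transient
    # desaturation before or despite therapy, a one-time ABG is drawn on
    # stable support)
    support_boost = 105,
    spo2_support_boost = 30,
    abg_noise_sd = 3,
    spo2_noise_sd = 1.5,
    spo2_clamp = c(50, 100),
    # severity cutpoints assigning oxygen delivery (ascending)
    device_thresholds = c(NASAL_CANNULA = 0.85, SIMPLE_MASK = 1.40,
                          RESERVOIR_MASK = 1.65, HIGH_FLOW = 1.80,
                          MECHANICAL_VENT = 1.96),
    # vasopressor use ~ 8%, dose category escalating with severity
    vaso_intercept = -3.3,
    vaso_slope = 1.4,
    # per-organ severity loadings
    organ_coeffs = list(
      platelets = c(log_median = log(197), slope = -0.35, sd = 0.45),
      bilirubin = c(log_median = log(0.7), slope = 0.35, sd = 0.60),
      creatinine = c(log_median = log(0.95), slope = 0.30, sd = 0.40),
      map = c(median = 76, slope = -6, sd = 8),
      gcs = c(rate = 1.5, center = 2.2)
    )
  ), class = "cohort_config")
}

validate_config <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config (see default_config())",
         call. = FALSE)
  }
  if (!is.numeric(config$n) || config$n < 1) {
    stop("config$n must be >= 1", call. = FALSE)
  }
  if (!is.numeric(config$seed) || !is.finite(config$seed)) {
    stop("config$seed must be a finite integer", call. = FALSE)
  }
  if (config$spo2_noise_sd < 0) {
    stop("spo2_noise_sd must be >= 0", call. = FALSE)
  }
  if (is.unsorted(config$device_thresholds)) {
    stop("device_thresholds must be ascending", call. = FALSE)
  }
  invisible(config)
}

# Per-patient sub-stream seed: patient i draws from its own seeded stream so
# that record i is identical whatever the cohort size. Kept below 2^31.
patient_seed <- function(seed, i) {
  (abs(seed) * 48271 + i * 2654435761) %% 2147483647
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic ED infection cohort
#'
#' Per patient: latent severity z ~ N(0,1); room-air ("true") PaO2 declines
#' in z through a saturating term plus a steep deterioration term; oxygen
#' delivery is assigned by severity cutpoints, and the effective arterial
#' tension rises with delivered FiO2; worst-in-24h SpO2 is the Severinghaus
#' saturation of the nadir tension — which reflects only part of the oxygen
#' support, since continuous monitoring catches transient desaturation
#' before or despite therapy — plus oximeter noise, rounded to whole
#' percent; the effective (fully supported) PaO2 is recorded with small ABG
#' noise only with probability
#' `plogis(miss_intercept + miss_slope * z)`, so sicker patients are
#' measured more often; non-respiratory labs are monotone transforms of z
#' with log-normal or normal noise; death is Bernoulli in a logistic model
#' on z. Each patient draws from a sub-stream seeded by (seed, patient
#' index), so the generator is deterministic given the seed and record i
#' does not change when n does.
#'
#' @param config A `cohort_config`, e.g. [default_config()].
#' @return An object of class `generated_cohort`: list with `records` (a
#'   cohort data frame, see [read_cohort()] for the schema) and `truth`
#'   (per-patient `severity` and room-air `true_pao2`), aligned one-to-one.
#' @examples
#' gc <- generate_cohort(default_config(n = 200, seed = 1))
#' head(gc$records)
#' @export
generate_cohort <- function(config = default_config()) {
  validate_config(config)
  n <- as.integer(config$n)
  dev_cuts <- config$device_thresholds

  # fixed-size draw block per patient sub-stream
  ne <- 12
  nu <- 4
  E <- matrix(0, n, ne)
  U <- matrix(0, n, nu)
  with_seed(config$seed, {
    for (i in seq_len(n)) {
      set.seed(patient_seed(config$seed, i))
      E[i, ] <- stats::rnorm(ne)
      U[i, ] <- stats::runif(nu)
    }
  })

  z <- E[, 1]

  # room-air gas exchange
  true_pao2 <- clamp(
    config$pao2_base -
      config$pao2_sat_drop * stats::plogis(z) -
      config$pao2_det_drop *
        stats::plogis(config$pao2_det_rate * (z - config$pao2_det_center)) +
      config$pao2_noise_sd * E[, 2],
    config$pao2_clamp[1], config$pao2_clamp[2])

  # oxygen delivery by severity
  device <- rep("ROOM_AIR", n)
  for (d in names(dev_cuts)) device[z >= dev_cuts[[d]]] <- d
  flow <- rep(NA_real_, n)
  set_fio2 <- rep(NA_real_, n)
  nc <- device == "NASAL_CANNULA"
  flow[nc] <- clamp(round(1 + 3 * (z[nc] - dev_cuts[["NASAL_CANNULA"]]) +
                            0.7 * E[nc, 3]), 1, 6)
  sm <- device == "SIMPLE_MASK"
  flow[sm] <- clamp(round(6 + 4 * (z[sm] - dev_cuts[["SIMPLE_MASK"]]) +
                            0.7 * E[sm, 3]), 5, 10)
  rm_ <- device == "RESERVOIR_MASK"
  flow[rm_] <- clamp(round(10 + 5 * (z[rm_] - dev_cuts[["RESERVOIR_MASK"]]) +
                             E[rm_, 3]), 6, 15)
  hf <- device == "HIGH_FLOW"
  set_fio2[hf] <- round(clamp(0.4 + 0.3 * (z[hf] - dev_cuts[["HIGH_FLOW"]]) +
                                0.08 * E[hf, 3], 0.25, 1), 2)
  mv <- device == "MECHANICAL_VENT"
  set_fio2[mv] <- round(clamp(0.4 +
                                0.35 * (z[mv] - dev_cuts[["MECHANICAL_VENT"]]) +
                                0.10 * E[mv, 3], 0.25, 1), 2)

  fio2 <- estimate_fio2(device, flow, set_fio2)
  effective_pao2 <- true_pao2 + config$support_boost * (fio2 - 0.21)
  nadir_pao2 <- true_pao2 + config$spo2_support_boost * (fio2 - 0.21)

  # worst-in-24h pulse oximetry: saturation of the nadir tension
  spo2 <- clamp(round(severinghaus_saturation(nadir_pao2) +
                        config$spo2_noise_sd * E[, 4]),
                config$spo2_clamp[1], config$spo2_clamp[2])

  # severity-dependent ABG measurement
  measured <- U[, 1] < stats::plogis(config$miss_intercept +
                                       config$miss_slope * z)
  pao2 <- ifelse(measured,
                 round(pmax(effective_pao2 + config$abg_noise_sd * E[, 5],
                            30), 1),
                 NA_real_)

  # non-respiratory organs
  oc <- config$organ_coeffs
  platelets <- round(clamp(exp(oc$platelets[["log_median"]] +
                                 oc$platelets[["slope"]] * z +
                                 oc$platelets[["sd"]] * E[, 6]), 2, 1000))
  bilirubin <- round(clamp(exp(oc$bilirubin[["log_median"]] +
                                 oc$bilirubin[["slope"]] * z +
                                 oc$bilirubin[["sd"]] * E[, 7]), 0.1, 40), 2)
  creatinine <- round(clamp(exp(oc$creatinine[["log_median"]] +
                                  oc$creatinine[["slope"]] * z +
                                  oc$creatinine[["sd"]] * E[, 8]), 0.2, 15), 2)
  map <- round(clamp(oc$map[["median"]] + oc$map[["slope"]] * z +
                       oc$map[["sd"]] * E[, 9], 30, 140))
  gcs_p <- stats::plogis(oc$gcs[["rate"]] * (z - oc$gcs[["center"]]))
  gcs <- 15L - as.integer(stats::qbinom(U[, 2], 12, gcs_p))

  vaso <- rep("NONE", n)
  on_vaso <- U[, 3] < stats::plogis(config$vaso_intercept +
                                      config$vaso_slope * z)
  cat_score <- z + 0.5 * E[, 10]
  vaso[on_vaso & cat_score < 1.8] <- "DOPA_LE5"
  vaso[on_vaso & cat_score >= 1.8 & cat_score < 2.4] <- "DOPA_5_15_OR_EPI_LE01"
  vaso[on_vaso & cat_score >= 2.4] <- "DOPA_GT15_OR_EPI_GT01"

  died <- U[, 4] < stats::plogis(config$mortality_intercept +
                                   config$mortality_slope * z)

  records <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    spo2_pct = spo2,
    pao2_mmhg = pao2,
    device = device,
    flow_lpm = flow,
    set_fio2 = set_fio2,
    platelets_k_ul = platelets,
    bilirubin_mg_dl = bilirubin,
    map_mmhg = map,
    vasopressor_cat = vaso,
    gcs = gcs,
    creatinine_mg_dl = creatinine,
    died_in_hospital = as.integer(died),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    patient_id = records$patient_id,
    severity = z,
    true_pao2 = true_pao2
  )
  structure(list(records = records, truth = truth, config = config),
            class = "generated_cohort")
}
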