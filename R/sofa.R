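# SOFA scoring: respiratory sub-score under seven missing-PaO2 strategies,
# the five non-respiratory organ sub-scores, and the 0-24 total.

#' Respiratory SOFA scoring methods
#'
#' The seven strategies compared by the package:
#' \describe{
#'   \item{CONV}{Conventional: missing PaO2 treated as normal (imputed
#'     100 mmHg by default), scored by PaO2/FiO2.}
#'   \item{A}{Piecewise SpO2->PaO2 conversion replaces PaO2 for all
#'     patients.}
#'   \item{B}{Piecewise conversion fills in missing PaO2 only.}
#'   \item{C}{Hill-equation SpO2->PaO2 estimate replaces PaO2 for all
#'     patients.}
#'   \item{D}{Hill-equation estimate fills in missing PaO2 only.}
#'   \item{E}{Direct SpO2-threshold score (plus one point for respiratory
#'     support) for all patients.}
#'   \item{F}{SpO2-threshold score when PaO2 is missing, PaO2/FiO2 score
#'     otherwise.}
#' }
#'
#' @export
sofa_methods <- c("CONV", "A", "B", "C", "D", "E", "F")

#' PaO2/FiO2 ratio
#'
#' The gas-exchange index of the respiratory SOFA row: arterial oxygen
#' tension divided by the inspired oxygen fraction.
#'
#' @param pao2 Arterial oxygen tension, mmHg (> 0). Vectorized.
#' @param fio2 Inspired oxygen fraction in [0.21, 1].
#' @return The dimensionless ratio.
#' @examples
#' pf_ratio(100, 0.21)
#' @export
pf_ratio <- function(pao2, fio2) {
  if (any(!is.finite(pao2)) || any(pao2 <= 0)) {
    stop("pao2 must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(fio2)) || any(fio2 < 0.21) || any(fio2 > 1)) {
    stop("fio2 must lie in [0.21, 1]", call. = FALSE)
  }
  pao2 / fio2
}

#' Respiratory SOFA sub-score from the PaO2/FiO2 ratio
#'
#' Classic thresholds: PF >= 400 scores 0; < 400 scores 1; < 300 scores 2;
#' < 200 scores 3 and < 100 scores 4, the last two only with respiratory
#' support. Without support the score is capped at 2.
#'
#' @param pf PaO2/FiO2 ratio (> 0). Vectorized.
#' @param support Logical; is the patient on respiratory support (any
#'   supplemental oxygen or ventilation)?
#' @return Integer scores 0-4.
#' @examples
#' resp_sofa_from_pf(c(450, 350, 250, 150, 90), support = TRUE)
#' @export
resp_sofa_from_pf <- function(pf, support) {
  if (any(!is.finite(pf)) || any(pf <= 0)) {
    stop("pf must be positive and finite", call. = FALSE)
  }
  support <- rep_len(as.logical(support), length(pf))
  base <- ifelse(pf < 100, 4L,
          ifelse(pf < 200, 3L,
          ifelse(pf < 300, 2L,
          ifelse(pf < 400, 1L, 0L))))
  ifelse(support, base, pmin(base, 2L))
}

#' Respiratory SOFA sub-score from SpO2 thresholds (methods E/F)
#'
#' Base score by saturation: SpO2 > 94% scores 0; (90, 94] scores 1;
#' (85, 90] scores 2; <= 85% scores 3. One point is added for respiratory
#' support (oxygen or ventilator), and the result is capped at 4.
#'
#' @param spo2 Peripheral oxygen saturation in percent, (0, 100].
#'   Vectorized.
#' @param support Logical respiratory-support flag.
#' @return Integer scores 0-4.
#' @examples
#' resp_sofa_spo2_thresholds(c(96, 93, 88, 84), support = FALSE)
#' @export
resp_sofa_spo2_thresholds <- function(spo2, support) {
  check_spo2(spo2)
  support <- rep_len(as.logical(support), length(spo2))
  base <- ifelse(spo2 > 94, 0L,
          ifelse(spo2 > 90, 1L,
          ifelse(spo2 > 85, 2L, 3L)))
  pmin(base + as.integer(support), 4L)
}

#' Respiratory SOFA sub-score for a cohort under one method
#'
#' Dispatches one of the seven strategies (see [sofa_methods]) over a cohort
#' table. Respiratory support is any delivery other than room air; FiO2 is
#' derived from the delivery columns via [estimate_fio2()].
#'
#' For `CONV`, missing PaO2 is imputed as a normal 100 mmHg and scored
#' through the PaO2/FiO2 ratio (`conv_mode = "impute_pao2_100"`), preserving
#' the patient's actual FiO2; with `conv_mode = "score_zero"` the respiratory
#' sub-score of PaO2-missing patients is set to 0 instead. Methods A/C/E
#' ignore measured PaO2 entirely; B/D/F fall back to the conventional
#' measured-PaO2 scoring whenever PaO2 is present.
#'
#' @param cohort A cohort data frame (see [read_cohort()] for the schema).
#' @param method One of `"CONV", "A".."F"`.
#' @param conv_mode How `CONV` handles missing PaO2:
#'   `"impute_pao2_100"` (default) or `"score_zero"`.
#' @param fio2_lookup Optional lookup table from [read_fio2_lookup()].
#' @return Integer vector of respiratory sub-scores, one per row.
#' @export
respiratory_sofa <- function(cohort, method,
                             conv_mode = c("impute_pao2_100", "score_zero"),
                             fio2_lookup = NULL) {
  method <- match.arg(method, sofa_methods)
  conv_mode <- match.arg(conv_mode)
  spo2 <- cohort$spo2_pct
  pao2 <- cohort$pao2_mmhg
  support <- cohort$device != "ROOM_AIR"
  fio2 <- estimate_fio2(cohort$device, cohort$flow_lpm, cohort$set_fio2,
                        lookup = fio2_lookup)

  score_pf <- function(p) resp_sofa_from_pf(pf_ratio(p, fio2), support)
  conv_scores <- function() {
    if (conv_mode == "impute_pao2_100") {
      score_pf(ifelse(is.na(pao2), 100, pao2))
    } else {
      sc <- rep(0L, length(spo2))
      if (any(!is.na(pao2))) {
        sc[!is.na(pao2)] <- resp_sofa_from_pf(
          pf_ratio(pao2[!is.na(pao2)], fio2[!is.na(pao2)]),
          support[!is.na(pao2)])
      }
      sc
    }
  }

  switch(method,
    CONV = conv_scores(),
    A = score_pf(estimate_pao2_piecewise(spo2)),
    B = score_pf(ifelse(is.na(pao2), estimate_pao2_piecewise(spo2), pao2)),
    C = score_pf(estimate_pao2_hill(spo2)),
    D = score_pf(ifelse(is.na(pao2), estimate_pao2_hill(spo2), pao2)),
    E = resp_sofa_spo2_thresholds(spo2, support),
    F = ifelse(is.na(pao2),
               resp_sofa_spo2_thresholds(spo2, support),
               score_pf(ifelse(is.na(pao2), 100, pao2)))
  )
}

#' Non-respiratory SOFA sub-scores
#'
#' Scores the five non-respiratory organ systems from worst-in-24h values:
#' coagulation by platelet count (10^3/uL), liver by bilirubin (mg/dL),
#' cardiovascular by mean arterial pressure and vasopressor dose category,
#' central nervous system by Glasgow Coma Scale, and renal by creatinine
#' (mg/dL). Renal scoring uses creatinine only (no urine output).
#'
#' @param cohort A cohort data frame (see [read_cohort()]).
#' @return A data frame with integer columns `coagulation`, `liver`,
#'   `cardiovascular`, `cns`, `renal`.
#' @export
nonrespiratory_sofa <- function(cohort) {
  plt <- cohort$platelets_k_ul
  bili <- cohort$bilirubin_mg_dl
  map <- cohort$map_mmhg
  vaso <- cohort$vasopressor_cat
  gcs <- cohort$gcs
  creat <- cohort$creatinine_mg_dl
  if (any(!gcs %in% 3:15)) {
    stop("gcs must be an integer in 3..15", call. = FALSE)
  }
  if (!all(vaso %in% vasopressor_categories)) {
    stop("unknown vasopressor category", call. = FALSE)
  }
  coagulation <- ifelse(plt < 20, 4L,
                 ifelse(plt < 50, 3L,
                 ifelse(plt < 100, 2L,
                 ifelse(plt < 150, 1L, 0L))))
  liver <- ifelse(bili >= 12, 4L,
           ifelse(bili >= 6, 3L,
           ifelse(bili >= 2, 2L,
           ifelse(bili >= 1.2, 1L, 0L))))
  cardiovascular <- ifelse(vaso == "DOPA_GT15_OR_EPI_GT01", 4L,
                    ifelse(vaso == "DOPA_5_15_OR_EPI_LE01", 3L,
                    ifelse(vaso == "DOPA_LE5", 2L,
                    ifelse(map < 70, 1L, 0L))))
  cns <- ifelse(gcs < 6, 4L,
         ifelse(gcs <= 9, 3L,
         ifelse(gcs <= 12, 2L,
         ifelse(gcs <= 14, 1L, 0L))))
  renal <- ifelse(creat >= 5, 4L,
           ifelse(creat >= 3.5, 3L,
           ifelse(creat >= 2, 2L,
           ifelse(creat >= 1.2, 1L, 0L))))
  data.frame(coagulation = coagulation, liver = liver,
             cardiovascular = cardiovascular, cns = cns, renal = renal)
}

#' Full SOFA breakdown for a cohort under one method
#'
#' Combines [respiratory_sofa()] with [nonrespiratory_sofa()] into the six
#' organ sub-scores (each 0-4) and their 0-24 total.
#'
#' @inheritParams respiratory_sofa
#' @return A data frame with columns `patient_id`, `method`, `respiratory`,
#'   `coagulation`, `liver`, `cardiovascular`, `cns`, `renal`, `total`.
#' @export
total_sofa <- function(cohort, method,
                       conv_mode = c("impute_pao2_100", "score_zero"),
                       fio2_lookup = NULL) {
  conv_mode <- match.arg(conv_mode)
  resp <- respiratory_sofa(cohort, method, conv_mode, fio2_lookup)
  other <- nonrespiratory_sofa(cohort)
  out <- cbind(
    data.frame(patient_id = cohort$patient_id,
               method = method,
               respiratory = as.integer(resp)),
    other
  )
  out$total <- out$respiratory + out$coagulation + out$liver +
    out$cardiovascular + out$cns + out$renal
  out
}

#' Score a cohort under several methods
#'
#' Applies [total_sofa()] for each requested method and stacks the results
#' into one long table.
#'
#' @inheritParams respiratory_sofa
#' @param methods Character vector, a subset of [sofa_methods].
#' @return A long data frame, one row per patient x method.
#' @export
score_cohort <- function(cohort, methods = sofa_methods,
                         conv_mode = c("impute_pao2_100", "score_zero"),
                         fio2_lookup = NULL) {
  conv_mode <- match.arg(conv_mode)
  methods <- match.arg(methods, sofa_methods, several.ok = TRUE)
  do.call(rbind, lapply(methods, function(m) {
    total_sofa(cohort, m, conv_mode, fio2_lookup)
  }))
}
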