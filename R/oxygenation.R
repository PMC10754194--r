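# Oxygenation physiology: the forward oxyhemoglobin dissociation curve and the
# SpO2 -> PaO2 estimators that back the SpO2-based respiratory SOFA methods.

#' Oxygen delivery devices
#'
#' Canonical device labels used throughout the package. `ROOM_AIR` means no
#' supplemental oxygen; `HIGH_FLOW` and `MECHANICAL_VENT` deliver a set FiO2
#' rather than a flow-derived one.
#'
#' @export
oxygen_devices <- c("ROOM_AIR", "NASAL_CANNULA", "SIMPLE_MASK",
                    "RESERVOIR_MASK", "HIGH_FLOW", "MECHANICAL_VENT")

#' Vasopressor dose categories
#'
#' Dose bands of the cardiovascular SOFA row: none; dopamine <= 5
#' ug/kg/min (or dobutamine); dopamine 5-15 or epinephrine/norepinephrine
#' <= 0.1; dopamine > 15 or epinephrine/norepinephrine > 0.1.
#'
#' @export
vasopressor_categories <- c("NONE", "DOPA_LE5", "DOPA_5_15_OR_EPI_LE01",
                            "DOPA_GT15_OR_EPI_GT01")

check_spo2 <- function(spo2) {
  if (!is.numeric(spo2) || any(!is.finite(spo2)) ||
      any(spo2 <= 0) || any(spo2 > 100)) {
    stop("spo2 must be a finite percentage in (0, 100]", call. = FALSE)
  }
  invisible(spo2)
}

#' Oxyhemoglobin saturation from oxygen tension (Severinghaus curve)
#'
#' Forward dissociation curve
#' \deqn{S = 100 \left(\frac{23400}{P^3 + 150P} + 1\right)^{-1}}
#' mapping arterial oxygen tension (mmHg) to hemoglobin saturation (%). The
#' curve is strictly increasing with P50 near 26.9 mmHg and approaches 100%
#' asymptotically. Used by the synthetic cohort generator to derive SpO2 from
#' simulated PaO2; it is deliberately distinct from the inverse estimators so
#' that estimation error in the simulation is realistic rather than circular.
#'
#' @param pao2 Arterial oxygen tension in mmHg, positive and finite.
#'   Vectorized.
#' @return Saturation in percent (0-100).
#' @examples
#' severinghaus_saturation(c(26.9, 60, 100))
#' @export
severinghaus_saturation <- function(pao2) {
  if (!is.numeric(pao2) || any(!is.finite(pao2)) || any(pao2 <= 0)) {
    stop("pao2 must be positive and finite", call. = FALSE)
  }
  100 / (23400 / (pao2^3 + 150 * pao2) + 1)
}

#' Piecewise-linear PaO2 estimate from SpO2 (methods A/B)
#'
#' The simplified bedside conversion: from SpO2 100% down to 90%, PaO2 falls
#' 4 mmHg per percentage point (100 -> 60 mmHg); from 90% to 80%, 1.5 mmHg per
#' point (60 -> 45 mmHg); below 80%, PaO2 is taken as half the SpO2 value.
#' SpO2 exactly 80 belongs to the middle segment (returns 45), keeping the map
#' continuous on [80, 100].
#'
#' @param spo2 Peripheral oxygen saturation in percent, in (0, 100].
#'   Vectorized.
#' @return Estimated PaO2 in mmHg.
#' @examples
#' estimate_pao2_piecewise(c(100, 95, 90, 80, 70))
#' @export
estimate_pao2_piecewise <- function(spo2) {
  check_spo2(spo2)
  ifelse(spo2 >= 90, 100 - 4 * (100 - spo2),
         ifelse(spo2 >= 80, 60 - 1.5 * (90 - spo2),
                spo2 / 2))
}

#' Hill-type PaO2 estimate from SpO2 (methods C/D)
#'
#' Inverts a Hill-form dissociation model,
#' \deqn{PaO_2 = \left(\frac{27.8^{2.81}\, s}{1 - 0.99\, s}\right)^{1/2.8},
#'   \quad s = SpO_2 / 100,}
#' whose half-saturation tension is approximately 27.8 mmHg and which
#' reproduces the classic anchor SpO2 90% -> PaO2 ~ 60 mmHg. The 0.99
#' coefficient keeps the denominator positive at s = 1, so saturations of
#' 100% map to a finite (~146 mmHg) tension. The equation is isolated here so
#' an alternative parameterization can be swapped in without touching the
#' scoring code.
#'
#' @inheritParams estimate_pao2_piecewise
#' @return Estimated PaO2 in mmHg; strictly increasing in `spo2`.
#' @examples
#' estimate_pao2_hill(c(90, 95, 100))
#' @export
estimate_pao2_hill <- function(spo2) {
  check_spo2(spo2)
  s <- spo2 / 100
  (27.8^2.81 * s / (1 - 0.99 * s))^(1 / 2.8)
}

#' Read a device/flow to FiO2 lookup table
#'
#' Reads a four-column CSV (`device`, `flow_lpm_min`, `flow_lpm_max`, `fio2`)
#' that overrides the built-in conversion used by [estimate_fio2()]. Rows are
#' matched by device and inclusive flow range.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame usable as the `lookup` argument of
#'   [estimate_fio2()].
#' @export
read_fio2_lookup <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("device", "flow_lpm_min", "flow_lpm_max", "fio2")
  if (!all(need %in% names(tab))) {
    stop("FiO2 lookup must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$device %in% oxygen_devices)) {
    stop("unknown device in FiO2 lookup", call. = FALSE)
  }
  if (any(!is.finite(tab$fio2)) || any(tab$fio2 < 0.21) || any(tab$fio2 > 1)) {
    stop("fio2 values in lookup must lie in [0.21, 1]", call. = FALSE)
  }
  tab
}

fio2_from_lookup <- function(lookup, device, flow) {
  rows <- lookup[lookup$device == device &
                 lookup$flow_lpm_min <= flow &
                 lookup$flow_lpm_max >= flow, , drop = FALSE]
  if (nrow(rows) == 0) return(NA_real_)
  rows$fio2[1]
}

#' Estimate the inspired oxygen fraction from the delivery device
#'
#' Converts an oxygen delivery record (device, flow in L/min, or a set FiO2)
#' into an inspired oxygen fraction:
#' \itemize{
#'   \item `ROOM_AIR`: 0.21.
#'   \item `NASAL_CANNULA`: 0.21 + 0.04 per L/min, flow capped at 6 L/min.
#'   \item `SIMPLE_MASK`: 0.40 at 5-6 L/min, 0.50 at 7-8, 0.60 at 9-10;
#'     flows outside 5-10 are clamped to the nearest band.
#'   \item `RESERVOIR_MASK`: min(0.21 + 0.10 x flow, 0.90), floored at 0.60.
#'   \item `HIGH_FLOW` / `MECHANICAL_VENT`: the set FiO2, verbatim.
#' }
#' The device/flow rules reconstruct a standard emergency-department
#' conversion; supply `lookup` (see [read_fio2_lookup()]) to use a local
#' table instead. Results always lie in [0.21, 1].
#'
#' @param device Character vector of devices (see [oxygen_devices]).
#' @param flow Oxygen flow in L/min; required (non-NA) for flow-based
#'   devices, ignored otherwise.
#' @param set_fio2 Set inspired fraction for `HIGH_FLOW`/`MECHANICAL_VENT`.
#' @param lookup Optional override table from [read_fio2_lookup()].
#' @return Numeric vector of FiO2 fractions in [0.21, 1].
#' @examples
#' estimate_fio2("NASAL_CANNULA", flow = 3)
#' estimate_fio2("MECHANICAL_VENT", set_fio2 = 0.8)
#' @export
estimate_fio2 <- function(device, flow = NA_real_, set_fio2 = NA_real_,
                          lookup = NULL) {
  n <- max(length(device), length(flow), length(set_fio2))
  device <- rep_len(as.character(device), n)
  flow <- rep_len(as.numeric(flow), n)
  set_fio2 <- rep_len(as.numeric(set_fio2), n)
  if (!all(device %in% oxygen_devices)) {
    stop("unknown oxygen delivery device", call. = FALSE)
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- switch(
      device[i],
      ROOM_AIR = 0.21,
      HIGH_FLOW = ,
      MECHANICAL_VENT = {
        if (!is.finite(set_fio2[i])) {
          stop("set_fio2 required for ", device[i], call. = FALSE)
        }
        if (set_fio2[i] < 0.21 || set_fio2[i] > 1) {
          stop("set_fio2 must lie in [0.21, 1]", call. = FALSE)
        }
        set_fio2[i]
      },
      {
        if (!is.finite(flow[i]) || flow[i] < 0) {
          stop("flow (L/min) required for ", device[i], call. = FALSE)
        }
        v <- if (!is.null(lookup)) fio2_from_lookup(lookup, device[i], flow[i])
             else NA_real_
        if (is.na(v)) {
          v <- switch(
            device[i],
            NASAL_CANNULA = 0.21 + 0.04 * min(flow[i], 6),
            SIMPLE_MASK = if (flow[i] <= 6) 0.40
                          else if (flow[i] <= 8) 0.50
                          else 0.60,
            RESERVOIR_MASK = max(0.60, min(0.21 + 0.10 * flow[i], 0.90))
          )
        }
        v
      }
    )
  }
  pmin(pmax(out, 0.21), 1)
}
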