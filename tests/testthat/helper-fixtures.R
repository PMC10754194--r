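# Hand-built records and brute-force oracles shared across the suite.

# Cohort rows with healthy defaults; override any field by name. Vector
# overrides are recycled into that many rows.
make_record <- function(...) {
  fields <- list(
    spo2_pct = 98,
    pao2_mmhg = NA_real_,
    device = "ROOM_AIR",
    flow_lpm = NA_real_,
    set_fio2 = NA_real_,
    platelets_k_ul = 250,
    bilirubin_mg_dl = 0.5,
    map_mmhg = 80,
    vasopressor_cat = "NONE",
    gcs = 15L,
    creatinine_mg_dl = 0.8,
    died_in_hospital = 0L
  )
  over <- list(...)
  for (nm in names(over)) fields[[nm]] <- over[[nm]]
  n <- max(vapply(fields, length, integer(1)))
  fields <- lapply(fields, rep_len, n)
  cbind(data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                   stringsAsFactors = FALSE),
        as.data.frame(fields, stringsAsFactors = FALSE))
}

make_cohort <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  out$patient_id <- sprintf("P%03d", seq_len(nrow(out)))
  out
}

# O(n^2) pairwise AUC estimator: mean over case/control pairs of
# 1{case > control} + 0.5 * 1{tie}. Independent of the midrank path.
auc_brute <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# O(n^2) DeLong structural components: per-case and per-control placement
# averages of the pairwise kernel, and the variance/covariance they imply.
delong_oracle <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  comp <- function(scores) {
    pos <- scores[labels]
    neg <- scores[!labels]
    psi <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
  }
  a <- comp(scores_a)
  b <- comp(scores_b)
  m <- sum(labels)
  n <- sum(!labels)
  var_a <- var(a$v10) / m + var(a$v01) / n
  var_b <- var(b$v10) / m + var(b$v01) / n
  cov_ab <- cov(a$v10, b$v10) / m + cov(a$v01, b$v01) / n
  list(auc_a = a$auc, auc_b = b$auc, var_a = var_a, var_b = var_b,
       cov_ab = cov_ab, var_delta = var_a + var_b - 2 * cov_ab)
}

# random heavily tied score/label instance for property tests
random_tied_instance <- function(max_n = 200) {
  n <- sample(4:max_n, 1)
  scores <- sample(0:8, n, replace = TRUE)
  labels <- stats::rbinom(n, 1, runif(1, 0.2, 0.8))
  if (sum(labels) == 0) labels[sample(n, 1)] <- 1
  if (sum(labels) == n) labels[sample(n, 1)] <- 0
  list(scores = scores, labels = labels == 1)
}
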