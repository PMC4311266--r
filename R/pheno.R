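#' Derived glycaemic phenotypes
#'
#' Pure functions for the physiologic phenotypes used in glycaemic-trait
#' association work: the insulinogenic index from paired 0/30-minute OGTT
#' measurements, trapezoid areas under OGTT excursion curves, the incretin
#' effect from paired oral and intravenous AUCs, blood-pressure medication
#' adjustment, and trait transforms. Missing inputs always propagate as
#' missing, never as zero.
#'
#' @name pheno_derive
NULL

#' Insulinogenic index
#'
#' (insulin 30 min - insulin baseline) / (glucose 30 min - glucose baseline),
#' an index of early-phase insulin secretion. Vectorised; elements with a
#' zero glucose increment yield NaN with an `glyrare_undefined_value`
#' warning, and missing inputs propagate as NA.
#'
#' @param ins0,ins30 insulin at 0 and 30 minutes (pmol/l)
#' @param glu0,glu30 glucose at 0 and 30 minutes (mmol/l)
#' @return numeric vector of index values
#' @export
insulinogenic_index <- function(ins0, ins30, glu0, glu30) {
  denom <- glu30 - glu0
  bad <- !is.na(denom) & denom == 0
  out <- (ins30 - ins0) / denom
  if (any(bad)) {
    out[bad] <- NaN
    glyrare_warn("glyrare_undefined_value",
                 "insulinogenic index undefined when glucose increment is zero")
  }
  out
}

#' OGTT record
#'
#' Time series of glucose and insulin during an oral glucose tolerance test.
#'
#' @param times minutes from glucose load, strictly increasing
#' @param glucose glucose per time point (mmol/l), or NULL
#' @param insulin insulin per time point (pmol/l), or NULL
#' @return an object of class `ogtt_record`
#' @export
ogtt_record <- function(times, glucose = NULL, insulin = NULL) {
  if (any(diff(times) <= 0))
    glyrare_stop("glyrare_bad_record", "OGTT times must be strictly increasing")
  for (v in list(glucose, insulin)) {
    if (!is.null(v)) {
      if (length(v) != length(times))
        glyrare_stop("glyrare_bad_record", "series length must match times")
      if (any(v < 0, na.rm = TRUE))
        glyrare_stop("glyrare_bad_record", "concentrations must be non-negative")
    }
  }
  structure(list(times = times, glucose = glucose, insulin = insulin),
            class = "ogtt_record")
}

#' Trapezoid area under an OGTT excursion curve
#'
#' Sum over adjacent time pairs of (t2 - t1) * (v1 + v2) / 2. Requires at
#' least three measured time points.
#'
#' @param record an [ogtt_record()]
#' @param series which series to integrate, "glucose" or "insulin"
#' @return area in concentration x minutes
#' @export
auc_trapezoid <- function(record, series = c("glucose", "insulin")) {
  series <- match.arg(series)
  v <- record[[series]]
  if (is.null(v))
    glyrare_stop("glyrare_bad_record", sprintf("record has no %s series", series))
  t <- record$times
  if (length(t) < 3)
    glyrare_stop("glyrare_too_few_points",
                 "AUC requires at least 3 OGTT time points")
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Incretin effect
#'
#' Relative augmentation of the insulin response after oral versus
#' intravenous glucose: (AUC_oral - AUC_iv) / AUC_oral.
#'
#' @param auc_ins_ogtt insulin AUC after oral glucose (pmol.min/l)
#' @param auc_ins_ivgtt insulin AUC after intravenous glucose (pmol.min/l)
#' @return fraction; NaN with a warning where the oral AUC is zero
#' @export
incretin_effect <- function(auc_ins_ogtt, auc_ins_ivgtt) {
  bad <- !is.na(auc_ins_ogtt) & auc_ins_ogtt == 0
  out <- (auc_ins_ogtt - auc_ins_ivgtt) / auc_ins_ogtt
  if (any(bad)) {
    out[bad] <- NaN
    glyrare_warn("glyrare_undefined_value",
                 "incretin effect undefined when the OGTT AUC is zero")
  }
  out
}

#' Adjust blood pressure for antihypertensive treatment
#'
#' Adds 15 mmHg to systolic and 10 mmHg to diastolic pressure for treated
#' individuals; untreated values pass through unchanged. The returned object
#' carries a `bp_meds_adjusted` attribute so a pipeline can guarantee the
#' adjustment is applied exactly once.
#'
#' @param sbp,dbp measured systolic / diastolic pressure (mmHg)
#' @param on_bp_meds logical vector, TRUE for treated individuals
#' @return data.frame with adjusted `sbp` and `dbp`
#' @export
adjust_bp_for_meds <- function(sbp, dbp, on_bp_meds) {
  if (isTRUE(attr(sbp, "bp_meds_adjusted")) || isTRUE(attr(dbp, "bp_meds_adjusted")))
    glyrare_stop("glyrare_double_adjustment",
                 "blood pressure values have already been medication-adjusted")
  out <- data.frame(sbp = sbp + ifelse(on_bp_meds, 15, 0),
                    dbp = dbp + ifelse(on_bp_meds, 10, 0))
  attr(out$sbp, "bp_meds_adjusted") <- TRUE
  attr(out$dbp, "bp_meds_adjusted") <- TRUE
  out
}

#' Transform a trait vector for association analysis
#'
#' Applies the configured transform (identity or natural log) and records it
#' in a `transform` attribute for provenance. Natural log requires strictly
#' positive values.
#'
#' @param values numeric trait vector (NAs propagate)
#' @param transform "none" or "log"
#' @return transformed vector with a `transform` attribute
#' @export
preprocess_trait <- function(values, transform = c("none", "log")) {
  transform <- match.arg(transform)
  out <- if (transform == "log") {
    if (any(values <= 0, na.rm = TRUE))
      glyrare_stop("glyrare_non_positive",
                   "natural-log transform requires strictly positive trait values")
    log(values)
  } else values
  attr(out, "transform") <- transform
  out
}
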