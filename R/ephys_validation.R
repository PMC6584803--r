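#' @title Electrophysiology validation
#' @description Membrane conductance from whole-cell current recordings,
#'   residual conductance after antibody application as a percentage of
#'   control, and concordance between motif-based selectivity predictions and
#'   measured inhibition.
#' @name ephys_validation
NULL

#' Construct a current recording
#'
#' @param time time, s.
#' @param voltage command voltage series, mV.
#' @param current whole-cell current series, pA.
#' @param condition `"control"` or `"antibody"`.
#' @return data.frame of class `cx_recording` with columns `time`, `voltage`,
#'   `current` and a `condition` attribute.
#' @export
cx_recording <- function(time, voltage, current, condition = c("control", "antibody")) {
  condition <- match.arg(condition)
  n <- length(time)
  if (length(voltage) != n || length(current) != n) stop("series lengths differ")
  out <- data.frame(time = time, voltage = voltage, current = current)
  attr(out, "condition") <- condition
  class(out) <- c("cx_recording", "data.frame")
  out
}

#' Read a recording from delimited text
#'
#' Expects columns `time` (s), `voltage` (mV), `current` (pA); any standard
#' delimiter accepted by [utils::read.table()] with `header = TRUE`.
#'
#' @param path file path.
#' @param condition condition label.
#' @param sep field separator (default tab).
#' @return a [cx_recording].
#' @export
read_recording <- function(path, condition = "control", sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("time", "voltage", "current")
  if (!all(need %in% names(d))) stop("recording lacks columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  cx_recording(d$time, d$voltage, d$current, condition)
}

#' Membrane conductance over a voltage-step window
#'
#' Mean current over the window divided by the command voltage (after
#' subtracting the zero-current potential), in nS (pA/mV). The command
#' voltage must be constant over the window. When a blocked-condition
#' recording is supplied (hemichannels blocked with divalent cations), its
#' conductance over the same window is subtracted as leak.
#'
#' @param rec a `cx_recording`.
#' @param step_window length-2 numeric, closed time interval in s (the
#'   depolarizing step, e.g. the +40 mV step).
#' @param v_rev zero-current (reversal) potential, mV (default 0).
#' @param leak_rec optional blocked-condition `cx_recording` for leak
#'   subtraction.
#' @return conductance, nS.
#' @export
membrane_conductance <- function(rec, step_window, v_rev = 0, leak_rec = NULL) {
  sel <- rec$time >= step_window[1] & rec$time <= step_window[2]
  if (!any(sel)) stop("step window lies outside the recording")
  v <- unique(rec$voltage[sel])
  if (length(v) != 1L) stop("command voltage not constant over the step window")
  dv <- v - v_rev
  if (dv == 0) stop("zero driving voltage over the step window")
  g <- mean(rec$current[sel]) / dv
  if (!is.null(leak_rec)) {
    g <- g - membrane_conductance(leak_rec, step_window, v_rev)
  }
  g
}

#' Residual conductance after antibody application
#'
#' `100 x G_post / G_pre`, both conductances measured on the same step window
#' with the same protocol. Scale-invariant: multiplying both recordings'
#' currents by a positive constant leaves the result unchanged.
#'
#' @param pre,post `cx_recording`s before/after antibody application.
#' @param step_window length-2 numeric, s.
#' @param v_rev reversal potential, mV.
#' @param leak_rec optional blocked-condition recording applied to both.
#' @return residual conductance, percent of control.
#' @export
residual_conductance <- function(pre, post, step_window, v_rev = 0, leak_rec = NULL) {
  vsel <- function(r) r$voltage[r$time >= step_window[1] & r$time <= step_window[2]]
  if (!identical(unique(vsel(pre)), unique(vsel(post)))) {
    stop("pre and post recordings use different voltage protocols over the window")
  }
  g_pre <- membrane_conductance(pre, step_window, v_rev, leak_rec)
  g_post <- membrane_conductance(post, step_window, v_rev, leak_rec)
  if (g_pre <= 0) stop("non-positive control conductance")
  100 * g_post / g_pre
}

#' Concordance between selectivity predictions and measured inhibition
#'
#' Joins motif-scan predictions with residual-conductance measurements by
#' isoform name (an explicit alias map handles naming discrepancies between
#' sources) and checks, per isoform, whether measured inhibition
#' (`residual < inhibition_cutoff`) agrees with the predicted class. Isoforms
#' present in only one input are listed under `unjoined`, never dropped
#' silently.
#'
#' @param calls a `cx_selectivity_table` (from [scan_family()]) or data.frame
#'   with `protein` and `predicted_class`.
#' @param records data.frame with `isoform` and `residual_pct` columns (e.g.
#'   [cx_conductance_table()]).
#' @param inhibition_cutoff residual-conductance cutoff in percent below
#'   which an isoform counts as inhibited (default 50; the measured values
#'   split bimodally at 16-25% vs 73-98%, so any cutoff between those bands
#'   gives the same classification).
#' @param aliases named character vector mapping record isoform names to
#'   prediction names (e.g. `c("hCx30.2/31.3" = "hCx30.2")`).
#' @return list of class `cx_concordance`: `table` (per-isoform data.frame),
#'   `concordant_fraction` (NA when the join is empty), `n_joined`,
#'   `unjoined` (list with `predictions_only`, `records_only`).
#' @export
concordance_report <- function(calls, records, inhibition_cutoff = 50,
                               aliases = NULL) {
  if (inhibition_cutoff < 0 || inhibition_cutoff > 100) stop("cutoff outside [0, 100]")
  preds <- data.frame(protein = calls$protein,
                      predicted_class = calls$predicted_class,
                      stringsAsFactors = FALSE)
  rec <- data.frame(isoform = records$isoform,
                    residual_pct = records$residual_pct,
                    stringsAsFactors = FALSE)
  rec$join_name <- rec$isoform
  if (!is.null(aliases)) {
    hit <- rec$isoform %in% names(aliases)
    rec$join_name[hit] <- unname(aliases[rec$isoform[hit]])
  }
  joined <- merge(rec, preds, by.x = "join_name", by.y = "protein")
  joined$measured_inhibited <- joined$residual_pct < inhibition_cutoff
  joined$predicted_inhibited <- joined$predicted_class == "inhibited"
  joined$concordant <- joined$measured_inhibited == joined$predicted_inhibited
  joined <- joined[order(joined$residual_pct), c("isoform", "join_name", "residual_pct",
                                                 "predicted_class", "measured_inhibited",
                                                 "predicted_inhibited", "concordant")]
  rownames(joined) <- NULL
  structure(list(
    table = joined,
    concordant_fraction = if (nrow(joined)) mean(joined$concordant) else NA_real_,
    n_joined = nrow(joined),
    n_concordant = sum(joined$concordant),
    inhibition_cutoff = inhibition_cutoff,
    unjoined = list(
      predictions_only = setdiff(preds$protein, joined$join_name),
      records_only = setdiff(rec$isoform, joined$isoform))),
    class = "cx_concordance")
}

#' @export
print.cx_concordance <- function(x, ...) {
  if (is.na(x$concordant_fraction)) {
    cat("Concordance: empty join, fraction undefined\n")
  } else {
    cat("Concordance:", x$n_concordant, "/", x$n_joined, "isoforms (cutoff",
        x$inhibition_cutoff, "%)\n")
  }
  if (length(x$unjoined$records_only) || length(x$unjoined$predictions_only)) {
    cat("unjoined - records:", paste(x$unjoined$records_only, collapse = ", "),
        "| predictions:", paste(x$unjoined$predictions_only, collapse = ", "), "\n")
  }
  invisible(x)
}
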