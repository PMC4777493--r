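#' Percentage of time below 90% oxygen saturation (T90)
#'
#' The fraction of SpO2 samples strictly below 90%, expressed as a
#' percentage of the studied time. T90 summarizes the degree of nocturnal
#' hypoxemia and enters the predictive models as a linear feature.
#'
#' @param spo2 An `osa_series` of saturations in [0, 100].
#' @return Percentage in [0, 100].
#' @export
t90 <- function(spo2) {
  stopifnot(inherits(spo2, "osa_series"))
  v <- spo2$values
  if (length(v) == 0) stop("empty SpO2 series", call. = FALSE)
  if (any(v < -1e-9 | v > 100 + 1e-9)) {
    stop("SpO2 values must lie in [0, 100]", call. = FALSE)
  }
  100 * sum(v < 90) / length(v)
}

#' Settings for whole-night feature extraction
#'
#' Defines the windowing and estimator scheme applied to every recording:
#' all analysis windows start one hour into the study; DFA uses 20 minutes
#' of flow, 80 minutes of quarter-rate flow (every 4th value kept) and 240
#' minutes of thoracic signal; the Lyapunov estimator uses 20-minute flow,
#' 80-minute quarter-rate flow and 170-minute thoracic windows; approximate
#' entropy is computed on the full recording block-averaged to
#' `apen_rate`; T90 uses the full SpO2 trace.
#'
#' @param window_start Offset of all analysis windows, seconds (default
#'   3600).
#' @param dfa_flow_min,dfa_flow2_min,dfa_thoracic_min DFA window lengths in
#'   minutes for the flow, quarter-rate flow and thoracic signals.
#' @param lle_flow_min,lle_flow2_min,lle_thoracic_min Lyapunov window
#'   lengths in minutes.
#' @param decimation Stride of the plain value-keeping decimation defining
#'   the `f2` family (default 4).
#' @param apen_rate Working rate for approximate entropy, Hz (default 1:
#'   breath-to-breath regularity survives block averaging to 1 Hz while an
#'   O(N^2) statistic on millions of raw samples would not run).
#' @param lle_rate_flow,lle_rate_thoracic Working rates for the Lyapunov
#'   estimator, Hz.
#' @param dfa_sign Either `"fast_minus_slow"` (default) or
#'   `"slow_minus_fast"`: the orientation of the dDFA difference
#'   parameters.
#' @param apen_subwindow_seconds Sub-window length for the ApEn high/low
#'   swing statistics.
#' @param lle_embed_dim Embedding dimension for respiratory signals.
#' @param breath_period Nominal breath duration, seconds; sets the Theiler
#'   window of the Lyapunov estimator to one mean breath.
#' @return A list of class `osa_feature_config`.
#' @export
feature_config <- function(window_start = 3600,
                           dfa_flow_min = 20, dfa_flow2_min = 80,
                           dfa_thoracic_min = 240,
                           lle_flow_min = 20, lle_flow2_min = 80,
                           lle_thoracic_min = 170,
                           decimation = 4,
                           apen_rate = 1,
                           lle_rate_flow = 2, lle_rate_thoracic = 1,
                           dfa_sign = c("fast_minus_slow", "slow_minus_fast"),
                           apen_subwindow_seconds = 300,
                           lle_embed_dim = 5,
                           breath_period = 4) {
  dfa_sign <- match.arg(dfa_sign)
  structure(as.list(environment()), class = "osa_feature_config")
}

# difference/mean pair with the exact round-trip identity
# X = m + d/2, Y = m - d/2
dm_pair <- function(X, Y) list(d = X - Y, m = (X + Y) / 2)

#' Extract the full per-subject feature vector
#'
#' Applies the whole windowing/estimator scheme of [feature_config()] to one
#' recording and assembles every derived parameter of the feature set:
#' per-signal DFA fast/slow exponents with their difference (`dDFA_*`) and
#' mean (`mDFA_*`); Lyapunov exponents for flow, quarter-rate flow and
#' thoracic windows with `dLLE`/`mLLE` (flow vs thoracic) and
#' `dLLE2`/`mLLE2` (quarter-rate flow vs thoracic); cross-signal
#' `dmDFA_t2 = mDFA_f2 - mDFA_t` and `mmDFA_t2 = (mDFA_f2 + mDFA_t) / 2`;
#' approximate-entropy swing statistics per signal with
#' `dAPEN = APEN_high + APEN_low` and `mAPEN = (APEN_high + APEN_low) / 2`;
#' and T90. Difference/mean pairs satisfy the exact identity
#' `X = m + d/2`, `Y = m - d/2`.
#'
#' @param rec A [sleep_recording()] long enough for the largest window after
#'   the one-hour offset.
#' @param demographics Optional list/row with `age`, `sex`, `bmi`,
#'   `epworth`; carried through into the feature vector.
#' @param config A [feature_config()].
#' @return Named list of class `osa_features`; the estimator settings are
#'   attached as attribute `"config"`.
#' @export
extract_features <- function(rec, demographics = NULL,
                             config = feature_config()) {
  stopifnot(inherits(rec, "sleep_recording"),
            inherits(config, "osa_feature_config"))
  cfg <- config
  need <- function(feature, channel, minutes) {
    avail <- series_duration(rec[[channel]])
    want <- cfg$window_start + minutes * 60
    if (want > avail + 1e-9) {
      stop(sprintf(
        "recording too short for %s: needs %.0f s of %s after the %.0f s offset, %.0f s available",
        feature, minutes * 60, channel, cfg$window_start, avail),
        call. = FALSE)
    }
  }
  need("DFA_f", "flow", cfg$dfa_flow_min)
  need("DFA_f2", "flow", cfg$dfa_flow2_min)   # same span after decimation
  need("DFA_t", "thoracic", cfg$dfa_thoracic_min)
  need("LLEf", "flow", cfg$lle_flow_min)
  need("LLEf2", "flow", cfg$lle_flow2_min)
  need("LLEt", "thoracic", cfg$lle_thoracic_min)

  flow2 <- decimate_keep_kth(rec$flow, cfg$decimation)

  dfa_f <- dfa(extract_window(rec$flow, cfg$window_start,
                              cfg$dfa_flow_min * 60))
  dfa_f2 <- dfa(extract_window(flow2, cfg$window_start,
                               cfg$dfa_flow2_min * 60))
  dfa_t <- dfa(extract_window(rec$thoracic, cfg$window_start,
                              cfg$dfa_thoracic_min * 60))

  theiler <- function(rate) max(1L, as.integer(round(cfg$breath_period * rate)))
  lle_for <- function(s, minutes, rate) {
    w <- extract_window(s, cfg$window_start, minutes * 60)
    rate <- min(rate, w$rate)
    lle_rosenstein(w, embed_dim = cfg$lle_embed_dim,
                   theiler_window = theiler(rate),
                   analysis_rate = rate)$lambda
  }
  LLEf <- lle_for(rec$flow, cfg$lle_flow_min, cfg$lle_rate_flow)
  LLEf2 <- lle_for(flow2, cfg$lle_flow2_min, cfg$lle_rate_flow)
  LLEt <- lle_for(rec$thoracic, cfg$lle_thoracic_min, cfg$lle_rate_thoracic)

  ap_f <- apen(resample_mean(rec$flow, min(cfg$apen_rate, rec$flow$rate)),
               subwindow_seconds = cfg$apen_subwindow_seconds)
  ap_t <- apen(resample_mean(rec$thoracic,
                             min(cfg$apen_rate, rec$thoracic$rate)),
               subwindow_seconds = cfg$apen_subwindow_seconds)

  ddfa <- function(res) {
    if (cfg$dfa_sign == "fast_minus_slow") dm_pair(res$alpha_fast, res$alpha_slow)
    else dm_pair(res$alpha_slow, res$alpha_fast)
  }
  p_f <- ddfa(dfa_f); p_f2 <- ddfa(dfa_f2); p_t <- ddfa(dfa_t)
  p_lle <- dm_pair(LLEf, LLEt)
  p_lle2 <- dm_pair(LLEf2, LLEt)
  p_t2 <- dm_pair(p_f2$m, p_t$m)

  fv <- list(
    LLEf = LLEf, LLEt = LLEt, dLLE = p_lle$d, mLLE = p_lle$m,
    LLEf2 = LLEf2, dLLE2 = p_lle2$d, mLLE2 = p_lle2$m,
    DFA_slow_f = dfa_f$alpha_slow, DFA_fast_f = dfa_f$alpha_fast,
    dDFA_f = p_f$d, mDFA_f = p_f$m,
    DFA_slow_f2 = dfa_f2$alpha_slow, DFA_fast_f2 = dfa_f2$alpha_fast,
    dDFA_f2 = p_f2$d, mDFA_f2 = p_f2$m,
    DFA_slow_t = dfa_t$alpha_slow, DFA_fast_t = dfa_t$alpha_fast,
    dDFA_t = p_t$d, mDFA_t = p_t$m,
    APEN_low_f = ap_f$apen_low, APEN_high_f = ap_f$apen_high,
    dAPEN_f = ap_f$apen_high + ap_f$apen_low,
    mAPEN_f = (ap_f$apen_high + ap_f$apen_low) / 2,
    APEN_low_t = ap_t$apen_low, APEN_high_t = ap_t$apen_high,
    dAPEN_t = ap_t$apen_high + ap_t$apen_low,
    mAPEN_t = (ap_t$apen_high + ap_t$apen_low) / 2,
    dmDFA_t2 = p_t2$d, mmDFA_t2 = p_t2$m,
    T90 = t90(rec$spo2)
  )
  for (dem in c("age", "sex", "bmi", "epworth")) {
    if (!is.null(demographics[[dem]])) fv[[dem]] <- demographics[[dem]]
  }
  structure(fv, class = "osa_features", config = cfg)
}

#' @export
print.osa_features <- function(x, ...) {
  cat("<osa_features>\n")
  num <- vapply(x, is.numeric, TRUE)
  print(round(unlist(x[num]), 4))
  invisible(x)
}

# display names used in the CSV contract (spaces in the DFA/APEN columns)
feature_display_names <- c(
  DFA_slow_f = "DFA slow_f", DFA_fast_f = "DFA fast_f",
  DFA_slow_f2 = "DFA slow_f2", DFA_fast_f2 = "DFA fast_f2",
  DFA_slow_t = "DFA slow_t", DFA_fast_t = "DFA fast_t",
  APEN_low_f = "APEN low_f", APEN_high_f = "APEN high_f",
  APEN_low_t = "APEN low_t", APEN_high_t = "APEN high_t",
  dmDFA_t2 = "dmDFAt2", mmDFA_t2 = "mmDFAt2"
)

#' Assemble a per-subject feature table
#'
#' Runs [extract_features()] over a cohort (as returned by
#' [generate_cohort()] with `signals = TRUE`) and binds the results with the
#' subject demographics and ground truth into one data frame, one row per
#' subject.
#'
#' @param cohort List with `subjects` and `recordings` as produced by
#'   [generate_cohort()].
#' @param config A [feature_config()].
#' @return Data frame with demographics, `ahi_true`, `ai`, `hi`, `severity`
#'   and all feature columns.
#' @export
feature_table <- function(cohort, config = feature_config()) {
  stopifnot(is.list(cohort), !is.null(cohort$subjects),
            !is.null(cohort$recordings))
  rows <- lapply(seq_len(nrow(cohort$subjects)), function(i) {
    fv <- extract_features(cohort$recordings[[i]], config = config)
    as.data.frame(fv[vapply(fv, function(v) length(v) == 1, TRUE)],
                  check.names = TRUE)
  })
  cbind(cohort$subjects, do.call(rbind, rows))
}

#' Write a feature table as CSV with a JSON settings sidecar
#'
#' Columns carry the field's display names (e.g. `DFA slow_f`,
#' `APEN high_t`, `mmDFAt2`); the estimator settings used to produce the
#' table are written alongside as `<path>.settings.json` for provenance.
#'
#' @param tab Data frame from [feature_table()].
#' @param path Output CSV path.
#' @param config The [feature_config()] that produced `tab`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tab, path, config = feature_config()) {
  out <- tab
  nm <- names(out)
  hit <- nm %in% names(feature_display_names)
  nm[hit] <- feature_display_names[nm[hit]]
  names(out) <- nm
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(unclass(config), paste0(path, ".settings.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a per-subject feature/demographics table
#'
#' Reads a CSV written by [write_feature_table()] (or any table using the
#' same column contract) back into syntactic column names.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  nm <- names(tab)
  rev_map <- stats::setNames(names(feature_display_names),
                             feature_display_names)
  hit <- nm %in% names(rev_map)
  nm[hit] <- rev_map[nm[hit]]
  names(tab) <- nm
  tab
}
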