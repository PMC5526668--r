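# Trajectory classification: rescue calls, fluorescence phenotypes, transient
# amplification signatures, final YFP/CFP ratios, amplification-timing rule.

#' Analysis configuration for trajectory classification
#'
#' Thresholds governing the classification of plate-reader trajectories.
#' `od_threshold` (OD_t) separates growing from extinct cultures and gates
#' fluorescence normalization; `fold_threshold` is the fold increase over the
#' ancestral OD-normalized fluorescence above which a channel is called
#' elevated (the default corresponds to the lowest fluorescence increase that
#' was still sufficient for rescue); the stringent criteria (`stringent_min_days`
#' days with fold above threshold at OD above `stringent_od_min`) protect
#' transient calls in extinct wells from low-OD noise.
#'
#' @param od_threshold OD600 threshold OD_t (plate-reader units), default 0.075.
#' @param fold_threshold fold-increase threshold over ancestor, default 2.77.
#' @param stringent_min_days minimum qualifying days for a transient call,
#'   default 2.
#' @param stringent_od_min minimum OD600 on qualifying days, default 0.3.
#' @param final_day day of the endpoint measurement; `NA` = last day present.
#' @param timing_rel_sd_tol relative-SD tolerance for the "high and flat"
#'   YFP/CFP timing rule, default 0.25.
#' @param timing_step_fold minimum late/early mean ratio for a mid-experiment
#'   step in the timing rule, default 2.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(od_threshold = 0.075, fold_threshold = 2.77,
                            stringent_min_days = 2L, stringent_od_min = 0.3,
                            final_day = NA, timing_rel_sd_tol = 0.25,
                            timing_step_fold = 2) {
  stopifnot(od_threshold > 0, fold_threshold > 0, stringent_min_days >= 1,
            stringent_od_min > 0)
  structure(list(od_threshold = od_threshold, fold_threshold = fold_threshold,
                 stringent_min_days = as.integer(stringent_min_days),
                 stringent_od_min = stringent_od_min, final_day = final_day,
                 timing_rel_sd_tol = timing_rel_sd_tol,
                 timing_step_fold = timing_step_fold),
            class = "analysis_config")
}

#' OD-normalize a fluorescence trajectory
#'
#' Fluorescence is divided by OD600 and set to exactly zero on days where
#' OD600 fell below `od_threshold` (strictly below: a reading exactly at the
#' threshold is normalized, not zeroed).
#'
#' @param series single-well plate data (columns `day`, `od600`, `yfp`, `cfp`).
#' @param cfg an [analysis_config()].
#' @return data.frame with `day`, `od600`, `norm_yfp`, `norm_cfp`.
#' @export
normalize_trajectory <- function(series, cfg = analysis_config()) {
  s <- as.data.frame(series)[, c("day", "od600", "yfp", "cfp")]
  s <- s[order(s$day), , drop = FALSE]
  suppress <- s$od600 < cfg$od_threshold
  data.frame(day = s$day, od600 = s$od600,
             norm_yfp = ifelse(suppress, 0, s$yfp / s$od600),
             norm_cfp = ifelse(suppress, 0, s$cfp / s$od600))
}

#' Ancestral fluorescence reference
#'
#' Arithmetic mean of OD-normalized YFP and CFP over replicate wells of the
#' unselected ancestor (single 24 h endpoint reading per well). Wells below
#' the OD threshold are dropped; if all are, no reference is definable.
#'
#' @param ancestor_wells data.frame with `od600`, `yfp`, `cfp` (one row per
#'   well).
#' @param cfg an [analysis_config()].
#' @return list of class `ancestral_reference` with `mean_norm_yfp`,
#'   `mean_norm_cfp`, `n_wells`.
#' @export
ancestral_reference <- function(ancestor_wells, cfg = analysis_config()) {
  w <- as.data.frame(ancestor_wells)
  if ("yfp_raw" %in% names(w)) names(w)[names(w) == "yfp_raw"] <- "yfp"
  if ("cfp_raw" %in% names(w)) names(w)[names(w) == "cfp_raw"] <- "cfp"
  keep <- w$od600 >= cfg$od_threshold
  if (!any(keep))
    stop("no ancestor well reached the OD threshold; reference undefined")
  w <- w[keep, , drop = FALSE]
  structure(list(mean_norm_yfp = mean(w$yfp / w$od600),
                 mean_norm_cfp = mean(w$cfp / w$od600),
                 n_wells = nrow(w)),
            class = "ancestral_reference")
}

final_day_of <- function(series, cfg) {
  if (is.na(cfg$final_day)) max(series$day) else as.integer(cfg$final_day)
}

#' Rescue classification
#'
#' A population is rescued if its OD600 strictly exceeds the OD threshold at
#' the end of the experiment; only the final day matters (transient dips below
#' threshold mid-experiment do not disqualify).
#'
#' @param series single-well plate data.
#' @param cfg an [analysis_config()].
#' @return logical flag.
#' @export
classify_rescue <- function(series, cfg = analysis_config()) {
  s <- as.data.frame(series)
  fd <- final_day_of(s, cfg)
  od <- s$od600[s$day == fd]
  if (length(od) != 1L) stop("final day ", fd, " missing or duplicated")
  od > cfg$od_threshold
}

#' Endpoint fluorescence-phenotype call
#'
#' For a rescued well, each channel is called elevated when the fold increase
#' of its final-day OD-normalized fluorescence over the ancestral reference
#' strictly exceeds the fold threshold. YFP-only elevation indicates an
#' expression up-mutation; joint YFP+CFP elevation indicates reporter-cassette
#' amplification.
#'
#' @param traj output of [normalize_trajectory()].
#' @param ref an [ancestral_reference()].
#' @param cfg an [analysis_config()].
#' @return list with `yfp_elevated`, `cfp_elevated`, `fold_yfp`, `fold_cfp`,
#'   and the combined `phenotype` label (`"YFP"`, `"YFP+CFP"`, `"none"`).
#' @export
classify_phenotype <- function(traj, ref, cfg = analysis_config()) {
  if (ref$mean_norm_yfp <= 0 || ref$mean_norm_cfp <= 0)
    stop("ancestral reference mean is zero; fold increase undefined")
  fd <- final_day_of(traj, cfg)
  row <- traj[traj$day == fd, , drop = FALSE]
  fold_yfp <- row$norm_yfp / ref$mean_norm_yfp
  fold_cfp <- row$norm_cfp / ref$mean_norm_cfp
  yfp_el <- fold_yfp > cfg$fold_threshold
  cfp_el <- fold_cfp > cfg$fold_threshold
  phenotype <- if (yfp_el && cfp_el) "YFP+CFP" else if (yfp_el) "YFP" else "none"
  list(yfp_elevated = yfp_el, cfp_elevated = cfp_el,
       fold_yfp = fold_yfp, fold_cfp = fold_cfp, phenotype = phenotype)
}

#' Stringent transient-elevation detection
#'
#' A channel shows transient elevation when on at least `stringent_min_days`
#' days the fold increase over the ancestor strictly exceeded the fold
#' threshold while OD600 strictly exceeded `stringent_od_min`. Used to find
#' populations that went extinct despite elevated fluorescence while excluding
#' false positives from noisy low-OD normalization.
#'
#' @param traj output of [normalize_trajectory()].
#' @param ref an [ancestral_reference()].
#' @param cfg an [analysis_config()].
#' @param channel `"yfp"` or `"cfp"`.
#' @return logical flag.
#' @export
detect_transient_elevation <- function(traj, ref, cfg = analysis_config(),
                                       channel = c("cfp", "yfp")) {
  channel <- match.arg(channel)
  norm <- traj[[paste0("norm_", channel)]]
  refmean <- if (channel == "yfp") ref$mean_norm_yfp else ref$mean_norm_cfp
  qual <- (norm / refmean > cfg$fold_threshold) & (traj$od600 > cfg$stringent_od_min)
  sum(qual) >= cfg$stringent_min_days
}

#' Amplification flag for cost analysis
#'
#' Counts a well as carrying a (transient) amplification for the
#' extinction-risk cost analysis: extinct wells qualify through the stringent
#' transient CFP criteria; rescued wells qualify through either endpoint CFP
#' elevation or the stringent transient criteria (a rescued well whose CFP
#' fold dropped back below threshold by the final day still counts here,
#' though not in endpoint phenotype tallies).
#'
#' @param rescued logical rescue flag.
#' @param cfp_elevated endpoint CFP elevation flag (rescued wells).
#' @param transient_cfp stringent transient CFP flag.
#' @return logical flag.
#' @export
amplified_for_cost <- function(rescued, cfp_elevated, transient_cfp) {
  if (rescued) isTRUE(cfp_elevated) || isTRUE(transient_cfp) else isTRUE(transient_cfp)
}

#' Final YFP/CFP ratio
#'
#' Ratio of raw (not OD-normalized) final-day fluorescence readings, in
#' internal plate-reader units. Elevated final ratios among rescued
#' amplifications indicate costly amplifications rescued in combination with
#' additional expression-increasing mutations.
#'
#' @param series single-well plate data.
#' @param cfg an [analysis_config()].
#' @return numeric ratio, or `NA` when the final CFP reading is zero.
#' @export
final_ratio <- function(series, cfg = analysis_config()) {
  s <- as.data.frame(series)
  fd <- final_day_of(s, cfg)
  row <- s[s$day == fd, , drop = FALSE]
  if (nrow(row) != 1L) stop("final day ", fd, " missing or duplicated")
  if (row$cfp == 0) return(NA_real_)
  row$yfp / row$cfp
}

#' Infer amplification timing from the YFP/CFP ratio trajectory
#'
#' When an amplification co-occurs with another expression-increasing
#' mutation, the per-day YFP/CFP ratio indicates their order: a ratio that is
#' high (above the plate median) and flat (relative SD below tolerance)
#' throughout means the amplification expanded only after the other mutation
#' (`amplification_second`); a sustained upward step at an intermediate
#' timepoint means the amplification came first (`amplification_first`).
#' Fewer than 4 valid days, or neither pattern, gives `indeterminate`.
#'
#' @param ratios per-day YFP/CFP ratios on days with OD at or above OD_t.
#' @param plate_median plate-level median final ratio used as the "high"
#'   reference level.
#' @param cfg an [analysis_config()].
#' @return one of `"amplification_first"`, `"amplification_second"`,
#'   `"indeterminate"`.
#' @export
infer_amplification_timing <- function(ratios, plate_median,
                                       cfg = analysis_config()) {
  r <- ratios[is.finite(ratios)]
  if (length(r) < 4L) return("indeterminate")
  m <- mean(r)
  if (m > plate_median && stats::sd(r) / m < cfg$timing_rel_sd_tol)
    return("amplification_second")
  # sustained step: best split with >= 2 days after, late mean >> early mean
  best <- 0
  for (k in 2:(length(r) - 2L)) {
    early <- mean(r[1:k]); late <- mean(r[(k + 1L):length(r)])
    if (early > 0 && late / early > best) best <- late / early
  }
  if (best > cfg$timing_step_fold) return("amplification_first")
  "indeterminate"
}

#' Flag amplified colony spots from fluorescence intensity
#'
#' Spot-intensity thresholding for single-step plating experiments: a spot is
#' flagged as carrying an amplification when its CFP intensity strictly
#' exceeds six times the mean intensity of all ancestor spots (default rule),
#' or, under the alternative rule, the ancestor mean plus six ancestor
#' standard deviations.
#'
#' @param spot_means numeric spot intensities.
#' @param ancestor_means numeric ancestor-spot intensities (at least 2).
#' @param rule `"fold"` (default, 6 x mean) or `"sd"` (mean + 6 SD).
#' @param factor multiplier, default 6.
#' @return logical vector parallel to `spot_means`.
#' @export
classify_spot_amplification <- function(spot_means, ancestor_means,
                                        rule = c("fold", "sd"), factor = 6) {
  rule <- match.arg(rule)
  if (length(ancestor_means) < 2L)
    stop("need at least 2 ancestor spots")
  thr <- if (rule == "fold") factor * mean(ancestor_means)
         else mean(ancestor_means) + factor * stats::sd(ancestor_means)
  spot_means > thr
}

#' Classify every well of a plate dataset
#'
#' Runs the full per-well pipeline: rescue call, endpoint phenotype, stringent
#' transient flags, cost-analysis amplification flag, final raw YFP/CFP ratio,
#' and the amplification-timing label for wells with a defined ratio
#' trajectory.
#'
#' @param plates a `plate_series` table ([read_plate_csv()]).
#' @param ref an [ancestral_reference()].
#' @param cfg an [analysis_config()].
#' @return data.frame with one row per (plate_id, well).
#' @export
classify_plate <- function(plates, ref, cfg = analysis_config()) {
  dt <- data.table::as.data.table(plates)
  wells <- unique(dt[, .(plate_id, well)])
  res <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    s <- dt[.(wells$plate_id[i], wells$well[i])]
    traj <- normalize_trajectory(s, cfg)
    rescued <- classify_rescue(s, cfg)
    ph <- classify_phenotype(traj, ref, cfg)
    t_yfp <- detect_transient_elevation(traj, ref, cfg, "yfp")
    t_cfp <- detect_transient_elevation(traj, ref, cfg, "cfp")
    res[[i]] <- data.frame(
      plate_id = wells$plate_id[i], well = wells$well[i],
      rescued = rescued,
      phenotype = if (rescued) ph$phenotype else "extinct",
      yfp_elevated = rescued && ph$yfp_elevated,
      cfp_elevated = rescued && ph$cfp_elevated,
      transient_yfp = t_yfp, transient_cfp = t_cfp,
      amplified_for_cost = amplified_for_cost(rescued, rescued && ph$cfp_elevated, t_cfp),
      final_ratio = final_ratio(s, cfg),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, res)
  # timing labels need the plate-level median final ratio as reference
  med <- stats::median(calls$final_ratio, na.rm = TRUE)
  timing <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    s <- dt[.(calls$plate_id[i], calls$well[i])]
    valid <- s$od600 >= cfg$od_threshold & s$cfp > 0
    timing[i] <- infer_amplification_timing(
      (s$yfp / s$cfp)[valid], plate_median = med, cfg = cfg)
  }
  calls$timing <- timing
  calls
}
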