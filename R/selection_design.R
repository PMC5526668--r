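# Quantitative design of the selection experiment: MIC determination,
# geometric drug schedule, generations under serial dilution.

#' Minimum inhibitory concentration from a replicate OD matrix
#'
#' The MIC is the lowest tested drug concentration at which OD600 after 24 h
#' is at or below `od_threshold` in every replicate (non-strict `<=`, so a
#' replicate reading exactly at the threshold still counts as inhibited).
#'
#' @param replicate_od numeric matrix, replicates x concentrations.
#' @param concentrations ascending tested concentrations (ug/mL), one per
#'   column.
#' @param od_threshold OD600 growth threshold, default 0.075.
#' @return list of class `mic_result` with `mic`, `tested_concentrations`,
#'   `replicate_od`.
#' @export
compute_mic <- function(replicate_od, concentrations, od_threshold = 0.075) {
  replicate_od <- as.matrix(replicate_od)
  if (ncol(replicate_od) != length(concentrations))
    stop("one OD column per tested concentration required")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly ascending")
  inhibited <- apply(replicate_od <= od_threshold, 2L, all)
  if (!any(inhibited))
    stop("no tested concentration inhibited all replicates (max tested: ",
         max(concentrations), ")")
  structure(list(mic = concentrations[which(inhibited)[1]],
                 tested_concentrations = concentrations,
                 replicate_od = replicate_od),
            class = "mic_result")
}

#' Geometric drug-concentration schedule
#'
#' Daily concentrations start at `start_fraction` of the strain-specific MIC
#' and increase geometrically so that the final-day concentration is
#' `total_fold` times the initial one: with `days` days there are `days - 1`
#' multiplicative steps, so the daily multiplier is
#' `total_fold^(1/(days - 1))`.
#'
#' @param mic strain-specific MIC (ug/mL).
#' @param days experiment length, default 10.
#' @param start_fraction day-1 concentration as fraction of MIC, default 0.5.
#' @param total_fold final/initial concentration ratio, default 10.
#' @return data.frame of class `schedule` with `day`, `concentration`,
#'   `relative_concentration` (multiples of MIC).
#' @export
make_schedule <- function(mic, days = 10L, start_fraction = 0.5,
                          total_fold = 10) {
  stopifnot(mic > 0, days >= 1)
  days <- as.integer(days)
  conc <- if (days == 1L) start_fraction * mic
          else start_fraction * mic * total_fold^((seq_len(days) - 1) / (days - 1))
  structure(data.frame(day = seq_len(days), concentration = conc,
                       relative_concentration = conc / mic),
            class = c("schedule", "data.frame"))
}

#' Maximum generations under daily serial dilution
#'
#' With daily regrowth to the same saturation density, the daily dilution
#' factor bounds the number of doublings per day at `log2(dilution_factor)`,
#' so the experiment-wide maximum is `days * log2(dilution_factor)`.
#'
#' @param dilution_factor daily dilution factor (e.g. 820 for 1:820).
#' @param days number of growth days, default 10.
#' @return list with `generations` (1 decimal) and `rounded` (integer).
#' @export
max_generations <- function(dilution_factor = 820, days = 10L) {
  stopifnot(dilution_factor > 1, days >= 1)
  g <- days * log2(dilution_factor)
  list(generations = round(g, 1), rounded = round(g))
}
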