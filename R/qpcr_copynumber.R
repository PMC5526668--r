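# Efficiency-corrected delta-delta-Cq copy-number quantification.

#' Copy number by efficiency-corrected delta-delta-Cq
#'
#' Relative copy number of the target locus in a sample versus an ancestral
#' calibrator, normalized to a reference locus:
#' \deqn{N = \frac{(1+E_t)^{Cq_{t,anc} - Cq_{t,sample}}}
#'              {(1+E_r)^{Cq_{r,anc} - Cq_{r,sample}}}}
#' where efficiencies `E` are fractions in (0, 1]; `E = 1` (100%) recovers the
#' classical `2^-ddCq`. The calibrator itself maps to `N = 1` by construction.
#'
#' @param sample list/row with `cq_target`, `cq_reference`,
#'   `efficiency_target`, `efficiency_reference`.
#' @param ancestor same fields for the ancestral calibrator (efficiencies are
#'   per-assay; the target/reference efficiencies of `sample` are used).
#' @return list of class `copy_number_estimate` with `copy_number`.
#' @export
copy_number_ddcq <- function(sample, ancestor) {
  et <- sample$efficiency_target
  er <- sample$efficiency_reference
  if (!is.finite(et) || et <= 0 || et > 1 || !is.finite(er) || er <= 0 || er > 1)
    stop("efficiencies must be fractions in (0, 1]")
  dcq_t <- ancestor$cq_target - sample$cq_target
  dcq_r <- ancestor$cq_reference - sample$cq_reference
  n <- (1 + et)^dcq_t / (1 + er)^dcq_r
  structure(list(copy_number = n, dcq_target = dcq_t, dcq_reference = dcq_r),
            class = "copy_number_estimate")
}

#' Aggregate technical qPCR replicates and estimate copy numbers
#'
#' Technical replicates are aggregated by mean Cq before applying the
#' delta-delta-Cq formula; the replicate SD of the copy number is propagated
#' by the first-order delta method, treating target and reference Cq means as
#' independent:
#' `sd(N) = N * sqrt((ln(1+E_t) * se_t)^2 + (ln(1+E_r) * se_r)^2)`,
#' with `se` the standard error of the replicate mean Cq of sample and
#' calibrator combined in quadrature.
#'
#' @param cq_table long table from [read_qpcr_csv()] (`sample_id`, `assay`,
#'   `cq`, `efficiency`).
#' @param calibrator `sample_id` of the ancestral calibrator.
#' @return data.frame with `sample_id`, `copy_number`, `replicate_sd`.
#' @export
copy_number_table <- function(cq_table, calibrator) {
  dt <- data.table::as.data.table(cq_table)
  if (!calibrator %in% dt$sample_id)
    stop("calibrator sample '", calibrator, "' not in table")
  agg <- dt[, .(cq = mean(cq), se = stats::sd(cq) / sqrt(.N),
                efficiency = efficiency[1]),
            by = .(sample_id, assay)]
  agg[is.na(se), se := 0]
  rec <- function(id) {
    t <- agg[sample_id == id & assay == "target"]
    r <- agg[sample_id == id & assay == "reference"]
    if (nrow(t) != 1L || nrow(r) != 1L)
      stop("sample '", id, "' needs one target and one reference assay")
    list(cq_target = t$cq, cq_reference = r$cq,
         se_target = t$se, se_reference = r$se,
         efficiency_target = t$efficiency, efficiency_reference = r$efficiency)
  }
  anc <- rec(calibrator)
  ids <- setdiff(unique(dt$sample_id), calibrator)
  out <- lapply(c(calibrator, ids), function(id) {
    s <- rec(id)
    est <- copy_number_ddcq(s, anc)
    se_t <- sqrt(s$se_target^2 + anc$se_target^2)
    se_r <- sqrt(s$se_reference^2 + anc$se_reference^2)
    sdn <- est$copy_number * sqrt((log(1 + s$efficiency_target) * se_t)^2 +
                                  (log(1 + s$efficiency_reference) * se_r)^2)
    data.frame(sample_id = id, copy_number = est$copy_number,
               replicate_sd = if (id == calibrator) 0 else sdn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlate qPCR copy number with final CFP fluorescence
#'
#' Pearson correlation with a two-sided t-based p-value, validating
#' constitutive CFP fluorescence as a proxy for reporter-cassette copy number.
#'
#' @param copies numeric copy numbers.
#' @param cfp_final paired final CFP fluorescence values.
#' @return list with `r` and `p_value`.
#' @export
correlate_copy_cfp <- function(copies, cfp_final) {
  pearson_correlation(copies, cfp_final)
}
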