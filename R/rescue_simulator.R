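# Stochastic serial-transfer evolutionary-rescue simulator. Generates plate
# datasets (OD600/YFP/CFP per well per day) with known per-well ground truth,
# plus annotated toy genomes with planted neighborhoods for the
# neighborhood-map module.

#' Scenario presets for the rescue simulator
#'
#' Each preset encodes the neighborhood properties of one reporter-cassette
#' integration locus: whether homologous flanking sequence elevates the
#' duplication rate, the relative length of the would-be amplicon (which
#' scales the per-copy amplification cost), and whether promoter co-option
#' mutations (deletion capture or terminator read-through) are available.
#' `B` and `E` sit between flanking duplicates; `E` has the shortest amplicon
#' and hence the cheapest amplifications; `BdIS5I` lacks the homology but
#' would amplify over a longer, costlier segment; `A` and `C` have neither
#' homology nor co-option routes; `D` has co-option but no homology.
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"BdIS5I"`.
#' @return list of class `scenario_preset`.
#' @export
scenario_preset <- function(name = c("A", "B", "C", "D", "E", "BdIS5I")) {
  name <- match.arg(name)
  p <- switch(name,
    A      = list(flanking_homology = FALSE, amplicon_len_factor = 1.5,  cooption_available = FALSE),
    B      = list(flanking_homology = TRUE,  amplicon_len_factor = 0.35, cooption_available = TRUE),
    C      = list(flanking_homology = FALSE, amplicon_len_factor = 1.5,  cooption_available = FALSE),
    D      = list(flanking_homology = FALSE, amplicon_len_factor = 1.5,  cooption_available = TRUE),
    E      = list(flanking_homology = TRUE,  amplicon_len_factor = 0.11, cooption_available = FALSE),
    BdIS5I = list(flanking_homology = FALSE, amplicon_len_factor = 2.0,  cooption_available = TRUE))
  p$name <- name
  p$baseline_expression <- 1
  structure(p, class = "scenario_preset")
}

#' Simulator parameters
#'
#' Defaults describe a 95-well, 10-day serial-transfer rescue experiment:
#' daily 1:820 dilution from saturation (~2e8 cells), up to 24 clone-level
#' doublings per day for an uninhibited lineage below carrying capacity
#' (population-level generations remain dilution-limited at ~log2(820)/day;
#' net daily growth of a lineage requires a fitness cost below
#' `1 - log2(820)/24 ~ 0.6`), a bacteriostatic threshold drug model (a
#' lineage grows on a day iff its expression multiple of the selected gene is
#' at least the day's drug concentration in MIC multiples, otherwise it is
#' static and only diluted), per-division mutation rates for each mutation
#' type, a biased random walk on amplification copy number, and multiplicative
#' lognormal measurement noise per channel. Mutation rates and expression
#' effects are synthetic calibrations chosen to reproduce qualitative regime
#' orderings, not measured values.
#'
#' @param ... overrides for any default field.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(...) {
  p <- list(
    n_wells = 95L, days = 10L, dilution = 820, capacity = 2e8,
    max_doublings = 24,
    # per-division rates
    rate_point = 2e-10, rate_is = 2e-10, rate_cooption = 1.5e-9,
    duplication_rate_homology = 1e-5, duplication_rate_base = 1e-9,
    secondary_rate = 2e-9,
    # amplification copy-number walk
    amp_step_up = 0.8, amp_step_down = 0.02,
    # fitness costs
    c_amp = 0.1, cost_point = 0.01, cost_is = 0.01, cost_cooption = 0.03,
    cost_secondary = 0.01,
    # expression multiples of ancestral leaky expression
    expr_point = 6, expr_is = 5, expr_cooption = 8, expr_secondary = 6,
    # readout model
    od_at_capacity = 0.9, od_floor = 0.02, yfp_per_od = 100, cfp_per_od = 100,
    noise_sd = 0.1, od_noise_sd = 0.03, autofluor = 1.0)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown sim parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  structure(p, class = "sim_params")
}

lineage_expression <- function(lin, p) {
  # expression multiple of the selected gene for each lineage row
  e <- rep(1, nrow(lin))
  e[lin$label == "point"] <- p$expr_point
  e[lin$label == "is_insertion"] <- p$expr_is
  e[lin$label == "cooption"] <- p$expr_cooption
  amp <- lin$label == "amplified"
  e[amp] <- lin$k[amp] * ifelse(lin$secondary[amp], p$expr_secondary, 1)
  e
}

lineage_cost <- function(lin, p, preset) {
  cost <- rep(0, nrow(lin))
  cost[lin$label == "point"] <- p$cost_point
  cost[lin$label == "is_insertion"] <- p$cost_is
  cost[lin$label == "cooption"] <- p$cost_cooption
  amp <- lin$label == "amplified"
  cost[amp] <- pmin(0.95, p$c_amp * (lin$k[amp] - 1) * preset$amplicon_len_factor +
                      ifelse(lin$secondary[amp], p$cost_secondary, 0))
  cost
}

new_lineage <- function(label, k, secondary, n) {
  data.frame(label = label, k = as.integer(k), secondary = secondary,
             N = as.numeric(n), stringsAsFactors = FALSE)
}

# founding size of a lineage born during a day's growth: a mutant arising at
# a uniformly random division depth expands for the rest of the day
# (Luria-Delbrueck jackpot flavor)
mutant_founding_size <- function(n_events, doublings) {
  if (n_events == 0L) return(numeric(0))
  floor(2^(stats::runif(n_events, 0, doublings)))
}

#' Simulate one well of a rescue experiment
#'
#' Daily cycle: binomial 1:`dilution` bottleneck, threshold-model growth or
#' stasis for each lineage under the day's drug concentration (with fitness
#' costs reducing the number of doublings), Poisson mutation events with
#' jackpot founding sizes, a biased random walk on amplification copy number
#' (copy number never drops below 1), then an endpoint readout: OD
#' proportional to total cells, YFP to expression-weighted cells, CFP to
#' copy-number-weighted cells, each with multiplicative lognormal noise and a
#' small additive floor.
#'
#' @param params a [sim_params()].
#' @param preset a [scenario_preset()].
#' @param schedule a [make_schedule()] schedule with `params$days` rows.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param plate_id,well labels for the emitted series.
#' @return list with `series` (day, od600, yfp, cfp data.frame) and `truth`
#'   (rescued flag, dominant lineage label, final/max copy number, final
#'   expression multiple of the dominant lineage).
#' @export
simulate_well <- function(params, preset, schedule, seed,
                          plate_id = "sim", well = "A01") {
  p <- params
  if (nrow(schedule) != p$days)
    stop("schedule length (", nrow(schedule), ") != days (", p$days, ")")
  set.seed(as.integer(seed))
  dup_rate <- if (preset$flanking_homology) p$duplication_rate_homology
              else p$duplication_rate_base
  lin <- new_lineage("ancestral", 1L, FALSE, round(p$capacity / p$dilution))
  out <- data.frame(day = integer(0), od600 = numeric(0), yfp = numeric(0),
                    cfp = numeric(0))
  truth_rescued <- FALSE; dom_label <- "ancestral"; dom_e <- 1
  kmax <- 1L; dom_k <- 1L
  od_true_final <- 0; yfp_fold_true <- 0; cfp_fold_true <- 0
  for (d in seq_len(p$days)) {
    rc <- schedule$relative_concentration[d]
    e <- lineage_expression(lin, p) * preset$baseline_expression
    cost <- lineage_cost(lin, p, preset)
    grows <- e >= rc & cost < 1
    fold <- ifelse(grows, 2^(p$max_doublings * (1 - cost)), 1)
    target <- lin$N * fold
    tot <- sum(target)
    if (tot > p$capacity) target <- target * (p$capacity / tot)
    divisions <- pmax(0, target - lin$N)
    # mutation events on the ancestral background
    anc <- which(lin$label == "ancestral")
    newlin <- list()
    if (length(anc) == 1L && divisions[anc] > 0) {
      dgrow <- p$max_doublings * (1 - cost[anc])
      spawn <- function(rate, label, k = 1L, secondary = FALSE) {
        nev <- stats::rpois(1L, rate * divisions[anc])
        if (nev > 0L) {
          sizes <- mutant_founding_size(nev, dgrow)
          sizes <- sizes[sizes >= 1]
          if (length(sizes))
            newlin[[length(newlin) + 1L]] <<-
              new_lineage(label, k, secondary, sum(sizes))
        }
      }
      spawn(p$rate_point, "point")
      spawn(p$rate_is, "is_insertion")
      if (preset$cooption_available) spawn(p$rate_cooption, "cooption")
      spawn(dup_rate, "amplified", k = 2L)
    }
    # secondary expression mutations on amplified backgrounds
    for (i in which(lin$label == "amplified" & !lin$secondary)) {
      if (divisions[i] <= 0) next
      nev <- stats::rpois(1L, p$secondary_rate * divisions[i])
      if (nev > 0L) {
        sizes <- mutant_founding_size(nev, p$max_doublings * (1 - cost[i]))
        sizes <- sizes[sizes >= 1]
        if (length(sizes))
          newlin[[length(newlin) + 1L]] <-
            new_lineage("amplified", lin$k[i], TRUE, sum(sizes))
      }
    }
    lin$N <- target
    if (length(newlin)) lin <- rbind(lin, do.call(rbind, newlin))
    # copy-number random walk under selection pressure
    amp <- which(lin$label == "amplified" & lin$N >= 1)
    for (i in amp) {
      e_i <- lin$k[i] * ifelse(lin$secondary[i], p$expr_secondary, 1)
      if (e_i < 1.5 * rc) {
        if (stats::runif(1) < p$amp_step_up) lin$k[i] <- lin$k[i] + 1L
      } else if (stats::runif(1) < p$amp_step_down) {
        lin$k[i] <- max(1L, lin$k[i] - 1L)
      }
    }
    if (length(amp)) kmax <- max(kmax, lin$k[amp])
    # endpoint readout (before the next day's dilution)
    e <- lineage_expression(lin, p) * preset$baseline_expression
    tot <- sum(lin$N)
    od_true <- p$od_at_capacity * tot / p$capacity
    per_od <- p$od_at_capacity / p$capacity
    yfp_true <- p$yfp_per_od * per_od * sum(lin$N * e)
    cfp_true <- p$cfp_per_od * per_od * sum(lin$N * lin$k)
    od_meas <- p$od_floor * exp(stats::rnorm(1, 0, p$od_noise_sd)) +
      od_true * exp(stats::rnorm(1, 0, p$od_noise_sd))
    yfp_meas <- p$autofluor + yfp_true * exp(stats::rnorm(1, 0, p$noise_sd))
    cfp_meas <- p$autofluor + cfp_true * exp(stats::rnorm(1, 0, p$noise_sd))
    out <- rbind(out, data.frame(day = d, od600 = od_meas, yfp = yfp_meas,
                                 cfp = cfp_meas))
    if (d == p$days) {
      truth_rescued <- od_true > 0.075
      i <- which.max(lin$N)
      dom_label <- lin$label[i]
      if (dom_label == "amplified" && lin$secondary[i])
        dom_label <- "amplified_plus"
      dom_e <- e[i]; dom_k <- lin$k[i]
      od_true_final <- od_true
      # noise-free population-mean fold increases over the ancestor
      yfp_fold_true <- if (tot > 0) sum(lin$N * e) / tot else 0
      cfp_fold_true <- if (tot > 0) sum(lin$N * lin$k) / tot else 0
    }
    # dilution into the next day's plate
    keep <- lin$N >= 1
    lin <- lin[keep, , drop = FALSE]
    if (d < p$days) {
      lin$N <- vapply(lin$N, function(nn)
        if (nn > 1e7) stats::rpois(1L, nn / p$dilution)
        else stats::rbinom(1L, round(nn), 1 / p$dilution), numeric(1))
      lin <- lin[lin$N >= 1, , drop = FALSE]
      if (nrow(lin) == 0L) lin <- new_lineage("ancestral", 1L, FALSE, 0)
    }
  }
  series <- data.frame(plate_id = plate_id, well = well, out,
                       stringsAsFactors = FALSE)
  list(series = series,
       truth = list(rescued = truth_rescued, dominant = dom_label,
                    final_k = dom_k, max_k = kmax, final_expression = dom_e,
                    od_true_final = od_true_final,
                    yfp_fold_true = yfp_fold_true,
                    cfp_fold_true = cfp_fold_true))
}

well_name <- function(i) {
  sprintf("%s%02d", LETTERS[((i - 1) %/% 12) + 1L], ((i - 1) %% 12) + 1L)
}

#' Simulate a plate of independent rescue wells
#'
#' Wells are simulated independently with per-well seeds derived from the
#' plate seed, so the same seed gives bit-identical output regardless of
#' chunking.
#'
#' @param params a [sim_params()].
#' @param preset a [scenario_preset()].
#' @param schedule a [make_schedule()] schedule.
#' @param n_wells number of wells; default `params$n_wells`.
#' @param seed plate RNG seed.
#' @param plate_id plate label.
#' @return list with `plates` (validated `plate_series` table) and `truth`
#'   (one row per well: rescued, dominant, final_k, max_k, final_expression).
#' @export
simulate_plate <- function(params, preset, schedule, n_wells = NULL, seed = 1L,
                           plate_id = NULL) {
  if (is.null(n_wells)) n_wells <- params$n_wells
  if (is.null(plate_id)) plate_id <- paste0("sim_", preset$name)
  series <- vector("list", n_wells)
  truth <- vector("list", n_wells)
  for (i in seq_len(n_wells)) {
    wseed <- (as.integer(seed) + 7919L * i) %% 2147483647L
    w <- simulate_well(params, preset, schedule, seed = wseed,
                       plate_id = plate_id, well = well_name(i))
    series[[i]] <- w$series
    truth[[i]] <- data.frame(plate_id = plate_id, well = well_name(i),
                             rescued = w$truth$rescued,
                             dominant = w$truth$dominant,
                             final_k = w$truth$final_k, max_k = w$truth$max_k,
                             final_expression = w$truth$final_expression,
                             od_true_final = w$truth$od_true_final,
                             yfp_fold_true = w$truth$yfp_fold_true,
                             cfp_fold_true = w$truth$cfp_fold_true,
                             stringsAsFactors = FALSE)
  }
  list(plates = validate_plate_series(do.call(rbind, series)),
       truth = do.call(rbind, truth))
}

#' Simulate an ancestor reference plate
#'
#' Unselected ancestral wells grown to saturation for 24 h: one endpoint
#' reading per well with the same readout noise model as [simulate_well()].
#'
#' @param params a [sim_params()].
#' @param n_wells number of wells, default `params$n_wells`.
#' @param seed RNG seed.
#' @return data.frame with `well`, `od600`, `yfp`, `cfp`.
#' @export
simulate_ancestor_plate <- function(params, n_wells = NULL, seed = 1L) {
  p <- params
  if (is.null(n_wells)) n_wells <- p$n_wells
  set.seed(as.integer(seed))
  od_true <- p$od_at_capacity
  od <- p$od_floor * exp(stats::rnorm(n_wells, 0, p$od_noise_sd)) +
    od_true * exp(stats::rnorm(n_wells, 0, p$od_noise_sd))
  yfp <- p$autofluor + p$yfp_per_od * od_true * exp(stats::rnorm(n_wells, 0, p$noise_sd))
  cfp <- p$autofluor + p$cfp_per_od * od_true * exp(stats::rnorm(n_wells, 0, p$noise_sd))
  data.frame(well = well_name(seq_len(n_wells)), od600 = od, yfp = yfp,
             cfp = cfp, stringsAsFactors = FALSE)
}

#' Simulate a copy-number validation panel
#'
#' Draws per-sample true reporter copy numbers and emits (a) a final CFP
#' fluorescence reading proportional to copy number with lognormal noise and
#' (b) qPCR records whose target Cq shifts by `-log2(k)/log2(1+E)` cycles per
#' copy-number doubling, for validating the delta-delta-Cq pipeline and the
#' copy-number/CFP correlation.
#'
#' @param n_samples number of samples, default 40.
#' @param seed RNG seed.
#' @param noise_sd lognormal CFP noise, default 0.05.
#' @param cq_noise_sd additive Cq noise SD per technical replicate, default
#'   0.05 cycles.
#' @param efficiency shared amplification efficiency fraction, default 0.95.
#' @param k_range integer range of true copy numbers, default 1..12.
#' @return list with `truth` (sample_id, k, cfp_final) and `cq` (long qPCR
#'   table with triplicates, calibrator sample `"ANC"` at k = 1).
#' @export
simulate_copy_number_panel <- function(n_samples = 40L, seed = 1L,
                                       noise_sd = 0.05, cq_noise_sd = 0.05,
                                       efficiency = 0.95, k_range = 1:12) {
  set.seed(as.integer(seed))
  k <- sample(k_range, n_samples, replace = TRUE)
  ids <- sprintf("S%02d", seq_len(n_samples))
  cfp <- 90 * k * exp(stats::rnorm(n_samples, 0, noise_sd))
  cq0_t <- 20; cq0_r <- 18
  rows <- list()
  add <- function(id, kk) {
    for (rep in 1:3) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = id, assay = "target",
        cq = cq0_t - log(kk) / log(1 + efficiency) +
          stats::rnorm(1, 0, cq_noise_sd),
        efficiency = efficiency, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = id, assay = "reference",
        cq = cq0_r + stats::rnorm(1, 0, cq_noise_sd),
        efficiency = efficiency, stringsAsFactors = FALSE)
    }
  }
  add("ANC", 1)
  for (i in seq_len(n_samples)) add(ids[i], k[i])
  list(truth = data.frame(sample_id = ids, k = k, cfp_final = cfp,
                          stringsAsFactors = FALSE),
       cq = do.call(rbind, rows))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Generate an annotated toy genome with planted neighborhoods
#'
#' Builds a random circular genome carrying three planted reporter-locus-like
#' neighborhoods with construction-known adaptive-potential tiers:
#' a `low` locus (closest upstream co-oriented terminator intrinsic, essential
#' gene blocking promoter capture), a `medium` locus (Rho-dependent upstream
#' terminator plus a capturable promoter/terminator pair), and a `high` locus
#' (same as medium, additionally between a planted direct-repeat pair).
#' Filler genes are placed on the minus strand with no minus-strand promoters
#' or terminators, so their truth tier is `low`. With `plant_loci = FALSE`
#' only fillers are produced: no repeats, all genes `low`.
#'
#' @param seed RNG seed.
#' @param genome_length genome length, default 30000.
#' @param n_filler number of minus-strand filler genes, default 12.
#' @param plant_loci plant the three locus neighborhoods?
#' @param repeat_hamming mismatches planted into the second repeat copy,
#'   default 3.
#' @param repeat_length planted repeat length, default 300.
#' @return list with `ann` (an [annotation_bundle()] with sequence), `truth`
#'   (gene_id, tier, and the three set flags), and `planted_repeat`
#'   (copy coordinates or `NULL`).
#' @export
make_toy_annotation <- function(seed, genome_length = 30000L, n_filler = 12L,
                                plant_loci = TRUE, repeat_hamming = 3L,
                                repeat_length = 300L) {
  set.seed(as.integer(seed))
  stopifnot(genome_length >= 25000L)
  seqv <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
  genes <- list(); promoters <- list(); terminators <- list(); truth <- list()
  add_gene <- function(id, start, end, strand, essential) {
    genes[[length(genes) + 1L]] <<- data.frame(
      id = id, start = start, end = end, strand = strand,
      essential = essential, stringsAsFactors = FALSE)
  }
  add_truth <- function(id, rho, del, dup) {
    tier <- if (rho && del && dup) "high" else if (rho || del) "medium" else "low"
    truth[[length(truth) + 1L]] <<- data.frame(
      gene_id = id, in_rho_set = rho, in_deletion_set = del,
      in_duplicate_set = dup, tier = tier, stringsAsFactors = FALSE)
  }
  planted_repeat <- NULL
  if (plant_loci) {
    # low-tier locus: intrinsic closest terminator; essential gene between
    # the only nearby promoter and the gene
    add_gene("ess_A", 4000L, 4800L, "-", TRUE)
    add_gene("gene_A", 5000L, 5900L, "+", FALSE)
    promoters[[length(promoters) + 1L]] <- data.frame(
      pos = 3500L, strand = "+", primary = TRUE)
    terminators[[length(terminators) + 1L]] <- data.frame(
      pos = 4900L, strand = "+", mode = "intrinsic")
    add_truth("ess_A", FALSE, FALSE, FALSE)
    add_truth("gene_A", FALSE, FALSE, FALSE)
    # medium-tier locus: rho closest terminator, capturable promoter
    add_gene("ess_D", 9000L, 9800L, "-", TRUE)
    add_gene("gene_D", 12000L, 12900L, "+", FALSE)
    promoters[[length(promoters) + 1L]] <- data.frame(
      pos = 11000L, strand = "+", primary = TRUE)
    terminators[[length(terminators) + 1L]] <- data.frame(
      pos = 11800L, strand = "+", mode = "rho")
    add_truth("ess_D", FALSE, FALSE, FALSE)
    add_truth("gene_D", TRUE, TRUE, FALSE)
    # high-tier locus: as medium, plus flanking direct repeats
    add_gene("ess_B", 17000L, 17800L, "-", TRUE)
    add_gene("gene_B", 20000L, 20900L, "+", FALSE)
    promoters[[length(promoters) + 1L]] <- data.frame(
      pos = 19000L, strand = "+", primary = TRUE)
    terminators[[length(terminators) + 1L]] <- data.frame(
      pos = 19800L, strand = "+", mode = "rho")
    r1 <- 18200L; r2 <- 21500L
    seqv[(r2 + 1):(r2 + repeat_length)] <- seqv[(r1 + 1):(r1 + repeat_length)]
    if (repeat_hamming > 0L) {
      at <- r2 + round(seq(20, repeat_length - 20, length.out = repeat_hamming))
      for (pos in at) {
        cur <- seqv[pos + 1L]
        seqv[pos + 1L] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
    planted_repeat <- list(start1 = r1, end1 = r1 + repeat_length,
                           start2 = r2, end2 = r2 + repeat_length,
                           hamming = as.integer(repeat_hamming))
    add_truth("ess_B", FALSE, FALSE, FALSE)
    add_truth("gene_B", TRUE, TRUE, TRUE)
  }
  # minus-strand fillers in the back half of the genome (no minus-strand
  # promoters or terminators exist, so they are all tier low)
  lo <- 23000L
  span <- genome_length - lo - 200L
  width <- 400L
  slots <- floor(span / (width + 100L))
  n_filler <- min(n_filler, slots)
  for (i in seq_len(n_filler)) {
    s <- lo + (i - 1L) * (width + 100L)
    id <- sprintf("filler%02d", i)
    add_gene(id, s, s + width, "-", i == 1L)  # one essential filler
    add_truth(id, FALSE, FALSE, FALSE)
  }
  ann <- annotation_bundle(
    genome_length,
    genes = do.call(rbind, genes),
    promoters = if (length(promoters)) do.call(rbind, promoters) else NULL,
    terminators = if (length(terminators)) do.call(rbind, terminators) else NULL,
    sequence = paste(seqv, collapse = ""), circular = TRUE)
  truth <- do.call(rbind, truth)
  truth <- truth[match(ann$genes$id, truth$gene_id), ]
  rownames(truth) <- NULL
  list(ann = ann, truth = truth, planted_repeat = planted_repeat)
}
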