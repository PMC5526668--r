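# shared fixture builders: all data is generated in code at test time

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# plant a direct-repeat pair into a random genome; returns the sequence and
# the planted copy coordinates (0-based half-open)
plant_repeat <- function(genome_len, rep_len, hamming, gap, start1 = NULL) {
  g <- sample(BASES, genome_len, replace = TRUE)
  if (is.null(start1))
    start1 <- sample.int(genome_len - 2L * rep_len - gap - 100L, 1L) + 50L
  start2 <- start1 + rep_len + gap
  g[(start2 + 1):(start2 + rep_len)] <- g[(start1 + 1):(start1 + rep_len)]
  if (hamming > 0L) {
    at <- start2 + sample.int(rep_len, hamming)
    for (p in at) g[p] <- sample(setdiff(BASES, g[p]), 1L)
  }
  list(seq = paste(g, collapse = ""),
       start1 = start1, start2 = start2, rep_len = rep_len, hamming = hamming,
       gap = gap)
}

# a small 3-well plate table covering rescue/extinct/transient cases
toy_plate <- function(days = 5L) {
  mk <- function(well, od, yfp, cfp)
    data.frame(plate_id = "P1", well = well, day = seq_len(days),
               od600 = od, yfp = yfp, cfp = cfp)
  rbind(
    mk("A01", c(0.9, 0.9, 0.9, 0.9, 0.9), 100 * 0.9 * c(1, 1, 4, 4, 4),
       100 * 0.9 * c(1, 1, 1, 1, 1)),                       # YFP-only rescue
    mk("A02", c(0.9, 0.9, 0.9, 0.02, 0.02), 100 * c(0.9, 0.9, 0.9, 0.02, 0.02),
       100 * c(0.9, 4 * 0.9, 4 * 0.9, 0.02, 0.02)),         # transient CFP, extinct
    mk("A03", rep(0.9, days), 100 * 0.9 * rep(5, days),
       100 * 0.9 * rep(5, days)))                           # YFP+CFP rescue
}

toy_reference <- function() {
  structure(list(mean_norm_yfp = 100, mean_norm_cfp = 100, n_wells = 95L),
            class = "ancestral_reference")
}
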