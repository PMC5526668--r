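# Chromosomal-neighborhood analysis: direct-repeat detection with Hamming
# tolerance, the three adaptive-potential property sets, and per-gene tiers.

repeat_postprocess <- function(m, min_len, max_mismatch, min_gap, max_gap) {
  df <- as.data.frame(m)
  if (nrow(df)) {
    df$gap <- df$start2 - (df$start1 + df$length)
    df <- df[df$length >= min_len & df$hamming <= max_mismatch &
               df$gap >= min_gap & df$gap <= max_gap, , drop = FALSE]
  } else df$gap <- integer(0)
  if (nrow(df) > 1L) {
    # merge overlapping qualifying reports on the same diagonal: keep the
    # longest extension, ties broken by leftmost coordinate
    df$diag <- df$start2 - df$start1
    df <- df[order(df$diag, -df$length, df$start1), , drop = FALSE]
    keep <- logical(nrow(df))
    for (dg in unique(df$diag)) {
      idx <- which(df$diag == dg)
      taken <- data.frame(s = integer(), e = integer())
      for (i in idx) {
        s <- df$start1[i]; e <- df$start1[i] + df$length[i]
        if (!any(taken$s < e & s < taken$e)) {
          keep[i] <- TRUE
          taken <- rbind(taken, data.frame(s = s, e = e))
        }
      }
    }
    df <- df[keep, , drop = FALSE]
    df$diag <- NULL
  }
  df <- df[order(df$start1, df$start2), , drop = FALSE]
  out <- data.frame(start1 = df$start1, end1 = df$start1 + df$length,
                    start2 = df$start2, end2 = df$start2 + df$length,
                    repeat_length = df$length, hamming = df$hamming,
                    gap = df$gap,
                    region_start = df$start1 + df$length,
                    region_end = df$start2)
  rownames(out) <- NULL
  class(out) <- c("repeat_region", "data.frame")
  out
}

#' Find direct (forward) repeats with Hamming tolerance
#'
#' Reports every maximal same-strand repeat pair satisfying the four search
#' criteria: repeat length at least `min_len`, Hamming distance at most
#' `max_mismatch`, and gap between the two copies (non-overlapping by
#' construction) within `[min_gap, max_gap]`. Default criteria are those used
#' for genome-wide flanking-duplicate detection (length >= 200 bp, Hamming
#' <= 8, gap 200 bp to 100 kb); for scanning a window around a single locus a
#' stricter `max_mismatch = 5` is conventional.
#'
#' The default method seeds on exact shared k-mers and extends along the
#' diagonal. The seed length `k = 22` is sound by pigeonhole: any repeat of
#' length >= 200 with <= 8 mismatches contains an exact common run of length
#' at least `ceil(192/9) >= 22`, so seeding misses nothing the exhaustive
#' scan finds (for custom criteria the seed is recomputed as
#' `floor((min_len - max_mismatch) / (max_mismatch + 1))`, capped at 31).
#' `method = "exhaustive"` runs the brute-force all-diagonal reference scan
#' instead (quadratic; small genomes only).
#'
#' Maximal windows are found first and the gap criteria applied afterwards, so
#' a pair whose maximal extension leaves a gap below `min_gap` (e.g. a tight
#' tandem) is excluded rather than trimmed. Overlapping reports on the same
#' diagonal are merged to the longest qualifying extension.
#'
#' @param sequence nucleotide string over A/C/G/T.
#' @param min_len minimum repeat length (bp), default 200.
#' @param max_mismatch maximum Hamming distance, default 8.
#' @param max_gap maximum distance between copies (bp), default 100000.
#' @param min_gap minimum distance between copies (bp), default 200.
#' @param circular treat the sequence as circular (pairs may wrap the origin).
#' @param method `"seeded"` (default) or `"exhaustive"`.
#' @return data.frame of class `repeat_region` with columns `start1`, `end1`,
#'   `start2`, `end2` (0-based half-open copies), `repeat_length`, `hamming`,
#'   `gap`, and the inter-repeat interval `region_start`, `region_end`.
#' @export
find_direct_repeats <- function(sequence, min_len = 200L, max_mismatch = 8L,
                                max_gap = 100000L, min_gap = 200L,
                                circular = FALSE,
                                method = c("seeded", "exhaustive")) {
  method <- match.arg(method)
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence)) stop("sequence must be over A/C/G/T")
  stopifnot(min_len > 0, max_mismatch >= 0, min_gap >= 0, max_gap >= min_gap)
  n <- nchar(sequence)
  if (n < 2L * min_len + min_gap) return(repeat_postprocess(
    matrix(integer(0), 0, 4, dimnames = list(NULL, c("start1", "start2", "length", "hamming"))),
    min_len, max_mismatch, min_gap, max_gap))
  scan_seq <- if (circular) paste0(sequence, sequence) else sequence
  m <- if (method == "seeded") {
    k <- max(4L, min(31L, (min_len - max_mismatch) %/% (max_mismatch + 1L)))
    cpp_repeat_scan_seeded(scan_seq, as.integer(min_len),
                           as.integer(max_mismatch), as.integer(k), 2000L)
  } else {
    cpp_repeat_scan_exhaustive(scan_seq, as.integer(min_len),
                               as.integer(max_mismatch))
  }
  if (circular && nrow(m)) {
    # restrict to one genome copy and offsets below n, then drop rotation
    # duplicates of the same unordered pair of copies
    d <- m[, "start2"] - m[, "start1"]
    m <- m[m[, "start1"] < n & d < n & m[, "length"] <= n, , drop = FALSE]
  }
  out <- repeat_postprocess(m, min_len, max_mismatch, min_gap, max_gap)
  if (circular && nrow(out)) {
    a <- out$start1 %% n; b <- out$start2 %% n
    key <- paste(pmin(a, b), pmax(a, b), out$repeat_length)
    out <- out[order(out$gap, out$start1), , drop = FALSE]
    out <- out[!duplicated(key[order(out$gap, out$start1)]), , drop = FALSE]
    out <- out[order(out$start1, out$start2), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Genes fully contained between flanking repeat copies
#'
#' Returns the ids of genes whose interval lies entirely inside the
#' inter-repeat interval of at least one repeat region. Genes straddling a
#' repeat copy are excluded (full-containment rule). Regions spanning less
#' than `min_region_span` and genes on an explicit exclusion list can be
#' dropped to reproduce manual curation of closely spaced repeats.
#'
#' @param repeats a `repeat_region` table ([find_direct_repeats()]).
#' @param genes gene table of an [annotation_bundle()].
#' @param min_region_span minimum inter-repeat span (bp), default 0.
#' @param exclude gene ids to drop regardless of containment.
#' @return character vector of gene ids.
#' @export
genes_between_repeats <- function(repeats, genes, min_region_span = 0L,
                                  exclude = character(0)) {
  if (nrow(repeats) == 0L || nrow(genes) == 0L) return(character(0))
  reps <- repeats[repeats$region_end - repeats$region_start >= min_region_span, ,
                  drop = FALSE]
  hit <- vapply(seq_len(nrow(genes)), function(i)
    any(genes$start[i] >= reps$region_start & genes$end[i] <= reps$region_end),
    logical(1))
  setdiff(genes$id[hit], exclude)
}

upstream_point_distance <- function(pos, gene_start, gene_end, strand,
                                    genome_length, circular) {
  # distance (>= 1) from a point feature to the 5' end of a gene, scanning
  # strictly upstream on the gene's strand; NA when not upstream (linear mode)
  if (strand == "+") d <- gene_start - 1L - pos else d <- pos - gene_end
  if (circular) d <- d %% genome_length
  ifelse(d >= 0, d + 1L, NA_integer_)
}

#' Closest upstream co-oriented terminator of a gene
#'
#' Scans strictly upstream of the gene's 5' end on the gene's strand (toward
#' lower coordinates for `+` genes, higher for `-`), wrapping around the
#' origin for circular genomes, and returns the nearest terminator on the same
#' strand, or `NULL` if there is none.
#'
#' @param gene one row of an annotation gene table.
#' @param terminators terminator table (`pos`, `strand`, `mode`).
#' @param genome_length genome length (bp).
#' @param circular wrap the scan around the origin.
#' @return list with `pos`, `mode`, `distance`, or `NULL`.
#' @export
closest_upstream_terminator <- function(gene, terminators, genome_length,
                                        circular = TRUE) {
  t <- terminators[terminators$strand == gene$strand, , drop = FALSE]
  if (nrow(t) == 0L) return(NULL)
  d <- upstream_point_distance(t$pos, gene$start, gene$end, gene$strand,
                               genome_length, circular)
  ok <- which(!is.na(d))
  if (!length(ok)) return(NULL)
  i <- ok[which.min(d[ok])]
  list(pos = t$pos[i], mode = t$mode[i], distance = d[i])
}

#' Genes downstream of a Rho-dependent terminator
#'
#' A gene belongs to the set when its closest upstream co-oriented terminator
#' is Rho-dependent (`mode = "rho"`); read-through across such terminators by
#' partial-loss-of-function Rho mutations co-opts the upstream promoter to the
#' gene. Genes with no upstream co-oriented terminator, or whose closest one
#' is intrinsic, are excluded.
#'
#' @param ann an [annotation_bundle()].
#' @return character vector of gene ids.
#' @export
rho_terminated_set <- function(ann) {
  g <- ann$genes
  hit <- vapply(seq_len(nrow(g)), function(i) {
    ct <- closest_upstream_terminator(g[i, ], ann$terminators,
                                      ann$genome_length, ann$circular)
    !is.null(ct) && ct$mode == "rho"
  }, logical(1))
  g$id[hit]
}

#' Genes reachable by a promoter-capture deletion
#'
#' A gene belongs to the set when, in the strand-upstream interval bounded by
#' the next upstream essential gene (any strand: deleting it is lethal), there
#' is at least one co-oriented primary promoter and a co-oriented terminator
#' strictly between that promoter and the gene. The terminator requirement
#' encodes that the promoter does not already read into the gene, so deleting
#' the intervening terminator-bearing DNA co-opts it.
#'
#' @param ann an [annotation_bundle()].
#' @return character vector of gene ids.
#' @export
deletion_cooption_set <- function(ann) {
  g <- ann$genes
  L <- ann$genome_length
  hit <- vapply(seq_len(nrow(g)), function(i) {
    gi <- g[i, ]
    ess <- g[g$essential & g$id != gi$id, , drop = FALSE]
    # distance to the nearest base of the nearest upstream essential gene
    if (nrow(ess)) {
      near <- if (gi$strand == "+") ess$end - 1L else ess$start
      de <- upstream_point_distance(near, gi$start, gi$end, gi$strand, L,
                                    ann$circular)
      lim <- if (all(is.na(de))) Inf else min(de, na.rm = TRUE)
    } else lim <- Inf
    p <- ann$promoters[ann$promoters$strand == gi$strand &
                         ann$promoters$primary, , drop = FALSE]
    if (nrow(p) == 0L) return(FALSE)
    dp <- upstream_point_distance(p$pos, gi$start, gi$end, gi$strand, L,
                                  ann$circular)
    t <- ann$terminators[ann$terminators$strand == gi$strand, , drop = FALSE]
    dt <- if (nrow(t)) upstream_point_distance(t$pos, gi$start, gi$end,
                                               gi$strand, L, ann$circular)
          else integer(0)
    for (k in seq_along(dp)) {
      if (is.na(dp[k]) || dp[k] >= lim) next
      if (any(!is.na(dt) & dt < dp[k])) return(TRUE)
    }
    FALSE
  }, logical(1))
  g$id[hit]
}

#' Classify genes by adaptive-potential tier
#'
#' Builds the three chromosomal-neighborhood property sets -- downstream of a
#' Rho-dependent terminator, deletion-co-optable promoter, and between
#' flanking duplicates -- and assigns each gene a tier: `high` when all three
#' properties hold, `medium` when at least one promoter co-option route (Rho
#' read-through or deletion capture) is available but not all three
#' properties, and `low` when neither co-option route exists.
#'
#' @param ann an [annotation_bundle()].
#' @param repeats a `repeat_region` table for the same genome; when `NULL`
#'   and `ann$sequence` is present, repeats are computed with
#'   [find_direct_repeats()] defaults.
#' @param min_region_span,exclude passed to [genes_between_repeats()].
#' @return list with `membership` (data.frame: `gene_id`, `in_rho_set`,
#'   `in_deletion_set`, `in_duplicate_set`, `tier`) and `venn_counts`
#'   (named counts of the 7 intersection cells plus `outside`).
#' @export
classify_genes <- function(ann, repeats = NULL, min_region_span = 0L,
                           exclude = character(0)) {
  if (is.null(repeats)) {
    if (is.null(ann$sequence))
      stop("no repeats given and annotation has no sequence")
    repeats <- find_direct_repeats(ann$sequence, circular = ann$circular)
  }
  rho <- rho_terminated_set(ann)
  del <- deletion_cooption_set(ann)
  dup <- genes_between_repeats(repeats, ann$genes,
                               min_region_span = min_region_span,
                               exclude = exclude)
  g <- ann$genes$id
  m <- data.frame(gene_id = g,
                  in_rho_set = g %in% rho,
                  in_deletion_set = g %in% del,
                  in_duplicate_set = g %in% dup,
                  stringsAsFactors = FALSE)
  m$tier <- ifelse(m$in_rho_set & m$in_deletion_set & m$in_duplicate_set,
                   "high",
                   ifelse(m$in_rho_set | m$in_deletion_set, "medium", "low"))
  cells <- c(
    rho_only = sum(m$in_rho_set & !m$in_deletion_set & !m$in_duplicate_set),
    deletion_only = sum(!m$in_rho_set & m$in_deletion_set & !m$in_duplicate_set),
    duplicate_only = sum(!m$in_rho_set & !m$in_deletion_set & m$in_duplicate_set),
    rho_deletion = sum(m$in_rho_set & m$in_deletion_set & !m$in_duplicate_set),
    rho_duplicate = sum(m$in_rho_set & !m$in_deletion_set & m$in_duplicate_set),
    deletion_duplicate = sum(!m$in_rho_set & m$in_deletion_set & m$in_duplicate_set),
    all_three = sum(m$in_rho_set & m$in_deletion_set & m$in_duplicate_set),
    outside = sum(!m$in_rho_set & !m$in_deletion_set & !m$in_duplicate_set))
  list(membership = m, venn_counts = cells)
}
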