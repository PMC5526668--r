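#' @useDynLib rescuemap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# ---- plate-reader time series ------------------------------------------------

#' Read a long-format plate-reader CSV
#'
#' Expects a tidy (long) CSV with one row per well and day and columns
#' `plate_id`, `well`, `day`, `od600`, `yfp`, `cfp`. Each `(plate_id, well)`
#' must carry a reading for every day `1..T` with no duplicates; all numeric
#' values must be finite and non-negative. Day 1 is the first measurement and
#' the last day is the experiment endpoint.
#'
#' @param path path to a CSV file.
#' @param wide if `TRUE`, the file is a plate-shaped wide export with columns
#'   `plate_id`, `well`, and one column per day named `d1..dT` for each channel
#'   prefix (`od600_d1`, `yfp_d1`, `cfp_d1`, ...); it is melted to long form.
#' @param strict if `TRUE` (default) `NA` values are an error; otherwise they
#'   are kept and propagate.
#' @return a `data.table` of class `plate_series` with columns
#'   `plate_id`, `well`, `day`, `od600`, `yfp`, `cfp`, keyed by plate and well.
#' @export
read_plate_csv <- function(path, wide = FALSE, strict = TRUE) {
  dt <- data.table::fread(path, colClasses = list(character = "well"))
  if (wide) dt <- plate_wide_to_long(dt)
  validate_plate_series(dt, strict = strict)
}

#' Convert a wide plate export to long form
#'
#' @param dt a data.table with `plate_id`, `well` and `<channel>_d<day>`
#'   columns for channels `od600`, `yfp`, `cfp`.
#' @return long-format data.table.
#' @export
plate_wide_to_long <- function(dt) {
  dt <- data.table::as.data.table(dt)
  long <- data.table::melt(dt, id.vars = c("plate_id", "well"),
                           variable.name = "var", value.name = "value")
  parts <- data.table::tstrsplit(as.character(long$var), "_d", fixed = TRUE)
  long[, `:=`(channel = parts[[1]], day = as.integer(parts[[2]]), var = NULL)]
  data.table::dcast(long, plate_id + well + day ~ channel, value.var = "value")
}

#' Validate an in-memory plate table
#'
#' @param dt data.frame/data.table with plate columns (`yfp`/`cfp` or the
#'   `yfp_raw`/`cfp_raw` aliases).
#' @param strict error on `NA` values.
#' @return validated keyed `data.table` of class `plate_series`.
#' @export
validate_plate_series <- function(dt, strict = TRUE) {
  dt <- data.table::as.data.table(dt)
  data.table::setnames(dt, old = c("yfp_raw", "cfp_raw"),
                       new = c("yfp", "cfp"), skip_absent = TRUE)
  need <- c("plate_id", "well", "day", "od600", "yfp", "cfp")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("plate data missing column(s): ", paste(miss, collapse = ", "))
  dt <- dt[, need, with = FALSE]
  dt[, day := as.integer(day)]
  num <- c("od600", "yfp", "cfp")
  for (v in num) dt[, (v) := as.numeric(get(v))]
  if (strict) {
    bad <- which(rowSums(is.na(dt[, ..num])) > 0L)
    if (length(bad))
      stop("NA reading(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           " (strict mode)")
  }
  for (v in num) {
    bad <- which(!is.na(dt[[v]]) & (!is.finite(dt[[v]]) | dt[[v]] < 0))
    if (length(bad))
      stop("negative or non-finite ", v, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  dup <- which(duplicated(dt[, .(plate_id, well, day)]))
  if (length(dup))
    stop("duplicate (plate_id, well, day) at row(s) ",
         paste(utils::head(dup, 5), collapse = ", "))
  # every well must cover days 1..T contiguously
  tmax <- max(dt$day)
  chk <- dt[, .(ok = identical(sort(day), 1:tmax)), by = .(plate_id, well)]
  if (any(!chk$ok)) {
    w <- chk[!(ok)][1]
    stop("ragged day range for plate ", w$plate_id, " well ", w$well,
         ": expected days 1..", tmax)
  }
  data.table::setkeyv(dt, c("plate_id", "well", "day"))
  data.table::setattr(dt, "class", c("plate_series", class(dt)))
  dt
}

#' Write a plate table to CSV
#'
#' @param plates a `plate_series` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plates, path) {
  data.table::fwrite(data.table::as.data.table(plates)[, .(
    plate_id, well, day, od600, yfp, cfp)], path)
  invisible(path)
}

# ---- genome annotation -------------------------------------------------------

#' Construct an annotation bundle
#'
#' The bundle is the internal genome-annotation container used by the
#' neighborhood classifier: strand-aware genes with essentiality flags,
#' promoters (point features with a primary flag), terminators (point features
#' with mode `intrinsic` or `rho`), an optional nucleotide sequence, and a
#' circularity flag. All internal coordinates are 0-based half-open.
#'
#' @param genome_length genome length in bp.
#' @param genes data.frame with `id`, `start`, `end`, `strand`, `essential`.
#' @param promoters data.frame with `pos`, `strand`, `primary`.
#' @param terminators data.frame with `pos`, `strand`, `mode`.
#' @param sequence optional nucleotide string of length `genome_length`.
#' @param circular is the chromosome circular? Default `TRUE` (bacterial).
#' @return object of class `annotation_bundle`.
#' @export
annotation_bundle <- function(genome_length, genes = NULL, promoters = NULL,
                              terminators = NULL, sequence = NULL,
                              circular = TRUE) {
  empty_genes <- data.frame(id = character(), start = integer(), end = integer(),
                            strand = character(), essential = logical(),
                            stringsAsFactors = FALSE)
  empty_pts <- function(extra, cls) {
    d <- data.frame(pos = integer(), strand = character(), stringsAsFactors = FALSE)
    d[[extra]] <- vector(cls, 0L)
    d
  }
  genes <- if (is.null(genes)) empty_genes else as.data.frame(genes)
  promoters <- if (is.null(promoters)) empty_pts("primary", "logical") else as.data.frame(promoters)
  terminators <- if (is.null(terminators)) empty_pts("mode", "character") else as.data.frame(terminators)
  if (nrow(genes)) {
    stopifnot(all(genes$start < genes$end),
              all(genes$start >= 0), all(genes$end <= genome_length))
    genes <- genes[order(genes$start), , drop = FALSE]
  }
  for (d in list(genes, promoters, terminators))
    if (nrow(d) && !all(d$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  if (nrow(terminators) && !all(terminators$mode %in% c("intrinsic", "rho")))
    stop("terminator mode must be 'intrinsic' or 'rho'")
  if (nrow(promoters)) promoters <- promoters[order(promoters$pos), , drop = FALSE]
  if (nrow(terminators)) terminators <- terminators[order(terminators$pos), , drop = FALSE]
  for (nm in c("promoters", "terminators")) {
    d <- get(nm)
    if (nrow(d) && (any(d$pos < 0) || any(d$pos >= genome_length)))
      stop(nm, " position outside [0, genome_length)")
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != genome_length)
      stop("sequence length (", nchar(sequence), ") != genome_length (",
           genome_length, ")")
  }
  rownames(genes) <- rownames(promoters) <- rownames(terminators) <- NULL
  structure(list(genome_length = as.integer(genome_length),
                 circular = isTRUE(circular),
                 genes = genes, promoters = promoters,
                 terminators = terminators, sequence = sequence),
            class = "annotation_bundle")
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat("annotation_bundle:", x$genome_length, "bp",
      if (x$circular) "(circular)" else "(linear)", "\n")
  cat("  genes:", nrow(x$genes),
      "| essential:", sum(x$genes$essential), "\n")
  cat("  promoters:", nrow(x$promoters),
      "| primary:", sum(x$promoters$primary), "\n")
  cat("  terminators:", nrow(x$terminators),
      "| rho:", sum(x$terminators$mode == "rho"), "\n")
  cat("  sequence:", if (is.null(x$sequence)) "absent" else "present", "\n")
  invisible(x)
}

#' Read genome annotation from GFF3
#'
#' GFF3 is 1-based closed; coordinates are converted to the internal 0-based
#' half-open convention. Recognized feature types are `gene` (attribute
#' `essential=true|false`), `promoter` (attribute `class=primary` marks primary
#' promoters) and `terminator` (attribute `mode=intrinsic|rho`). Point features
#' (promoters, terminators) are collapsed to their interval midpoint.
#'
#' @param path GFF3 file.
#' @param genome_length genome length in bp; if `NA`, taken from the
#'   `##sequence-region` directive.
#' @param sequence optional genome sequence string or path to a FASTA file.
#' @param circular circular chromosome flag.
#' @return an [annotation_bundle()].
#' @export
read_annotation_gff3 <- function(path, genome_length = NA, sequence = NULL,
                                 circular = TRUE) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (is.na(genome_length)) {
    sl <- GenomicRanges::seqinfo(gr)
    genome_length <- suppressWarnings(GenomeInfoDb::seqlengths(sl)[1])
    if (is.na(genome_length)) {
      lines <- readLines(path, n = 50L)
      reg <- grep("^##sequence-region", lines, value = TRUE)
      if (length(reg))
        genome_length <- as.integer(utils::tail(strsplit(reg[1], "\\s+")[[1]], 1))
    }
    if (is.na(genome_length))
      stop("genome_length not given and not recoverable from the GFF3 header")
  }
  df <- as.data.frame(gr)
  if (any(df$end > genome_length))
    stop("feature end beyond genome_length (", genome_length, ")")
  grab <- function(type) df[df$type == type, , drop = FALSE]
  g <- grab("gene")
  genes <- data.frame(
    id = if ("ID" %in% names(g)) as.character(g$ID) else paste0("gene", seq_len(nrow(g))),
    start = g$start - 1L, end = g$end,                     # 1-based closed -> 0-based half-open
    strand = as.character(g$strand),
    essential = tolower(as.character(g$essential)) %in% "true",
    stringsAsFactors = FALSE)
  p <- grab("promoter")
  promoters <- data.frame(
    pos = as.integer(floor((p$start - 1L + p$end) / 2)),   # midpoint, internal coords
    strand = as.character(p$strand),
    primary = if (nrow(p) && "class" %in% names(p))
      tolower(as.character(p$class)) %in% "primary" else logical(nrow(p)),
    stringsAsFactors = FALSE)
  t <- grab("terminator")
  if (nrow(t) && !all(tolower(as.character(t$mode)) %in% c("intrinsic", "rho")))
    stop("unknown terminator mode token; expected intrinsic|rho")
  terminators <- data.frame(
    pos = as.integer(floor((t$start - 1L + t$end) / 2)),
    strand = as.character(t$strand),
    mode = tolower(as.character(t$mode)),
    stringsAsFactors = FALSE)
  if (!is.null(sequence) && file.exists(sequence))
    sequence <- as.character(Biostrings::readDNAStringSet(sequence)[[1]])
  annotation_bundle(genome_length, genes, promoters, terminators,
                    sequence = sequence, circular = circular)
}

#' Write an annotation bundle to GFF3 (1-based closed coordinates)
#'
#' @param ann an [annotation_bundle()].
#' @param path output GFF3 path.
#' @param seqname chromosome name to print.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(ann, path, seqname = "chr") {
  esc <- function(x) gsub("[;=,\t]", "_", x)
  lines <- c("##gff-version 3",
             paste("##sequence-region", seqname, 1, ann$genome_length))
  fmt <- function(start0, end0, type, strand, attrs)
    paste(seqname, "rescuemap", type, start0 + 1L, end0, ".", strand, ".", attrs,
          sep = "\t")
  g <- ann$genes
  if (nrow(g))
    lines <- c(lines, fmt(g$start, g$end, "gene", g$strand,
                          paste0("ID=", esc(g$id), ";essential=",
                                 tolower(as.character(g$essential)))))
  p <- ann$promoters
  if (nrow(p))
    lines <- c(lines, fmt(p$pos, p$pos + 1L, "promoter", p$strand,
                          paste0("ID=prom", seq_len(nrow(p)), ";class=",
                                 ifelse(p$primary, "primary", "secondary"))))
  t <- ann$terminators
  if (nrow(t))
    lines <- c(lines, fmt(t$pos, t$pos + 1L, "terminator", t$strand,
                          paste0("ID=term", seq_len(nrow(t)), ";mode=", t$mode)))
  writeLines(lines, path)
  invisible(path)
}

#' Read genome annotation from three TSV tables
#'
#' TSV tables use the internal 0-based half-open convention directly.
#'
#' @param genes_tsv TSV with `id`, `start`, `end`, `strand`, `essential`.
#' @param promoters_tsv TSV with `pos`, `strand`, `primary`.
#' @param terminators_tsv TSV with `pos`, `strand`, `mode`.
#' @param genome_length genome length in bp.
#' @param sequence optional sequence string or FASTA path.
#' @param circular circular flag.
#' @return an [annotation_bundle()].
#' @export
read_annotation_tsv <- function(genes_tsv, promoters_tsv, terminators_tsv,
                                genome_length, sequence = NULL, circular = TRUE) {
  if (!is.null(sequence) && file.exists(sequence))
    sequence <- as.character(Biostrings::readDNAStringSet(sequence)[[1]])
  annotation_bundle(genome_length,
                    genes = utils::read.delim(genes_tsv),
                    promoters = utils::read.delim(promoters_tsv),
                    terminators = utils::read.delim(terminators_tsv),
                    sequence = sequence, circular = circular)
}

# ---- interval output ---------------------------------------------------------

#' Write repeat regions (or plain intervals) to BED
#'
#' Internal coordinates are 0-based half-open, as is BED, so no shift is
#' applied. For [find_direct_repeats()] output the name column carries
#' `len<L>_ham<h>_gap<g>`.
#'
#' @param regions a data.frame with `start`, `end` and optionally
#'   `repeat_length`, `hamming`, `gap`, or a `repeat_region` table.
#' @param path output BED path.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path, chrom = "chr") {
  regions <- as.data.frame(regions)
  if (nrow(regions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if (all(c("repeat_length", "hamming", "gap") %in% names(regions)))
    sprintf("len%d_ham%d_gap%d", regions$repeat_length, regions$hamming, regions$gap)
  else if ("name" %in% names(regions)) regions$name
  else sprintf("region%d", seq_len(nrow(regions)))
  writeLines(paste(chrom, regions$start, regions$end, name, sep = "\t"), path)
  invisible(path)
}

# ---- qPCR --------------------------------------------------------------------

#' Read a qPCR Cq table
#'
#' Long CSV with columns `sample_id`, `assay` (`target` or `reference`),
#' `cq`, `efficiency` (fraction in (0, 1]); one row per technical replicate.
#'
#' @param path CSV path.
#' @return validated `data.table`.
#' @export
read_qpcr_csv <- function(path) {
  dt <- data.table::fread(path)
  need <- c("sample_id", "assay", "cq", "efficiency")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("qPCR table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(dt$assay %in% c("target", "reference")))
    stop("assay must be 'target' or 'reference'")
  if (any(!is.finite(dt$cq) | dt$cq <= 0)) stop("Cq values must be finite and positive")
  if (any(dt$efficiency <= 0 | dt$efficiency > 1))
    stop("efficiency must be a fraction in (0, 1]")
  dt
}
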