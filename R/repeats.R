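#' Read RepeatMasker .out annotation
#'
#' Parses the whitespace-delimited `.out` table (three header lines,
#' 1-based inclusive query coordinates) into the package's repeat record
#' `data.frame`: `contig`, `start`, `end` (0-based half-open), `order`,
#' `family` (split from the class/family column), `divergence` (the
#' percent-divergence column).
#'
#' @param path File path.
#' @return Repeat record `data.frame`.
#' @export
read_rm_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) >= 3) lines <- lines[-(1:3)]
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (!length(lines)) return(empty_repeats())
  f <- strsplit(lines, "\\s+")
  cf <- vapply(f, `[[`, character(1), 11)
  parts <- strsplit(cf, "/", fixed = TRUE)
  data.frame(
    contig = vapply(f, `[[`, character(1), 5),
    start = as.numeric(vapply(f, `[[`, character(1), 6)) - 1,
    end = as.numeric(vapply(f, `[[`, character(1), 7)),
    order = vapply(parts, `[[`, character(1), 1),
    family = vapply(parts, function(p) if (length(p) > 1) p[2] else p[1],
                    character(1)),
    divergence = as.numeric(vapply(f, `[[`, character(1), 2)),
    stringsAsFactors = FALSE
  )
}

#' Write repeat records as RepeatMasker .out
#'
#' Inverse of [read_rm_out()] for fixtures and synthetic annotation;
#' fills the alignment-score and unused columns with placeholders.
#' @param records Repeat record `data.frame`.
#' @param path File path.
#' @export
write_rm_out <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW  perc perc perc  query     position in query     matching repeat",
    "score  div. del. ins.  sequence  begin end    (left)   repeat class/family begin end (left) ID",
    ""
  ), con)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    writeLines(sprintf(
      " 1000 %5.1f  0.0  0.0  %s %d %d (0) + %s %s/%s 1 %d (0) %d",
      r$divergence, r$contig, r$start + 1, r$end, r$family,
      r$order, r$family, r$end - r$start, i
    ), con)
  }
  invisible(path)
}

#' Per-family repeat summaries
#'
#' Groups records by (order, family) and reports copy count, total bp,
#' percent of genome and mean copy length — the genome-wide repeat
#' catalog arithmetic. Each record counts fully; overlaps are not
#' deduplicated here (use [pct_repetitive()] for union coverage).
#'
#' @param records Repeat record `data.frame`.
#' @param genome_bp Assembly size used as the percentage denominator.
#' @return `data.frame`: `order`, `family`, `count`, `total_bp`,
#'   `pct_of_genome`, `mean_length`.
#' @export
family_summary <- function(records, genome_bp) {
  stopifnot(genome_bp > 0)
  if (nrow(records) == 0) {
    return(data.frame(order = character(), family = character(),
                      count = integer(), total_bp = numeric(),
                      pct_of_genome = numeric(), mean_length = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(records$order, records$family, sep = "\r")
  bp <- records$end - records$start
  agg <- data.frame(
    key = unique(key), stringsAsFactors = FALSE
  )
  cnt <- tapply(bp, key, length)
  tot <- tapply(bp, key, sum)
  agg$count <- as.integer(cnt[agg$key])
  agg$total_bp <- as.numeric(tot[agg$key])
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  out <- data.frame(
    order = vapply(parts, `[[`, character(1), 1),
    family = vapply(parts, `[[`, character(1), 2),
    count = agg$count,
    total_bp = agg$total_bp,
    pct_of_genome = 100 * agg$total_bp / genome_bp,
    mean_length = agg$total_bp / agg$count,
    stringsAsFactors = FALSE
  )
  out[order(out$order, out$family), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Enrichment ratio of region vs genome repeat density
#'
#' The comparison arithmetic used for breakpoint-region repeat tables:
#' the region's percent coverage by a family relative to the genome-wide
#' percent, expressed as a percentage (100 means no enrichment).
#' @param region_pct,genome_pct Percent coverage in the regions / genome.
#' @return `100 * region_pct / genome_pct` (`NA` when `genome_pct` is 0).
#' @export
enrichment_ratio <- function(region_pct, genome_pct) {
  ifelse(genome_pct == 0, NA_real_, 100 * region_pct / genome_pct)
}

#' Repeat enrichment around breakpoints
#'
#' Builds the union of `flank` bp on both sides of every breakpoint
#' (clipped to contig bounds), computes per-family stats inside those
#' regions and genome-wide, and reports the enrichment ratio and the
#' mean-length difference per family. By default records are clipped at
#' region boundaries for the region stats; `clip = FALSE` counts any
#' overlapping record in full.
#'
#' @param records Repeat record `data.frame`.
#' @param breakpoints `data.frame` with `contig`, `pos`.
#' @param contigs A [contig_set()] (for clipping flanks at contig ends).
#' @param flank Half-width of each breakpoint region in bp.
#' @param genome_bp Genome size denominator for the genome-wide stats.
#' @param clip Clip records at region boundaries for region stats.
#' @return `data.frame` with genome (`genome_*`) and region (`region_*`)
#'   count/bp/pct/mean-length columns plus `ratio_pct` and `delta_mean`
#'   per family, and the region set as attribute `regions`.
#' @export
region_enrichment <- function(records, breakpoints, contigs, flank = 75000,
                              genome_bp, clip = TRUE) {
  if (flank <= 0) stop("flank must be positive")
  regions <- breakpoint_regions(breakpoints, contigs, flank)
  region_bp <- union_bp(regions)
  gen <- family_summary(records, genome_bp)
  names(gen) <- c("order", "family", "genome_count", "genome_bp",
                  "genome_pct", "genome_mean")
  reg_records <- clip_to_regions(records, regions, clip)
  if (region_bp > 0 && nrow(reg_records)) {
    reg <- family_summary(reg_records, region_bp)
    names(reg) <- c("order", "family", "region_count", "region_bp",
                    "region_pct", "region_mean")
    out <- merge(gen, reg, by = c("order", "family"), all.x = TRUE)
  } else {
    out <- gen
    out$region_count <- NA_integer_; out$region_bp <- NA_real_
    out$region_pct <- NA_real_; out$region_mean <- NA_real_
  }
  out$ratio_pct <- enrichment_ratio(out$region_pct, out$genome_pct)
  out$delta_mean <- out$region_mean - out$genome_mean
  out <- out[order(out$order, out$family), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "regions") <- regions
  out
}

breakpoint_regions <- function(breakpoints, contigs, flank) {
  if (nrow(breakpoints) == 0) return(empty_intervals())
  L <- contig_length(contigs, breakpoints$contig)
  merge_intervals(data.frame(
    contig = breakpoints$contig,
    start = pmax(0, breakpoints$pos - flank),
    end = pmin(L, breakpoints$pos + flank),
    stringsAsFactors = FALSE
  ), 0)
}

# records restricted to the region set; clipped at boundaries or kept
# whole when clip = FALSE
clip_to_regions <- function(records, regions, clip = TRUE) {
  if (nrow(records) == 0 || nrow(regions) == 0) return(records[0, , drop = FALSE])
  gr <- as_gr(records)
  gb <- GenomicRanges::reduce(as_gr(regions))
  hits <- GenomicRanges::findOverlaps(gr, gb)
  if (!length(hits)) return(records[0, , drop = FALSE])
  q <- S4Vectors::queryHits(hits)
  out <- records[q, , drop = FALSE]
  if (clip) {
    ov <- GenomicRanges::pintersect(gr[q], gb[S4Vectors::subjectHits(hits)])
    out$start <- GenomicRanges::start(ov) - 1
    out$end <- GenomicRanges::end(ov)
  } else {
    out <- out[!duplicated(q), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Percent of a region set covered by repeats
#'
#' Union-based coverage: overlapping and nested records are deduplicated
#' before dividing by the region span, so the result never exceeds 100.
#' @param records Repeat record `data.frame`.
#' @param regions Interval `data.frame`.
#' @return Percentage of region bp covered by at least one record.
#' @export
pct_repetitive <- function(records, regions) {
  denom <- union_bp(regions)
  if (denom == 0) return(NA_real_)
  100 * sum(covered_bp(merge_intervals(regions, 0),
                       records[, c("contig", "start", "end")])) / denom
}

#' Repeat divergence landscape
#'
#' Bins each record's bp by its divergence from the family consensus (a
#' proxy for copy age) and reports percent-of-genome per (family, bin) —
#' the data behind repeat-landscape plots. Records without a divergence
#' value are excluded and their count reported as an attribute.
#'
#' @param records Repeat record `data.frame`.
#' @param bin_width Divergence bin width in percent.
#' @param genome_bp Genome size denominator.
#' @return Matrix family x divergence-bin of percent of genome, with
#'   attribute `n_missing_divergence`.
#' @export
divergence_landscape <- function(records, bin_width = 1.0, genome_bp) {
  stopifnot(bin_width > 0, genome_bp > 0)
  has <- !is.na(records$divergence)
  r <- records[has, , drop = FALSE]
  if (nrow(r) == 0) {
    m <- matrix(numeric(0), 0, 0)
    attr(m, "n_missing_divergence") <- sum(!has)
    return(m)
  }
  bin <- floor(r$divergence / bin_width)
  bins <- seq(0, max(bin))
  fams <- sort(unique(paste(r$order, r$family, sep = "/")))
  m <- matrix(0, length(fams), length(bins),
              dimnames = list(fams, sprintf("[%g,%g)", bins * bin_width,
                                            (bins + 1) * bin_width)))
  bp <- r$end - r$start
  fam <- paste(r$order, r$family, sep = "/")
  for (i in seq_len(nrow(r))) {
    m[fam[i], bin[i] + 1] <- m[fam[i], bin[i] + 1] + bp[i]
  }
  m <- 100 * m / genome_bp
  attr(m, "n_missing_divergence") <- sum(!has)
  m
}
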