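#' Genomic intervals
#'
#' Throughout the package an interval set is a plain `data.frame` with
#' columns `contig` (character), `start` and `end` (integer-valued, 0-based
#' half-open, so a span of `[0, 10)` covers the first ten bases). This is the
#' same convention as BED; conversion to 1-based inclusive coordinates
#' happens only at VCF/sync/AGP boundaries.
#'
#' @param contig Character vector of contig ids.
#' @param start,end Numeric vectors, 0-based half-open.
#' @return A `data.frame` with columns `contig`, `start`, `end`.
#' @export
intervals <- function(contig = character(), start = integer(), end = integer()) {
  x <- data.frame(
    contig = as.character(contig),
    start = as.numeric(start),
    end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("contig", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$contig) | !nzchar(x$contig))) {
    stop("interval contig ids must be non-empty")
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop("invalid interval (need 0 <= start < end) at row ", bad[1])
  }
  invisible(x)
}

empty_intervals <- function() {
  data.frame(contig = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

# 0-based half-open data.frame <-> 1-based GRanges
as_gr <- function(x) {
  GenomicRanges::GRanges(x$contig, IRanges::IRanges(x$start + 1, x$end))
}

gr_as_df <- function(gr) {
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  df[order(df$contig, df$start), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Merge intervals that are closer than a gap
#'
#' Collapses, per contig, any intervals whose separating gap is at most
#' `max_gap` bp (so touching or overlapping intervals always merge). This is
#' the `bedtools merge -d` operation used when consolidating flagged windows
#' into candidate regions.
#'
#' @param x Interval `data.frame` (see [intervals()]).
#' @param max_gap Maximum gap in bp across which two intervals are joined.
#' @return Sorted, disjoint interval `data.frame` covering the input union.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  if (!is.numeric(max_gap) || length(max_gap) != 1 || is.na(max_gap) || max_gap < 0) {
    stop("max_gap must be a single non-negative number")
  }
  validate_intervals(x)
  if (nrow(x) == 0) return(empty_intervals())
  gr <- GenomicRanges::reduce(as_gr(x), min.gapwidth = max_gap + 1)
  gr_as_df(gr)
}

#' Keep intervals sufficiently covered by another set
#'
#' Returns the intervals of `a` whose total overlap with the union of `b`
#' is at least `min_frac` of their own length — the `bedtools intersect
#' -f` filter used to require dual evidence over a candidate region.
#'
#' @param a,b Interval `data.frame`s.
#' @param min_frac Required covered fraction of each `a` interval, in (0, 1].
#' @return The qualifying rows of `a` (original spans, original order).
#' @export
intersect_fraction <- function(a, b, min_frac) {
  if (!is.numeric(min_frac) || length(min_frac) != 1 || is.na(min_frac) ||
      min_frac <= 0 || min_frac > 1) {
    stop("min_frac must be a single value in (0, 1]")
  }
  validate_intervals(a)
  validate_intervals(b)
  if (nrow(a) == 0) return(empty_intervals())
  cov <- covered_bp(a, b)
  a[cov >= min_frac * (a$end - a$start), , drop = FALSE] |> `rownames<-`(NULL)
}

# per-row bp of each interval of `a` covered by union(b)
covered_bp <- function(a, b) {
  if (nrow(b) == 0) return(numeric(nrow(a)))
  ga <- as_gr(a)
  gb <- GenomicRanges::reduce(as_gr(b))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
  cov <- numeric(nrow(a))
  if (length(hits)) {
    ov <- suppressWarnings(GenomicRanges::pintersect(
      ga[S4Vectors::queryHits(hits)], gb[S4Vectors::subjectHits(hits)]
    ))
    w <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    cov[as.integer(names(w))] <- as.numeric(w)
  }
  cov
}

#' Total bp in the union of an interval set
#' @param x Interval `data.frame`.
#' @return Number of distinct bases covered.
#' @export
union_bp <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(0)
  sum(GenomicRanges::width(GenomicRanges::reduce(as_gr(x))))
}

#' Read / write BED3
#'
#' Minimal 3-column BED support (0-based half-open, tab separated), the
#' interchange format for all interval lists.
#' @param path File path.
#' @return `read_bed` returns an interval `data.frame`.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("contig", "start", "end"),
                         colClasses = c("character", "numeric", "numeric"))
  validate_intervals(x)
  x
}

#' @rdname read_bed
#' @param x Interval `data.frame` to write.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  utils::write.table(
    x[, c("contig", "start", "end")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
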