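#' Classify a BAC-end pair against an assembly
#'
#' Mirrors the standard clone-pair validation classes. Only hits with an
#' E-value strictly below `e_threshold` count; the best such hit per end
#' is used. Classes: `unaligned` (no end passes), `1` (one end passes),
#' `4` (top hits on different contigs), `2` (same contig, convergent
#' orientation — forward end before reverse end — and outer span within
#' `span_range`), `3` otherwise (wrong orientation or span).
#'
#' @param hits_end1,hits_end2 `data.frame`s of hits per end: `contig`,
#'   `pos`, `strand`, `e_value`. May be empty.
#' @param span_range Valid clone span `(min, max)` in bp.
#' @param e_threshold Maximum (exclusive) E-value for a hit to count.
#' @return One of `"unaligned"`, `"1"`, `"2"`, `"3"`, `"4"`.
#' @export
classify_bac_pair <- function(hits_end1, hits_end2, span_range = c(5e4, 4e5),
                              e_threshold = 1e-150) {
  top <- function(h) {
    if (is.null(h) || nrow(h) == 0) return(NULL)
    h <- h[h$e_value < e_threshold, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    h[which.min(h$e_value), , drop = FALSE]
  }
  t1 <- top(hits_end1); t2 <- top(hits_end2)
  if (is.null(t1) && is.null(t2)) return("unaligned")
  if (is.null(t1) || is.null(t2)) return("1")
  if (t1$contig != t2$contig) return("4")
  fwd <- if (t1$strand == "+") t1 else t2
  rev <- if (t1$strand == "+") t2 else t1
  convergent <- t1$strand != t2$strand && fwd$pos <= rev$pos
  span <- abs(t2$pos - t1$pos) + 1
  if (convergent && span >= span_range[1] && span <= span_range[2]) return("2")
  "3"
}

#' Classify a table of BAC-end pairs
#'
#' Vectorized driver over a clone table (one row per clone, as produced
#' by [simulate_bac_ends()]).
#' @param pairs Clone table with per-end `contig1/pos1/strand1/e_value1`
#'   and `contig2/...` columns.
#' @inheritParams classify_bac_pair
#' @return Character vector of classes, one per clone.
#' @export
classify_bac_pairs <- function(pairs, span_range = c(5e4, 4e5),
                               e_threshold = 1e-150) {
  vapply(seq_len(nrow(pairs)), function(i) {
    classify_bac_pair(
      data.frame(contig = pairs$contig1[i], pos = pairs$pos1[i],
                 strand = pairs$strand1[i], e_value = pairs$e_value1[i],
                 stringsAsFactors = FALSE),
      data.frame(contig = pairs$contig2[i], pos = pairs$pos2[i],
                 strand = pairs$strand2[i], e_value = pairs$e_value2[i],
                 stringsAsFactors = FALSE),
      span_range, e_threshold
    )
  }, character(1))
}

#' Average likelihood-score ranks across libraries
#'
#' Ranks every assembly within each sequencing library by its overall
#' likelihood score (dense ranks, higher score = rank 1, ties share a
#' rank), then averages the ranks across libraries. The result is a
#' scale-free composite: any monotone per-library transform of the
#' scores leaves it unchanged.
#'
#' @param scores Numeric matrix or `data.frame`, assemblies x libraries,
#'   with assembly ids as row names.
#' @return `data.frame` sorted by average rank then assembly id:
#'   `assembly`, `avg_rank`, plus one rank column per library.
#' @export
rank_average <- function(scores) {
  m <- as.matrix(scores)
  if (is.null(rownames(m))) rownames(m) <- paste0("assembly", seq_len(nrow(m)))
  ranks <- apply(m, 2, function(col) {
    # dense rank, best (highest) score = 1
    match(col, sort(unique(col), decreasing = TRUE))
  })
  ranks <- matrix(ranks, nrow = nrow(m), dimnames = dimnames(m))
  avg <- rowMeans(ranks)
  out <- data.frame(assembly = rownames(m), avg_rank = avg,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ranks))
  out <- out[order(out$avg_rank, out$assembly), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardized PCA over assembly metric vectors
#'
#' Principal component analysis of the per-assembly metric table with
#' columns centered and scaled to unit variance, so metrics on wildly
#' different scales (likelihood scores, NG50, base-pair totals)
#' contribute comparably. Constant columns are dropped with a warning
#' (they carry no variance to decompose). For reproducibility the sign
#' of each component is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param metrics `data.frame` with an `assembly` id column and numeric
#'   metric columns, or a numeric matrix with row names.
#' @return List: `scores` (assemblies x components), `loadings`
#'   (metrics x components), `explained` (variance per component; sums
#'   to the number of metric columns kept).
#' @export
pca_metrics <- function(metrics) {
  if (is.data.frame(metrics) && "assembly" %in% names(metrics)) {
    ids <- metrics$assembly
    m <- as.matrix(metrics[, setdiff(names(metrics), "assembly"), drop = FALSE])
    rownames(m) <- ids
  } else {
    m <- as.matrix(metrics)
  }
  if (nrow(m) < 3) stop("PCA needs at least 3 assemblies")
  const <- apply(m, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("dropping constant metric column(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  list(scores = scores, loadings = loadings, explained = p$sdev^2)
}

#' Select the best assembly
#'
#' Applies the ranking rule: the winner is the assembly with the best
#' (lowest) average likelihood rank among those satisfying optional
#' constraints, e.g. a total-size band around the genome-size estimate.
#'
#' @param ranked Output of [rank_average()].
#' @param metrics Optional `data.frame` with `assembly` and `total_bp`
#'   columns (needed when `size_band` is given).
#' @param size_band Optional `c(min_bp, max_bp)` constraint on
#'   `total_bp`.
#' @return List: `assembly` (winner id), `avg_rank`, `runner_up`,
#'   `margin` (runner-up average rank minus winner's).
#' @export
select_assembly <- function(ranked, metrics = NULL, size_band = NULL) {
  ok <- ranked
  if (!is.null(size_band)) {
    stopifnot(!is.null(metrics))
    sz <- stats::setNames(metrics$total_bp, metrics$assembly)[ranked$assembly]
    ok <- ranked[sz >= size_band[1] & sz <= size_band[2], , drop = FALSE]
  }
  if (nrow(ok) == 0) stop("no assembly satisfies the constraints")
  list(
    assembly = ok$assembly[1],
    avg_rank = ok$avg_rank[1],
    runner_up = if (nrow(ok) > 1) ok$assembly[2] else NA_character_,
    margin = if (nrow(ok) > 1) ok$avg_rank[2] - ok$avg_rank[1] else NA_real_
  )
}
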