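#' Half-up rounding
#'
#' R's `round()` rounds half to even; published tables almost always
#' round half away from zero, so every printed figure in this package
#' goes through this single helper.
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Old-vs-new comparison table
#'
#' For every label shared between the two inputs, reports the absolute
#' difference (`new - old`) and the percent change relative to the *old*
#' value, rounded half-up to one decimal. A `Total` row sums the shared
#' labels. Labels with `old = 0` get `NA` percent change.
#'
#' @param old,new Named numeric vectors (e.g. per-linkage-group anchored
#'   sizes of two assemblies).
#' @param total Append the `Total` row (default `TRUE`).
#' @return `data.frame`: `label`, `value_old`, `value_new`, `difference`,
#'   `pct_change`.
#' @export
compare_table <- function(old, new, total = TRUE) {
  labels <- intersect(names(old), names(new))
  if (!length(labels)) stop("no shared labels between old and new")
  o <- as.numeric(old[labels]); n <- as.numeric(new[labels])
  if (total) {
    labels <- c(labels, "Total")
    o <- c(o, sum(o)); n <- c(n, sum(n))
  }
  d <- n - o
  data.frame(
    label = labels, value_old = o, value_new = n, difference = d,
    pct_change = ifelse(o == 0, NA_real_, round_half_up(100 * d / o, 1)),
    stringsAsFactors = FALSE
  )
}

#' Annotation category comparison
#'
#' [compare_table()] over annotation feature counts, without a total row
#' (annotation categories overlap, so their sum is not meaningful).
#' @inheritParams compare_table
#' @export
annotation_compare <- function(old, new) {
  compare_table(old, new, total = FALSE)
}

#' Polishing correction summary
#'
#' Per-type percentages of consensus-polishing corrections (insertions,
#' substitutions, deletions), rounded half-up to two decimals.
#' @param counts Named numeric vector with elements `insertions`,
#'   `substitutions`, `deletions`.
#' @return List of class `correction_summary`: the counts, `total` and
#'   `pct` (named, two decimals).
#' @export
correction_summary <- function(counts) {
  need <- c("insertions", "substitutions", "deletions")
  stopifnot(all(need %in% names(counts)))
  counts <- counts[need]
  total <- sum(counts)
  structure(list(
    n_insertions = unname(counts["insertions"]),
    n_substitutions = unname(counts["substitutions"]),
    n_deletions = unname(counts["deletions"]),
    total = total,
    pct = round_half_up(100 * counts / total, 2)
  ), class = "correction_summary")
}

#' @export
print.correction_summary <- function(x, ...) {
  cat(sprintf("%s corrections: %.2f%% insertions, %.2f%% substitutions, %.2f%% deletions\n",
              format(x$total, big.mark = ","), x$pct["insertions"],
              x$pct["substitutions"], x$pct["deletions"]))
  invisible(x)
}

#' Gap bookkeeping from an AGP
#'
#' Counts gap rows and gap bp in an AGP and expresses the gap content as
#' a percentage of the assembly, two decimals half-up. By default the
#' denominator is the total span of the AGP objects; pass `total_bp` to
#' use the full assembly size (anchored plus unanchored) instead.
#'
#' @param agp AGP `data.frame` (see [read_agp()]).
#' @param total_bp Optional denominator override in bp.
#' @return List: `n_gaps`, `gap_bp`, `pct_n`.
#' @export
gap_report <- function(agp, total_bp = NULL) {
  gaps <- agp[agp$component_type %in% c("N", "U"), , drop = FALSE]
  gap_bp <- if (nrow(gaps)) sum(as.numeric(gaps$component_id)) else 0
  if (is.null(total_bp)) {
    total_bp <- sum(tapply(agp$object_end, agp$object, max))
  }
  list(
    n_gaps = nrow(gaps),
    gap_bp = gap_bp,
    pct_n = round_half_up(100 * gap_bp / total_bp, 2)
  )
}

#' Write a comparison table as markdown or CSV
#'
#' @param x `data.frame` from [compare_table()].
#' @param path File path; `.md` gets a pipe table, anything else CSV.
#' @export
write_report <- function(x, path) {
  if (grepl("\\.md$", path)) {
    header <- paste0("| ", paste(names(x), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(x)), collapse = "|"), "|")
    rows <- apply(x, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, sep, rows), path)
  } else {
    utils::write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}
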