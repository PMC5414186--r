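#' Contig sets
#'
#' A `contig_set` is the package's assembly container: an ordered set of
#' uniquely named contigs with lengths and, optionally, sequences (a
#' [Biostrings::DNAStringSet]). Lengths alone are enough for interval and
#' coverage work; sequences are needed for breaking, anchoring and FASTA
#' output.
#'
#' @param lengths Named numeric vector of contig lengths, or `NULL` when
#'   `seq` is given.
#' @param seq Optional named `DNAStringSet` (or named character vector).
#' @return An object of class `contig_set` with elements `id`, `length`
#'   and `seq` (`NULL` when sequence-free).
#' @export
contig_set <- function(lengths = NULL, seq = NULL) {
  if (!is.null(seq)) {
    if (is.character(seq)) seq <- Biostrings::DNAStringSet(seq)
    if (is.null(names(seq)) || anyDuplicated(names(seq))) {
      stop("sequences must carry unique names")
    }
    if (is.null(lengths)) {
      lengths <- stats::setNames(Biostrings::width(seq), names(seq))
    } else if (!identical(as.numeric(unname(lengths[names(seq)])),
                          as.numeric(Biostrings::width(seq)))) {
      stop("declared lengths disagree with sequence lengths")
    }
  }
  if (is.null(lengths) || length(lengths) == 0) stop("empty contig set")
  if (is.null(names(lengths)) || anyDuplicated(names(lengths))) {
    stop("contig ids must be unique and named")
  }
  if (any(lengths < 1)) stop("contig lengths must be >= 1")
  structure(
    list(id = names(lengths), length = as.numeric(unname(lengths)), seq = seq),
    class = "contig_set"
  )
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set: %d contigs, %s bp%s\n",
              length(x$id), format(sum(x$length), big.mark = ","),
              if (is.null(x$seq)) " (lengths only)" else ""))
  invisible(x)
}

#' @rdname contig_set
#' @param x A `contig_set`.
#' @export
contig_lengths <- function(x) {
  stopifnot(inherits(x, "contig_set"))
  stats::setNames(x$length, x$id)
}

contig_length <- function(x, id) {
  i <- match(id, x$id)
  if (anyNA(i)) stop("unknown contig: ", id[which(is.na(i))[1]])
  x$length[i]
}

#' Assembly summary metrics
#'
#' Standard contiguity statistics for an assembly: totals, gap content
#' (runs of `N`), longest and mean contig, N50 and NG50. N50 is the length
#' at which the cumulative sum of descending contig lengths reaches half
#' the assembly size; NG50 uses half the *estimated genome size* instead,
#' which makes assemblies of different total size comparable. When the
#' assembly is too small to reach half the genome estimate, NG50 is
#' reported as 0 with a warning (ranking code treats 0 as worst).
#'
#' @param contigs A [contig_set()].
#' @param genome_size_estimate Estimated genome size in bp (required for
#'   NG50; there is no defensible default, so it must be supplied).
#' @return List of class `assembly_metrics`: `total_bp`, `non_gap_bp`,
#'   `gap_bp`, `n_contigs`, `longest`, `mean_len`, `n50`, `ng50`, `pct_n`.
#' @export
assembly_metrics <- function(contigs, genome_size_estimate) {
  stopifnot(inherits(contigs, "contig_set"))
  if (!is.numeric(genome_size_estimate) || genome_size_estimate <= 0) {
    stop("genome_size_estimate must be positive")
  }
  len <- contigs$length
  total <- sum(len)
  gap_bp <- 0
  if (!is.null(contigs$seq)) {
    gap_bp <- sum(Biostrings::letterFrequency(contigs$seq, "N"))
  }
  ng50 <- nx_length(len, genome_size_estimate / 2)
  if (is.na(ng50)) {
    warning("assembly smaller than half the genome size estimate; NG50 reported as 0")
    ng50 <- 0
  }
  structure(list(
    total_bp = total,
    non_gap_bp = total - gap_bp,
    gap_bp = gap_bp,
    n_contigs = length(len),
    longest = max(len),
    mean_len = total / length(len),
    n50 = nx_length(len, total / 2),
    ng50 = ng50,
    pct_n = 100 * gap_bp / total
  ), class = "assembly_metrics")
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("assembly: %d contigs, %s bp (%.2f%% N)\n",
           "longest %s, mean %s, N50 %s, NG50 %s\n"),
    x$n_contigs, format(x$total_bp, big.mark = ","), x$pct_n,
    format(x$longest, big.mark = ","), format(round(x$mean_len), big.mark = ","),
    format(x$n50, big.mark = ","), format(x$ng50, big.mark = ",")
  ))
  invisible(x)
}

# length at which descending cumulative lengths first reach `half`;
# NA when unreachable
nx_length <- function(lengths, half) {
  s <- sort(lengths, decreasing = TRUE)
  i <- which(cumsum(s) >= half)
  if (length(i) == 0) return(NA_real_)
  s[i[1]]
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings keeping the package's `contig_set`
#' container; output is wrapped at 80 columns.
#' @param path File path.
#' @return `read_fasta` returns a [contig_set()] with sequence.
#' @export
read_fasta <- function(path) {
  contig_set(seq = Biostrings::readDNAStringSet(path))
}

#' @rdname read_fasta
#' @param contigs A `contig_set` carrying sequence.
#' @export
write_fasta <- function(contigs, path) {
  stopifnot(inherits(contigs, "contig_set"))
  if (is.null(contigs$seq)) stop("contig_set has no sequences to write")
  Biostrings::writeXStringSet(contigs$seq, path, width = 80)
  invisible(path)
}
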