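#' Minimal VCF read / write for variant site lists
#'
#' The misassembly scan needs only CHROM, POS and QUAL; these helpers
#' move site tables in and out of a minimal single-sample-free VCF
#' (1-based POS in the file, 0-based in memory).
#'
#' @param path File path.
#' @return `read_vcf` returns a `data.frame` of `contig`, `pos`
#'   (0-based), `qual`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(contig = character(), pos = numeric(), qual = numeric(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    contig = vapply(f, `[[`, character(1), 1),
    pos = as.numeric(vapply(f, `[[`, character(1), 2)) - 1,
    qual = as.numeric(vapply(f, `[[`, character(1), 6)),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_vcf
#' @param sites Variant site `data.frame` (`contig`, `pos`, `qual`).
#' @export
write_vcf <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(sites)) {
    writeLines(sprintf("%s\t%d\t.\tN\tA\t%.4g\t.\t.",
                       sites$contig, as.integer(sites$pos + 1), sites$qual), con)
  }
  invisible(path)
}

#' Read / write marker-hit tables
#'
#' Tab-separated with header: `marker`, `map`, `linkage_group`,
#' `map_position`, `contig`, `contig_pos` (0-based), `strand`.
#' @param path File path.
#' @export
read_marker_hits <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "character",
                                   "numeric", "character", "numeric",
                                   "character"))
}

#' @rdname read_marker_hits
#' @param hits Marker-hit `data.frame`.
#' @export
write_marker_hits <- function(hits, path) {
  cols <- c("marker", "map", "linkage_group", "map_position",
            "contig", "contig_pos", "strand")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write pair placement tables
#'
#' BEDPE-like TSV with header: per-end contig/start/end/strand columns,
#' 0-based half-open.
#' @param path File path.
#' @export
read_pairs <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_pairs
#' @param pairs Pair `data.frame`.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a scenario truth table
#'
#' Serializes the ground truth of a synthetic scenario (junctions,
#' lift-over map, optional sex-determination region bounds) as JSON and
#' reads it back losslessly.
#' @param truth List with elements `junctions`, `map` and optionally
#'   `sd_region`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x
}
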