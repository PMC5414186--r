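#' Assign contigs to linkage groups
#'
#' A contig is anchored to the linkage group holding the plurality of its
#' marker hits, provided that group has at least `min_markers` hits on
#' the contig (the two-marker rule by default). Contigs whose hits give
#' `min_markers`-strong support to two or more groups are additionally
#' flagged as *problem* contigs — the map-conflict count used as a
#' per-assembly misassembly metric — but are still assigned to their
#' plurality group. A tie between top groups leaves the contig
#' unanchored.
#'
#' @param hits Marker-hit `data.frame` (`contig`, `linkage_group`, ...).
#' @param min_markers Minimum hits on one linkage group to anchor.
#' @return List: `assignments` (named character vector contig ->
#'   linkage group), `unanchored` (contig ids), `problem` (contig ids
#'   with multi-group support).
#' @export
assign_contigs <- function(hits, min_markers = 2) {
  assignments <- character(0)
  unanchored <- character(0)
  problem <- character(0)
  for (ctg in unique(hits$contig)) {
    tab <- sort(table(hits$linkage_group[hits$contig == ctg]), decreasing = TRUE)
    if (tab[1] < min_markers) {
      unanchored <- c(unanchored, ctg)
      next
    }
    if (length(tab) > 1 && tab[2] == tab[1]) {
      unanchored <- c(unanchored, ctg)
      if (tab[2] >= min_markers) problem <- c(problem, ctg)
      next
    }
    assignments[ctg] <- names(tab)[1]
    if (length(tab) > 1 && tab[2] >= min_markers) problem <- c(problem, ctg)
  }
  list(assignments = assignments, unanchored = unanchored, problem = problem)
}

#' Count problem contigs
#'
#' Number of contigs with at least `min_markers` hits on two or more
#' linkage groups — the candidate-assembly misassembly metric derived
#' from map alignment.
#' @inheritParams assign_contigs
#' @return Integer count.
#' @export
count_problem_contigs <- function(hits, min_markers = 2) {
  if (nrow(hits) == 0) return(0L)
  length(assign_contigs(hits, min_markers)$problem)
}

#' Order and orient anchored contigs
#'
#' Within each linkage group, contigs are ordered by the median map
#' position of their hits (ties broken by contig id for determinism).
#' Orientation is the sign of the Spearman rank correlation between
#' position on the contig and map position: positive is `+`, negative is
#' `-`, and zero or undefined (all map positions tied) is `ambiguous`
#' and laid out as `+`.
#'
#' @param assignment Output of [assign_contigs()].
#' @param hits Marker-hit `data.frame`.
#' @return `data.frame` of class `chromosome_layout`: `linkage_group`,
#'   `contig`, `orientation` (`+`, `-` or `ambiguous`), ordered by group
#'   then placement.
#' @export
order_orient <- function(assignment, hits) {
  asg <- assignment$assignments
  rows <- lapply(names(asg), function(ctg) {
    h <- hits[hits$contig == ctg & hits$linkage_group == asg[[ctg]], , drop = FALSE]
    rho <- if (nrow(h) < 2 || stats::sd(h$map_position) == 0 ||
               stats::sd(h$contig_pos) == 0) 0
    else suppressWarnings(stats::cor(h$contig_pos, h$map_position,
                                     method = "spearman"))
    if (is.na(rho)) rho <- 0
    data.frame(
      linkage_group = asg[[ctg]], contig = ctg,
      median_pos = stats::median(h$map_position),
      orientation = if (rho > 0) "+" else if (rho < 0) "-" else "ambiguous",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(linkage_group = character(), contig = character(),
                      median_pos = numeric(), orientation = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$linkage_group, out$median_pos, out$contig), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("chromosome_layout", class(out))
  out
}

#' Build linkage-group pseudomolecules and AGP
#'
#' Concatenates each linkage group's contigs in layout order and
#' orientation (`-` contigs reverse-complemented, `ambiguous` treated as
#' `+`), separating consecutive contigs with a fixed run of `gap` `N`s,
#' and records the construction as AGP v2.1 rows (component type `W`,
#' gap type `contig`, linkage yes, evidence `map`). The gap count is
#' therefore `sum(placements - 1)` over linkage groups.
#'
#' @param layout Output of [order_orient()].
#' @param contigs A [contig_set()] with sequence.
#' @param gap Join gap size in bp.
#' @return List: `fasta` ([contig_set()] of pseudomolecules), `agp`
#'   (`data.frame` of AGP rows), `n_gaps`, `gap_bp`.
#' @export
build_chromosomes <- function(layout, contigs, gap = 1e4) {
  stopifnot(inherits(contigs, "contig_set"), !is.null(contigs$seq))
  agp <- list()
  seqs <- character(0)
  for (lg in unique(layout$linkage_group)) {
    lay <- layout[layout$linkage_group == lg, , drop = FALSE]
    parts <- character(0)
    at <- 0; partno <- 0
    for (i in seq_len(nrow(lay))) {
      if (i > 1) {
        partno <- partno + 1
        agp[[length(agp) + 1]] <- data.frame(
          object = lg, object_beg = at + 1, object_end = at + gap,
          part_number = partno, component_type = "N", component_id = gap,
          component_beg = "contig", component_end = "yes", orientation = "map",
          stringsAsFactors = FALSE
        )
        parts <- c(parts, strrep("N", gap))
        at <- at + gap
      }
      ctg <- lay$contig[i]
      L <- contig_length(contigs, ctg)
      ori <- lay$orientation[i]
      s <- as.character(contigs$seq[[ctg]])
      if (ori == "-") {
        s <- as.character(Biostrings::reverseComplement(contigs$seq[[ctg]]))
      }
      partno <- partno + 1
      agp[[length(agp) + 1]] <- data.frame(
        object = lg, object_beg = at + 1, object_end = at + L,
        part_number = partno, component_type = "W", component_id = ctg,
        component_beg = "1", component_end = as.character(L),
        orientation = if (ori == "-") "-" else "+",
        stringsAsFactors = FALSE
      )
      parts <- c(parts, s)
      at <- at + L
    }
    seqs[lg] <- paste(parts, collapse = "")
  }
  agp <- do.call(rbind, agp)
  n_gaps <- sum(agp$component_type == "N")
  list(
    fasta = contig_set(seq = Biostrings::DNAStringSet(seqs)),
    agp = agp,
    n_gaps = n_gaps,
    gap_bp = if (n_gaps) sum(as.numeric(agp$component_id[agp$component_type == "N"])) else 0
  )
}

#' Write / read AGP v2.1
#'
#' Nine-column tab-separated AGP (1-based inclusive object and component
#' coordinates).
#' @param agp AGP `data.frame` from [build_chromosomes()].
#' @param path File path.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                         col.names = c("object", "object_beg", "object_end",
                                       "part_number", "component_type",
                                       "component_id", "component_beg",
                                       "component_end", "orientation"),
                         colClasses = c("character", "numeric", "numeric",
                                        "integer", "character", "character",
                                        "character", "character", "character"))
  x
}

#' Reconstruct pseudomolecules from AGP plus contigs
#'
#' The AGP round-trip inverse of [build_chromosomes()]: replaying the AGP
#' rows against the contig sequences must reproduce the anchored FASTA
#' byte for byte.
#'
#' @param agp AGP `data.frame`.
#' @param contigs A [contig_set()] with sequence.
#' @return [contig_set()] of reconstructed objects.
#' @export
agp_to_fasta <- function(agp, contigs) {
  stopifnot(inherits(contigs, "contig_set"), !is.null(contigs$seq))
  seqs <- vapply(unique(agp$object), function(obj) {
    rows <- agp[agp$object == obj, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    paste(vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (r$component_type == "N") return(strrep("N", as.numeric(r$component_id)))
      s <- Biostrings::subseq(contigs$seq[[r$component_id]],
                              as.numeric(r$component_beg),
                              as.numeric(r$component_end))
      if (r$orientation == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1)), collapse = "")
  }, character(1))
  contig_set(seq = Biostrings::DNAStringSet(seqs))
}
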