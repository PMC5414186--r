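#' Variant-density windows
#'
#' Tiles every contig with fixed non-overlapping windows and counts the
#' variant sites passing the quality filter (strictly greater than
#' `min_qual`). A window is flagged when its count strictly exceeds
#' `density_threshold` variants per kbp scaled by the window's true width,
#' i.e. more than 10 qualifying variants in a full 10 kbp window at the
#' defaults; the last partial window of a contig is scaled by its actual
#' width.
#'
#' @param sites `data.frame` of variant sites: `contig`, `pos` (0-based),
#'   `qual`.
#' @param contigs A [contig_set()].
#' @param window Window width in bp.
#' @param min_qual Quality cutoff; only sites with `qual > min_qual` count.
#' @param density_threshold Variants per kbp above which a window flags.
#' @return `data.frame`: `contig`, `start`, `end`, `variant_count`,
#'   `flagged`.
#' @export
variant_density_windows <- function(sites, contigs, window = 1e4,
                                    min_qual = 10, density_threshold = 1.0) {
  stopifnot(inherits(contigs, "contig_set"), window > 0)
  bad <- !(sites$contig %in% contigs$id)
  if (any(bad)) stop("variant site on unknown contig: ", sites$contig[which(bad)[1]])
  over <- sites$pos >= contig_length(contigs, sites$contig)
  if (any(over)) {
    i <- which(over)[1]
    stop(sprintf("variant beyond contig end: %s:%d", sites$contig[i], sites$pos[i]))
  }
  keep <- sites[sites$qual > min_qual, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_along(contigs$id), function(i) {
    id <- contigs$id[i]; L <- contigs$length[i]
    starts <- seq(0, max(0, L - 1), by = window)
    ends <- pmin(starts + window, L)
    pos <- keep$pos[keep$contig == id]
    cnt <- tabulate(findInterval(pos, starts), nbins = length(starts))
    data.frame(contig = id, start = starts, end = ends, variant_count = cnt,
               flagged = cnt > density_threshold * (ends - starts) / 1000,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Physical (fragment) coverage of mate pairs
#'
#' Physical coverage at a base is the number of concordant pairs whose
#' *outer fragment span* `[min start, max end)` covers it — clone
#' coverage, not read coverage. A pair is concordant when both ends map
#' to the same contig, in convergent (+/-) orientation, with an outer
#' span within `[0.5, 2] x insert_mean`; anything else (including
#' inter-contig pairs) contributes nowhere. Positions within
#' `end_exclusion` of a contig end are masked: spanning coverage is
#' structurally depressed there, so dips are uninformative.
#'
#' @param pairs Pair table as produced by [simulate_matepair_placements()]
#'   (columns `contig1,start1,end1,strand1,contig2,start2,end2,strand2`).
#' @param contigs A [contig_set()].
#' @param insert_mean Stated library insert size in bp.
#' @param end_exclusion Masked margin at each contig end in bp.
#' @param proper_only Drop discordant pairs (the default; `FALSE` keeps
#'   every same-contig pair regardless of orientation or span).
#' @return Object of class `physcov_track`: per-contig run-length encoded
#'   coverage plus the masked margins.
#' @export
physical_coverage <- function(pairs, contigs, insert_mean = 4e4,
                              end_exclusion = 2e5, proper_only = TRUE) {
  stopifnot(inherits(contigs, "contig_set"))
  unknown <- setdiff(c(pairs$contig1, pairs$contig2), contigs$id)
  if (length(unknown)) stop("pair on unknown contig: ", unknown[1])
  same <- pairs$contig1 == pairs$contig2
  span_start <- pmin(pairs$start1, pairs$start2)
  span_end <- pmax(pairs$end1, pairs$end2)
  concordant <- same
  if (proper_only) {
    span <- span_end - span_start
    concordant <- same & pairs$strand1 != pairs$strand2 &
      span >= 0.5 * insert_mean & span <= 2 * insert_mean
  }
  frag <- pairs[concordant, , drop = FALSE]
  lens <- contig_lengths(contigs)
  cov <- lapply(contigs$id, function(id) {
    on <- frag$contig1 == id
    if (!any(on)) return(S4Vectors::Rle(0L, lens[[id]]))
    IRanges::coverage(
      IRanges::IRanges(span_start[concordant][on] + 1, span_end[concordant][on]),
      width = lens[[id]]
    )
  })
  names(cov) <- contigs$id
  structure(list(coverage = cov, lengths = lens,
                 end_exclusion = end_exclusion),
            class = "physcov_track")
}

#' @export
print.physcov_track <- function(x, ...) {
  cat(sprintf("physcov_track: %d contigs, end exclusion %s bp\n",
              length(x$coverage), format(x$end_exclusion, big.mark = ",")))
  invisible(x)
}

# unmasked interior of a contig under the track's end exclusion
unmasked_span <- function(track, id) {
  L <- track$lengths[[id]]
  lo <- track$end_exclusion
  hi <- L - track$end_exclusion
  if (hi <= lo) return(NULL)
  c(lo, hi)
}

#' Low physical-coverage regions
#'
#' Maximal runs of unmasked positions whose physical coverage is strictly
#' below `min_cov`.
#'
#' @param track A [physical_coverage()] track.
#' @param min_cov Coverage threshold.
#' @return Interval `data.frame`.
#' @export
low_coverage_regions <- function(track, min_cov = 20) {
  stopifnot(inherits(track, "physcov_track"))
  out <- list()
  for (id in names(track$coverage)) {
    span <- unmasked_span(track, id)
    if (is.null(span)) next
    low <- IRanges::slice(track$coverage[[id]], upper = min_cov - 1L,
                          rangesOnly = TRUE)
    low <- IRanges::restrict(low, start = span[1] + 1L, end = span[2])
    if (length(low)) {
      out[[id]] <- data.frame(contig = id, start = IRanges::start(low) - 1,
                              end = IRanges::end(low), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_intervals())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Candidate misassembly regions from dual evidence
#'
#' Merges the flagged variant-density windows (gap up to `merge_gap`),
#' merges the low physical-coverage regions the same way, and keeps each
#' merged high-variant region covered at least `min_frac` by the merged
#' low-coverage set — the dual-signal candidates.
#'
#' @param flagged_windows Output of [variant_density_windows()].
#' @param low_cov Output of [low_coverage_regions()].
#' @param merge_gap Merge distance in bp.
#' @param min_frac Required overlap fraction of each merged variant region.
#' @return Interval `data.frame` of candidate regions.
#' @export
candidate_regions <- function(flagged_windows, low_cov, merge_gap = 2e4,
                              min_frac = 0.8) {
  fw <- flagged_windows[flagged_windows$flagged, c("contig", "start", "end")]
  hv <- merge_intervals(fw, merge_gap)
  lc <- merge_intervals(low_cov, merge_gap)
  intersect_fraction(hv, lc, min_frac)
}

#' Map conflicts on contigs
#'
#' A contig conflicts with a map when its marker hits belong to two or
#' more linkage groups; each adjacent change of linkage group along the
#' contig yields one conflict interval, the gap between the two nearest
#' hits of different groups (where the chimeric junction must lie).
#'
#' @param hits Marker-hit `data.frame` (see [simulate_markers()]).
#' @return `data.frame`: `contig`, `start`, `end`, `map`.
#' @export
map_conflicts <- function(hits) {
  out <- list()
  if (nrow(hits)) {
    for (key in unique(paste(hits$contig, hits$map))) {
      h <- hits[paste(hits$contig, hits$map) == key, , drop = FALSE]
      h <- h[order(h$contig_pos), , drop = FALSE]
      chg <- which(h$linkage_group[-1] != h$linkage_group[-nrow(h)])
      for (i in chg) {
        out[[length(out) + 1]] <- data.frame(
          contig = h$contig[1], start = h$contig_pos[i],
          end = h$contig_pos[i + 1], map = h$map[1],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(cbind(empty_intervals(), data.frame(map = character())))
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Adjudicate candidate misassemblies against two maps
#'
#' Combines the dual-signal candidates with the conflicts from the two
#' maps into a final call set:
#' * a region where either map conflicts is always accepted (verdict
#'   `accepted` when sequence signals coincide, `map_only` otherwise);
#' * a dual-signal region where a map has same-linkage-group markers both
#'   within `flank` upstream and downstream (concordant spanning
#'   alignment) and no conflict is `rejected_by_maps`;
#' * a dual-signal region with *no* markers from either map in its span
#'   and no concordant spanning is accepted on sequence evidence alone;
#' * any other dual-signal region (markers present but uninformative)
#'   is conservatively `rejected_by_maps`.
#' Overlapping calls are de-duplicated by interval union.
#'
#' @param candidates Dual-signal regions from [candidate_regions()].
#' @param conflicts Map conflicts from [map_conflicts()] (both maps in
#'   one table, distinguished by the `map` column).
#' @param hits Marker-hit table for both maps.
#' @param flank Distance within which flanking concordant markers count.
#' @return `data.frame` of class `misassembly_calls`: interval columns
#'   plus logical evidence flags `hd_variants`, `low_physcov`,
#'   `rad_conflict`, `rh_conflict` and a `verdict` column.
#' @export
adjudicate <- function(candidates, conflicts, hits, flank = 1e6) {
  maps <- unique(hits$map)
  conf_by_map <- split(conflicts, conflicts$map)
  rows <- list()
  add <- function(contig, start, end, hd, lc, conf_maps, verdict) {
    rows[[length(rows) + 1]] <<- data.frame(
      contig = contig, start = start, end = end,
      hd_variants = hd, low_physcov = lc,
      rad_conflict = "RAD" %in% conf_maps, rh_conflict = "RH" %in% conf_maps,
      verdict = verdict, stringsAsFactors = FALSE
    )
  }
  # conflict regions, merged across maps where they overlap
  all_conf <- merge_intervals(conflicts, 0)
  for (i in seq_len(nrow(all_conf))) {
    reg <- all_conf[i, , drop = FALSE]
    which_maps <- names(conf_by_map)[vapply(conf_by_map, function(cf) {
      any(covered_bp(reg, cf) > 0)
    }, logical(1))]
    dual <- nrow(candidates) > 0 && covered_bp(reg, candidates) > 0
    add(reg$contig, reg$start, reg$end, dual, dual, which_maps, "map_only")
  }
  # dual-signal candidates not already covered by a conflict
  for (i in seq_len(nrow(candidates))) {
    reg <- candidates[i, , drop = FALSE]
    if (nrow(all_conf) && any(covered_bp(reg, all_conf) > 0)) next
    in_span <- hits$contig == reg$contig &
      hits$contig_pos >= reg$start & hits$contig_pos < reg$end
    concordant <- vapply(maps, function(m) {
      h <- hits[hits$map == m & hits$contig == reg$contig, , drop = FALSE]
      up <- h[h$contig_pos < reg$start & h$contig_pos >= reg$start - flank, ]
      dn <- h[h$contig_pos >= reg$end & h$contig_pos < reg$end + flank, ]
      nrow(up) > 0 && nrow(dn) > 0 &&
        length(intersect(up$linkage_group, dn$linkage_group)) > 0
    }, logical(1))
    verdict <- if (any(concordant)) "rejected_by_maps"
    else if (!any(in_span)) "accepted"
    else "rejected_by_maps"
    add(reg$contig, reg$start, reg$end, TRUE, TRUE, character(0), verdict)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    contig = character(), start = numeric(), end = numeric(),
    hd_variants = logical(), low_physcov = logical(),
    rad_conflict = logical(), rh_conflict = logical(),
    verdict = character(), stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  # map-only calls flagged with dual evidence are promoted to accepted
  out$verdict[out$verdict == "map_only" & out$hd_variants] <- "accepted"
  class(out) <- c("misassembly_calls", class(out))
  out
}

#' Accepted misassembly calls
#'
#' The accepted set is every call whose verdict is `accepted` (sequence
#' evidence, possibly with map conflicts) or `map_only` (map conflict
#' alone).
#' @param calls Output of [adjudicate()].
#' @return The accepted rows.
#' @export
accepted_calls <- function(calls) {
  calls[calls$verdict %in% c("accepted", "map_only"), , drop = FALSE]
}

#' Summary of calls by evidence class
#'
#' Tabulates accepted calls the way curation reports usually present
#' them: both maps, one map only, and sequence-signal-only classes.
#' @param calls Output of [adjudicate()].
#' @return Named list of counts.
#' @export
call_summary <- function(calls) {
  acc <- accepted_calls(calls)
  list(
    both_maps = sum(acc$rad_conflict & acc$rh_conflict),
    rad_only = sum(acc$rad_conflict & !acc$rh_conflict),
    rh_only = sum(acc$rh_conflict & !acc$rad_conflict),
    dual_signal = sum(acc$hd_variants & acc$low_physcov),
    signal_no_maps = sum(acc$hd_variants & acc$low_physcov &
                           !acc$rad_conflict & !acc$rh_conflict),
    total = nrow(acc)
  )
}

#' Narrow accepted calls to safe break regions
#'
#' Intersects each accepted call with every map-conflict interval that
#' overlaps it. A conflict interval is the gap between the two nearest
#' markers of different linkage groups, so the intersection across maps
#' contains the chimeric junction and — crucially — no marker of either
#' map in its interior: breaking anywhere inside it leaves both
#' fragments with single-linkage-group marker content. Calls without
#' overlapping conflicts (sequence-signal-only calls, whose spans are
#' marker-free by the acceptance rule) keep their own span.
#'
#' @param calls Output of [adjudicate()].
#' @param conflicts The [map_conflicts()] table used during adjudication.
#' @return Interval `data.frame`, one row per accepted call.
#' @export
refine_break_regions <- function(calls, conflicts) {
  acc <- accepted_calls(calls)
  out <- lapply(seq_len(nrow(acc)), function(i) {
    s <- acc$start[i]; e <- acc$end[i]
    ov <- conflicts[conflicts$contig == acc$contig[i] &
                      conflicts$start < e & conflicts$end > s, , drop = FALSE]
    for (r in seq_len(nrow(ov))) {
      s <- max(s, ov$start[r]); e <- min(e, ov$end[r])
    }
    if (s >= e) { s <- acc$start[i]; e <- acc$end[i] }
    data.frame(contig = acc$contig[i], start = s, end = e,
               stringsAsFactors = FALSE)
  })
  if (!length(out)) return(empty_intervals())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Choose a safe breakpoint inside a region
#'
#' Picks the legal position nearest the region midpoint, where a position
#' is illegal when it falls inside any transcript alignment or inside any
#' single repeat record — breaking there would bisect a gene model or a
#' repeat copy. Deterministic: on a distance tie the leftmost position
#' wins.
#'
#' @param region One-row interval `data.frame` (or list with `contig`,
#'   `start`, `end`).
#' @param transcripts,repeats Interval `data.frame`s of blocking
#'   annotation.
#' @return List `contig`, `pos`.
#' @export
choose_breakpoint <- function(region, transcripts = empty_intervals(),
                              repeats = empty_intervals()) {
  contig <- region$contig[1]
  start <- region$start[1]; end <- region$end[1]
  blocks <- rbind(
    transcripts[transcripts$contig == contig, c("contig", "start", "end")],
    repeats[repeats$contig == contig, c("contig", "start", "end")]
  )
  blocks <- merge_intervals(blocks, 0)
  mid <- floor((start + end) / 2)
  legal <- gr_as_df(suppressWarnings(GenomicRanges::setdiff(
    as_gr(data.frame(contig = contig, start = start, end = end)),
    if (nrow(blocks)) as_gr(blocks) else GenomicRanges::GRanges()
  )))
  if (nrow(legal) == 0) {
    stop(sprintf("no legal breakpoint in %s:[%d,%d); blocked by %d annotation intervals",
                 contig, start, end, nrow(blocks)))
  }
  # nearest position to mid within the legal intervals, leftmost on tie
  cand <- ifelse(mid < legal$start, legal$start,
                 ifelse(mid >= legal$end, legal$end - 1, mid))
  d <- abs(cand - mid)
  best <- which(d == min(d))
  pos <- min(cand[best])
  list(contig = contig, pos = pos)
}

#' Break contigs at chosen positions
#'
#' Splits each contig at its breakpoints; `k` breakpoints raise the
#' contig count by exactly `k` and conserve every base. Fragment ids are
#' the parent id with `.1`, `.2`, ... appended left to right.
#'
#' @param contigs A [contig_set()] with sequence.
#' @param breakpoints `data.frame` with `contig`, `pos` (0-based position;
#'   the split yields `[0, pos)` and `[pos, len)`).
#' @return A new [contig_set()].
#' @export
break_contigs <- function(contigs, breakpoints) {
  stopifnot(inherits(contigs, "contig_set"))
  if (is.list(breakpoints) && !is.data.frame(breakpoints)) {
    breakpoints <- as.data.frame(breakpoints, stringsAsFactors = FALSE)
  }
  if (nrow(breakpoints) == 0) return(contigs)
  bad <- !(breakpoints$contig %in% contigs$id)
  if (any(bad)) stop("breakpoint on unknown contig: ", breakpoints$contig[which(bad)[1]])
  inside <- breakpoints$pos > 0 &
    breakpoints$pos < contig_length(contigs, breakpoints$contig)
  if (!all(inside)) stop("breakpoint not strictly inside its contig")
  pieces <- list()
  for (i in seq_along(contigs$id)) {
    id <- contigs$id[i]
    cuts <- sort(unique(breakpoints$pos[breakpoints$contig == id]))
    if (!length(cuts)) {
      pieces[[id]] <- stats::setNames(
        if (is.null(contigs$seq)) contigs$length[i] else
          as.character(contigs$seq[[id]]), id)
      next
    }
    b <- c(0, cuts, contigs$length[i])
    nm <- paste0(id, ".", seq_len(length(b) - 1))
    if (is.null(contigs$seq)) {
      pieces[[id]] <- stats::setNames(diff(b), nm)
    } else {
      pieces[[id]] <- stats::setNames(vapply(seq_along(nm), function(j) {
        as.character(Biostrings::subseq(contigs$seq[[id]], b[j] + 1, b[j + 1]))
      }, character(1)), nm)
    }
  }
  flat <- unlist(unname(pieces))
  if (is.null(contigs$seq)) contig_set(lengths = flat)
  else contig_set(seq = Biostrings::DNAStringSet(flat))
}

#' Run the full misassembly scan
#'
#' Convenience wrapper chaining [variant_density_windows()],
#' [physical_coverage()], [low_coverage_regions()],
#' [candidate_regions()], [map_conflicts()] and [adjudicate()] with the
#' standard parameters.
#'
#' @param contigs A [contig_set()].
#' @param sites Variant site table.
#' @param pairs Mate-pair placement table.
#' @param hits Marker-hit table (both maps).
#' @param window,min_qual,density_threshold,insert_mean,end_exclusion,min_cov,merge_gap,min_frac
#'   Stage parameters, see the stage functions.
#' @return [adjudicate()] output.
#' @export
scan_misassemblies <- function(contigs, sites, pairs, hits,
                               window = 1e4, min_qual = 10,
                               density_threshold = 1.0, insert_mean = 4e4,
                               end_exclusion = 2e5, min_cov = 20,
                               merge_gap = 2e4, min_frac = 0.8) {
  dw <- variant_density_windows(sites, contigs, window, min_qual, density_threshold)
  track <- physical_coverage(pairs, contigs, insert_mean, end_exclusion)
  lc <- low_coverage_regions(track, min_cov)
  cand <- candidate_regions(dw, lc, merge_gap, min_frac)
  conf <- map_conflicts(hits)
  adjudicate(cand, conf, hits)
}
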