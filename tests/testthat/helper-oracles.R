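# Brute-force oracles, deliberately simple and independent of the
# package's interval machinery: everything is done per base on small
# coordinate ranges.

# O(n^2) pairwise merge by repeated union of any two intervals whose gap
# is <= max_gap
oracle_merge <- function(x, max_gap) {
  if (nrow(x) == 0) return(x)
  rows <- split(x, seq_len(nrow(x)))
  repeat {
    merged <- FALSE
    for (i in seq_along(rows)) {
      for (j in seq_along(rows)) {
        if (i >= j) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$contig == b$contig &&
            max(a$start, b$start) - min(a$end, b$end) <= max_gap) {
          rows[[i]] <- data.frame(contig = a$contig,
                                  start = min(a$start, b$start),
                                  end = max(a$end, b$end))
          rows[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-base covered length of each interval of `a` by the union of `b`
oracle_covered <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    bases <- seq(a$start[i], a$end[i] - 1)
    hit <- rep(FALSE, length(bases))
    for (j in seq_len(nrow(b))) {
      if (b$contig[j] != a$contig[i]) next
      hit <- hit | (bases >= b$start[j] & bases < b$end[j])
    }
    sum(hit)
  }, numeric(1))
}

# N50/NG50 by explicit prefix-sum enumeration
oracle_nx <- function(lengths, half) {
  s <- sort(lengths, decreasing = TRUE)
  run <- 0
  for (l in s) {
    run <- run + l
    if (run >= half) return(l)
  }
  NA_real_
}

# per-base physical coverage by span stacking
oracle_physcov <- function(spans, len) {
  cov <- integer(len)
  for (i in seq_len(nrow(spans))) {
    idx <- seq(spans$start[i] + 1, spans$end[i])
    cov[idx] <- cov[idx] + 1L
  }
  cov
}

random_intervals <- function(n, contigs = c("c1", "c2", "c3"), max_pos = 1e5,
                             max_len = 8000) {
  start <- floor(runif(n, 0, max_pos - max_len))
  data.frame(
    contig = sample(contigs, n, replace = TRUE),
    start = start,
    end = start + ceiling(runif(n, 1, max_len)),
    stringsAsFactors = FALSE
  )
}

# dense ranks (best = highest score), averaged across columns
oracle_rank_average <- function(m) {
  ranks <- apply(m, 2, function(col) {
    vapply(col, function(v) 1L + sum(unique(col) > v), integer(1))
  })
  rowMeans(matrix(ranks, nrow = nrow(m)))
}

# small scenario for fast unit tests (not the acceptance conditions)
small_scenario <- function(seed = 1L) {
  cfg <- default_scenario(seed)
  cfg$chromosomes <- stats::setNames(rep(5e5, 4), paste0("chr", 1:4))
  cfg$insert_mean <- 5e3
  cfg$insert_sd <- 500
  cfg$pair_count <- 4000L
  cfg
}

# fraction of truth junctions contained in some interval of `set`
junction_recall <- function(junctions, set) {
  if (nrow(junctions) == 0) return(NA_real_)
  mean(vapply(seq_len(nrow(junctions)), function(i) {
    any(set$contig == junctions$contig[i] &
          set$start <= junctions$pos[i] & set$end > junctions$pos[i])
  }, logical(1)))
}

# accepted intervals containing no truth junction
false_calls <- function(junctions, set) {
  if (nrow(set) == 0) return(0L)
  sum(vapply(seq_len(nrow(set)), function(i) {
    !any(junctions$contig == set$contig[i] &
           junctions$pos >= set$start[i] & junctions$pos < set$end[i])
  }, logical(1)))
}

# re-express coordinates of an original contig on its broken pieces
relift_points <- function(breakpoints, contig, pos) {
  out_contig <- contig
  out_pos <- pos
  for (ctg in unique(breakpoints$contig)) {
    cuts <- sort(breakpoints$pos[breakpoints$contig == ctg])
    on <- contig == ctg
    idx <- findInterval(pos[on], cuts) + 1L
    out_contig[on] <- paste0(ctg, ".", idx)
    out_pos[on] <- pos[on] - c(0, cuts)[idx]
  }
  data.frame(contig = out_contig, pos = out_pos, stringsAsFactors = FALSE)
}
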