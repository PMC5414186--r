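SYNC_ALLELES <- c("A", "T", "C", "G", "N", "del")

#' Pooled allele counts
#'
#' Container for Popoolation2-style sync data: per-site, per-pool counts
#' of A, T, C, G, N and deletions. Internally positions are 0-based; the
#' sync file format is 1-based and the conversion happens in
#' [read_sync()]/[write_sync()] only.
#'
#' @param contig,pos,ref Site coordinates (0-based `pos`) and reference base.
#' @param counts List of one `n x 6` integer matrix per pool, columns
#'   `A,T,C,G,N,del`.
#' @return Object of class `pool_counts`: `sites` data.frame plus `counts`.
#' @export
pool_counts <- function(contig, pos, ref, counts) {
  stopifnot(length(counts) >= 2)
  n <- length(pos)
  for (m in counts) {
    stopifnot(is.matrix(m), nrow(m) == n, ncol(m) == 6, all(m >= 0))
  }
  counts <- lapply(counts, function(m) {
    colnames(m) <- SYNC_ALLELES
    m
  })
  structure(list(
    sites = data.frame(contig = as.character(contig), pos = as.numeric(pos),
                       ref = as.character(ref), stringsAsFactors = FALSE),
    counts = counts
  ), class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("pool_counts: %d sites, %d pools\n",
              nrow(x$sites), length(x$counts)))
  invisible(x)
}

#' Read / write Popoolation2 sync files
#'
#' Tab-separated: contig, 1-based position, reference base, then one
#' `A:T:C:G:N:del` column per pool.
#' @param path File path.
#' @return `read_sync` returns a [pool_counts()] object.
#' @export
read_sync <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  npool <- length(parts[[1]]) - 3L
  stopifnot(npool >= 2)
  contig <- vapply(parts, `[[`, character(1), 1)
  pos <- as.numeric(vapply(parts, `[[`, character(1), 2)) - 1
  ref <- vapply(parts, `[[`, character(1), 3)
  counts <- lapply(seq_len(npool), function(p) {
    m <- do.call(rbind, lapply(parts, function(x) {
      as.integer(strsplit(x[[3 + p]], ":", fixed = TRUE)[[1]])
    }))
    colnames(m) <- SYNC_ALLELES
    m
  })
  pool_counts(contig, pos, ref, counts)
}

#' @rdname read_sync
#' @param x A `pool_counts` object.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "pool_counts"))
  cols <- vapply(x$counts, function(m) {
    apply(m, 1, paste, collapse = ":")
  }, character(nrow(x$sites)))
  lines <- paste(x$sites$contig, format(x$sites$pos + 1, scientific = FALSE,
                                        trim = TRUE),
                 x$sites$ref, apply(cbind(cols), 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Per-pool allele frequencies
#'
#' Frequencies over the five real alleles (A, T, C, G, deletion); N counts
#' are ignored. Pools with depth below `min_depth` at a site are
#' uncallable there (frequencies `NA`).
#'
#' @param x A [pool_counts()] object.
#' @param min_depth Minimum callable pool depth.
#' @return List with one `n x 5` frequency matrix per pool and a `depth`
#'   matrix (`n x n_pools`).
#' @export
allele_frequencies <- function(x, min_depth = 10) {
  stopifnot(inherits(x, "pool_counts"))
  keep <- setdiff(SYNC_ALLELES, "N")
  depth <- vapply(x$counts, function(m) rowSums(m[, keep, drop = FALSE]),
                  numeric(nrow(x$sites)))
  depth <- matrix(depth, nrow = nrow(x$sites))
  freq <- lapply(seq_along(x$counts), function(p) {
    f <- x$counts[[p]][, keep, drop = FALSE] / depth[, p]
    f[depth[, p] < min_depth, ] <- NA_real_
    f
  })
  list(freq = freq, depth = depth)
}

# counts of the two most frequent alleles at each site, pooled over the two
# pools; returns list(c_a, c_b): n x 2 matrices of focal-allele counts
top2_counts <- function(x, pool_a, pool_b) {
  keep <- setdiff(SYNC_ALLELES, "N")
  ma <- x$counts[[pool_a]][, keep, drop = FALSE]
  mb <- x$counts[[pool_b]][, keep, drop = FALSE]
  tot <- ma + mb
  ord <- t(apply(tot, 1, order, decreasing = TRUE))
  idx1 <- cbind(seq_len(nrow(tot)), ord[, 1])
  idx2 <- cbind(seq_len(nrow(tot)), ord[, 2])
  list(a = cbind(ma[idx1], ma[idx2]), b = cbind(mb[idx1], mb[idx2]))
}

#' Per-site FST from pooled counts
#'
#' The classical pi-based pool-seq estimator on the two most frequent
#' alleles at each site. Within-pool diversity uses the sample-size
#' correction on read counts, `pi_k = n_k/(n_k - 1) * 2 p_k q_k` with
#' `n_k` the focal-allele read depth of pool `k`; total diversity `pi_T`
#' is computed from the combined counts with `n = n_a + n_b`; then
#' `FST = (pi_T - (pi_a + pi_b)/2) / pi_T`. A site monomorphic across
#' both pools has `FST = 0`; a site where either pool is below
#' `min_depth` (or has fewer than two focal reads) is `NA`.
#'
#' @param x A [pool_counts()] object.
#' @param pool_a,pool_b Pool indices.
#' @param min_depth Minimum callable pool depth.
#' @return Numeric vector of per-site FST in `[0, 1]` (or `NA`).
#' @export
site_fst <- function(x, pool_a = 1, pool_b = 2, min_depth = 10) {
  stopifnot(inherits(x, "pool_counts"))
  tc <- top2_counts(x, pool_a, pool_b)
  na <- rowSums(tc$a); nb <- rowSums(tc$b)
  pa <- tc$a[, 1] / na; pb <- tc$b[, 1] / nb
  pi_a <- na / (na - 1) * 2 * pa * (1 - pa)
  pi_b <- nb / (nb - 1) * 2 * pb * (1 - pb)
  nt <- na + nb
  pt <- (tc$a[, 1] + tc$b[, 1]) / nt
  pi_t <- nt / (nt - 1) * 2 * pt * (1 - pt)
  fst <- ifelse(pi_t == 0, 0, (pi_t - (pi_a + pi_b) / 2) / pi_t)
  fst[na < pmax(min_depth, 2) | nb < pmax(min_depth, 2)] <- NA_real_
  pmin(pmax(fst, 0), 1)
}

#' Call sex-patterned variants
#'
#' A site is sex-patterned when it is fixed or nearly fixed in the
#' homogametic pool (minor-allele frequency at most `fixed_tol`) while
#' that same minor allele sits at intermediate frequency
#' (`[inter_lo, inter_hi]`) in the heterogametic pool — the expected
#' signature of a variant on the Y (or W) haplotype of a non-recombining
#' sex-determination region. SNPs and deletion alleles are treated alike.
#'
#' @param x A [pool_counts()] object.
#' @param homogametic Index of the homogametic pool (XX or ZZ).
#' @param fixed_tol Max minor-allele frequency in the homogametic pool.
#' @param inter_lo,inter_hi Intermediate-frequency band for the
#'   heterogametic pool.
#' @param min_depth Minimum callable pool depth.
#' @return `data.frame`: site columns plus `hom_minor_freq`, `het_freq`
#'   (heterogametic frequency of the homogametic minor allele) and
#'   `passes` (logical; `NA`-frequency sites never pass).
#' @export
sex_patterned <- function(x, homogametic = 1, fixed_tol = 0.1,
                          inter_lo = 0.3, inter_hi = 0.7, min_depth = 10) {
  stopifnot(inherits(x, "pool_counts"))
  heterogametic <- if (homogametic == 1) 2L else 1L
  tc <- top2_counts(x, homogametic, heterogametic)
  nh <- rowSums(tc$a); nt <- rowSums(tc$b)
  # minor allele of the homogametic pool among the two focal alleles
  hom_minor <- pmin(tc$a[, 1], tc$a[, 2]) / nh
  minor_is_first <- tc$a[, 1] < tc$a[, 2]
  het_minor_count <- ifelse(minor_is_first, tc$b[, 1], tc$b[, 2])
  het_freq <- het_minor_count / nt
  callable <- nh >= min_depth & nt >= min_depth
  passes <- callable & hom_minor <= fixed_tol &
    het_freq >= inter_lo & het_freq <= inter_hi
  passes[is.na(passes)] <- FALSE
  cbind(x$sites,
        data.frame(hom_minor_freq = hom_minor, het_freq = het_freq,
                   passes = passes))
}

#' Windowed FST and sex-patterned tracks
#'
#' Tiles each contig (anchored linkage group or unanchored contig) with
#' fixed windows and reports the mean per-site FST and the count of
#' passing sex-patterned sites per window.
#'
#' @param x A [pool_counts()] object.
#' @param contigs A [contig_set()] giving the spans to tile (defaults to
#'   the extent of the observed sites).
#' @param window Window width in bp.
#' @param homogametic Index of the homogametic pool.
#' @param ... Passed to [sex_patterned()].
#' @return `data.frame`: `contig`, `start`, `end`, `n_sites`, `mean_fst`,
#'   `sex_patterned`.
#' @export
window_tracks <- function(x, contigs = NULL, window = 1e4,
                          homogametic = 1, ...) {
  stopifnot(inherits(x, "pool_counts"))
  fst <- site_fst(x, homogametic, if (homogametic == 1) 2 else 1)
  sp <- sex_patterned(x, homogametic = homogametic, ...)
  lens <- if (is.null(contigs)) {
    tapply(x$sites$pos, x$sites$contig, function(p) max(p) + 1)
  } else contig_lengths(contigs)
  out <- do.call(rbind, lapply(names(lens), function(ch) {
    L <- lens[[ch]]
    starts <- seq(0, max(0, L - 1), by = window)
    on_ch <- x$sites$contig == ch
    bin <- findInterval(x$sites$pos[on_ch], starts)
    df <- data.frame(contig = ch, start = starts,
                     end = pmin(starts + window, L),
                     n_sites = 0L, mean_fst = NA_real_, sex_patterned = 0L,
                     stringsAsFactors = FALSE)
    if (any(on_ch)) {
      tab <- tabulate(bin, nbins = length(starts))
      df$n_sites <- tab
      mf <- tapply(fst[on_ch], bin, mean, na.rm = TRUE)
      df$mean_fst[as.integer(names(mf))] <- as.numeric(mf)
      cnt <- tapply(sp$passes[on_ch], bin, sum)
      df$sex_patterned[as.integer(names(cnt))] <- as.integer(cnt)
    }
    df
  }))
  rownames(out) <- NULL
  out
}

#' Delimit sex-determination regions from a windowed track
#'
#' Finds maximal runs of at least `min_run_windows` consecutive windows
#' whose sex-patterned count reaches `count_threshold`, tolerating
#' single-window dropouts inside a run. Region boundaries are the
#' outermost qualifying windows.
#'
#' @param track Output of [window_tracks()].
#' @param min_run_windows Minimum qualifying windows per region.
#' @param count_threshold Minimum sex-patterned count for a window to
#'   qualify.
#' @return Interval `data.frame` (`contig`, `start`, `end`), one row per
#'   detected region.
#' @export
detect_sd_region <- function(track, min_run_windows = 5, count_threshold = 5) {
  out <- empty_intervals()
  for (ch in unique(track$contig)) {
    t <- track[track$contig == ch, , drop = FALSE]
    t <- t[order(t$start), , drop = FALSE]
    q <- t$sex_patterned >= count_threshold
    # group qualifying windows, bridging gaps of a single window
    runs <- list(); cur <- integer(0); gap <- 0L
    for (i in seq_along(q)) {
      if (q[i]) {
        cur <- c(cur, i); gap <- 0L
      } else if (length(cur)) {
        gap <- gap + 1L
        if (gap > 1L) { runs <- c(runs, list(cur)); cur <- integer(0); gap <- 0L }
      }
    }
    if (length(cur)) runs <- c(runs, list(cur))
    for (r in runs) {
      if (length(r) >= min_run_windows) {
        out <- rbind(out, data.frame(contig = ch, start = t$start[r[1]],
                                     end = t$end[r[length(r)]],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Tally sex-patterned variants on and off a target linkage group
#'
#' @param sp Output of [sex_patterned()].
#' @param target_lg Contig/linkage-group id of interest.
#' @return List `on`, `off`, `total` of passing-site counts (on + off =
#'   total by construction).
#' @export
tally_sex_patterned <- function(sp, target_lg) {
  pass <- sp[sp$passes, , drop = FALSE]
  on <- sum(pass$contig == target_lg)
  list(on = on, off = nrow(pass) - on, total = nrow(pass))
}
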