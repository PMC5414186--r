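#' Synthetic assembly-curation scenarios
#'
#' The generators in this module build a genome of known chromosomes,
#' engineer inter-chromosomal chimeric joins into it, and then emit every
#' evidence track the curation pipeline consumes — variant calls with a
#' halo of elevated density around each join, large-insert mate pairs whose
#' concordant spanning coverage collapses at joins, markers for two map
#' flavours, BAC-end pairs, and pooled allele counts with an engineered
#' sex-determination region. All generators are deterministic under their
#' `seed` argument, and each returns its ground truth so recovery can be
#' asserted exactly.
#'
#' @param seed Integer seed.
#' @return `default_scenario()` returns the list of scenario parameters
#'   used throughout the package's tests: five 2 Mbp chromosomes
#'   (10 Mbp genome), 10 chimeric joins, variant background 0.1/kbp
#'   rising to 3/kbp within a 20 kbp halo of each join, a 40 kbp +/- 4 kbp
#'   insert mate-pair library of 7,500 pairs (~30x physical clone coverage),
#'   markers every 50 kbp (RAD flavour; RH flavour three times sparser),
#'   and pooled counts at 40x depth every 200 bp.
#' @export
default_scenario <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    chromosomes = stats::setNames(rep(2e6, 5), paste0("chr", 1:5)),
    n_joins = 10L,
    marker_spacing = 5e4,
    background_variant_rate = 0.1,  # per kbp
    junction_variant_rate = 3,      # per kbp
    junction_halo = 2e4,
    insert_mean = 4e4,
    insert_sd = 4e3,
    pair_count = 7500L,
    pool_depth_mean = 40,
    site_spacing = 200,
    repeat_fraction = 0
  )
}

# run `expr` under `seed`, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome of known chromosomes
#'
#' Generates random-base chromosomes, optionally seeded with interspersed
#' transposon-like copies and terminal satellite arrays so that repeat
#' parsing and enrichment code can be exercised against known annotation.
#'
#' @param config Scenario list, see [default_scenario()]. Uses
#'   `chromosomes`, `insert_mean` and `repeat_fraction`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with `genome` (a [contig_set()] of true chromosomes with
#'   sequence) and `repeats` (annotation `data.frame` with columns
#'   `contig`, `start`, `end`, `order`, `family`, `divergence`).
#' @export
simulate_genome <- function(config = default_scenario(), seed = config$seed) {
  lens <- config$chromosomes
  if (length(lens) < 2) stop("need at least 2 chromosomes to make chimeric joins possible")
  if (any(lens < 10 * config$insert_mean)) {
    stop("chromosome shorter than 10x insert_mean; coverage tracks undefined")
  }
  with_seed(seed, {
    seqs <- vapply(lens, function(L) random_dna(L), character(1))
    rep_frac <- config$repeat_fraction %||% 0
    repeats <- empty_repeats()
    if (rep_frac > 0) {
      te_unit <- random_dna(500)
      sat_unit <- random_dna(200)
      for (i in seq_along(seqs)) {
        L <- lens[i]
        placed <- plant_repeats(seqs[i], L, te_unit, sat_unit, rep_frac,
                                names(lens)[i])
        seqs[i] <- placed$seq
        repeats <- rbind(repeats, placed$ann)
      }
    }
    genome <- contig_set(seq = Biostrings::DNAStringSet(stats::setNames(seqs, names(lens))))
    list(genome = genome, repeats = repeats)
  })
}

empty_repeats <- function() {
  data.frame(contig = character(), start = numeric(), end = numeric(),
             order = character(), family = character(), divergence = numeric(),
             stringsAsFactors = FALSE)
}

# overwrite non-overlapping slots with TE copies plus terminal satellite
# arrays; returns modified sequence and its annotation
plant_repeats <- function(seq, L, te_unit, sat_unit, frac, contig) {
  te_len <- nchar(te_unit)
  sat_copies <- 10L
  sat_len <- sat_copies * nchar(sat_unit)
  n_te <- max(0L, round((frac * L - 2 * sat_len) / te_len))
  slot_starts <- seq(sat_len + 1000, L - sat_len - 1000 - te_len, by = 2 * te_len)
  n_te <- min(n_te, length(slot_starts))
  starts <- sort(sample(slot_starts, n_te))
  for (s in starts) substr(seq, s + 1, s + te_len) <- te_unit
  sat <- strrep(sat_unit, sat_copies)
  substr(seq, 1, sat_len) <- sat
  substr(seq, L - sat_len + 1, L) <- sat
  ann <- rbind(
    data.frame(contig = contig, start = starts, end = starts + te_len,
               order = "DNA", family = "TcMar-Tc1",
               divergence = round(stats::runif(n_te, 0, 25), 1),
               stringsAsFactors = FALSE),
    data.frame(contig = contig, start = c(0, L - sat_len), end = c(sat_len, L),
               order = "Satellite", family = "Satellite",
               divergence = round(stats::runif(2, 0, 10), 1),
               stringsAsFactors = FALSE)
  )
  list(seq = seq, ann = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A contig map records how chimeric-contig coordinates tile onto true
# chromosomes: one row per segment, forward strand throughout.
identity_map <- function(genome) {
  data.frame(
    contig = genome$id, dst_start = 0, dst_end = genome$length,
    chr = genome$id, src_start = 0, src_end = genome$length,
    stringsAsFactors = FALSE
  )
}

#' Engineer inter-chromosomal chimeric joins
#'
#' Cuts the true chromosomes into `2 * n_joins` segments (sizes jittered
#' around equal) and concatenates pairs of segments drawn from *different*
#' chromosomes, producing `n_joins` chimeric contigs each carrying one
#' known junction near its middle. Total sequence is conserved exactly.
#'
#' @param sim Output of [simulate_genome()] (or a bare [contig_set()]).
#' @param n_joins Number of chimeric joins; 0 returns the genome unchanged.
#' @param seed Integer seed.
#' @param min_segment Smallest admissible segment (keeps junctions clear of
#'   the end-exclusion mask at the default scan settings).
#' @return List with `contigs` (the chimeric assembly), `junctions`
#'   (`data.frame` of `contig`, `pos` truth breakpoints) and `map`
#'   (segment lift-over table between contig and chromosome coordinates).
#' @export
induce_misassemblies <- function(sim, n_joins, seed = 1L, min_segment = 4e5) {
  genome <- if (inherits(sim, "contig_set")) sim else sim$genome
  if (n_joins == 0) {
    return(list(contigs = genome, junctions = data.frame(
      contig = character(), pos = numeric(), stringsAsFactors = FALSE),
      map = identity_map(genome)))
  }
  n_seg <- 2L * as.integer(n_joins)
  lens <- contig_lengths(genome)
  # proportional segment allocation, at least one per chromosome
  k <- pmax(1L, round(n_seg * lens / sum(lens)))
  while (sum(k) > n_seg) k[which.max(k)] <- k[which.max(k)] - 1L
  while (sum(k) < n_seg) k[which.min(k)] <- k[which.min(k)] + 1L
  if (max(k) > n_seg / 2) {
    stop("n_joins infeasible: one chromosome would contribute more than half the segments")
  }
  if (any(lens / k < min_segment)) {
    stop("n_joins infeasible: segments would be shorter than min_segment")
  }
  with_seed(seed, {
    segs <- do.call(rbind, lapply(seq_along(lens), function(i) {
      L <- lens[i]; ki <- k[i]
      cuts <- if (ki == 1) numeric(0) else {
        eq <- L * seq_len(ki - 1) / ki
        round(eq + stats::runif(ki - 1, -0.1, 0.1) * L / ki)
      }
      b <- c(0, cuts, L)
      data.frame(chr = names(lens)[i], src_start = b[-length(b)], src_end = b[-1],
                 stringsAsFactors = FALSE)
    }))
    # pair segments from different chromosomes: repeatedly draw one segment
    # from each of the two chromosomes with most segments remaining
    segs <- segs[sample.int(nrow(segs)), , drop = FALSE]
    pool <- split(seq_len(nrow(segs)), segs$chr)
    pairs <- vector("list", n_joins)
    for (j in seq_len(n_joins)) {
      sizes <- vapply(pool, length, integer(1))
      top2 <- names(sort(sizes, decreasing = TRUE))[1:2]
      i1 <- pool[[top2[1]]][1]; pool[[top2[1]]] <- pool[[top2[1]]][-1]
      i2 <- pool[[top2[2]]][1]; pool[[top2[2]]] <- pool[[top2[2]]][-1]
      pairs[[j]] <- c(i1, i2)
    }
    ids <- sprintf("ctg%03d", seq_len(n_joins))
    map <- do.call(rbind, lapply(seq_len(n_joins), function(j) {
      s <- segs[pairs[[j]], , drop = FALSE]
      w <- s$src_end - s$src_start
      data.frame(contig = ids[j], dst_start = c(0, w[1]), dst_end = cumsum(w),
                 chr = s$chr, src_start = s$src_start, src_end = s$src_end,
                 stringsAsFactors = FALSE)
    }))
    junctions <- data.frame(
      contig = ids,
      pos = map$dst_end[seq(1, nrow(map), by = 2)],
      stringsAsFactors = FALSE
    )
    seqs <- Biostrings::DNAStringSet(vapply(split(map, map$contig)[ids], function(m) {
      paste(vapply(seq_len(nrow(m)), function(r) {
        as.character(Biostrings::subseq(genome$seq[[m$chr[r]]],
                                        m$src_start[r] + 1, m$src_end[r]))
      }, character(1)), collapse = "")
    }, character(1)))
    names(seqs) <- ids
    list(contigs = contig_set(seq = seqs), junctions = junctions, map = map)
  })
}

# vectorized lift of true-chromosome points onto (possibly chimeric)
# contigs; maps may carry a per-segment strand column (default "+")
lift_points <- function(map, chr, pos) {
  strand <- map$strand %||% rep("+", nrow(map))
  out_contig <- rep(NA_character_, length(pos))
  out_pos <- rep(NA_real_, length(pos))
  for (r in seq_len(nrow(map))) {
    hit <- chr == map$chr[r] & pos >= map$src_start[r] & pos < map$src_end[r]
    out_contig[hit] <- map$contig[r]
    out_pos[hit] <- if (strand[r] == "+") {
      map$dst_start[r] + (pos[hit] - map$src_start[r])
    } else {
      map$dst_start[r] + (map$src_end[r] - 1 - pos[hit])
    }
  }
  data.frame(contig = out_contig, pos = out_pos, stringsAsFactors = FALSE)
}

#' Fragment a genome into junction-free contigs
#'
#' Cuts each chromosome into consecutive segments (sizes jittered around
#' equal) and emits each segment as its own contig, optionally reverse
#' complemented — a clean assembly whose true order and orientation are
#' known, for validating anchoring.
#'
#' @param sim Output of [simulate_genome()].
#' @param pieces Segments per chromosome.
#' @param orientation `"random"` flips roughly half the contigs;
#'   `"forward"` keeps them all `+`.
#' @param seed Integer seed.
#' @return List: `contigs` (a [contig_set()]), `map` (lift-over table
#'   with a `strand` column) and `truth` (`data.frame` of
#'   `linkage_group`, `contig`, `orientation` in true order).
#' @export
fragment_genome <- function(sim, pieces = 4, orientation = c("random", "forward"),
                            seed = 1L) {
  orientation <- match.arg(orientation)
  genome <- if (inherits(sim, "contig_set")) sim else sim$genome
  lens <- contig_lengths(genome)
  with_seed(seed, {
    map <- do.call(rbind, lapply(names(lens), function(ch) {
      L <- lens[[ch]]
      eq <- L * seq_len(pieces - 1) / pieces
      cuts <- if (pieces > 1) round(eq + stats::runif(pieces - 1, -0.1, 0.1) * L / pieces)
      else numeric(0)
      b <- c(0, cuts, L)
      strand <- if (orientation == "random") {
        sample(c("+", "-"), pieces, replace = TRUE)
      } else rep("+", pieces)
      data.frame(
        contig = sprintf("%s_p%d", ch, seq_len(pieces)),
        dst_start = 0, dst_end = diff(b),
        chr = ch, src_start = b[-length(b)], src_end = b[-1],
        strand = strand, stringsAsFactors = FALSE
      )
    }))
    seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(map)), function(r) {
      s <- Biostrings::subseq(genome$seq[[map$chr[r]]],
                              map$src_start[r] + 1, map$src_end[r])
      if (map$strand[r] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1)))
    names(seqs) <- map$contig
    truth <- data.frame(
      linkage_group = sub("^chr", "LG", map$chr),
      contig = map$contig, orientation = map$strand,
      stringsAsFactors = FALSE
    )
    list(contigs = contig_set(seq = seqs), map = map, truth = truth)
  })
}

#' Simulate variant calls with junction halos
#'
#' Places Poisson background variants along each contig and a denser
#' Poisson process within `halo` bp of each engineered junction, emulating
#' the pile-up of disagreeing long-read alignments over a chimeric join.
#' A fixed fraction of sites receive a quality at or below the filter
#' threshold so quality filtering is exercised.
#'
#' @param contigs [contig_set()] of the (chimeric) assembly.
#' @param junctions Truth junction `data.frame` (`contig`, `pos`).
#' @param background_rate,junction_rate Variants per kbp outside/inside halos.
#' @param halo Halo half-width in bp around each junction.
#' @param qual_fail_frac Fraction of sites drawn with quality <= 10.
#' @param seed Integer seed.
#' @return `data.frame` of `contig`, `pos` (0-based), `qual`.
#' @export
simulate_variant_calls <- function(contigs, junctions,
                                   background_rate = 0.1, junction_rate = 3,
                                   halo = 2e4, qual_fail_frac = 0.1, seed = 1L) {
  stopifnot(background_rate >= 0, junction_rate >= 0)
  with_seed(seed, {
    out <- list()
    for (i in seq_along(contigs$id)) {
      id <- contigs$id[i]; L <- contigs$length[i]
      n_bg <- stats::rpois(1, background_rate / 1000 * L)
      pos <- if (n_bg) floor(stats::runif(n_bg, 0, L)) else numeric(0)
      j <- junctions[junctions$contig == id, , drop = FALSE]
      for (p in j$pos) {
        lo <- max(0, p - halo); hi <- min(L, p + halo)
        n_j <- stats::rpois(1, max(0, junction_rate - background_rate) / 1000 * (hi - lo))
        if (n_j) pos <- c(pos, floor(stats::runif(n_j, lo, hi)))
      }
      if (length(pos)) {
        out[[id]] <- data.frame(contig = id, pos = sort(pos), stringsAsFactors = FALSE)
      }
    }
    sites <- if (length(out)) do.call(rbind, out) else
      data.frame(contig = character(), pos = numeric(), stringsAsFactors = FALSE)
    n <- nrow(sites)
    fail <- stats::runif(n) < qual_fail_frac
    sites$qual <- ifelse(fail, stats::runif(n, 0, 10), stats::runif(n, 11, 60))
    rownames(sites) <- NULL
    sites
  })
}

#' Simulate large-insert mate-pair placements
#'
#' Samples fragments from the *true* chromosomes (length normal around the
#' library insert) and lifts the two end reads onto the chimeric contigs.
#' Fragments whose ends land on different contigs are emitted as
#' inter-contig pairs; by construction no concordant fragment spans an
#' engineered junction, so spanning physical coverage dips to zero there.
#'
#' @param sim Output of [simulate_genome()] (true chromosomes).
#' @param map Contig lift-over map from [induce_misassemblies()].
#' @param insert_mean,insert_sd Fragment length distribution in bp.
#' @param pair_count Number of pairs to draw.
#' @param read_len End-read length in bp.
#' @param seed Integer seed.
#' @return `data.frame` with one row per pair: `contig1`, `start1`, `end1`,
#'   `strand1`, `contig2`, `start2`, `end2`, `strand2` (contig coordinates,
#'   0-based half-open; end 1 is the fragment's left end on the forward
#'   strand, end 2 the right end on the reverse strand).
#' @export
simulate_matepair_placements <- function(sim, map, insert_mean = 4e4,
                                         insert_sd = 4e3, pair_count = 15000,
                                         read_len = 100, seed = 1L) {
  genome <- if (inherits(sim, "contig_set")) sim else sim$genome
  lens <- contig_lengths(genome)
  if (any(lens < 10 * insert_mean)) {
    stop("chromosome shorter than 10x insert_mean; coverage tracks undefined")
  }
  with_seed(seed, {
    chr <- sample(names(lens), pair_count, replace = TRUE, prob = lens / sum(lens))
    flen <- pmax(2 * read_len, round(stats::rnorm(pair_count, insert_mean, insert_sd)))
    flen <- pmin(flen, lens[chr])
    fstart <- floor(stats::runif(pair_count, 0, lens[chr] - flen + 1))
    left <- lift_points(map, chr, fstart)
    right <- lift_points(map, chr, fstart + flen - 1)  # last base of fragment
    data.frame(
      contig1 = left$contig, start1 = left$pos,
      end1 = pmin(left$pos + read_len, contig_length_safe(map, left$contig)),
      strand1 = "+",
      contig2 = right$contig,
      start2 = pmax(0, right$pos + 1 - read_len), end2 = right$pos + 1,
      strand2 = "-",
      stringsAsFactors = FALSE
    )
  })
}

contig_length_safe <- function(map, contig) {
  lens <- tapply(map$dst_end, map$contig, max)
  as.numeric(lens[contig])
}

#' Simulate map marker hits
#'
#' Emits markers at regular spacing along each true chromosome with
#' monotone map positions (1 map unit per Mbp), lifted onto the chimeric
#' contigs — so a chimeric contig shows hits from exactly two linkage
#' groups. `tie_frac > 0` coarsens a fraction of map positions onto a
#' shared grid, reproducing the ambiguous-orientation situation of genetic
#' maps with co-segregating markers.
#'
#' @param sim Output of [simulate_genome()].
#' @param map Contig lift-over map.
#' @param spacing Marker spacing in bp.
#' @param map_id Label for the map flavour (e.g. `"RAD"` or `"RH"`).
#' @param tie_frac Fraction of markers whose map positions are tied.
#' @param seed Integer seed.
#' @return `data.frame` of marker hits: `marker`, `map`, `linkage_group`,
#'   `map_position`, `contig`, `contig_pos`, `strand`.
#' @export
simulate_markers <- function(sim, map, spacing = 5e4, map_id = "RAD",
                             tie_frac = 0, seed = 1L) {
  genome <- if (inherits(sim, "contig_set")) sim else sim$genome
  lens <- contig_lengths(genome)
  with_seed(seed, {
    hits <- do.call(rbind, lapply(names(lens), function(ch) {
      pos <- seq(spacing / 2, lens[ch] - 1, by = spacing)
      if (!length(pos)) return(NULL)
      mp <- pos / 1e6
      if (tie_frac > 0) {
        tied <- stats::runif(length(mp)) < tie_frac
        mp[tied] <- floor(mp[tied] / 0.5) * 0.5  # collapse onto 0.5-unit grid
      }
      data.frame(
        marker = sprintf("%s_%s_m%04d", map_id, ch, seq_along(pos)),
        map = map_id, linkage_group = sub("^chr", "LG", ch),
        map_position = mp, chr = ch, chr_pos = pos,
        stringsAsFactors = FALSE
      )
    }))
    lifted <- lift_points(map, hits$chr, hits$chr_pos)
    hits$contig <- lifted$contig
    hits$contig_pos <- lifted$pos
    hits$strand <- "+"
    hits[!is.na(hits$contig), setdiff(names(hits), c("chr", "chr_pos"))]
  })
}

#' Simulate pooled allele counts with a sex-determination region
#'
#' Generates sync-style per-site counts for two pools. Background sites
#' share an allele frequency drawn from a Beta(0.5, 0.5) law truncated to
#' (0.05, 0.95) — a neutral-SFS-like choice. Inside the engineered
#' sex-determination region the homogametic pool is fixed for the
#' reference while the heterogametic pool sits near 0.5 (Beta(50, 50)),
#' the signature of a non-recombining XY (or, with `system = "zw"`, WZ)
#' region. Coverage is Poisson around `depth`; counts binomial. A small
#' fraction of sites use the deletion allele instead of a SNP.
#'
#' @param sim Output of [simulate_genome()] (sites are placed on the true
#'   chromosomes, i.e. the anchored linkage groups).
#' @param sd_region List/vector `(contig, start, end)` of the truth region.
#' @param depth Mean pool coverage.
#' @param site_spacing Distance between simulated sites in bp.
#' @param system `"xy"` (pool 1 homogametic, as for XX females vs XY males)
#'   or `"zw"` (pool 2 homogametic).
#' @param del_frac Fraction of sites whose alternate allele is a deletion.
#' @param seed Integer seed.
#' @return A `pool_counts` object (see [read_sync()]) with a `truth`
#'   element giving per-site true pool frequencies, and the homogametic
#'   pool index as attribute `homogametic`.
#' @export
simulate_pool_counts <- function(sim, sd_region, depth = 40, site_spacing = 200,
                                 system = c("xy", "zw"), del_frac = 0.05,
                                 seed = 1L) {
  system <- match.arg(system)
  genome <- if (inherits(sim, "contig_set")) sim else sim$genome
  lens <- contig_lengths(genome)
  hom <- if (system == "xy") 1L else 2L
  het <- 3L - hom
  with_seed(seed, {
    sites <- do.call(rbind, lapply(names(lens), function(ch) {
      pos <- seq(site_spacing / 2, lens[ch] - 1, by = site_spacing)
      data.frame(contig = ch, pos = pos, stringsAsFactors = FALSE)
    }))
    n <- nrow(sites)
    bases <- c("A", "T", "C", "G")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    alt[stats::runif(n) < del_frac] <- "del"
    in_region <- if (is.null(sd_region)) rep(FALSE, n) else {
      sites$contig == sd_region[[1]] &
        sites$pos >= as.numeric(sd_region[[2]]) &
        sites$pos < as.numeric(sd_region[[3]])
    }
    # true alternate-allele frequency per pool
    f_bg <- truncated_beta(n, 0.5, 0.5, 0.05, 0.95)
    f <- matrix(0, n, 2)
    f[, 1] <- f[, 2] <- f_bg
    f[in_region, hom] <- 0
    f[in_region, het] <- stats::rbeta(sum(in_region), 50, 50)
    counts <- lapply(1:2, function(p) {
      cov <- stats::rpois(n, depth)
      nalt <- stats::rbinom(n, cov, f[, p])
      m <- matrix(0L, n, 6, dimnames = list(NULL, SYNC_ALLELES))
      m[cbind(seq_len(n), match(ref, SYNC_ALLELES))] <- cov - nalt
      m[cbind(seq_len(n), match(alt, SYNC_ALLELES))] <-
        m[cbind(seq_len(n), match(alt, SYNC_ALLELES))] + nalt
      m
    })
    pc <- pool_counts(sites$contig, sites$pos, ref, counts)
    pc$truth <- data.frame(contig = sites$contig, pos = sites$pos,
                           f_pool1 = f[, 1], f_pool2 = f[, 2],
                           in_region = in_region, stringsAsFactors = FALSE)
    attr(pc, "homogametic") <- hom
    pc
  })
}

truncated_beta <- function(n, a, b, lo, hi) {
  x <- stats::rbeta(n, a, b)
  while (any(bad <- x < lo | x > hi)) x[bad] <- stats::rbeta(sum(bad), a, b)
  x
}

#' Simulate a full misassembly-scan scenario
#'
#' Orchestrates the generators: genome, chimeric joins, variant calls,
#' mate pairs, and marker hits for both map flavours (a dense RAD-style
#' map with a share of tied positions and a three-fold sparser RH-style
#' map), with sub-seeds derived deterministically from `seed`.
#'
#' @param config Scenario list, see [default_scenario()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List: `sim` (genome), `mis` (contigs/junctions/map),
#'   `variants`, `pairs`, `hits` (both maps combined).
#' @export
simulate_scenario <- function(config = default_scenario(), seed = config$seed) {
  seed <- as.integer(seed)
  sim <- simulate_genome(config, seed = seed)
  mis <- induce_misassemblies(sim, config$n_joins, seed = seed + 101L)
  variants <- simulate_variant_calls(
    mis$contigs, mis$junctions,
    background_rate = config$background_variant_rate,
    junction_rate = config$junction_variant_rate,
    halo = config$junction_halo, seed = seed + 202L
  )
  pairs <- simulate_matepair_placements(
    sim, mis$map, insert_mean = config$insert_mean,
    insert_sd = config$insert_sd, pair_count = config$pair_count,
    seed = seed + 303L
  )
  hits <- rbind(
    simulate_markers(sim, mis$map, spacing = config$marker_spacing,
                     map_id = "RAD", tie_frac = 0.2, seed = seed + 404L),
    simulate_markers(sim, mis$map, spacing = config$marker_spacing * 3,
                     map_id = "RH", seed = seed + 505L)
  )
  list(sim = sim, mis = mis, variants = variants, pairs = pairs, hits = hits)
}

#' Simulate BAC-end pairs with truth classes
#'
#' Samples clone spans from the true chromosomes (uniform within
#' `insert_range`, ~150 kbp by default) and lifts the two end reads onto
#' the chimeric contigs. Each pair receives BLAST-like E-values (a
#' fraction failing the alignment threshold) and, optionally, a recorded
#' orientation flip to create incorrectly oriented pairs. The generator
#' assigns the truth class geometrically: `unaligned` (no passing end),
#' `1` (one passing end), `4` (ends on different contigs), `3` (flipped
#' orientation or out-of-range span), else `2`.
#'
#' @param sim Output of [simulate_genome()].
#' @param map Contig lift-over map.
#' @param insert_range Clone span range `(min, max)` bp.
#' @param n Number of clones.
#' @param read_len End-read length bp.
#' @param fail_frac Per-end probability of a sub-threshold E-value.
#' @param flip_frac Per-clone probability of a recorded orientation flip.
#' @param span_range Valid clone span range used for truth classing.
#' @param seed Integer seed.
#' @return `data.frame`, one row per clone: per-end `contig`, `pos`,
#'   `strand`, `e_value` columns and `truth_class`.
#' @export
simulate_bac_ends <- function(sim, map, insert_range = c(1e5, 2e5), n = 2000,
                              read_len = 500, fail_frac = 0.05,
                              flip_frac = 0.02, span_range = c(5e4, 4e5),
                              seed = 1L) {
  genome <- if (inherits(sim, "contig_set")) sim else sim$genome
  lens <- contig_lengths(genome)
  with_seed(seed, {
    chr <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
    span <- round(stats::runif(n, insert_range[1], insert_range[2]))
    span <- pmin(span, lens[chr])
    s <- floor(stats::runif(n, 0, lens[chr] - span + 1))
    left <- lift_points(map, chr, s)
    right <- lift_points(map, chr, s + span - 1)
    strand1 <- rep("+", n); strand2 <- rep("-", n)
    flip <- stats::runif(n) < flip_frac
    strand2[flip] <- "+"
    e1 <- ifelse(stats::runif(n) < fail_frac, 10^-stats::runif(n, 50, 140),
                 10^-stats::runif(n, 160, 250))
    e2 <- ifelse(stats::runif(n) < fail_frac, 10^-stats::runif(n, 50, 140),
                 10^-stats::runif(n, 160, 250))
    pass1 <- e1 < 1e-150; pass2 <- e2 < 1e-150
    truth <- character(n)
    obs_span <- ifelse(left$contig == right$contig,
                       (right$pos + 1) - left$pos, NA)
    truth[!pass1 & !pass2] <- "unaligned"
    truth[xor(pass1, pass2)] <- "1"
    both <- pass1 & pass2
    diffc <- both & left$contig != right$contig
    truth[diffc] <- "4"
    same <- both & !diffc
    bad <- same & (flip | obs_span < span_range[1] | obs_span > span_range[2])
    truth[bad] <- "3"
    truth[same & !bad] <- "2"
    data.frame(
      clone = sprintf("bac%05d", seq_len(n)),
      contig1 = left$contig, pos1 = left$pos, strand1 = strand1, e_value1 = e1,
      contig2 = right$contig, pos2 = right$pos, strand2 = strand2, e_value2 = e2,
      truth_class = truth, stringsAsFactors = FALSE
    )
  })
}
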