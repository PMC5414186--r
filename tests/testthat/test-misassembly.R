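cs2 <- contig_set(c(c1 = 50000, c2 = 30000))

empty_cand <- function() data.frame(contig = character(), start = numeric(),
                                    end = numeric(), stringsAsFactors = FALSE)

test_that("variant density windows apply strict quality and density cutoffs", {
  # 11 variants in one 10 kbp window flags it; 10 does not
  mk <- function(n, qual = 30) data.frame(contig = "c1", pos = seq_len(n) * 100,
                                          qual = qual)
  w11 <- variant_density_windows(mk(11), cs2)
  expect_true(w11$flagged[w11$contig == "c1"][1])
  w10 <- variant_density_windows(mk(10), cs2)
  expect_false(any(w10$flagged))
  # quality exactly 10 is excluded (QUAL > 10 is strict)
  wq <- variant_density_windows(mk(11, qual = 10), cs2)
  expect_equal(sum(wq$variant_count), 0)
  # partial last window scales its threshold by true width
  cs_part <- contig_set(c(p = 12000))
  sites <- data.frame(contig = "p", pos = 10000 + seq_len(3) * 400, qual = 30)
  wp <- variant_density_windows(sites, cs_part)
  expect_equal(wp$end[2] - wp$start[2], 2000)
  expect_true(wp$flagged[2])  # 3 > 1/kbp * 2 kbp
  expect_error(variant_density_windows(data.frame(contig = "c1", pos = 60000,
                                                  qual = 30), cs2),
               "beyond contig end")
})

test_that("raising min_qual or density threshold never flags more windows", {
  set.seed(21)
  sites <- data.frame(contig = "c1", pos = sort(floor(runif(300, 0, 50000))),
                      qual = runif(300, 0, 60))
  base <- sum(variant_density_windows(sites, cs2)$flagged)
  for (q in c(20, 40)) {
    expect_lte(sum(variant_density_windows(sites, cs2, min_qual = q)$flagged), base)
  }
  for (d in c(1.5, 3)) {
    expect_lte(sum(variant_density_windows(sites, cs2,
                                           density_threshold = d)$flagged), base)
  }
})

test_that("physical coverage equals a per-base span-stacking oracle", {
  set.seed(8)
  n <- 200
  start <- floor(runif(n, 0, 45000))
  flen <- pmax(200, round(rnorm(n, 4000, 500)))
  pairs <- data.frame(
    contig1 = "c1", start1 = start, end1 = start + 100, strand1 = "+",
    contig2 = "c1", start2 = pmin(start + flen - 100, 49900),
    end2 = pmin(start + flen, 50000), strand2 = "-"
  )
  track <- physical_coverage(pairs, cs2, insert_mean = 4000, end_exclusion = 0)
  spans <- data.frame(start = pairs$start1, end = pairs$end2)
  span_ok <- (spans$end - spans$start) >= 2000 & (spans$end - spans$start) <= 8000
  want <- oracle_physcov(spans[span_ok, ], 50000)
  expect_identical(as.integer(track$coverage[["c1"]]), want)
  # a single spanning pair covers exactly its outer span
  one <- data.frame(contig1 = "c1", start1 = 100, end1 = 200, strand1 = "+",
                    contig2 = "c1", start2 = 40000, end2 = 40100, strand2 = "-")
  t1 <- physical_coverage(one, cs2, insert_mean = 4e4, end_exclusion = 0)
  v <- as.integer(t1$coverage[["c1"]])
  expect_equal(sum(v), 40000)
  expect_equal(unique(v[101:40100]), 1L)
  # inter-contig pairs contribute nowhere
  split_pair <- data.frame(contig1 = "c1", start1 = 100, end1 = 200, strand1 = "+",
                           contig2 = "c2", start2 = 100, end2 = 200, strand2 = "-")
  t2 <- physical_coverage(split_pair, cs2, insert_mean = 4e4, end_exclusion = 0)
  expect_equal(sum(as.integer(t2$coverage[["c1"]])), 0)
  expect_error(physical_coverage(
    data.frame(contig1 = "nope", start1 = 1, end1 = 2, strand1 = "+",
               contig2 = "nope", start2 = 3, end2 = 4, strand2 = "-"), cs2),
    "unknown contig")
})

test_that("low-coverage regions respect the strict threshold and the end mask", {
  one <- data.frame(contig1 = "c1", start1 = 0, end1 = 100, strand1 = "+",
                    contig2 = "c1", start2 = 49900, end2 = 50000, strand2 = "-")
  # uniform coverage 1 with min_cov 1 yields nothing (strict <)
  track <- physical_coverage(one, cs2, insert_mean = 5e4, end_exclusion = 1000)
  expect_equal(nrow(low_coverage_regions(track, min_cov = 1)), 1)  # only c2
  got <- low_coverage_regions(track, min_cov = 1)
  expect_equal(got$contig, "c2")
  # min_cov 2: whole unmasked interior of both contigs is low
  low2 <- low_coverage_regions(track, min_cov = 2)
  expect_equal(low2, data.frame(contig = c("c1", "c2"), start = c(1000, 1000),
                                end = c(49000, 29000)))
})

test_that("candidate regions require both signals at 80% overlap", {
  fw <- data.frame(contig = "c1", start = c(0, 35000), end = c(10000, 45000),
                   variant_count = c(20, 20), flagged = c(TRUE, TRUE))
  # disjoint low coverage: no candidates
  expect_equal(nrow(candidate_regions(fw, intervals("c2", 0, 5000))), 0)
  # low coverage over 80% of the first merged window only
  lc <- intervals("c1", 2000, 10000)
  got <- candidate_regions(fw, lc)
  expect_equal(got, data.frame(contig = "c1", start = 0, end = 10000))
})

test_that("map conflicts bracket the junction between differing groups", {
  hits <- data.frame(
    marker = paste0("m", 1:6), map = "RAD",
    linkage_group = c("LG1", "LG1", "LG1", "LG2", "LG2", "LG2"),
    map_position = c(1, 2, 3, 7, 8, 9),
    contig = "c1", contig_pos = c(1000, 2000, 3000, 9000, 10000, 11000),
    strand = "+"
  )
  conf <- map_conflicts(hits)
  expect_equal(nrow(conf), 1)
  expect_equal(conf$start, 3000)
  expect_equal(conf$end, 9000)
  # single-group contigs yield nothing
  expect_equal(nrow(map_conflicts(hits[1:3, ])), 0)
  expect_equal(nrow(map_conflicts(hits[0, ])), 0)
})

test_that("adjudication applies the three curation rules", {
  mkhits <- function(map, lgs, pos) data.frame(
    marker = paste0(map, seq_along(pos)), map = map, linkage_group = lgs,
    map_position = seq_along(pos), contig = "c1", contig_pos = pos, strand = "+"
  )
  cand <- intervals("c1", 20000, 30000)
  # rule 1: both maps concordant across the region -> rejected
  hits_conc <- rbind(mkhits("RAD", rep("LG1", 4), c(5000, 15000, 35000, 45000)),
                     mkhits("RH", rep("LG1", 4), c(6000, 16000, 36000, 46000)))
  calls <- adjudicate(cand, map_conflicts(hits_conc), hits_conc)
  expect_equal(calls$verdict, "rejected_by_maps")
  # rule 2: no markers from either map in the span -> accepted on signals
  hits_none <- rbind(mkhits("RAD", rep("LG1", 2), c(5000, 15000)),
                     mkhits("RH", rep("LG1", 2), c(6000, 16000)))
  # flanking on one side only: uninformative but present nowhere in span
  calls2 <- adjudicate(cand, map_conflicts(hits_none), hits_none)
  expect_equal(calls2$verdict, "accepted")
  expect_true(calls2$hd_variants & calls2$low_physcov)
  expect_false(calls2$rad_conflict | calls2$rh_conflict)
  # rule 3: map conflict alone -> accepted as map_only
  hits_conf <- mkhits("RAD", c("LG1", "LG1", "LG2", "LG2"),
                      c(5000, 15000, 35000, 45000))
  calls3 <- adjudicate(empty_cand(), map_conflicts(hits_conf), hits_conf)
  expect_equal(calls3$verdict, "map_only")
  expect_true(calls3$rad_conflict)
  expect_false(calls3$rh_conflict)
  expect_equal(nrow(accepted_calls(calls3)), 1)
})

test_that("breakpoint choice avoids annotation and matches an exhaustive scan", {
  region <- intervals("c1", 1000, 2000)
  # no annotation: exact midpoint
  expect_equal(choose_breakpoint(region)$pos, 1500)
  # midpoint inside a repeat: first legal base outside, nearest side wins
  reps <- intervals("c1", 1400, 1550)
  expect_equal(choose_breakpoint(region, repeats = reps)$pos, 1550)
  # equidistant legal candidates: leftmost wins
  reps_tie <- intervals("c1", 1400, 1601)
  expect_equal(choose_breakpoint(region, repeats = reps_tie)$pos, 1399)
  expect_error(choose_breakpoint(region, repeats = intervals("c1", 0, 3000)),
               "no legal breakpoint")
  # random layouts vs exhaustive position scan
  set.seed(31)
  for (rep in 1:30) {
    tr <- random_intervals(sample(0:4, 1), contigs = "c1", max_pos = 2000,
                           max_len = 300)
    rp <- random_intervals(sample(0:4, 1), contigs = "c1", max_pos = 2000,
                           max_len = 300)
    blocked <- function(p) {
      any(tr$start <= p & p < tr$end) || any(rp$start <= p & p < rp$end)
    }
    legal <- Filter(Negate(blocked), 1000:1999)
    if (!length(legal)) {
      expect_error(choose_breakpoint(region, tr, rp), "no legal")
    } else {
      d <- abs(legal - 1500)
      want <- min(legal[d == min(d)])
      expect_equal(choose_breakpoint(region, tr, rp)$pos, want)
    }
  }
})

test_that("breaking contigs adds exactly k contigs and conserves sequence", {
  cs <- contig_set(seq = c(a = strrep("ACGT", 25), b = strrep("GATTACA", 10)))
  bp <- data.frame(contig = c("a", "a", "b"), pos = c(40, 80, 21))
  broken <- break_contigs(cs, bp)
  expect_equal(length(broken$id), length(cs$id) + nrow(bp))
  expect_equal(sum(broken$length), sum(cs$length))
  expect_equal(paste0(as.character(broken$seq[["a.1"]]),
                      as.character(broken$seq[["a.2"]]),
                      as.character(broken$seq[["a.3"]])),
               as.character(cs$seq[["a"]]))
  expect_identical(break_contigs(cs, bp[0, ]), cs)
  expect_error(break_contigs(cs, data.frame(contig = "a", pos = 0)),
               "strictly inside")
  expect_error(break_contigs(cs, data.frame(contig = "zz", pos = 5)),
               "unknown contig")
})

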