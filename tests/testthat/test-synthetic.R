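# Deterministic fast scenario for generator checks
cfg <- small_scenario(1)
sim <- simulate_genome(cfg)
mis <- induce_misassemblies(sim, 4, seed = 2, min_segment = 1e5)

test_that("genome simulation is deterministic and conserves length", {
  sim2 <- simulate_genome(cfg)
  expect_identical(as.character(sim$genome$seq), as.character(sim2$genome$seq))
  expect_equal(sum(contig_lengths(sim$genome)), sum(cfg$chromosomes))
  short <- cfg
  short$chromosomes <- c(chr1 = 1e4, chr2 = 1e4)
  expect_error(simulate_genome(short), "10x insert_mean")
})

test_that("planted repeat copies hit the requested genome fraction", {
  rcfg <- small_scenario(4)
  rcfg$repeat_fraction <- 0.2
  rsim <- simulate_genome(rcfg)
  frac <- sum(rsim$repeats$end - rsim$repeats$start) /
    sum(contig_lengths(rsim$genome))
  expect_gt(frac, 0.18)
  expect_lt(frac, 0.22)
})

test_that("chimeric joins conserve bases and record junctions inside contigs", {
  expect_equal(sum(mis$contigs$length), sum(sim$genome$length))
  expect_equal(nrow(mis$junctions), 4)
  for (i in seq_len(nrow(mis$junctions))) {
    L <- contig_lengths(mis$contigs)[[mis$junctions$contig[i]]]
    expect_gt(mis$junctions$pos[i], 0)
    expect_lt(mis$junctions$pos[i], L)
  }
  # two sides of each junction come from different chromosomes
  for (ctg in mis$junctions$contig) {
    m <- mis$map[mis$map$contig == ctg, ]
    expect_equal(nrow(m), 2)
    expect_false(m$chr[1] == m$chr[2])
  }
  none <- induce_misassemblies(sim, 0)
  expect_identical(none$contigs, sim$genome)
  expect_equal(nrow(none$junctions), 0)
  expect_error(induce_misassemblies(sim, 500, seed = 1), "infeasible")
})

test_that("variant calls follow the Poisson background and halo rates", {
  vars <- simulate_variant_calls(mis$contigs, mis$junctions,
                                 background_rate = 0.2, junction_rate = 3,
                                 halo = 1e4, qual_fail_frac = 0.1, seed = 9)
  total_bp <- sum(mis$contigs$length)
  halo_bp <- nrow(mis$junctions) * 2e4
  lambda <- 0.2 / 1000 * (total_bp - halo_bp) + 3 / 1000 * halo_bp
  expect_lt(abs(nrow(vars) - lambda), 3 * sqrt(lambda))
  # quality mixture: ~10% at or below the QUAL 10 cutoff
  p_fail <- mean(vars$qual <= 10)
  se <- sqrt(0.1 * 0.9 / nrow(vars))
  expect_lt(abs(p_fail - 0.1), 3 * se)
  # rate 0 background, all variants inside halos
  vars0 <- simulate_variant_calls(mis$contigs, mis$junctions,
                                  background_rate = 0, junction_rate = 3,
                                  halo = 2e4, seed = 10)
  for (i in seq_len(nrow(vars0))) {
    j <- mis$junctions[mis$junctions$contig == vars0$contig[i], ]
    expect_true(any(abs(vars0$pos[i] - j$pos) <= 2e4))
  }
})

test_that("mate pairs give expected physical coverage and zero junction spanning", {
  pairs <- simulate_matepair_placements(sim, mis$map, insert_mean = cfg$insert_mean,
                                        insert_sd = cfg$insert_sd,
                                        pair_count = cfg$pair_count, seed = 5)
  expect_equal(nrow(pairs), cfg$pair_count)
  track <- physical_coverage(pairs, mis$contigs, insert_mean = cfg$insert_mean,
                             end_exclusion = 0)
  # expectation: pair_count * insert / genome
  genome_bp <- sum(contig_lengths(sim$genome))
  expected <- cfg$pair_count * cfg$insert_mean / genome_bp
  mid_cov <- mean(vapply(mis$contigs$id, function(id) {
    as.numeric(track$coverage[[id]][round(contig_lengths(mis$contigs)[[id]] / 4)])
  }, numeric(1)))
  expect_lt(abs(mid_cov - expected) / expected, 0.35)
  # concordant spanning coverage at each junction base is exactly zero
  for (i in seq_len(nrow(mis$junctions))) {
    v <- as.numeric(track$coverage[[mis$junctions$contig[i]]][mis$junctions$pos[i]])
    expect_equal(v, 0)
  }
})

test_that("markers lift with monotone positions and chimeras span two groups", {
  hits <- simulate_markers(sim, mis$map, spacing = 2e4, map_id = "RAD", seed = 6)
  # chimeric contigs carry exactly two linkage groups
  for (ctg in mis$junctions$contig) {
    expect_equal(length(unique(hits$linkage_group[hits$contig == ctg])), 2)
  }
  # against the unbroken genome: one group per contig, positions monotone
  clean_hits <- simulate_markers(sim, induce_misassemblies(sim, 0)$map,
                                 spacing = 2e4, map_id = "RAD", seed = 6)
  for (ctg in unique(clean_hits$contig)) {
    h <- clean_hits[clean_hits$contig == ctg, ]
    expect_equal(length(unique(h$linkage_group)), 1)
    h <- h[order(h$contig_pos), ]
    expect_true(all(diff(h$map_position) > 0))
  }
})

test_that("pool counts place the engineered signature inside the region only", {
  lens <- contig_set(c(chr1 = 2e6, chr2 = 2e6))
  pc <- simulate_pool_counts(lens, sd_region = list("chr1", 5e5, 1e6),
                             depth = 200, site_spacing = 500, seed = 8)
  tr <- pc$truth
  expect_true(all(tr$f_pool1[tr$in_region] == 0))
  expect_true(all(abs(tr$f_pool2[tr$in_region] - 0.5) < 0.4))
  # at high depth the heterogametic observed frequency concentrates near 0.5
  af <- allele_frequencies(pc)
  reg <- tr$in_region
  het_alt <- 1 - af$freq[[2]][cbind(which(reg),
                                    match(pc$sites$ref[reg], c("A", "T", "C", "G", "del")))]
  expect_lt(abs(mean(het_alt) - 0.5), 0.05)
  # outside the region the two pools share their truth frequency
  expect_equal(tr$f_pool1[!reg], tr$f_pool2[!reg])
})

test_that("BAC-end truth classes partition the clone set", {
  bac <- simulate_bac_ends(sim, mis$map, insert_range = c(5e4, 8e4),
                           n = 400, span_range = c(2e4, 2e5), seed = 12)
  expect_equal(nrow(bac), 400)
  expect_true(all(bac$truth_class %in% c("1", "2", "3", "4", "unaligned")))
  expect_equal(sum(table(bac$truth_class)), 400)
  # with no joins and no failures every clone is type 2
  bac2 <- simulate_bac_ends(sim, induce_misassemblies(sim, 0)$map,
                            insert_range = c(5e4, 8e4),
                            n = 100, fail_frac = 0, flip_frac = 0,
                            span_range = c(2e4, 2e5), seed = 13)
  expect_true(all(bac2$truth_class == "2"))
})
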