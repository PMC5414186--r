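site1 <- function(a, b) {
  pool_counts("c", 0, "A", list(matrix(a, 1, 6), matrix(b, 1, 6)))
}

test_that("allele frequencies exclude N and honour the depth cutoff", {
  x <- site1(c(30, 0, 0, 0, 5, 0), c(15, 15, 0, 0, 0, 0))
  af <- allele_frequencies(x)
  expect_equal(unname(af$freq[[1]][1, "A"]), 1)  # N ignored
  expect_equal(unname(af$freq[[2]][1, "A"]), 0.5)
  expect_equal(unname(af$freq[[2]][1, "T"]), 0.5)
  shallow <- site1(c(5, 4, 0, 0, 0, 0), c(15, 15, 0, 0, 0, 0))
  expect_true(all(is.na(allele_frequencies(shallow)$freq[[1]][1, ])))
})

test_that("FST has the expected fixed points and the worked value", {
  # identical deep pools: no differentiation
  expect_equal(site_fst(site1(c(15, 15, 0, 0, 0, 0), c(15, 15, 0, 0, 0, 0))), 0)
  # fixed difference: complete differentiation
  expect_equal(site_fst(site1(c(30, 0, 0, 0, 0, 0), c(0, 30, 0, 0, 0, 0))), 1)
  # monomorphic combined site is 0, not undefined
  expect_equal(site_fst(site1(c(30, 0, 0, 0, 0, 0), c(30, 0, 0, 0, 0, 0))), 0)
  # shallow pool: undefined
  expect_true(is.na(site_fst(site1(c(5, 0, 0, 0, 0, 0), c(30, 0, 0, 0, 0, 0)))))
  # worked value: p_a = 1 (n = 50) vs p_b = 0.5 (n = 50), independently
  # evaluated from the pi-based formula with the n/(n-1) correction
  got <- site_fst(site1(c(50, 0, 0, 0, 0, 0), c(25, 25, 0, 0, 0, 0)))
  pi_a <- 50 / 49 * 2 * 1 * 0
  pi_b <- 50 / 49 * 2 * 0.5 * 0.5
  pi_t <- 100 / 99 * 2 * 0.75 * 0.25
  want <- (pi_t - (pi_a + pi_b) / 2) / pi_t
  expect_equal(got, want, tolerance = 1e-9)
  expect_equal(round(want, 4), 0.3265)
})

test_that("FST is symmetric in pool order and stable under count scaling", {
  set.seed(17)
  for (rep in 1:20) {
    a <- c(rmultinom(1, 60, c(0.5, 0.3, 0.1, 0.1)), 0, 0)
    b <- c(rmultinom(1, 80, c(0.2, 0.4, 0.2, 0.2)), 0, 0)
    x <- site1(a, b)
    swapped <- site1(b, a)
    expect_equal(site_fst(x, 1, 2), site_fst(swapped, 1, 2), tolerance = 1e-12)
    # scaling both pools only tightens the n/(n-1) correction: at large
    # counts the estimate approaches the uncorrected analytic value
    x100 <- site1(a * 100, b * 100)
    keep <- order(a[1:4] + b[1:4], decreasing = TRUE)[1:2]
    pa <- a[keep[1]] / sum(a[keep]); pb <- b[keep[1]] / sum(b[keep])
    pt <- (a[keep[1]] + b[keep[1]]) / (sum(a[keep]) + sum(b[keep]))
    pi_t <- 2 * pt * (1 - pt)
    fst_inf <- (pi_t - (2 * pa * (1 - pa) + 2 * pb * (1 - pb)) / 2) / pi_t
    expect_equal(site_fst(x100), fst_inf, tolerance = 0.02)
  }
})

test_that("sex-patterned calling needs fixation plus intermediacy", {
  # homogametic fixed, heterogametic at 0.5: passes
  p1 <- sex_patterned(site1(c(30, 0, 0, 0, 0, 0), c(15, 15, 0, 0, 0, 0)),
                      homogametic = 1)
  expect_true(p1$passes)
  # both at 0.5: homogametic not fixed
  p2 <- sex_patterned(site1(c(15, 15, 0, 0, 0, 0), c(15, 15, 0, 0, 0, 0)),
                      homogametic = 1)
  expect_false(p2$passes)
  # heterogametic nearly fixed for the alternate: not intermediate
  p3 <- sex_patterned(site1(c(30, 0, 0, 0, 0, 0), c(3, 27, 0, 0, 0, 0)),
                      homogametic = 1)
  expect_false(p3$passes)
  # deletion alleles are treated like SNPs
  p4 <- sex_patterned(site1(c(30, 0, 0, 0, 0, 0), c(15, 0, 0, 0, 0, 15)),
                      homogametic = 1)
  expect_true(p4$passes)
  # boundary: homogametic minor exactly at fixed_tol passes
  p5 <- sex_patterned(site1(c(27, 3, 0, 0, 0, 0), c(15, 15, 0, 0, 0, 0)),
                      homogametic = 1, fixed_tol = 0.1)
  expect_true(p5$passes)
})

test_that("window tracks conserve counts and localize the signal", {
  lens <- contig_set(c(chrA = 4e5, chrB = 2e5))
  pc <- simulate_pool_counts(lens, sd_region = list("chrA", 1e5, 2e5),
                             depth = 40, site_spacing = 200, seed = 19)
  tr <- window_tracks(pc, contigs = lens, window = 1e4, homogametic = 1)
  sp <- sex_patterned(pc, homogametic = 1)
  expect_equal(sum(tr$sex_patterned), sum(sp$passes))
  expect_equal(sum(tr$n_sites), nrow(pc$sites))
  # windows inside the region hold nearly all passing sites
  inside <- tr$contig == "chrA" & tr$start >= 1e5 & tr$end <= 2e5
  expect_gt(sum(tr$sex_patterned[inside]) / sum(tr$sex_patterned), 0.95)
  # mean FST is elevated inside the region
  expect_gt(mean(tr$mean_fst[inside], na.rm = TRUE),
            mean(tr$mean_fst[!inside], na.rm = TRUE) + 0.1)
  ta <- tally_sex_patterned(sp, "chrA")
  expect_equal(ta$on + ta$off, ta$total)
})

test_that("region detection finds runs, tolerates dropouts, splits on real gaps", {
  mk <- function(counts) data.frame(contig = "c", start = seq_along(counts) * 1e4 - 1e4,
                                    end = seq_along(counts) * 1e4,
                                    n_sites = 50, mean_fst = 0.1,
                                    sex_patterned = counts)
  expect_equal(nrow(detect_sd_region(mk(rep(0, 20)), 3, 5)), 0)
  # a run with a single-window dropout stays one region
  tr <- mk(c(0, 0, 8, 9, 0, 7, 8, 9, 0, 0))
  got <- detect_sd_region(tr, 3, 5)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 2e4)
  expect_equal(got$end, 8e4)
  # two separated runs give two regions
  tr2 <- mk(c(8, 8, 8, 0, 0, 0, 8, 8, 8))
  expect_equal(nrow(detect_sd_region(tr2, 3, 5)), 2)
  # runs shorter than min_run_windows are dropped
  expect_equal(nrow(detect_sd_region(mk(c(0, 8, 8, 0, 0)), 3, 5)), 0)
})

test_that("sync files round-trip counts and coordinates", {
  lens <- contig_set(c(z = 5e4))
  pc <- simulate_pool_counts(lens, sd_region = NULL, depth = 30,
                             site_spacing = 1000, seed = 23)
  path <- tempfile(fileext = ".sync")
  write_sync(pc, path)
  back <- read_sync(path)
  expect_equal(back$sites$contig, pc$sites$contig)
  expect_equal(back$sites$pos, pc$sites$pos)
  expect_identical(back$counts[[1]], pc$counts[[1]])
  expect_identical(back$counts[[2]], pc$counts[[2]])
  # file is 1-based
  first <- strsplit(readLines(path, 1), "\t")[[1]]
  expect_equal(as.numeric(first[2]), pc$sites$pos[1] + 1)
})
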