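test_that("loop signal change reads the constructed pixel ratio exactly", {
  n <- 60
  res <- 1e4
  base <- 20 / (abs(outer(1:n, 1:n, "-")) + 1)
  lp <- loops_at_bins(c(10, 25), c(35, 50), res, chrom = "chrT")
  before <- bview_from_dense(base, resolution = res, chrom = "chrT")
  same <- loop_signal_change(before, before, lp)
  expect_equal(same$loops$ratio, c(1, 1))
  expect_equal(same$mean_ratio, 1)   # i.e. a 0% change

  # scale the loop pixels by 0.4 and renormalize totals away
  after_m <- base
  for (k in 1:2) {
    i <- same$loops$bin1[k] + 1L; j <- same$loops$bin2[k] + 1L
    after_m[i, j] <- 0.4 * after_m[i, j]
    after_m[j, i] <- after_m[i, j]
  }
  after <- bview_from_dense(after_m, resolution = res, chrom = "chrT")
  sc <- loop_signal_change(before, after, lp)
  depth_factor <- before$total / after$total
  expect_equal(sc$mean_ratio, 0.4 * depth_factor, tolerance = 1e-12)

  # a loop at a masked bin is flagged and excluded from the mean
  masked <- before
  masked$balanced[11, ] <- NA; masked$balanced[, 11] <- NA
  sc2 <- loop_signal_change(masked, after, lp)
  expect_identical(sc2$loops$flag, c("undefined", "ok"))
  expect_equal(sum(sc2$loops$flag == "ok"), 1L)
})

test_that("loop signal summary is invariant to depth rescaling", {
  n <- 60
  base <- 20 / (abs(outer(1:n, 1:n, "-")) + 1)
  lp <- loops_at_bins(10, 40, 1e4, chrom = "chrT")
  b1 <- bview_from_dense(base, resolution = 1e4, chrom = "chrT")
  b2 <- bview_from_dense(3 * base, resolution = 1e4, chrom = "chrT")
  sc <- loop_signal_change(b1, b2, lp)
  expect_equal(sc$mean_ratio, 1, tolerance = 1e-12)
})

test_that("APA is flat on uniform signal and recovers planted loop peaks", {
  # distance-only matrix -> O/E == 1 -> enrichment exactly 1
  n <- 80
  flat <- 50 / (abs(outer(1:n, 1:n, "-")) + 1)
  lp <- loops_at_bins(20, 55, 1e4, chrom = "chrT")
  res <- apa(bview_from_dense(flat, resolution = 1e4, chrom = "chrT"), lp,
             half_window = 10)
  expect_equal(res$center_enrichment, 1, tolerance = 1e-12)
  expect_equal(res$n_loops, 1L)

  # planted loops with factor 10
  tr <- hic_truth(n_bins = 200, resolution = 1e4, delta = 0, tad_factor = 1,
                  n_loops = 8, loop_factor = 10, n_stripes = 0, depth = 2e6,
                  seed = 2)
  pair <- simulate_hic_pair(tr, seed = 21)
  b <- kr_balance(pair$before, min_nnz = 5)
  lps <- loops_at_bins(tr$loops$bin1, tr$loops$bin2, 1e4)
  ap <- apa(b, lps, half_window = 10)
  expect_gt(ap$center_enrichment, 7)
  expect_lt(ap$center_enrichment, 13)

  # shuffled non-loop pixels calibrate to no enrichment
  tr0 <- hic_truth(n_bins = 200, resolution = 1e4, delta = 0, tad_factor = 1,
                   n_loops = 0, n_stripes = 0, depth = 2e6, seed = 2)
  b0 <- kr_balance(simulate_hic_pair(tr0, seed = 23)$before, min_nnz = 5)
  set.seed(6)
  i0 <- sample(12:150, 40, replace = TRUE)
  null_lp <- loops_at_bins(i0, i0 + sample(25:40, 40, TRUE), 1e4)
  ap0 <- apa(b0, null_lp, half_window = 10)
  expect_equal(ap0$center_enrichment, 1, tolerance = 0.1)

  expect_error(apa(b0, loops_at_bins(5, 12, 1e4), half_window = 10),
               "no usable loops")
})

test_that("APA grouping aggregates each group over its own loop count", {
  tr <- hic_truth(n_bins = 200, resolution = 1e4, delta = 0, tad_factor = 1,
                  n_loops = 6, loop_factor = 8, n_stripes = 0, depth = 2e6,
                  seed = 4)
  b <- kr_balance(simulate_hic_pair(tr, seed = 25)$before, min_nnz = 5)
  lps <- loops_at_bins(tr$loops$bin1, tr$loops$bin2, 1e4)
  lps$subcomp <- rep(c("A1", "B1"), each = 3)
  grouped <- apa(b, lps, half_window = 8, group_by = "subcomp")
  expect_named(grouped, c("A1", "B1"))
  expect_equal(grouped$A1$n_loops, 3L)
  expect_equal(grouped$B1$n_loops, 3L)
  solo <- apa(b, lps[lps$subcomp == "A1", ], half_window = 8)
  expect_equal(grouped$A1$matrix, solo$matrix)
})

test_that("differential loops honor the anchor slop on both ends", {
  lp <- loop_set(data.frame(chrom1 = "chr1", start1 = c(1e5, 5e5),
                            end1 = c(1.1e5, 5.1e5),
                            chrom2 = "chr1", start2 = c(3e5, 9e5),
                            end2 = c(3.1e5, 9.1e5)))
  same <- differential_loops(lp, lp)
  expect_equal(same$lost_fraction, 0)
  expect_length(same$gained, 0L)

  shifted <- lp
  shifted$start1 <- lp$start1 + 1.5e4; shifted$end1 <- lp$end1 + 1.5e4
  shifted$start2 <- lp$start2 + 1.5e4; shifted$end2 <- lp$end2 + 1.5e4
  # 15 kb shift with 10 kb slop on both sides still overlaps
  d <- differential_loops(lp, shifted, slop = 1e4)
  expect_equal(d$lost_fraction, 0)
  # no slop: a 15 kb shift of a 10 kb anchor cannot overlap
  d0 <- differential_loops(lp, shifted, slop = 0)
  expect_equal(d0$lost_fraction, 1)

  other <- lp
  other$chrom1 <- other$chrom2 <- "chr9"
  d2 <- differential_loops(lp, other)
  expect_equal(d2$lost_fraction, 1)
  expect_equal(d2$gained, 1:2)
})

test_that("differential loops agree with a brute-force overlap oracle", {
  set.seed(77)
  brute <- function(bf, af, slop) {
    vapply(seq_len(nrow(bf)), function(i) {
      hit <- FALSE
      for (j in seq_len(nrow(af))) {
        o1 <- max(bf$start1[i] - slop, af$start1[j] - slop) <
              min(bf$end1[i] + slop, af$end1[j] + slop)
        o2 <- max(bf$start2[i] - slop, af$start2[j] - slop) <
              min(bf$end2[i] + slop, af$end2[j] + slop)
        cc <- bf$chrom1[i] == af$chrom1[j] && bf$chrom2[i] == af$chrom2[j]
        if (cc && o1 && o2) { hit <- TRUE; break }
      }
      hit
    }, logical(1))
  }
  rand_loops <- function(n) {
    s1 <- sample(1e6, n); s2 <- s1 + sample(5e4:2e5, n, TRUE)
    loop_set(data.frame(
      chrom1 = sample(c("chr1", "chr2"), n, TRUE), start1 = s1,
      end1 = s1 + 1e4, chrom2 = "chr1", start2 = s2, end2 = s2 + 1e4))
  }
  for (k in 1:30) {
    bf <- rand_loops(sample(3:10, 1))
    bf$chrom2 <- bf$chrom1
    af <- rand_loops(sample(3:10, 1))
    af$chrom2 <- af$chrom1
    d <- differential_loops(bf, af, slop = 1e4)
    expect_identical(d$kept, brute(bf, af, 1e4))
    # lost(before, after) mirrors gained(after, before)
    expect_equal(d$lost, differential_loops(af, bf, slop = 1e4)$gained)
  }
})

test_that("stripe aggregation reports enrichment over flanking background", {
  # direct construction: flat decay + one left stripe of factor 3
  n <- 80
  res <- 1e4
  m <- 30 / (abs(outer(1:n, 1:n, "-")) + 1)
  a <- 30
  m[a, (a + 1):(a + 15)] <- 3 * m[a, (a + 1):(a + 15)]
  m[(a + 1):(a + 15), a] <- m[a, (a + 1):(a + 15)]
  stripes <- data.frame(chrom = "chrT", start = (a - 1) * res, end = a * res,
                        orientation = "left")
  sa <- stripe_aggregate(bview_from_dense(m, resolution = res, chrom = "chrT"),
                         stripes, extent = 15)
  expect_equal(sa$ratio, 3, tolerance = 0.1)

  # no stripes anywhere -> ratio about 1
  sa0 <- stripe_aggregate(
    bview_from_dense(30 / (abs(outer(1:n, 1:n, "-")) + 1),
                     resolution = res, chrom = "chrT"),
    stripes, extent = 15)
  expect_equal(sa0$ratio, 1, tolerance = 0.05)

  # mirror symmetry: reversing the genome turns a left stripe into a right
  # stripe with the identical profile
  m2 <- 30 / (abs(outer(1:n, 1:n, "-")) + 1)
  m2[a, (a + 1):(a + 10)] <- 2 * m2[a, (a + 1):(a + 10)]
  m2[(a + 1):(a + 10), a] <- m2[a, (a + 1):(a + 10)]
  left <- stripe_aggregate(bview_from_dense(m2, resolution = res,
                                            chrom = "chrT"),
                           data.frame(chrom = "chrT", start = (a - 1) * res,
                                      end = a * res, orientation = "left"),
                           extent = 10)
  m2r <- m2[n:1, n:1]
  a_r <- n + 1 - a
  right <- stripe_aggregate(bview_from_dense(m2r, resolution = res,
                                             chrom = "chrT"),
                            data.frame(chrom = "chrT",
                                       start = (a_r - 1) * res,
                                       end = a_r * res,
                                       orientation = "right"),
                            extent = 10)
  expect_equal(right$profile, left$profile, tolerance = 1e-12)

  # planted stripes in the generator remain clearly enriched after balancing
  tr <- hic_truth(n_bins = 200, resolution = 1e4, delta = 0, tad_factor = 1,
                  n_loops = 0, n_stripes = 4, stripe_factor = 3, depth = 2e6,
                  seed = 9)
  pair <- simulate_hic_pair(tr, seed = 31)
  bb <- kr_balance(pair$before, min_nnz = 5)
  sdf <- data.frame(chrom = "chrS", start = tr$stripes$anchor * 1e4,
                    end = (tr$stripes$anchor + 1) * 1e4,
                    orientation = tr$stripes$orientation)
  sag <- stripe_aggregate(bb, sdf, extent = 15)
  expect_gt(sag$ratio, 1.7)
})

test_that("loops are classified by stripe-anchor overlap at both ends", {
  anchors <- interval_set(data.frame(chrom = "chr1",
                                     start = c(1e5, 5e5), end = c(2e5, 6e5)))
  lp <- loop_set(data.frame(
    chrom1 = "chr1", start1 = c(1.2e5, 1.2e5, 7e5),
    end1 = c(1.3e5, 1.3e5, 7.1e5),
    chrom2 = "chr1", start2 = c(5.2e5, 8e5, 9e5),
    end2 = c(5.3e5, 8.1e5, 9.1e5)))
  expect_identical(classify_loops_by_stripe(lp, anchors),
                   c("both", "one", "none"))

  # randomized fixtures against a brute-force all-pairs scan
  set.seed(88)
  for (k in 1:10) {
    sa <- interval_set(data.frame(chrom = "chr1",
                                  start = s <- sample(1e6, 6),
                                  end = s + sample(2e4, 6)))
    s1 <- sample(1e6, 8); s2 <- s1 + 2e5
    lps <- loop_set(data.frame(chrom1 = "chr1", start1 = s1, end1 = s1 + 1e4,
                               chrom2 = "chr1", start2 = s2, end2 = s2 + 1e4))
    got <- classify_loops_by_stripe(lps, sa)
    want <- vapply(seq_len(8), function(i) {
      h1 <- any(lps$start1[i] < sa$end & sa$start < lps$end1[i])
      h2 <- any(lps$start2[i] < sa$end & sa$start < lps$end2[i])
      c("none", "one", "both")[h1 + h2 + 1L]
    }, character(1))
    expect_identical(got, want)
  }
})
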