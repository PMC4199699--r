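nine_locus_map <- function() {
  linkage_map(sprintf("m%d", 1:9), rep(1, 9), c(0, 10, 20, 30, 40, 50, 60, 80, 100))
}

test_that("donor segment calling uses midpoint and terminal conventions", {
  map <- nine_locus_map()
  calls <- setNames(rep("RR", 9), map$locus)
  calls[c("m4", "m5", "m6")] <- "DD"   # donor at 30, 40, 50; RR flanks 20, 60
  s <- call_donor_segments(calls, map)
  expect_equal(s[, c("start", "end", "zygosity")],
               data.frame(start = 25, end = 55, zygosity = "homozygous_donor"))

  # all recurrent -> nothing called
  expect_equal(nrow(call_donor_segments(setNames(rep("RR", 9), map$locus), map)), 0L)

  # terminal run extends to the group end
  map2 <- linkage_map(c("z0", "a", "b", "z1"), rep(1, 4), c(0, 80, 95, 100))
  c2 <- setNames(c("RR", "RR", "DD", "DD"), map2$locus)
  s2 <- call_donor_segments(c2, map2)
  expect_equal(c(s2$start, s2$end), c(87.5, 100))

  # heterozygous runs are separate segments with their zygosity
  c3 <- setNames(rep("RR", 9), map$locus)
  c3[c("m4", "m5")] <- "RD"
  s3 <- call_donor_segments(c3, map)
  expect_equal(s3$zygosity, "heterozygous")

  # missing calls bridge a run up to the gap limit, then split it
  c4 <- setNames(rep("RR", 9), map$locus)
  c4[c("m2", "m4")] <- "DD"; c4["m3"] <- NA          # 10 and 30, 20 cM apart
  expect_equal(nrow(call_donor_segments(c4, map, max_gap_cM = 20)), 1L)
  expect_equal(nrow(call_donor_segments(c4, map, max_gap_cM = 15)), 2L)

  # a group with no non-missing call is reported uncalled
  mapg <- linkage_map(c("p1", "q1"), c(1, 2), c(0, 0))
  cg <- setNames(c("DD", NA), mapg$locus)
  sg <- call_donor_segments(cg, mapg)
  expect_equal(attr(sg, "uncalled")$group, "2")
})

test_that("greedy selection covers maximally and breaks ties by line id", {
  segs <- data.frame(line_id = c("A", "B", "C"), group = "1",
                     start = c(0, 40, 45), end = c(50, 100, 55),
                     zygosity = "homozygous_donor")
  sel <- select_nonredundant(segs, min_gain = 1)
  expect_setequal(as.character(sel), c("A", "B"))  # C adds nothing

  # containment: only the larger line is picked
  seg2 <- data.frame(line_id = c("big", "small"), group = "1",
                     start = c(10, 20), end = c(60, 30), zygosity = "homozygous_donor")
  expect_equal(as.character(select_nonredundant(seg2)), "big")

  # identical lines: exactly one, lexicographically first
  seg3 <- data.frame(line_id = c("L2", "L1"), group = "1",
                     start = 0, end = 40, zygosity = "homozygous_donor")
  expect_equal(as.character(select_nonredundant(seg3)), "L1")

  # multi-segment lines can be excluded up front
  seg4 <- rbind(segs,
                data.frame(line_id = "multi", group = "1",
                           start = c(60, 80), end = c(70, 90),
                           zygosity = "homozygous_donor"))
  sel4 <- select_nonredundant(seg4, single_fragment_only = TRUE)
  expect_false("multi" %in% sel4)
  expect_length(select_nonredundant(segs[0, ]), 0L)
})

test_that("coverage report union arithmetic matches rasterization", {
  map <- linkage_map(c("x0", "x1"), c(1, 1), c(0, 100))
  segs <- data.frame(line_id = "L", group = "1",
                     start = c(10, 50), end = c(30, 60), zygosity = "homozygous_donor")
  rep_ <- coverage_report(segs, map)
  expect_equal(rep_$covered_cM, 30)
  expect_equal(rep_$n_fragments, 2L)
  expect_equal(rep_$percent_covered, 30.0)

  # overlap merges to full coverage
  seg2 <- data.frame(line_id = c("a", "b"), group = "1",
                     start = c(0, 40), end = c(60, 100), zygosity = "homozygous_donor")
  expect_equal(coverage_report(seg2, map)$percent_covered, 100.0)

  # empty panel: zeros everywhere
  rep0 <- coverage_report(segs[0, ], map)
  expect_equal(rep0$covered_cM, 0)
  expect_equal(rep0$percent_covered, 0.0)

  expect_error(coverage_report(
    data.frame(line_id = "x", group = "1", start = 50, end = 120,
               zygosity = "homozygous_donor"), map), "outside")

  set.seed(9)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    st <- runif(n, 0, 90)
    rs <- data.frame(line_id = paste0("L", seq_len(n)), group = "1",
                     start = st, end = pmin(st + runif(n, 1, 30), 100),
                     zygosity = "homozygous_donor")
    expect_lt(abs(coverage_report(rs, map)$covered_cM -
                    oracle_raster_coverage(rs, 100)), 0.05)
  }
})

test_that("greedy attains the exhaustive optimum on small instances", {
  set.seed(15)
  for (i in 1:12) {
    n <- sample(3:10, 1)
    st <- runif(n, 0, 90)
    segs <- data.frame(line_id = sprintf("L%02d", seq_len(n)), group = "1",
                       start = st, end = pmin(st + runif(n, 2, 40), 100),
                       zygosity = "homozygous_donor")
    sel <- select_nonredundant(segs, min_gain = 0)
    got <- .union_cov(attr(sel, "segments"))
    expect_equal(got, oracle_best_coverage(segs), tolerance = 1e-9)
  }
})

test_that("backcross panel calling raises no phantom segments at zero error", {
  map <- example_backbone_map()
  spec <- pedigree_spec(list(ped_cross(1), ped_backcross("Am", 4, 25),
                             ped_self(2, 25)), seed = 41)
  pop <- simulate_pedigree(spec, map)$population
  geno <- genotype_population(pop, make_codominant_markers(map),
                              line_ids = sprintf("IL%02d", 1:25))$ssr
  segs <- call_donor_segments(geno, map)
  for (k in seq_len(nrow(segs))) {
    p <- pop[[match(segs$line_id[k], sprintf("IL%02d", 1:25))]]
    d <- diplotype(p)[[as.character(segs$group[k])]]
    donor <- d$state %in% c("Au", "Het")
    # every called segment overlaps a true donor-carrying region
    expect_true(any(donor & d$start < segs$end[k] & d$end > segs$start[k]))
  }
})
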