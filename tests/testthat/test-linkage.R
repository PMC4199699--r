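test_that("Kosambi transforms match closed forms and invert exactly", {
  expect_equal(kosambi_cM(0), 0)
  expect_equal(kosambi_cM(0.1), 25 * log(1.2 / 0.8))
  expect_equal(round(kosambi_cM(0.1), 2), 10.14)
  r <- seq(0.01, 0.49, by = 0.01)
  expect_lt(max(abs(kosambi_inverse(kosambi_cM(r)) - r)), 1e-12)
  d <- seq(0, 300, by = 7.5)
  expect_lt(max(abs(kosambi_cM(kosambi_inverse(d)) - d)), 1e-9)
  # strictly increasing
  expect_true(all(diff(kosambi_cM(seq(0, 0.499, by = 0.001))) > 0))
  expect_error(kosambi_cM(0.5), "0.5")
  expect_error(kosambi_inverse(-1))
})

test_that("codominant rf estimator handles perfect linkage and independence", {
  # all parental classes, no recombinant gametes
  perfect <- matrix(c(25, 0, 0, 0, 50, 0, 0, 0, 25), 3, 3, byrow = TRUE)
  e <- estimate_rf_codominant(perfect)
  expect_equal(e$r_hat, 0, tolerance = 1e-6)
  expect_gt(e$lod, 3)
  # independent loci: the balanced table
  indep <- round(outer(c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25)) * 400)
  e2 <- estimate_rf_codominant(indep)
  expect_gt(e2$r_hat, 0.45)
  expect_lt(e2$lod, 0.05)
  expect_error(estimate_rf_codominant(matrix(0, 3, 3)), "empty")
})

test_that("dominant rf estimator matches the moment oracle on the worked table", {
  # coupling, n = 400 at r = 0.1: both-absent class (1-r)^2/4 = 81/400,
  # singles (1-(1-r)^2)/4 = 19/400 each, both-present (2+(1-r)^2)/4 = 281/400
  tab <- matrix(c(281, 19, 19, 81), 2, 2, byrow = TRUE)
  e <- estimate_rf_dominant(tab, "coupling")
  moment <- 1 - sqrt(4 * 81 / 400)
  expect_equal(moment, 0.1)
  expect_lt(abs(e$r_hat - moment), 0.01)
  expect_lt(abs(e$r_hat - oracle_rf_dominant_grid(tab, "coupling")), 0.001 + 1e-9)

  # no recombinant-informative classes -> r = 0
  tab0 <- matrix(c(300, 0, 0, 100), 2, 2, byrow = TRUE)
  expect_equal(estimate_rf_dominant(tab0, "coupling")$r_hat, 0, tolerance = 1e-6)

  # repulsion signature: complementary presence, never jointly absent
  tabr <- matrix(c(200, 100, 100, 0), 2, 2, byrow = TRUE)
  er <- estimate_rf_dominant(tabr, "unknown")
  expect_identical(er$phase, "repulsion")
  expect_lt(er$r_hat, 0.05)
  expect_lt(abs(er$r_hat - oracle_rf_dominant_grid(tabr, "repulsion")),
            0.001 + 1e-9)

  # degenerate tiny single-class table is flagged
  deg <- matrix(c(3, 0, 0, 0), 2, 2)
  expect_true(estimate_rf_dominant(deg, "coupling")$low_information)
})

test_that("EM estimates track the grid-likelihood oracle on random tables", {
  set.seed(11)
  for (i in 1:60) {
    r <- runif(1, 0, 0.5); n <- sample(50:500, 1)
    tc <- rand_codom_table(r, n)
    expect_lt(abs(estimate_rf_codominant(tc)$r_hat -
                    oracle_rf_codominant_grid(tc)), 0.001 + 1e-9)
    td <- rand_dom_table(r, n, "coupling")
    expect_lt(abs(estimate_rf_dominant(td, "coupling")$r_hat -
                    oracle_rf_dominant_grid(td, "coupling")), 0.001 + 1e-9)
  }
})

test_that("LOD is zero at independence and positive under linkage", {
  set.seed(3)
  for (r in c(0.05, 0.2)) {
    e <- estimate_rf_codominant(rand_codom_table(r, 400))
    expect_lt(e$r_hat, 0.5)
    expect_gt(e$lod, 3)
  }
  flat <- round(outer(c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25)) * 800)
  expect_lt(estimate_rf_codominant(flat)$lod, 0.05)
})

test_that("threshold grouping respects edges, LOD gate and nesting", {
  est <- data.frame(locus_a = c("a", "b"), locus_b = c("b", "c"),
                    r_hat = c(0.05, 0.4), lod = c(10, 10), phase = "coupling",
                    n = 100)
  g <- group_loci(est, markers = c("a", "b", "c"))
  at25 <- g$groups[[1]]
  expect_setequal(vapply(at25, paste, "", collapse = ","), c("a,b", "c"))

  # chain a-b-c each r = 0.2: one group at 0.25, singletons at 0.05
  chain <- data.frame(locus_a = c("a", "b"), locus_b = c("b", "c"),
                      r_hat = 0.2, lod = 10, phase = "coupling", n = 100)
  gc_ <- group_loci(chain)
  expect_length(gc_$groups[[1]], 1L)
  expect_length(final_groups(gc_), 3L)

  # low-LOD edge is never used
  weak <- data.frame(locus_a = "a", locus_b = "b", r_hat = 0.01, lod = 1,
                     phase = "coupling", n = 20)
  expect_length(final_groups(group_loci(weak, markers = c("a", "b"))), 2L)

  # nesting: every stricter-threshold group lies inside one looser group
  set.seed(5)
  nm <- letters[1:12]
  pairs <- t(combn(nm, 2))
  est2 <- data.frame(locus_a = pairs[, 1], locus_b = pairs[, 2],
                     r_hat = runif(nrow(pairs), 0, 0.5), lod = 10,
                     phase = "coupling", n = 100)
  g2 <- group_loci(est2)
  for (k in seq_along(g2$thresholds)[-1]) {
    for (sub in g2$groups[[k]]) {
      holders <- vapply(g2$groups[[k - 1]], function(sup) all(sub %in% sup),
                        logical(1))
      expect_equal(sum(holders), 1L)
    }
  }
})
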