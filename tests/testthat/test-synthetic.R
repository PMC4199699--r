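one_group_map <- function(len = 100) {
  linkage_map(c("m0", "m1"), c(1, 1), c(0, len))
}

test_that("gamete crossover count follows the map length in morgans", {
  map <- one_group_map(100)
  f1 <- combine_gametes(lapply(founder_painting(map, "Am")$groups, `[[`, "h1"),
                        lapply(founder_painting(map, "Au")$groups, `[[`, "h1"),
                        founder_painting(map, "Am")$bounds)
  set.seed(101)
  n <- 5000
  xo <- vapply(seq_len(n), function(i) {
    length(simulate_gamete(f1)[[1]]$origin) - 1L
  }, integer(1))
  # Poisson(1): mean 1, se = 1/sqrt(n); visible switches equal drawn
  # crossovers because the whole chromosome is heterospecific
  expect_lt(abs(mean(xo) - 1), 3 / sqrt(n))
  # and the donor allele is transmitted at ~50% anywhere without distortion
  carry <- vapply(seq_len(2000), function(i) {
    introgramap:::.origin_at(simulate_gamete(f1)[[1]], 37) == "Au"
  }, logical(1))
  expect_lt(abs(mean(carry) - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("complete elimination and graded distortion act on transmission", {
  map <- one_group_map(100)
  f1 <- combine_gametes(lapply(founder_painting(map, "Am")$groups, `[[`, "h1"),
                        lapply(founder_painting(map, "Au")$groups, `[[`, "h1"),
                        founder_painting(map, "Am")$bounds)
  set.seed(7)
  elim <- data.frame(group = 1, start_cM = 40, end_cM = 60, donor_prob = 0)
  hits <- vapply(seq_len(3000), function(i) {
    introgramap:::.origin_at(simulate_gamete(f1, elim)[[1]], 50) == "Au"
  }, logical(1))
  expect_equal(sum(hits), 0L)

  skew <- data.frame(group = 1, start_cM = 40, end_cM = 60, donor_prob = 0.2)
  hits2 <- vapply(seq_len(3000), function(i) {
    introgramap:::.origin_at(simulate_gamete(f1, skew)[[1]], 50) == "Au"
  }, logical(1))
  expect_lt(abs(mean(hits2) - 0.2), 3 * sqrt(0.2 * 0.8 / 3000))

  bad <- data.frame(group = 1, start_cM = 90, end_cM = 120, donor_prob = 0.5)
  expect_error(simulate_gamete(f1, bad), "outside map bounds")
})

test_that("pedigrees are deterministic and match closed-form expectations", {
  map <- example_backbone_map()
  spec <- pedigree_spec(list(ped_cross(1), ped_self(1, 50)), seed = 99)
  a <- simulate_pedigree(spec, map)
  b <- simulate_pedigree(spec, map)
  expect_identical(a, b)
  expect_length(a$population, 50L)
  expect_true(all(vapply(a$population, painting_is_valid, logical(1))))

  # selfing halves heterozygosity per generation: F3 expects 0.25
  spec2 <- pedigree_spec(list(ped_cross(1), ped_self(2, 300)), seed = 5)
  f3 <- simulate_pedigree(spec2, map)$population
  hets <- vapply(f3, het_fraction, numeric(1))
  expect_lt(abs(mean(hets) - 0.25), 3 * stats::sd(hets) / sqrt(length(hets)))

  # F2 donor allele frequency is 1/2 without distortion
  spec3 <- pedigree_spec(list(ped_cross(1), ped_self(1, 400)), seed = 6)
  f2 <- simulate_pedigree(spec3, map)$population
  dfs <- vapply(f2, donor_fraction, numeric(1))
  expect_lt(abs(mean(dfs) - 0.5), 3 * stats::sd(dfs) / sqrt(length(dfs)))
})

test_that("per-locus F2 donor frequency is Mendelian across the map", {
  map <- example_backbone_map()
  spec <- pedigree_spec(list(ped_cross(1), ped_self(1, 250)), seed = 13)
  f2 <- simulate_pedigree(spec, map)$population
  mk <- make_codominant_markers(map)
  g <- genotype_population(f2, mk)$ssr$calls
  # donor allele count per locus ~ Binomial(2n, 1/2); binomial test at
  # alpha = 0.001 should pass for >= 99% of loci
  pvals <- apply(g, 2, function(col) {
    x <- sum(col == "DD") * 2L + sum(col == "RD")
    stats::binom.test(x, 2L * length(col))$p.value
  })
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("dominance masking and codominant calls follow the painting", {
  map <- one_group_map(100)
  fam <- founder_painting(map, "Am")
  het <- combine_gametes(lapply(fam$groups, `[[`, "h1"),
                         lapply(founder_painting(map, "Au")$groups, `[[`, "h1"),
                         fam$bounds)
  mk <- data.frame(name = c("am_f", "au_f", "sh", "ssr"), group = 1,
                   position_cM = c(10, 20, 30, 40),
                   system = c("dominant", "dominant", "dominant", "codominant"),
                   species = c("Am_specific", "Au_specific", "shared", NA))
  g <- genotype_from_painting(het, mk)
  expect_equal(unname(g), c("1", "1", "1", "RD"))  # het: both fragments visible
  g_am <- genotype_from_painting(fam, mk)
  expect_equal(unname(g_am), c("1", "0", "1", "RR"))  # Au fragment absent
  au <- founder_painting(map, "Au")
  expect_equal(unname(genotype_from_painting(au, mk)), c("0", "1", "1", "DD"))
  off <- data.frame(name = "x", group = 1, position_cM = 150,
                    system = "dominant", species = "shared")
  expect_error(genotype_from_painting(fam, off), "outside")
  expect_error(genotype_from_painting(fam, mk, error_rate = 0.6), "0.5")
})

test_that("tiling invariant holds across simulated generations", {
  map <- example_backbone_map()
  spec <- pedigree_spec(list(ped_cross(1), ped_backcross("Am", 2, 20),
                             ped_self(1, 20)), seed = 21)
  pop <- simulate_pedigree(spec, map)$population
  expect_true(all(vapply(pop, painting_is_valid, logical(1))))
})

test_that("fertility model respects its binomial mean and clamping", {
  map <- one_group_map(100)
  fam <- founder_painting(map, "Am")
  set.seed(31)
  seeds <- vapply(seq_len(800), function(i) {
    simulate_fertility(fam, baseline = 0.9, penalty = 0, n_spikelets = 100)$n_seeds
  }, numeric(1))
  expect_lt(abs(mean(seeds) - 180), 3 * stats::sd(seeds) / sqrt(800))
  expect_equal(simulate_fertility(fam, 0, 0.5, 50)$n_seeds, 0)
  het <- combine_gametes(lapply(fam$groups, `[[`, "h1"),
                         lapply(founder_painting(map, "Au")$groups, `[[`, "h1"),
                         fam$bounds)
  # penalty equal to baseline on a fully heterospecific genome -> clamped to 0
  expect_equal(simulate_fertility(het, 0.9, 0.9, 50)$n_seeds, 0)
})
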