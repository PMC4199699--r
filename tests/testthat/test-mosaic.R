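test_that("fragment species assignment follows the reference parents", {
  parents <- fragment_matrix(rbind(am = c(1, 1, 0, 0, NA),
                                   au = c(0, 1, 1, 0, NA)))
  lab <- assign_fragment_species(parents, am_lines = "am", au_lines = "au")
  expect_equal(unname(lab), c("Am_specific", "shared", "Au_specific",
                              "unassigned", "unassigned"))
  expect_error(assign_fragment_species(parents, character(0), "au"),
               "at least one")
})

test_that("subgroup anchoring takes the interval hull and flags conflicts", {
  anchors <- data.frame(fragment = c("f1", "f2", "f3", "f5"),
                        group = c("3", "3", "1", "5"),
                        position_cM = c(40, 55, 10, 80))
  a <- anchor_subgroup(c("f1", "f2"), anchors)
  expect_equal(a[c("status", "group", "start", "end")],
               list(status = "anchored", group = "3", start = 40, end = 55))
  # members on two linkage groups: the duplicated-block situation is flagged
  cf <- anchor_subgroup(c("f3", "f5"), anchors)
  expect_equal(cf$status, "conflict")
  expect_setequal(cf$groups, c("1", "5"))
  expect_equal(anchor_subgroup("nope", anchors)$status, "unanchored")
})

test_that("subgroup classification implements the repulsion/coupling rule", {
  species <- c(a1 = "Am_specific", a2 = "Am_specific",
               u1 = "Au_specific", u2 = "Au_specific")
  anchors <- data.frame(fragment = c("a1", "a2", "u1", "u2"), group = "2",
                        position_cM = c(10, 20, 12, 22))
  # single-species subgroup -> homozygous label
  hom <- classify_subgroup(c("a1", "a2"), species, anchors = anchors)
  expect_equal(hom$composition, "Am_only")
  expect_equal(hom$label, "homozygous_Am")
  expect_equal(hom$phase_relation, "not_applicable")

  # all Am-Au pairs in repulsion -> heterozygous region
  ph_rep <- data.frame(locus_a = c("a1", "a1", "a2", "a2", "a1", "u1"),
                       locus_b = c("u1", "u2", "u1", "u2", "a2", "u2"),
                       phase = c("repulsion", "repulsion", "repulsion",
                                 "repulsion", "coupling", "coupling"),
                       lod = 10)
  het <- classify_subgroup(names(species), species, ph_rep, anchors)
  expect_equal(het$label, "heterozygous")
  expect_equal(het$phase_relation, "repulsion")
  expect_length(het$internal_breakpoints, 0L)

  # Am and Au fragments co-segregating in coupling -> mosaic with breakpoint
  ph_cpl <- data.frame(locus_a = c("a1", "u2"), locus_b = c("u2", "a1"),
                       phase = "coupling", lod = 10)[1, , drop = FALSE]
  mos <- classify_subgroup(c("a1", "u2"), species, ph_cpl, anchors)
  expect_equal(mos$label, "mosaic")
  expect_equal(mos$phase_relation, "coupling")
  expect_equal(mos$internal_breakpoints, (10 + 22) / 2)

  # no usable phase edge -> unresolved, no label
  weak <- data.frame(locus_a = "a1", locus_b = "u1", phase = "coupling", lod = 1)
  un <- classify_subgroup(c("a1", "u1"), species, weak, anchors)
  expect_equal(un$status, "unresolved")
  expect_true(is.na(un$label))

  # label invariant table holds on every emitted call
  for (cl in list(hom, het, mos)) {
    if (!is.na(cl$label)) {
      if (cl$label == "heterozygous") {
        expect_true(cl$composition == "mixed" && cl$phase_relation == "repulsion")
      }
      if (cl$label == "mosaic") {
        expect_true(cl$composition == "mixed" && cl$phase_relation == "coupling")
      }
      if (cl$composition == "Am_only") expect_equal(cl$label, "homozygous_Am")
      if (cl$composition == "Au_only") expect_equal(cl$label, "homozygous_Au")
    }
  }
})

test_that("founder reconstruction counts label transitions as crossovers", {
  map <- linkage_map(c("x0", "x1"), c(1, 1), c(0, 100))
  species <- c(a1 = "Am_specific", a2 = "Am_specific", u1 = "Au_specific",
               u2 = "Au_specific")
  anchors <- data.frame(fragment = names(species), group = "1",
                        position_cM = c(0, 40, 60, 100))
  # one fully monospecific group -> single segment, no events
  calls_am <- list(classify_subgroup(c("a1", "a2"), species, anchors = anchors))
  rec0 <- reconstruct_founder(calls_am, map)
  expect_equal(sum(rec0$crossover_events), 0L)
  expect_equal(nrow(rec0$painting), 1L)
  expect_equal(rec0$anchored_fraction, 0.4)

  # adjacent Am then Au intervals -> one crossover midway between them
  calls2 <- list(classify_subgroup(c("a1", "a2"), species, anchors = anchors),
                 classify_subgroup(c("u1", "u2"), species, anchors = anchors))
  rec2 <- reconstruct_founder(calls2, map)
  expect_equal(sum(rec2$crossover_events), 1L)
  expect_equal(rec2$events$position_cM, 50)
  expect_equal(rec2$anchored_fraction, 0.8)

  # contradictory overlapping labels are a hard error
  anchors3 <- data.frame(fragment = names(species), group = "1",
                         position_cM = c(0, 60, 40, 100))
  calls3 <- list(classify_subgroup(c("a1", "a2"), species, anchors = anchors3),
                 classify_subgroup(c("u1", "u2"), species, anchors = anchors3))
  expect_error(reconstruct_founder(calls3, map), "conflicting")
})

test_that("reconstruction is invariant to fragment input order", {
  map <- example_backbone_map()
  frags <- make_dominant_markers(map, spacing = 4)
  case <- sim_founder_case(17, map, frags, n_offspring = 120)
  rec_a <- reconstruct_from_population(case$pop, anchors_of(frags), map)$reconstruction
  perm <- sample(ncol(case$pop$calls))
  pop_b <- fragment_matrix(case$pop$calls[, perm], species = case$pop$species[perm])
  rec_b <- reconstruct_from_population(pop_b, anchors_of(frags), map)$reconstruction
  expect_equal(rec_a$crossover_events, rec_b$crossover_events)
  pa <- rec_a$painting[order(rec_a$painting$group, rec_a$painting$start), ]
  pb <- rec_b$painting[order(rec_b$painting$group, rec_b$painting$start), ]
  rownames(pa) <- rownames(pb) <- NULL
  expect_equal(pa, pb)
})

test_that("planted crossovers on a dense single chromosome are recovered", {
  map <- linkage_map(c("x0", "x1"), c(1, 1), c(0, 150))
  frags <- make_dominant_markers(map, spacing = 2)
  set.seed(23)
  found_case <- sim_founder_case(23, map, frags, n_offspring = 200)
  rec <- reconstruct_from_population(found_case$pop, anchors_of(frags),
                                     map)$reconstruction
  sc <- score_events(rec$events, found_case$planted)
  if (sc["planted"] > 0) {
    expect_gte(sc["recovered"] / sc["planted"], 0.8)
    expect_lte(sc["false_pos"], max(1, 0.2 * sc["planted"]))
  }
  # painting never leaves the anchored hulls
  expect_true(all(rec$painting$start >= 0 & rec$painting$end <= 150))
})
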