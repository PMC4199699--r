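# Independent oracles used across the suite. They are deliberately written
# from first principles (grid search, rasterization, exhaustive enumeration)
# and never call the code paths they check.

or_grid <- seq(0, 0.5, by = 0.001)

# dominant F2 class probabilities, derived independently: with s = (1-r)^2
# (coupling) or r^2 (repulsion), P(both absent) = s/4, each single-absent
# class (1-s)/4, both present (2+s)/4. Table order: n11, n10, n01, n00.
oracle_rf_dominant_grid <- function(counts, phase) {
  s <- if (phase == "coupling") (1 - or_grid)^2 else or_grid^2
  p11 <- (2 + s) / 4; p10 <- (1 - s) / 4; p00 <- s / 4
  ll <- counts[1, 1] * log(pmax(p11, 1e-300)) +
    (counts[1, 2] + counts[2, 1]) * log(pmax(p10, 1e-300)) +
    counts[2, 2] * log(pmax(p00, 1e-300))
  or_grid[which.max(ll)]
}

# codominant F2 class log-probabilities on the grid, computed once: with
# p = 1-r, q = r the nine class probabilities are
#   p^2/4  pq/2  q^2/4
#   pq/2  (p^2+q^2)/2  pq/2   (middle row/col swapped accordingly)
#   q^2/4  pq/2  p^2/4
.codom_logp <- local({
  p <- 1 - or_grid; q <- or_grid
  m <- cbind(p^2 / 4, p * q / 2, q^2 / 4,
             p * q / 2, (p^2 + q^2) / 2, p * q / 2,
             q^2 / 4, p * q / 2, p^2 / 4)
  log(pmax(m, 1e-300))
})

oracle_rf_codominant_grid <- function(counts) {
  # counts 3x3, rows AA/Aa/aa, cols BB/Bb/bb; as.vector is row-major here
  # because .codom_logp columns are laid out row by row
  v <- as.vector(t(counts))
  or_grid[which.max(.codom_logp %*% v)]
}

# brute-force union coverage by 0.01-cM rasterization
oracle_raster_coverage <- function(segments, group_length, step = 0.01) {
  mid <- seq(step / 2, group_length - step / 2, by = step)
  hit <- rep(FALSE, length(mid))
  for (i in seq_len(nrow(segments))) {
    hit <- hit | (mid >= segments$start[i] & mid <= segments$end[i])
  }
  sum(hit) * step
}

# plain interval-union length of a (single-group) segment table
.union_cov <- function(s) {
  if (nrow(s) == 0L) return(0)
  o <- order(s$start)
  st <- s$start[o]; en <- s$end[o]
  tot <- 0; cs <- st[1]; ce <- en[1]
  for (k in seq_along(st)[-1]) {
    if (st[k] <= ce) ce <- max(ce, en[k]) else { tot <- tot + ce - cs; cs <- st[k]; ce <- en[k] }
  }
  tot + ce - cs
}

# exhaustive maximum coverage over every subset of lines (single group)
oracle_best_coverage <- function(segments) {
  lines <- unique(segments$line_id)
  best <- 0
  for (mask in seq_len(2^length(lines)) - 1L) {
    pick <- lines[bitwAnd(mask, 2^(seq_along(lines) - 1L)) > 0L]
    s <- segments[segments$line_id %in% pick, , drop = FALSE]
    if (nrow(s) > 0L) {
      o <- order(s$start)
      st <- s$start[o]; en <- s$end[o]
      tot <- 0; cs <- st[1]; ce <- en[1]
      for (k in seq_along(st)[-1]) {
        if (st[k] <= ce) ce <- max(ce, en[k]) else { tot <- tot + ce - cs; cs <- st[k]; ce <- en[k] }
      }
      best <- max(best, tot + ce - cs)
    }
  }
  best
}

# simulate one hybrid-derived founder plus its selfed offspring population
# and the ground-truth planted breakpoints
sim_founder_case <- function(seed, map, frags, n_offspring = 200) {
  set.seed(seed)
  fam <- founder_painting(map, "Am")
  fau <- founder_painting(map, "Au")
  f1 <- combine_gametes(simulate_gamete(fam), simulate_gamete(fau), fam$bounds)
  founder <- combine_gametes(simulate_gamete(f1), simulate_gamete(f1), f1$bounds)
  planted <- do.call(rbind, lapply(names(founder$groups), function(g) {
    p <- unlist(lapply(c("h1", "h2"), function(h) {
      s <- founder$groups[[g]][[h]]
      if (length(s$start) > 1L) s$start[-1] else numeric(0)
    }))
    if (length(p)) data.frame(group = g, pos = p, stringsAsFactors = FALSE) else NULL
  }))
  offspring <- lapply(seq_len(n_offspring), function(i) {
    combine_gametes(simulate_gamete(founder), simulate_gamete(founder),
                    founder$bounds)
  })
  pop <- genotype_population(offspring, frags)$fragments
  list(founder = founder, planted = planted, pop = pop, offspring = offspring)
}

# score inferred crossover events against planted breakpoints
score_events <- function(events, planted, tol_cM = 5) {
  n_planted <- if (is.null(planted)) 0L else nrow(planted)
  recovered <- 0L
  if (n_planted > 0L) for (i in seq_len(n_planted)) {
    e <- events[events$group == planted$group[i], , drop = FALSE]
    if (nrow(e) > 0L && min(abs(e$position_cM - planted$pos[i])) <= tol_cM) {
      recovered <- recovered + 1L
    }
  }
  false_pos <- 0L
  if (nrow(events) > 0L) for (i in seq_len(nrow(events))) {
    p <- planted[planted$group == events$group[i], , drop = FALSE]
    if (is.null(p) || nrow(p) == 0L ||
        min(abs(p$pos - events$position_cM[i])) > tol_cM) {
      false_pos <- false_pos + 1L
    }
  }
  c(planted = n_planted, recovered = recovered, false_pos = false_pos)
}

# random fragment anchor table from a marker scheme
anchors_of <- function(frags) {
  data.frame(fragment = frags$name, group = frags$group,
             position_cM = frags$position_cM, stringsAsFactors = FALSE)
}

# small utility: multinomial 3x3 F2 table at a given r (independent of the
# package: uses the closed-form class probabilities above)
rand_codom_table <- function(r, n) {
  p <- 1 - r; q <- r
  probs <- c(p^2 / 4, p * q / 2, q^2 / 4,
             p * q / 2, (p^2 + q^2) / 2, p * q / 2,
             q^2 / 4, p * q / 2, p^2 / 4)
  matrix(stats::rmultinom(1, n, probs), 3, 3, byrow = TRUE)
}

rand_dom_table <- function(r, n, phase = "coupling") {
  s <- if (phase == "coupling") (1 - r)^2 else r^2
  p <- c((2 + s) / 4, (1 - s) / 4, (1 - s) / 4, s / 4)
  matrix(stats::rmultinom(1, n, p), 2, 2, byrow = TRUE)
}
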