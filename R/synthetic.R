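# Internal segment representation: list(start, end, origin) of parallel
# vectors; segments tile a group interval contiguously, adjacent segments on
# one homolog always differ in origin.

.seg <- function(start, end, origin) list(start = start, end = end, origin = origin)

.merge_seg <- function(s) {
  if (length(s$origin) <= 1L) return(s)
  keep <- c(TRUE, s$origin[-1] != s$origin[-length(s$origin)])
  run_last <- c(which(keep)[-1] - 1L, length(s$origin))
  .seg(s$start[keep], s$end[run_last], s$origin[keep])
}

.seg_extract <- function(s, a, b) {
  i <- which(s$end > a & s$start < b)
  .seg(pmax(s$start[i], a), pmin(s$end[i], b), s$origin[i])
}

.origin_at <- function(s, pos) {
  # segments tile [start1, endK]; positions on boundaries resolve rightward
  i <- findInterval(pos, s$start)
  i[i < 1L] <- 1L
  s$origin[i]
}

.map_bounds <- function(map) {
  gs <- tapply(map$position_cM, as.character(map$group), min)
  ge <- tapply(map$position_cM, as.character(map$group), max)
  list(groups = names(gs), start = gs, end = ge)
}

#' Homozygous founder chromosome painting
#'
#' Builds the painting of a pure parental genome on a map: every homolog of
#' every linkage group is a single segment of the given origin.
#'
#' @param map A [linkage_map()].
#' @param origin `"Am"` (T. monococcum) or `"Au"` (T. urartu).
#' @return An object of class `chrom_painting`: per linkage group a pair of
#'   homolog segment lists plus the group bounds in cM.
#' @export
founder_painting <- function(map, origin = c("Am", "Au")) {
  origin <- match.arg(origin)
  b <- .map_bounds(map)
  groups <- lapply(seq_along(b$groups), function(i) {
    s <- .seg(b$start[i], b$end[i], origin)
    list(h1 = s, h2 = s)
  })
  names(groups) <- b$groups
  structure(list(groups = groups, bounds = b), class = "chrom_painting")
}

#' @export
print.chrom_painting <- function(x, ...) {
  d <- diplotype(x)
  tot <- sum(x$bounds$end - x$bounds$start)
  fr <- function(st) sum(vapply(d, function(g)
    sum((g$end - g$start)[g$state == st]), numeric(1))) / max(tot, 1e-12)
  cat(sprintf("Chromosome painting: %d group(s); Am/Am %.1f%%, Au/Au %.1f%%, Het %.1f%%\n",
              length(x$groups), 100 * fr("Am"), 100 * fr("Au"), 100 * fr("Het")))
  invisible(x)
}

.validate_painting <- function(p, tol = 1e-9) {
  for (g in seq_along(p$groups)) {
    for (h in c("h1", "h2")) {
      s <- p$groups[[g]][[h]]
      if (length(s$start) == 0L) return(FALSE)
      if (abs(s$start[1] - p$bounds$start[g]) > tol) return(FALSE)
      if (abs(s$end[length(s$end)] - p$bounds$end[g]) > tol) return(FALSE)
      if (length(s$start) > 1L) {
        if (any(abs(s$start[-1] - s$end[-length(s$end)]) > tol)) return(FALSE)
        if (any(s$origin[-1] == s$origin[-length(s$origin)])) return(FALSE)
      }
    }
  }
  TRUE
}

#' Check the tiling invariant of a painting
#'
#' Segments of every homolog must tile the group interval contiguously with
#' no two adjacent segments of equal origin.
#'
#' @param p A `chrom_painting`.
#' @return `TRUE`/`FALSE`.
#' @export
painting_is_valid <- function(p) .validate_painting(p)

#' Simulate one meiotic gamete from a parental painting
#'
#' Crossover counts per linkage group are Poisson with mean group length / 100
#' (no interference); breakpoint positions are uniform on the group; the
#' gamete alternates between the two parental homologs at the breakpoints.
#' Segregation distortion is imposed by rejection sampling: a gamete carrying
#' the donor (Au) origin at a distortion region's midpoint is accepted with
#' probability equal to the stated donor transmission probability, a
#' non-carrier with the complement, so that donor transmission from a
#' heterozygous parent equals the stated probability (regions where the parent
#' is homozygous are ignored: transmission there is forced).
#'
#' @param parent A `chrom_painting`.
#' @param distortion Optional data frame with columns `group`, `start_cM`,
#'   `end_cM`, `donor_prob` (in [0, 1]).
#' @return Single-homolog painting: list per group of segment lists.
#' @export
simulate_gamete <- function(parent, distortion = NULL) {
  b <- parent$bounds
  if (!is.null(distortion)) .check_distortion(distortion, b)
  repeat {
    gam <- lapply(seq_along(b$groups), function(gi) {
      gs <- b$start[gi]; ge <- b$end[gi]
      len <- ge - gs
      k <- stats::rpois(1L, len / 100)
      pos <- if (k > 0L) sort(stats::runif(k, gs, ge)) else numeric(0)
      cuts <- c(gs, pos, ge)
      src <- if (stats::runif(1) < 0.5) c("h1", "h2") else c("h2", "h1")
      parts <- lapply(seq_len(length(cuts) - 1L), function(j) {
        .seg_extract(parent$groups[[gi]][[src[(j - 1L) %% 2L + 1L]]],
                     cuts[j], cuts[j + 1L])
      })
      .merge_seg(.seg(unlist(lapply(parts, `[[`, "start")),
                      unlist(lapply(parts, `[[`, "end")),
                      unlist(lapply(parts, `[[`, "origin"))))
    })
    names(gam) <- b$groups
    if (is.null(distortion)) return(gam)
    acc <- 1
    for (k in seq_len(nrow(distortion))) {
      gi <- match(as.character(distortion$group[k]), b$groups)
      mid <- (distortion$start_cM[k] + distortion$end_cM[k]) / 2
      o1 <- .origin_at(parent$groups[[gi]]$h1, mid)
      o2 <- .origin_at(parent$groups[[gi]]$h2, mid)
      if (o1 == o2) next  # parent homozygous here, no gametic selection
      p <- distortion$donor_prob[k]
      acc <- acc * if (.origin_at(gam[[gi]], mid) == "Au") p else 1 - p
    }
    if (stats::runif(1) < acc) return(gam)
  }
}

.check_distortion <- function(distortion, bounds) {
  need <- c("group", "start_cM", "end_cM", "donor_prob")
  if (!all(need %in% names(distortion))) {
    stop("distortion needs columns: ", paste(need, collapse = ", "))
  }
  if (any(distortion$donor_prob < 0 | distortion$donor_prob > 1)) {
    stop("donor_prob must lie in [0, 1]")
  }
  gi <- match(as.character(distortion$group), bounds$groups)
  if (any(is.na(gi))) stop("distortion region on unknown linkage group")
  bad <- distortion$start_cM < bounds$start[gi] - 1e-9 |
    distortion$end_cM > bounds$end[gi] + 1e-9 |
    distortion$start_cM > distortion$end_cM
  if (any(bad)) stop("distortion region outside map bounds")
  invisible(TRUE)
}

#' Combine two gametes into an offspring painting
#'
#' @param gamete1,gamete2 Single-homolog paintings from [simulate_gamete()].
#' @param bounds Group bounds (taken from either parent painting).
#' @return A `chrom_painting`.
#' @export
combine_gametes <- function(gamete1, gamete2, bounds) {
  groups <- lapply(seq_along(bounds$groups), function(i) {
    list(h1 = gamete1[[i]], h2 = gamete2[[i]])
  })
  names(groups) <- bounds$groups
  structure(list(groups = groups, bounds = bounds), class = "chrom_painting")
}

#' Derived diplotype segments of a painting
#'
#' Overlays the two homologs and reports maximal segments with constant state
#' `Am` (both homologs Am), `Au` (both Au) or `Het` (one each).
#'
#' @param p A `chrom_painting`.
#' @return List per group of `list(start, end, state)` vectors.
#' @export
diplotype <- function(p) {
  out <- lapply(seq_along(p$groups), function(gi) {
    h1 <- p$groups[[gi]]$h1; h2 <- p$groups[[gi]]$h2
    cuts <- sort(unique(c(h1$start, h2$start, p$bounds$end[gi])))
    a <- .origin_at(h1, cuts[-length(cuts)])
    b2 <- .origin_at(h2, cuts[-length(cuts)])
    state <- ifelse(a == b2, a, "Het")
    s <- .merge_seg(.seg(cuts[-length(cuts)], cuts[-1], state))
    list(start = s$start, end = s$end, state = s$origin)
  })
  names(out) <- p$bounds$groups
  out
}

#' Genome fractions of a painting
#'
#' `donor_fraction` is the fraction of the (diploid) genome with Au origin;
#' `het_fraction` is the fraction of the map length whose diplotype is
#' heterospecific (Am/Au).
#'
#' @param p A `chrom_painting`.
#' @return Scalar in [0, 1].
#' @export
donor_fraction <- function(p) {
  tot <- sum(p$bounds$end - p$bounds$start)
  if (tot == 0) return(0)
  au <- 0
  for (gi in seq_along(p$groups)) for (h in c("h1", "h2")) {
    s <- p$groups[[gi]][[h]]
    au <- au + sum((s$end - s$start)[s$origin == "Au"])
  }
  au / (2 * tot)
}

#' @rdname donor_fraction
#' @export
het_fraction <- function(p) {
  tot <- sum(p$bounds$end - p$bounds$start)
  if (tot == 0) return(0)
  d <- diplotype(p)
  het <- sum(vapply(d, function(g) sum((g$end - g$start)[g$state == "Het"]),
                    numeric(1)))
  het / tot
}

#' Pedigree specification for the cross simulator
#'
#' The first step must be a cross of the two founder genomes (`Am` x `Au`);
#' subsequent steps are selfing or backcross generations. Population sizes
#' are per step; within a multi-generation step each new individual descends
#' from one parent of the previous generation (cycled), emulating single-seed
#' descent.
#'
#' @param steps List of steps from [ped_cross()], [ped_self()],
#'   [ped_backcross()].
#' @param seed Optional integer seed recorded in the spec and applied by
#'   [simulate_pedigree()] (one global generator, for reproducibility).
#' @return An object of class `pedigree_spec`.
#' @export
pedigree_spec <- function(steps, seed = NULL) {
  if (length(steps) == 0L || steps[[1]]$type != "cross") {
    stop("first pedigree step must be a cross of the two founders")
  }
  sizes <- vapply(steps, function(s) s$size, numeric(1))
  if (any(sizes < 1)) stop("population sizes must be >= 1")
  structure(list(steps = steps, seed = seed), class = "pedigree_spec")
}

#' @rdname pedigree_spec
#' @param size Number of individuals produced by the step (or per generation
#'   within the step).
#' @export
ped_cross <- function(size = 1L) list(type = "cross", size = as.integer(size))

#' @rdname pedigree_spec
#' @param generations Number of successive generations within the step.
#' @export
ped_self <- function(generations = 1L, size = 1L) {
  list(type = "self", generations = as.integer(generations), size = as.integer(size))
}

#' @rdname pedigree_spec
#' @param recurrent Origin of the recurrent parent, `"Am"` or `"Au"`.
#' @export
ped_backcross <- function(recurrent = "Am", generations = 1L, size = 1L) {
  stopifnot(recurrent %in% c("Am", "Au"))
  list(type = "backcross", recurrent = recurrent,
       generations = as.integer(generations), size = as.integer(size))
}

#' Simulate a pedigree of interspecific crosses
#'
#' Runs the meiosis simulator through a pedigree: founders are fully
#' homozygous Am and Au genomes on the map; crossing, selfing and
#' backcrossing follow the spec. Identical seed and spec give identical
#' output.
#'
#' @param spec A [pedigree_spec()].
#' @param map A [linkage_map()].
#' @param distortion Optional segregation-distortion regions, see
#'   [simulate_gamete()].
#' @return List with `population` (list of `chrom_painting`) and `log`
#'   (data frame of executed steps).
#' @export
simulate_pedigree <- function(spec, map, distortion = NULL) {
  stopifnot(inherits(spec, "pedigree_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  founder_am <- founder_painting(map, "Am")
  founder_au <- founder_painting(map, "Au")
  bounds <- founder_am$bounds
  pop <- NULL
  log <- list()
  gen_label <- "founders"
  for (st in spec$steps) {
    if (st$type == "cross") {
      pop <- lapply(seq_len(st$size), function(i) {
        combine_gametes(simulate_gamete(founder_am, distortion),
                        simulate_gamete(founder_au, distortion), bounds)
      })
      gen_label <- "F1"
      log[[length(log) + 1L]] <- data.frame(step = "cross", generation = gen_label,
                                            size = st$size)
    } else if (st$type == "self") {
      for (g in seq_len(st$generations)) {
        pop <- lapply(seq_len(st$size), function(i) {
          par <- pop[[(i - 1L) %% length(pop) + 1L]]
          combine_gametes(simulate_gamete(par, distortion),
                          simulate_gamete(par, distortion), bounds)
        })
        gen_label <- if (grepl("^F[0-9]+$", gen_label)) {
          sprintf("F%d", as.integer(sub("F", "", gen_label)) + 1L)
        } else paste0(gen_label, "S1")
        log[[length(log) + 1L]] <- data.frame(step = "self", generation = gen_label,
                                              size = st$size)
      }
    } else if (st$type == "backcross") {
      rec <- if (st$recurrent == "Am") founder_am else founder_au
      for (g in seq_len(st$generations)) {
        pop <- lapply(seq_len(st$size), function(i) {
          par <- pop[[(i - 1L) %% length(pop) + 1L]]
          combine_gametes(simulate_gamete(par, distortion),
                          simulate_gamete(rec, distortion), bounds)
        })
        gen_label <- if (grepl("^BC[0-9]+$", gen_label)) {
          sprintf("BC%d", as.integer(sub("BC", "", gen_label)) + 1L)
        } else "BC1"
        log[[length(log) + 1L]] <- data.frame(step = "backcross",
                                              generation = gen_label, size = st$size)
      }
    } else stop("unknown pedigree step type: ", st$type)
  }
  list(population = pop, log = do.call(rbind, log))
}

#' Marker schemes for genotyping simulated paintings
#'
#' `make_dominant_markers` lays dominant (AFLP-type) fragments on a regular
#' grid along every linkage group, alternating Am- and Au-specific fragments
#' so that both species are informative everywhere; `make_codominant_markers`
#' turns the map loci themselves into codominant SSR-type markers.
#'
#' @param map A [linkage_map()].
#' @param spacing Fragment spacing in cM.
#' @return Data frame with columns `name`, `group`, `position_cM`, `system`
#'   and (dominant only) `species`.
#' @export
make_dominant_markers <- function(map, spacing = 2) {
  b <- .map_bounds(map)
  out <- list()
  for (gi in seq_along(b$groups)) {
    pos <- unique(c(seq(b$start[gi], b$end[gi], by = spacing), b$end[gi]))
    out[[gi]] <- data.frame(
      name = sprintf("frag_%s_%03d", b$groups[gi], seq_along(pos)),
      group = b$groups[gi], position_cM = pos,
      system = "dominant",
      species = rep(c("Am_specific", "Au_specific"), length.out = length(pos)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @rdname make_dominant_markers
#' @export
make_codominant_markers <- function(map) {
  data.frame(name = map$locus, group = map$group,
             position_cM = map$position_cM, system = "codominant",
             stringsAsFactors = FALSE)
}

#' Genotype a painting at marker positions
#'
#' Codominant loci report `RR` (Am/Am), `DD` (Au/Au) or `RD`; a dominant
#' Am-specific fragment is present iff at least one homolog has Am origin at
#' its position (symmetrically for Au-specific) — the heterozygote is
#' indistinguishable from the presence homozygote, the defining property of
#' AFLP scoring; `shared` fragments are always present. Calls are perturbed
#' independently with probability `error_rate` (dominant calls flip;
#' codominant calls move to one of the other two states).
#'
#' @param p A `chrom_painting`.
#' @param markers Marker data frame, see [make_dominant_markers()].
#' @param error_rate Miscall probability in [0, 0.5).
#' @return Named character vector of calls (`"1"`/`"0"` for dominant,
#'   `"RR"`/`"DD"`/`"RD"` for codominant).
#' @export
genotype_from_painting <- function(p, markers, error_rate = 0) {
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  b <- p$bounds
  gi <- match(as.character(markers$group), b$groups)
  if (any(is.na(gi))) stop("marker on unknown linkage group")
  off <- markers$position_cM < b$start[gi] - 1e-9 |
    markers$position_cM > b$end[gi] + 1e-9
  if (any(off)) stop("marker position outside its linkage group")
  calls <- character(nrow(markers))
  for (g in unique(gi)) {
    i <- which(gi == g)
    o1 <- .origin_at(p$groups[[g]]$h1, markers$position_cM[i])
    o2 <- .origin_at(p$groups[[g]]$h2, markers$position_cM[i])
    dom <- markers$system[i] == "dominant"
    if (any(dom)) {
      sp <- markers$species[i][dom]
      present <- ifelse(sp == "Am_specific", o1[dom] == "Am" | o2[dom] == "Am",
                 ifelse(sp == "Au_specific", o1[dom] == "Au" | o2[dom] == "Au",
                        TRUE))
      calls[i[dom]] <- ifelse(present, "1", "0")
    }
    if (any(!dom)) {
      calls[i[!dom]] <- ifelse(o1[!dom] == o2[!dom],
                               ifelse(o1[!dom] == "Am", "RR", "DD"), "RD")
    }
  }
  if (error_rate > 0) {
    flip <- stats::runif(length(calls)) < error_rate
    if (any(flip)) {
      dom <- markers$system == "dominant"
      fd <- flip & dom
      calls[fd] <- ifelse(calls[fd] == "1", "0", "1")
      fc <- which(flip & !dom)
      for (j in fc) calls[j] <- sample(setdiff(c("RR", "DD", "RD"), calls[j]), 1L)
    }
  }
  names(calls) <- markers$name
  calls
}

#' Genotype a whole population
#'
#' @param population List of `chrom_painting` (e.g. from
#'   [simulate_pedigree()]).
#' @param markers Marker data frame; dominant and codominant markers may be
#'   mixed.
#' @param error_rate Miscall probability.
#' @param line_ids Optional line identifiers.
#' @return List with `fragments` (a [fragment_matrix()] carrying the marker
#'   species labels) and/or `ssr` (an [ssr_matrix()]); absent components are
#'   `NULL`.
#' @export
genotype_population <- function(population, markers, error_rate = 0,
                                line_ids = NULL) {
  if (is.null(line_ids)) line_ids <- sprintf("L%04d", seq_along(population))
  calls <- t(vapply(population, genotype_from_painting, character(nrow(markers)),
                    markers = markers, error_rate = error_rate))
  rownames(calls) <- line_ids
  colnames(calls) <- markers$name
  dom <- markers$system == "dominant"
  out <- list(fragments = NULL, ssr = NULL)
  if (any(dom)) {
    fm <- matrix(as.integer(calls[, dom, drop = FALSE]), nrow(calls), sum(dom),
                 dimnames = list(line_ids, markers$name[dom]))
    out$fragments <- fragment_matrix(fm, species = markers$species[dom])
  }
  if (any(!dom)) out$ssr <- ssr_matrix(calls[, !dom, drop = FALSE])
  out
}

#' Simulate seed set of a plant
#'
#' A stand-in fertility model for generating test data (the underlying
#' biology is not modelled): expected fertility is
#' `clamp(baseline - penalty * het_fraction, 0, 1)` where `het_fraction` is
#' the heterospecific (Am/Au) fraction of the genome; seeds are drawn
#' binomially from the available florets.
#'
#' @param p A `chrom_painting`.
#' @param baseline Baseline fertility in [0, 1].
#' @param penalty Fertility penalty per unit heterospecific genome fraction.
#' @param n_spikelets Number of spikelets scored.
#' @param florets_per_spikelet Florets per spikelet (default 2).
#' @return One-row data frame: `n_spikelets`, `n_seeds`,
#'   `florets_per_spikelet`, `expected_fertility`.
#' @export
simulate_fertility <- function(p, baseline, penalty, n_spikelets,
                               florets_per_spikelet = 2L) {
  if (baseline < 0 || baseline > 1) stop("baseline must be in [0, 1]")
  f <- min(max(baseline - penalty * het_fraction(p), 0), 1)
  seeds <- stats::rbinom(1L, n_spikelets * florets_per_spikelet, f)
  data.frame(n_spikelets = n_spikelets, n_seeds = seeds,
             florets_per_spikelet = florets_per_spikelet,
             expected_fertility = f)
}
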