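#' Assign species specificity of dominant fragments from reference parents
#'
#' A fragment is `Am_specific` when present in at least one T. monococcum
#' reference line and absent in every T. urartu reference (and symmetrically
#' `Au_specific`); present in both species it is `shared`; with no presence
#' observed (or no non-missing reference call) it is `unassigned`.
#'
#' @param parents A [fragment_matrix()] of reference-parent profiles.
#' @param am_lines,au_lines Row ids of the Am and Au reference lines.
#' @return Named character vector of labels, one per fragment.
#' @export
assign_fragment_species <- function(parents, am_lines, au_lines) {
  stopifnot(inherits(parents, "fragment_matrix"))
  x <- parents$calls
  if (!all(c(am_lines, au_lines) %in% rownames(x))) {
    stop("reference line(s) not present in the parent profiles")
  }
  if (length(am_lines) == 0L || length(au_lines) == 0L) {
    stop("at least one reference parent per species is required")
  }
  pres_am <- colSums(x[am_lines, , drop = FALSE] == 1L, na.rm = TRUE) > 0L
  pres_au <- colSums(x[au_lines, , drop = FALSE] == 1L, na.rm = TRUE) > 0L
  lab <- rep("unassigned", ncol(x))
  lab[pres_am & !pres_au] <- "Am_specific"
  lab[pres_au & !pres_am] <- "Au_specific"
  lab[pres_am & pres_au] <- "shared"
  names(lab) <- colnames(x)
  lab
}

#' Anchor table from a fragment-to-backbone-locus mapping
#'
#' @param mapping Named character vector: fragment name -> backbone locus
#'   name.
#' @param backbone A [linkage_map()].
#' @return Data frame with columns `fragment`, `group`, `position_cM`.
#' @export
anchors_from_map <- function(mapping, backbone) {
  i <- match(unname(mapping), backbone$locus)
  if (any(is.na(i))) {
    stop("unknown backbone locus: ",
         paste(unique(mapping[is.na(i)]), collapse = ", "))
  }
  data.frame(fragment = names(mapping), group = backbone$group[i],
             position_cM = backbone$position_cM[i], stringsAsFactors = FALSE)
}

#' Anchor a fragment subgroup to the backbone map
#'
#' The anchor is the smallest closed interval on one linkage group containing
#' every anchored member. Members anchoring to two or more groups flag a
#' conflict (the duplicated-chromosome-block situation), and the subgroup is
#' reported unanchored-with-conflict rather than silently dropped.
#'
#' @param members Character vector of fragment names.
#' @param anchors Data frame `fragment`, `group`, `position_cM` (see
#'   [anchors_from_map()]); fragments absent from it are unanchored.
#' @return List with `status` (`"anchored"`, `"unanchored"`, `"conflict"`),
#'   and for anchored subgroups `group`, `start`, `end`.
#' @export
anchor_subgroup <- function(members, anchors) {
  a <- anchors[anchors$fragment %in% members, , drop = FALSE]
  if (nrow(a) == 0L) return(list(status = "unanchored"))
  gs <- unique(as.character(a$group))
  if (length(gs) > 1L) {
    return(list(status = "conflict", groups = gs))
  }
  list(status = "anchored", group = gs,
       start = min(a$position_cM), end = max(a$position_cM))
}

# Two-colour the phase graph: coupling edge => same haplotype side,
# repulsion edge => opposite sides. Returns per-member side (1/2, NA if the
# member is outside the largest coloured component) plus conflict flags.
.phase_colouring <- function(members, phases) {
  n <- length(members)
  side <- rep(NA_integer_, n)
  names(side) <- members
  adj <- lapply(members, function(m) integer(0))
  names(adj) <- members
  rel <- list()
  for (k in seq_len(nrow(phases))) {
    a <- phases$locus_a[k]; b <- phases$locus_b[k]
    adj[[a]] <- c(adj[[a]], match(b, members))
    adj[[b]] <- c(adj[[b]], match(a, members))
    rel[[paste(a, b)]] <- phases$phase[k]
    rel[[paste(b, a)]] <- phases$phase[k]
  }
  conflict <- FALSE
  comp_id <- rep(NA_integer_, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp_id[s])) next
    comp <- comp + 1L
    comp_id[s] <- comp
    side[s] <- 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[members[v]]]) {
        want <- if (rel[[paste(members[v], members[w])]] == "coupling") {
          side[v]
        } else 3L - side[v]
        if (is.na(side[w])) {
          side[w] <- want
          comp_id[w] <- comp
          queue <- c(queue, w)
        } else if (side[w] != want) conflict <- TRUE
      }
    }
  }
  list(side = side, component = comp_id, conflict = conflict,
       n_components = comp)
}

#' Classify a linkage subgroup of segregating fragments
#'
#' Implements the two-case rule for subgroups that mix Am- and Au-specific
#' fragments: all Am-Au pairs in repulsion means the two species' fragments
#' sit on opposite homologs of the founder, so the region is heterozygous;
#' coupling between Am and Au fragments means they co-segregate on one
#' homolog, the signature of an interspecific crossing-over (a mosaic
#' chromosome). Larger subgroups are handled by two-colouring the pairwise
#' phase graph into the two haplotype sides and counting species transitions
#' along the anchored order of each side; every transition is an internal
#' breakpoint placed midway between the flanking fragments. Single-species
#' subgroups are labelled homozygous for that species.
#'
#' @param members Character vector of fragment names.
#' @param species Named character vector of fragment species labels.
#' @param phases Data frame of pairwise phase estimates with columns
#'   `locus_a`, `locus_b`, `phase`, `lod` (e.g. [rf_table()] rows).
#' @param anchors Anchor table, see [anchor_subgroup()].
#' @param min_lod Minimum LOD for a phase edge to be used; a mixed subgroup
#'   with no qualifying Am-Au edge is reported unresolved.
#' @return An object of class `subgroup_call`: list with `members`,
#'   `composition` (`Am_only`/`Au_only`/`mixed`), `phase_relation`
#'   (`coupling`/`repulsion`/`not_applicable`), `label` (`homozygous_Am`,
#'   `homozygous_Au`, `heterozygous`, `mosaic`, or `NA` when unresolved),
#'   `anchor`, `internal_breakpoints` (cM positions), `status` and `flags`.
#' @export
classify_subgroup <- function(members, species, phases = NULL, anchors = NULL,
                              min_lod = 3.0) {
  sp <- species[members]
  am <- members[!is.na(sp) & sp == "Am_specific"]
  au <- members[!is.na(sp) & sp == "Au_specific"]
  anchor <- if (is.null(anchors)) list(status = "unanchored") else
    anchor_subgroup(members, anchors)
  flags <- list(phase_conflict = FALSE, multi_component = FALSE)
  mk <- function(composition, phase_relation, label, status = "ok",
                 breakpoints = numeric(0)) {
    structure(list(members = members, composition = composition,
                   phase_relation = phase_relation, label = label,
                   anchor = anchor, internal_breakpoints = breakpoints,
                   status = status, flags = flags),
              class = "subgroup_call")
  }
  if (length(am) > 0L && length(au) == 0L) {
    return(mk("Am_only", "not_applicable", "homozygous_Am"))
  }
  if (length(au) > 0L && length(am) == 0L) {
    return(mk("Au_only", "not_applicable", "homozygous_Au"))
  }
  if (length(am) == 0L && length(au) == 0L) {
    return(mk("mixed", "not_applicable", NA_character_, status = "unresolved"))
  }
  # mixed subgroup: need phase evidence
  if (is.null(phases)) {
    return(mk("mixed", "not_applicable", NA_character_, status = "unresolved"))
  }
  ph <- phases[phases$locus_a %in% members & phases$locus_b %in% members &
                 phases$phase %in% c("coupling", "repulsion") &
                 phases$lod >= min_lod, , drop = FALSE]
  cross_edge <- (ph$locus_a %in% am & ph$locus_b %in% au) |
    (ph$locus_a %in% au & ph$locus_b %in% am)
  if (!any(cross_edge)) {
    return(mk("mixed", "not_applicable", NA_character_, status = "unresolved"))
  }
  informative <- c(am, au)
  ph <- ph[ph$locus_a %in% informative & ph$locus_b %in% informative, , drop = FALSE]
  col <- .phase_colouring(informative, ph)
  flags$phase_conflict <- col$conflict
  if (col$n_components > 1L) {
    flags$multi_component <- TRUE
    main <- which.max(tabulate(col$component))
    informative <- informative[col$component == main]
    col$side <- col$side[informative]
  }
  pos <- anchors$position_cM[match(informative, anchors$fragment)]
  breakpoints <- numeric(0)
  for (s in 1:2) {
    on_side <- informative[!is.na(col$side[informative]) &
                             col$side[informative] == s & !is.na(pos[match(informative, informative)])]
    p <- anchors$position_cM[match(on_side, anchors$fragment)]
    keep <- !is.na(p)
    on_side <- on_side[keep]; p <- p[keep]
    o <- order(p)
    on_side <- on_side[o]; p <- p[o]
    spp <- species[on_side]
    if (length(spp) > 1L) {
      tr <- which(spp[-1] != spp[-length(spp)])
      breakpoints <- c(breakpoints, (p[tr] + p[tr + 1L]) / 2)
    }
  }
  if (length(breakpoints) > 0L) {
    mk2 <- mk("mixed", "coupling", "mosaic", breakpoints = sort(breakpoints))
    mk2$flags <- flags
    return(mk2)
  }
  mk2 <- mk("mixed", "repulsion", "heterozygous")
  mk2$flags <- flags
  mk2
}

#' @export
print.subgroup_call <- function(x, ...) {
  anc <- if (x$anchor$status == "anchored") {
    sprintf("LG%s %.1f-%.1f cM", x$anchor$group, x$anchor$start, x$anchor$end)
  } else x$anchor$status
  cat(sprintf("Subgroup (%d fragments): %s, %s [%s]%s\n",
              length(x$members), x$composition,
              ifelse(is.na(x$label), "unresolved", x$label), anc,
              if (length(x$internal_breakpoints)) {
                sprintf(", %d internal breakpoint(s)", length(x$internal_breakpoints))
              } else ""))
  invisible(x)
}

#' Call founder subgroups from a segregating dominant-marker population
#'
#' The full inference driver for one hybrid-derived founder genotyped through
#' a selfed offspring population:
#' monomorphic-present fragments mark regions where the founder is homozygous
#' for the fragment's species, and maximal runs of them along the backbone
#' become homozygous subgroup calls; segregating fragments are paired within
#' a map window, their recombination fraction and phase estimated
#' ([estimate_rf_dominant()]), joined into linkage subgroups
#' ([group_loci()]) and classified by the repulsion/coupling rule
#' ([classify_subgroup()]).
#'
#' @param pop A [fragment_matrix()] of the offspring population whose
#'   `species` labels are set (see [assign_fragment_species()]).
#' @param anchors Anchor table (`fragment`, `group`, `position_cM`).
#' @param mono_threshold Presence fraction at or above which (or at or below
#'   whose complement) a fragment is treated as monomorphic.
#' @param rf_window Only anchored fragment pairs within this many cM are
#'   tested for linkage (plus all pairs involving unanchored fragments).
#' @param rf_start,rf_step,rf_threshold,min_lod Grouping schedule passed to
#'   [group_loci()]; `rf_threshold` is the final (strictest) threshold whose
#'   groups are classified.
#' @return List of `subgroup_call` objects.
#' @export
call_subgroups <- function(pop, anchors, mono_threshold = 0.98,
                           rf_window = 15, rf_start = 0.25, rf_step = 0.05,
                           rf_threshold = 0.05, min_lod = 3.0) {
  stopifnot(inherits(pop, "fragment_matrix"))
  x <- pop$calls
  species <- pop$species
  frac <- colMeans(x == 1L, na.rm = TRUE)
  scored <- colSums(!is.na(x)) > 0L
  informative <- scored & species[colnames(x)] %in% c("Am_specific", "Au_specific")
  mono_pres <- informative & !is.na(frac) & frac >= mono_threshold
  segregating <- informative & !is.na(frac) &
    frac < mono_threshold & frac > 1 - mono_threshold
  calls <- list()

  ## homozygous runs from monomorphic-present fragments; segregating
  ## stretches between them are recorded so that linkage subgroups can be
  ## refined by backbone contiguity (a subgroup must sit in one map interval)
  amap <- anchors[anchors$fragment %in% colnames(x)[mono_pres | segregating], ,
                  drop = FALSE]
  stretch <- stats::setNames(rep(NA_character_, sum(segregating)),
                             colnames(x)[segregating])
  for (g in unique(as.character(amap$group))) {
    ag <- amap[as.character(amap$group) == g, , drop = FALSE]
    ag <- ag[order(ag$position_cM), , drop = FALSE]
    state <- ifelse(mono_pres[ag$fragment], species[ag$fragment], "segregating")
    run_id <- cumsum(c(TRUE, state[-1] != state[-length(state)]))
    for (r in unique(run_id)) {
      i <- which(run_id == r)
      if (state[i[1]] == "segregating") {
        stretch[ag$fragment[i]] <- sprintf("%s_%d", g, r)
        next
      }
      calls[[length(calls) + 1L]] <-
        classify_subgroup(ag$fragment[i], species, phases = NULL,
                          anchors = anchors, min_lod = min_lod)
    }
  }

  ## linkage subgroups from segregating fragments
  seg_names <- colnames(x)[segregating]
  if (length(seg_names) >= 1L) {
    pairs <- .candidate_pairs(seg_names, anchors, rf_window)
    ests <- vector("list", nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$a[k]; b <- pairs$b[k]
      tab <- .presence_table(x[, a], x[, b])
      if (sum(tab) < 1) next
      ests[[k]] <- estimate_rf_dominant(tab, phase = "unknown",
                                        locus_a = a, locus_b = b)
    }
    ests <- ests[!vapply(ests, is.null, logical(1))]
    if (length(ests) > 0L) {
      tab <- rf_table(ests)
      grouping <- group_loci(tab, markers = seg_names, rf_start = rf_start,
                             rf_end = rf_threshold, rf_step = rf_step,
                             min_lod = min_lod)
      for (grp in final_groups(grouping)) {
        # refine by backbone contiguity: a subgroup interrupted by a
        # monomorphic run (or spanning several map stretches) is split into
        # its per-stretch pieces; unanchored members stay one piece
        key <- stretch[grp]
        key[is.na(key)] <- "unanchored"
        for (piece in split(grp, key)) {
          cl <- classify_subgroup(piece, species, phases = tab,
                                  anchors = anchors, min_lod = min_lod)
          # these fragments segregate, so the founder is heterozygous at
          # their sites; a single-species piece has no cross-species phase
          # partner to localise the second haplotype and stays unresolved
          # rather than being painted with its composition label
          if (cl$composition %in% c("Am_only", "Au_only")) {
            cl$label <- NA_character_
            cl$status <- "unresolved"
          }
          calls[[length(calls) + 1L]] <- cl
        }
      }
    } else {
      for (s in seg_names) {
        calls[[length(calls) + 1L]] <-
          classify_subgroup(s, species, phases = NULL, anchors = anchors,
                            min_lod = min_lod)
      }
    }
  }
  calls
}

.presence_table <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  matrix(c(sum(a == 1L & b == 1L), sum(a == 1L & b == 0L),
           sum(a == 0L & b == 1L), sum(a == 0L & b == 0L)),
         2, 2, byrow = TRUE)
}

.candidate_pairs <- function(frags, anchors, window) {
  i <- match(frags, anchors$fragment)
  grp <- as.character(anchors$group[i])
  pos <- anchors$position_cM[i]
  anch <- !is.na(i)
  out <- list()
  # anchored pairs on the same group within the window
  for (g in unique(grp[anch])) {
    j <- which(anch & grp == g)
    j <- j[order(pos[j])]
    for (u in seq_along(j)) {
      v <- u + 1L
      while (v <= length(j) && pos[j[v]] - pos[j[u]] <= window) {
        out[[length(out) + 1L]] <- c(frags[j[u]], frags[j[v]])
        v <- v + 1L
      }
    }
  }
  # unanchored fragments are paired with everything
  una <- which(!anch)
  for (u in una) {
    for (v in seq_along(frags)) {
      if (v != u && (v > u || anch[v])) {
        out[[length(out) + 1L]] <- c(frags[u], frags[v])
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(a = character(0), b = character(0)))
  }
  m <- do.call(rbind, out)
  data.frame(a = m[, 1], b = m[, 2], stringsAsFactors = FALSE)
}

#' Reconstruct a founder's chromosome contribution from subgroup calls
#'
#' Paints each linkage group with the anchored subgroup intervals in map
#' order and counts crossover events: one event between each pair of adjacent
#' anchored intervals with different labels (placed midway between the facing
#' interval ends, mirroring breakpoints drawn between bordering
#' polymorphisms), plus the internal breakpoints of mosaic subgroups.
#' Unresolved or unanchored subgroups are not painted; gaps are excluded from
#' all counts.
#'
#' @param calls List of `subgroup_call` objects (see [call_subgroups()]).
#' @param backbone A [linkage_map()].
#' @return An object of class `founder_reconstruction`: list with `painting`
#'   (data frame `group`, `start`, `end`, `label`), `events` (data frame
#'   `group`, `position_cM`, `type`), `crossover_events` (named per-group
#'   counts), `anchored_fraction`.
#' @export
reconstruct_founder <- function(calls, backbone) {
  painted <- list()
  for (cl in calls) {
    if (cl$status != "ok" || is.na(cl$label)) next
    if (cl$anchor$status != "anchored") next
    painted[[length(painted) + 1L]] <-
      data.frame(group = cl$anchor$group, start = cl$anchor$start,
                 end = cl$anchor$end, label = cl$label,
                 n_internal = length(cl$internal_breakpoints),
                 stringsAsFactors = FALSE)
    attr(painted[[length(painted)]], "breaks") <- cl$internal_breakpoints
  }
  gl <- map_group_lengths(backbone)
  total <- sum(gl)
  groups <- names(gl)
  if (length(painted) == 0L) {
    return(structure(list(
      painting = data.frame(group = character(0), start = numeric(0),
                            end = numeric(0), label = character(0)),
      events = data.frame(group = character(0), position_cM = numeric(0),
                          type = character(0)),
      crossover_events = stats::setNames(rep(0L, length(groups)), groups),
      anchored_fraction = 0), class = "founder_reconstruction"))
  }
  internal <- do.call(rbind, lapply(painted, function(p) {
    br <- attr(p, "breaks")
    if (length(br) == 0L) return(NULL)
    data.frame(group = p$group, position_cM = br, type = "mosaic_internal",
               stringsAsFactors = FALSE)
  }))
  pf <- do.call(rbind, painted)
  pf <- pf[order(pf$group, pf$start, pf$end), , drop = FALSE]
  rownames(pf) <- NULL
  events <- list()
  for (g in unique(pf$group)) {
    pg <- pf[pf$group == g, , drop = FALSE]
    if (nrow(pg) > 1L) {
      ov <- which(pg$start[-1] < pg$end[-nrow(pg)] - 1e-9)
      bad <- ov[pg$label[ov] != pg$label[ov + 1L]]
      if (length(bad) > 0L) {
        stop(sprintf(
          "conflicting overlapping intervals on group %s: [%s]", g,
          paste(sprintf("%.1f-%.1f %s", pg$start[c(bad, bad + 1L)],
                        pg$end[c(bad, bad + 1L)], pg$label[c(bad, bad + 1L)]),
                collapse = "; ")))
      }
      for (i in seq_len(nrow(pg) - 1L)) {
        if (pg$label[i] != pg$label[i + 1L]) {
          events[[length(events) + 1L]] <-
            data.frame(group = g,
                       position_cM = (pg$end[i] + pg$start[i + 1L]) / 2,
                       type = "boundary", stringsAsFactors = FALSE)
        }
      }
    }
  }
  events <- rbind(do.call(rbind, events), internal)
  if (is.null(events)) {
    events <- data.frame(group = character(0), position_cM = numeric(0),
                         type = character(0))
  }
  events <- events[order(events$group, events$position_cM), , drop = FALSE]
  rownames(events) <- NULL
  counts <- stats::setNames(rep(0L, length(groups)), groups)
  if (nrow(events) > 0L) {
    tb <- table(factor(events$group, levels = groups))
    counts[names(tb)] <- as.integer(tb)
  }
  painted_len <- sum(vapply(unique(pf$group), function(g) {
    pg <- pf[pf$group == g, , drop = FALSE]
    .union_length(pg$start, pg$end)
  }, numeric(1)))
  structure(list(painting = pf[, c("group", "start", "end", "label")],
                 events = events, crossover_events = counts,
                 anchored_fraction = painted_len / total),
            class = "founder_reconstruction")
}

#' @export
print.founder_reconstruction <- function(x, ...) {
  cat(sprintf("Founder reconstruction: %d painted interval(s), %d crossover event(s), %.1f%% of map anchored\n",
              nrow(x$painting), sum(x$crossover_events),
              100 * x$anchored_fraction))
  print(x$crossover_events)
  invisible(x)
}

#' One-call mosaic reconstruction from population and parent profiles
#'
#' Convenience wrapper: assigns fragment species from the reference parents
#' (when given), calls subgroups and reconstructs the founder painting.
#'
#' @param pop Offspring [fragment_matrix()].
#' @param anchors Anchor table (`fragment`, `group`, `position_cM`).
#' @param backbone A [linkage_map()].
#' @param parents Optional reference-parent [fragment_matrix()].
#' @param am_lines,au_lines Reference line ids (required with `parents`).
#' @param ... Passed to [call_subgroups()].
#' @return List with `calls` and `reconstruction`.
#' @export
reconstruct_from_population <- function(pop, anchors, backbone,
                                        parents = NULL, am_lines = NULL,
                                        au_lines = NULL, ...) {
  if (!is.null(parents)) {
    pop <- fragment_matrix(pop$calls,
                           species = assign_fragment_species(parents, am_lines, au_lines))
  }
  calls <- call_subgroups(pop, anchors, ...)
  list(calls = calls, reconstruction = reconstruct_founder(calls, backbone))
}
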