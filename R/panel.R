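# length of the union of closed intervals [start_i, end_i]
.union_length <- function(start, end) {
  if (length(start) == 0L) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      tot <- tot + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  tot + (cur_e - cur_s)
}

#' Call donor segments of introgression lines from SSR fingerprints
#'
#' Maximal runs of consecutive donor calls (`DD` or `RD`) along each linkage
#' group become segments; a run's boundary is placed midway between its
#' outermost donor locus and the nearest flanking `RR` locus (segments are
#' reported only at marker resolution, so the midpoint is the natural
#' convention); terminal runs extend to the group end. Missing calls bridge a
#' run up to `max_gap_cM` of missing span, beyond which the run splits.
#' Runs of `DD` and `RD` are reported as separate segments with their
#' zygosity.
#'
#' @param m An [ssr_matrix()] (or a named character vector of calls for a
#'   single line).
#' @param map A [linkage_map()] carrying the genotyped loci.
#' @param max_gap_cM Maximum missing-data span bridged within a run.
#' @param line_id Line id used when `m` is a bare call vector.
#' @return Data frame with columns `line_id`, `group`, `start`, `end`,
#'   `zygosity` (`homozygous_donor` or `heterozygous`). Groups with no
#'   non-missing call for a line are reported in the `"uncalled"` attribute.
#' @export
call_donor_segments <- function(m, map, max_gap_cM = 20, line_id = "line1") {
  if (inherits(m, "ssr_matrix")) {
    calls <- m$calls
  } else {
    calls <- matrix(m, 1L, length(m), dimnames = list(line_id, names(m)))
  }
  loci <- intersect(colnames(calls), map$locus)
  if (length(loci) == 0L) stop("no genotyped locus is on the map")
  mi <- match(loci, map$locus)
  grp <- as.character(map$group[mi])
  pos <- map$position_cM[mi]
  b <- .map_bounds(map)
  out <- list()
  uncalled <- list()
  for (ln in rownames(calls)) {
    for (g in unique(grp)) {
      sel <- which(grp == g)
      sel <- sel[order(pos[sel])]
      cl <- calls[ln, loci[sel]]
      p <- pos[sel]
      if (all(is.na(cl))) {
        uncalled[[length(uncalled) + 1L]] <- data.frame(line_id = ln, group = g)
        next
      }
      segs <- .donor_runs(cl, p, max_gap_cM,
                          b$start[match(g, b$groups)], b$end[match(g, b$groups)])
      if (nrow(segs) > 0L) {
        out[[length(out) + 1L]] <- cbind(data.frame(line_id = ln, group = g,
                                                    stringsAsFactors = FALSE),
                                         segs)
      }
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(line_id = character(0), group = character(0),
               start = numeric(0), end = numeric(0), zygosity = character(0))
  rownames(res) <- NULL
  attr(res, "uncalled") <- if (length(uncalled)) do.call(rbind, uncalled) else NULL
  res
}

# donor runs within one group; cl = calls sorted by position p
.donor_runs <- function(cl, p, max_gap_cM, gstart, gend) {
  known <- !is.na(cl)
  kp <- p[known]; kc <- cl[known]
  if (length(kc) == 0L) return(data.frame())
  donor <- kc %in% c("DD", "RD")
  # run ids over donor loci: split when zygosity changes, an RR intervenes
  # (handled by donor FALSE) or the gap between consecutive donor loci
  # exceeds max_gap_cM
  segs <- list()
  i <- 1L
  while (i <= length(kc)) {
    if (!donor[i]) { i <- i + 1L; next }
    j <- i
    while (j + 1L <= length(kc) && donor[j + 1L] && kc[j + 1L] == kc[i] &&
           kp[j + 1L] - kp[j] <= max_gap_cM) j <- j + 1L
    # boundaries: midpoint to nearest flanking non-donor (RR) or different-
    # zygosity donor locus; terminal runs extend to the group ends
    left <- if (i == 1L) gstart else (kp[i - 1L] + kp[i]) / 2
    right <- if (j == length(kc)) gend else (kp[j] + kp[j + 1L]) / 2
    segs[[length(segs) + 1L]] <-
      data.frame(start = left, end = right,
                 zygosity = if (kc[i] == "DD") "homozygous_donor" else "heterozygous",
                 stringsAsFactors = FALSE)
    i <- j + 1L
  }
  if (length(segs) == 0L) return(data.frame())
  do.call(rbind, segs)
}

#' Select a nonredundant introgression-line panel
#'
#' Greedy maximum-coverage selection: lines are added in order of the new map
#' length (cM) their donor segments contribute, until no remaining line adds
#' more than `min_gain` cM. A line whose segments are fully contained in the
#' selected union (zero gain) is never added. Ties are broken by
#' lexicographic line id, making the selection deterministic.
#'
#' @param segments Data frame of called segments (see
#'   [call_donor_segments()]).
#' @param single_fragment_only If `TRUE`, lines carrying two or more segments
#'   are excluded before selection (the single-introgression panel design).
#' @param min_gain Minimum coverage gain (cM) for adding a line; the default
#'   1 cM suppresses sub-resolution slivers.
#' @return Character vector of selected line ids (in selection order), with
#'   the selected segments in attribute `"segments"`.
#' @export
select_nonredundant <- function(segments, single_fragment_only = FALSE,
                                min_gain = 1) {
  if (nrow(segments) == 0L) {
    out <- character(0); attr(out, "segments") <- segments; return(out)
  }
  if (single_fragment_only) {
    nseg <- table(segments$line_id)
    keep <- names(nseg)[nseg == 1L]
    segments <- segments[segments$line_id %in% keep, , drop = FALSE]
  }
  lines <- sort(unique(segments$line_id))
  covered <- list()  # per group: matrix of selected intervals
  cov_len <- function(extra = NULL) {
    gs <- unique(c(names(covered), if (!is.null(extra)) extra$group))
    sum(vapply(gs, function(g) {
      s <- covered[[g]]
      st <- c(if (!is.null(s)) s$start, extra$start[extra$group == g])
      en <- c(if (!is.null(s)) s$end, extra$end[extra$group == g])
      .union_length(st, en)
    }, numeric(1)))
  }
  selected <- character(0)
  base_len <- 0
  remaining <- lines
  while (length(remaining) > 0L) {
    gains <- vapply(remaining, function(ln) {
      cov_len(segments[segments$line_id == ln, , drop = FALSE]) - base_len
    }, numeric(1))
    best <- max(gains)
    if (best <= min_gain || best <= 0) break  # never add a zero-gain line
    pick <- remaining[gains == best][1L]  # lexicographic tie-break
    selected <- c(selected, pick)
    sl <- segments[segments$line_id == pick, , drop = FALSE]
    for (g in unique(sl$group)) {
      covered[[g]] <- rbind(covered[[g]],
                            sl[sl$group == g, c("start", "end"), drop = FALSE])
    }
    base_len <- cov_len()
    remaining <- setdiff(remaining, pick)
  }
  out <- selected
  attr(out, "segments") <- segments[segments$line_id %in% selected, , drop = FALSE]
  out
}

#' Per-linkage-group coverage report of an introgression panel
#'
#' @param segments Data frame of donor segments of the panel lines.
#' @param map A [linkage_map()].
#' @return An object of class `panel_report`: data frame with one row per
#'   linkage group (`group`, `length_cM`, `covered_cM` = union of segments,
#'   `n_fragments`, `percent_covered` rounded to one decimal) plus a
#'   `"totals"` attribute.
#' @export
coverage_report <- function(segments, map) {
  gl <- map_group_lengths(map)
  b <- .map_bounds(map)
  if (nrow(segments) > 0L) {
    gi <- match(as.character(segments$group), b$groups)
    if (any(is.na(gi))) stop("segment on unknown linkage group")
    off <- segments$start < b$start[gi] - 1e-9 | segments$end > b$end[gi] + 1e-9 |
      segments$start > segments$end
    if (any(off)) stop("segment outside its linkage group")
  }
  rows <- lapply(names(gl), function(g) {
    s <- segments[as.character(segments$group) == g, , drop = FALSE]
    cov <- .union_length(s$start, s$end)
    data.frame(group = g, length_cM = unname(gl[g]), covered_cM = cov,
               n_fragments = nrow(s),
               percent_covered = round(100 * cov / gl[g], 1),
               stringsAsFactors = FALSE)
  })
  rep_ <- do.call(rbind, rows)
  attr(rep_, "totals") <- data.frame(
    covered_cM = sum(rep_$covered_cM), length_cM = sum(rep_$length_cM),
    n_fragments = sum(rep_$n_fragments),
    percent_covered = round(100 * sum(rep_$covered_cM) / sum(rep_$length_cM), 1))
  class(rep_) <- c("panel_report", "data.frame")
  rep_
}

#' @export
print.panel_report <- function(x, ...) {
  print.data.frame(x)
  t <- attr(x, "totals")
  cat(sprintf("Total: %.1f of %.1f cM covered (%d fragments; %.1f%%)\n",
              t$covered_cM, t$length_cM, t$n_fragments, t$percent_covered))
  invisible(x)
}
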