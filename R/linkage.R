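#' Kosambi mapping function
#'
#' Converts a recombination fraction r into a Kosambi map distance
#' d = 25 ln((1 + 2r) / (1 - 2r)) cM, and back (r = tanh(d/50) / 2). The two
#' are mutual inverses; `kosambi_cM` is strictly increasing on [0, 0.5).
#'
#' @param r Recombination fraction(s) in [0, 0.5).
#' @param d_cM Map distance(s) in cM, >= 0.
#' @return Numeric vector of distances (cM) or recombination fractions.
#' @examples
#' kosambi_cM(0.1)            # 10.14 cM
#' kosambi_inverse(kosambi_cM(0.3))
#' @export
kosambi_cM <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5)) {
    stop("r must lie in [0, 0.5)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cM
#' @export
kosambi_inverse <- function(d_cM) {
  if (any(!is.finite(d_cM)) || any(d_cM < 0)) stop("d_cM must be >= 0")
  0.5 * tanh(2 * d_cM / 100)
}

# F2 two-locus genotype class probabilities, coupling-phase F1 (AB/ab), no
# interference. Rows: count of "a" alleles at locus A (0,1,2) = AA,Aa,aa;
# columns likewise for locus B. Built by convolving the four gamete types.
.f2_class_probs <- function(r) {
  g <- c(AB = (1 - r) / 2, Ab = r / 2, aB = r / 2, ab = (1 - r) / 2)
  a_of <- c(AB = 0L, Ab = 0L, aB = 1L, ab = 1L)  # "a" dose contributed
  b_of <- c(AB = 0L, Ab = 1L, aB = 0L, ab = 1L)
  p <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    p[a_of[i] + a_of[j] + 1L, b_of[i] + b_of[j] + 1L] <-
      p[a_of[i] + a_of[j] + 1L, b_of[i] + b_of[j] + 1L] + g[i] * g[j]
  }
  p
}

.f2_loglik <- function(r, counts) {
  p <- .f2_class_probs(r)
  sum(counts[p > 0 | counts > 0] * log(pmax(p[p > 0 | counts > 0], 1e-300)))
}

.new_rf_estimate <- function(locus_a, locus_b, r_hat, lod, phase, n,
                             loglik, boundary = FALSE, low_information = FALSE) {
  structure(list(locus_a = locus_a, locus_b = locus_b,
                 r_hat = r_hat, lod = lod, phase = phase,
                 n_informative = n, loglik = loglik,
                 boundary = boundary, low_information = low_information),
            class = "rf_estimate")
}

#' @export
print.rf_estimate <- function(x, ...) {
  cat(sprintf("r_hat = %.4f  LOD = %.2f  phase = %s  n = %d%s\n",
              x$r_hat, x$lod, x$phase, x$n_informative,
              if (x$low_information) "  [low information]" else ""))
  invisible(x)
}

#' Two-point recombination fraction from a codominant F2 table
#'
#' Maximum-likelihood estimate of r from a 3x3 table of two-locus F2 genotype
#' counts (rows: AA, Aa, aa at locus A; columns: BB, Bb, bb at locus B, with
#' A/B the alleles of one parent). The double heterozygote class is a mixture
#' of the two phase configurations; the estimate is obtained by EM over the
#' expected number of recombinant gametes (tolerance 1e-8 on r, at most 500
#' iterations, grid-search fallback on non-convergence). The LOD score is
#' log10 L(r_hat) - log10 L(0.5).
#'
#' @param counts 3x3 matrix of genotype counts.
#' @param locus_a,locus_b Optional locus names carried into the result.
#' @return An object of class `rf_estimate` with fields `r_hat` (clamped to
#'   [0, 0.5]), `lod`, `phase`, `n_informative`, `loglik` and flags
#'   `boundary`, `low_information`.
#' @export
estimate_rf_codominant <- function(counts, locus_a = "A", locus_b = "B") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3))) stop("counts must be a 3x3 table")
  if (any(counts < 0)) stop("counts must be >= 0")
  n <- sum(counts)
  if (n < 1) stop("empty genotype table")
  # recombinant gametes contributed by each class (double het handled in EM)
  rec <- matrix(c(0, 1, 2,
                  1, NA, 1,
                  2, 1, 0), 3, 3, byrow = TRUE)
  r <- 0.25
  converged <- FALSE
  for (it in seq_len(500)) {
    e_hh <- 2 * r^2 / (r^2 + (1 - r)^2)  # E[rec gametes | double het]
    rec[2, 2] <- e_hh
    r_new <- sum(counts * rec) / (2 * n)
    r_new <- min(max(r_new, 0), 0.5)
    if (abs(r_new - r) < 1e-8) { r <- r_new; converged <- TRUE; break }
    r <- r_new
  }
  if (!converged) {
    grid <- seq(0, 0.5, by = 0.0005)
    ll <- vapply(grid, .f2_loglik, numeric(1), counts = counts)
    r <- grid[which.max(ll)]
  }
  ll_hat <- .f2_loglik(r, counts)
  lod <- (ll_hat - .f2_loglik(0.5, counts)) / log(10)
  .new_rf_estimate(locus_a, locus_b, r, max(lod, 0), "coupling", n, ll_hat,
                   boundary = r <= 0 || r >= 0.5)
}

# Dominant F2 class probabilities. Order of the 2x2 presence table:
# rows = fragment A (present, absent), cols = fragment B (present, absent).
# Coupling (non-null alleles on the same F1 homolog):
#   P(A-B-) = (2 + (1-r)^2)/4, P(A-bb) = P(aaB-) = (1 - (1-r)^2)/4,
#   P(aabb) = (1-r)^2/4.
# Repulsion swaps (1-r) for r in the double-null class:
#   P(aabb) = r^2/4, P(A-bb) = P(aaB-) = (1 - r^2)/4, P(A-B-) = (2 + r^2)/4.
.dom_class_probs <- function(r, phase) {
  s <- if (phase == "coupling") (1 - r)^2 else r^2
  matrix(c((2 + s) / 4, (1 - s) / 4,
           (1 - s) / 4, s / 4), 2, 2, byrow = TRUE)
}

.dom_loglik <- function(r, counts, phase) {
  p <- .dom_class_probs(r, phase)
  sum(counts * log(pmax(p, 1e-300)))
}

#' Two-point recombination fraction from a dominant F2 presence table
#'
#' Estimates r between two dominant (AFLP-type) fragments in an F2-type
#' population from the 2x2 table of joint presence/absence counts, under the
#' standard no-interference class probabilities for coupling and repulsion
#' phase. With `phase = "unknown"` both phase likelihoods are maximized and
#' the higher one is returned; an exact tie yields phase `"unknown"` (such
#' pairs carry no usable phase signal).
#'
#' @param counts 2x2 matrix: rows = fragment A (present, absent), columns =
#'   fragment B (present, absent).
#' @param phase `"coupling"`, `"repulsion"` or `"unknown"`.
#' @param locus_a,locus_b Optional fragment names carried into the result.
#' @return An `rf_estimate` (see [estimate_rf_codominant()]). Degenerate
#'   tables (single observed class, n < 10) are flagged `low_information`.
#' @export
estimate_rf_dominant <- function(counts, phase = c("unknown", "coupling", "repulsion"),
                                 locus_a = "A", locus_b = "B") {
  phase <- match.arg(phase)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2x2 table")
  if (any(counts < 0)) stop("counts must be >= 0")
  n <- sum(counts)
  if (n < 1) stop("empty presence/absence table")
  fit_one <- function(ph) {
    opt <- stats::optimize(.dom_loglik, c(0, 0.5), counts = counts, phase = ph,
                           maximum = TRUE, tol = 1e-9)
    # optimize never returns the exact interval ends; snap if boundary is better
    cand <- c(opt$maximum, 0, 0.5)
    ll <- vapply(cand, .dom_loglik, numeric(1), counts = counts, phase = ph)
    list(r = cand[which.max(ll)], ll = max(ll))
  }
  if (phase == "unknown") {
    fc <- fit_one("coupling"); fr <- fit_one("repulsion")
    if (abs(fc$ll - fr$ll) < 1e-9) {
      fit <- if (fc$ll >= fr$ll) fc else fr
      phase_out <- "unknown"
    } else if (fc$ll > fr$ll) { fit <- fc; phase_out <- "coupling"
    } else { fit <- fr; phase_out <- "repulsion" }
  } else {
    fit <- fit_one(phase); phase_out <- phase
  }
  lod <- if (phase_out == "unknown") 0 else
    (fit$ll - .dom_loglik(0.5, counts, phase_out)) / log(10)
  low_info <- sum(counts > 0) <= 1L && n < 10
  .new_rf_estimate(locus_a, locus_b, fit$r, max(lod, 0), phase_out, n, fit$ll,
                   boundary = fit$r <= 0 || fit$r >= 0.5,
                   low_information = low_info)
}

#' Collect two-point estimates into a data frame
#'
#' @param estimates List of `rf_estimate` objects.
#' @return Data frame with columns `locus_a`, `locus_b`, `r_hat`, `lod`,
#'   `phase`, `n`.
#' @export
rf_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(locus_a = e$locus_a, locus_b = e$locus_b, r_hat = e$r_hat,
               lod = e$lod, phase = e$phase, n = e$n_informative,
               stringsAsFactors = FALSE)
  }))
}

# minimal union-find over 1..n
.uf_components <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_along(edges_i)) {
    a <- find(edges_i[k]); b <- find(edges_j[k])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Threshold-stepped single-linkage marker grouping
#'
#' Reproduces the stepped grouping used in linkage-map construction: markers
#' are joined into single-linkage connected components over edges with
#' `r_hat <= threshold` and `lod >= min_lod`, for a descending sequence of
#' recombination-fraction thresholds (default 0.250 down to 0.050 in steps of
#' 0.050). The trajectory is nested: groups at a stricter threshold refine
#' groups at a looser one.
#'
#' @param estimates Data frame as from [rf_table()] (or a list of
#'   `rf_estimate` objects).
#' @param markers Optional character vector of all marker names (defaults to
#'   those appearing in `estimates`); markers without qualifying edges come
#'   out as singletons.
#' @param rf_start,rf_end,rf_step Threshold schedule (descending).
#' @param min_lod LOD gate; edges below it are never used.
#' @return An object of class `linkage_grouping`: list with `thresholds` and
#'   `groups` (for each threshold, a list of member character vectors).
#' @export
group_loci <- function(estimates, markers = NULL,
                       rf_start = 0.250, rf_end = 0.050, rf_step = 0.050,
                       min_lod = 3.0) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- rf_table(estimates)
  }
  if (is.null(markers)) {
    markers <- sort(unique(c(estimates$locus_a, estimates$locus_b)))
  }
  n <- length(markers)
  idx <- stats::setNames(seq_len(n), markers)
  thresholds <- seq(rf_start, rf_end, by = -abs(rf_step))
  ok_lod <- estimates$lod >= min_lod
  groups <- lapply(thresholds, function(thr) {
    use <- ok_lod & estimates$r_hat <= thr
    comp <- .uf_components(n, idx[estimates$locus_a[use]], idx[estimates$locus_b[use]])
    unname(split(markers, comp))
  })
  structure(list(thresholds = thresholds, groups = groups),
            class = "linkage_grouping")
}

#' @export
print.linkage_grouping <- function(x, ...) {
  for (i in seq_along(x$thresholds)) {
    cat(sprintf("rf <= %.3f: %d group(s)\n", x$thresholds[i], length(x$groups[[i]])))
  }
  invisible(x)
}

#' Groups at the strictest threshold of a grouping trajectory
#'
#' @param grouping A `linkage_grouping` from [group_loci()].
#' @return List of member character vectors at the final (smallest) threshold.
#' @export
final_groups <- function(grouping) {
  stopifnot(inherits(grouping, "linkage_grouping"))
  grouping$groups[[length(grouping$groups)]]
}
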