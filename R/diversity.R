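#' Pairwise genetic distances from dominant-fragment profiles
#'
#' Distances between lines are computed over jointly non-missing fragments
#' only (pairwise deletion, no imputation). With joint presence/absence counts
#' a (1/1), b (1/0), c (0/1), d (0/0):
#' jaccard = 1 - a/(a+b+c); dice = 1 - 2a/(2a+b+c);
#' simple_matching = (b+c)/(a+b+c+d). All lie in [0, 1]. Pairs with no
#' jointly non-missing fragment get `NA` and are flagged in the
#' `"flagged_pairs"` attribute; for jaccard/dice a pair whose jointly scored
#' fragments are all absent is defined to have distance 0.
#'
#' @param m A [fragment_matrix()].
#' @param metric `"jaccard"` (default, standard for AFLP data), `"dice"` or
#'   `"simple_matching"`.
#' @return Symmetric distance matrix with line ids as dimnames.
#' @export
pairwise_distance <- function(m, metric = c("jaccard", "dice", "simple_matching")) {
  metric <- match.arg(metric)
  stopifnot(inherits(m, "fragment_matrix"))
  x <- m$calls
  if (nrow(x) < 2L) stop("need at least two lines for pairwise distances")
  P <- x; P[is.na(P)] <- 0L                       # presence, missing -> 0
  Q <- 1L - x; Q[is.na(Q)] <- 0L                  # absence, missing -> 0
  a <- tcrossprod(P)
  b <- tcrossprod(P, Q)
  c_ <- t(b)
  d_ <- tcrossprod(Q)
  nn <- a + b + c_ + d_                           # jointly non-missing
  if (metric == "jaccard") {
    den <- a + b + c_
    dist <- ifelse(den > 0, 1 - a / den, 0)
  } else if (metric == "dice") {
    den <- 2 * a + b + c_
    dist <- ifelse(den > 0, 1 - 2 * a / den, 0)
  } else {
    dist <- ifelse(nn > 0, (b + c_) / nn, 0)
  }
  dist[nn == 0] <- NA_real_
  diag(dist) <- 0
  flagged <- which(nn == 0 & upper.tri(nn), arr.ind = TRUE)
  if (nrow(flagged) > 0) {
    warning(sprintf("%d line pair(s) share no non-missing fragment", nrow(flagged)))
  }
  dimnames(dist) <- list(rownames(x), rownames(x))
  attr(dist, "flagged_pairs") <- flagged
  dist
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical (Torgerson) scaling: the squared distances are double-centred and
#' eigendecomposed; coordinates come from the top-k nonnegative eigenvalues
#' and the explained fraction of each axis is its eigenvalue divided by the
#' sum of positive eigenvalues. Negative eigenvalues (non-Euclidean input)
#' are reported but not used and no correction is applied.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param k Number of axes requested (>= 1).
#' @return An object of class `pcoa_result`: list with `coordinates`
#'   (ids x k; axes beyond the available positive eigenvalues are zero),
#'   `eigenvalues` (all n), `explained_fraction` (length k, non-increasing).
#' @export
pcoa <- function(d, k = 3L) {
  if (k < 1L) stop("k must be >= 1")
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two points")
  if (any(is.na(d))) stop("distance matrix contains NA")
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = min(k, n - 1L), eig = TRUE))
  eig <- fit$eig
  pos_sum <- sum(eig[eig > 0])
  coords <- matrix(0, n, k, dimnames = list(rownames(d), paste0("PCo", seq_len(k))))
  if (pos_sum <= .Machine$double.eps) {
    warning("all eigenvalues are zero; coordinates set to 0, explained fractions to 0")
    expl <- rep(0, k)
  } else {
    got <- fit$points
    coords[, seq_len(ncol(got))] <- got
    expl <- pmax(eig, 0)[seq_len(k)] / pos_sum
    expl[is.na(expl)] <- 0
  }
  structure(list(coordinates = coords, eigenvalues = eig,
                 explained_fraction = expl),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d points, %d axes; explained: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = ", ")))
  if (any(x$eigenvalues < -1e-8)) {
    cat(sprintf("  (%d negative eigenvalue(s) reported, not used)\n",
                sum(x$eigenvalues < -1e-8)))
  }
  invisible(x)
}

#' Count species-specific polymorphic fragments
#'
#' A fragment is polymorphic if both presence and absence occur among the
#' included lines; it is specific to group 1 if it is present in at least one
#' group-1 line and absent in every non-excluded group-2 line whose call is
#' not missing (and symmetrically). Excluded lines (e.g. putative
#' intermediate/introgressed accessions) are removed before any counting.
#'
#' @param m A [fragment_matrix()].
#' @param group_of_line Named character vector mapping line id to one of two
#'   group labels.
#' @param excluded_lines Character vector of line ids removed before counting.
#' @return List with `n_polymorphic`, per-group specific counts (named by the
#'   group labels) and the vectors of specific fragment names.
#' @export
count_species_specific <- function(m, group_of_line, excluded_lines = character()) {
  stopifnot(inherits(m, "fragment_matrix"))
  x <- m$calls
  lv <- unique(stats::na.omit(unname(group_of_line)))
  if (length(lv) != 2L) stop("exactly two line groups are required")
  keep <- setdiff(rownames(x), excluded_lines)
  x <- x[keep, , drop = FALSE]
  gl <- group_of_line[rownames(x)]
  g1 <- !is.na(gl) & gl == lv[1]
  g2 <- !is.na(gl) & gl == lv[2]
  if (!any(g1) || !any(g2)) stop("a group is empty after exclusions")
  pres <- function(rows) colSums(x[rows, , drop = FALSE] == 1L, na.rm = TRUE)
  abs_ok <- function(rows) colSums(x[rows, , drop = FALSE] == 1L, na.rm = TRUE) == 0L
  p1 <- pres(g1); p2 <- pres(g2)
  poly <- colSums(x == 1L, na.rm = TRUE) > 0L & colSums(x == 0L, na.rm = TRUE) > 0L
  spec1 <- p1 > 0L & abs_ok(g2)
  spec2 <- p2 > 0L & abs_ok(g1)
  out <- list(n_polymorphic = sum(poly),
              specific_fragments = list(colnames(x)[spec1], colnames(x)[spec2]))
  counts <- c(sum(spec1), sum(spec2))
  names(counts) <- lv
  names(out$specific_fragments) <- lv
  out$n_specific <- counts
  out
}
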