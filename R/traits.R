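#' Spikelet fertility percentage
#'
#' Fertility is the observed seed count divided by the number of available
#' florets (florets per spikelet times spikelets scored), expressed as a
#' percentage and reported to one decimal. The computation is linear in
#' seeds and inverse-linear in spikelets. Seed counts exceeding the floret
#' number give values above 100 with a warning (over-counts are flagged, not
#' rejected).
#'
#' @param n_seeds Seed count(s), >= 0.
#' @param n_spikelets Spikelet count(s), > 0.
#' @param florets_per_spikelet Florets per spikelet (default 2, the
#'   conventional assumption for these wheats).
#' @return Numeric vector of percentages in steps of 0.1.
#' @examples
#' fertility_percent(7, 100)   # 3.5
#' fertility_percent(0, 58)    # 0
#' @export
fertility_percent <- function(n_seeds, n_spikelets, florets_per_spikelet = 2) {
  if (any(n_spikelets <= 0)) stop("n_spikelets must be > 0")
  if (any(n_seeds < 0)) stop("n_seeds must be >= 0")
  pct <- 100 * n_seeds / (florets_per_spikelet * n_spikelets)
  if (any(pct > 100)) warning("fertility above 100%: more seeds than florets")
  round(pct, 1)
}

#' Fertility distribution summary
#'
#' Bins fertility percentages into classes of `bin_width` (default 10:
#' [0,10), [10,20), ..., [90,100]), reports all modal classes (ties give a
#' multimodal distribution, e.g. the bimodal case) and the mean.
#'
#' @param values Fertility percentages in [0, 100].
#' @param bin_width Class width in percentage points.
#' @return An object of class `fertility_summary`: list with `histogram`
#'   (named bin counts), `mode_class` (matrix of the (low, high) bounds of
#'   every maximal bin), `bimodal` (`TRUE` if two or more bins tie for the
#'   maximum), `mean`, `n`.
#' @export
fertility_histogram <- function(values, bin_width = 10) {
  if (length(values) == 0L) stop("no fertility values")
  if (any(is.na(values)) || any(values < 0 | values > 100)) {
    stop("fertility values must lie in [0, 100]")
  }
  breaks <- seq(0, 100, by = bin_width)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  names(counts) <- sprintf("[%g,%g%s", breaks[-length(breaks)], breaks[-1],
                           c(rep(")", length(breaks) - 2L), "]"))
  top <- which(counts == max(counts))
  mode_class <- cbind(low = breaks[top], high = breaks[top + 1L])
  structure(list(histogram = counts, mode_class = mode_class,
                 bimodal = length(top) >= 2L, mean = mean(values),
                 n = length(values)),
            class = "fertility_summary")
}

#' @export
print.fertility_summary <- function(x, ...) {
  cat(sprintf("Fertility: n = %d, mean = %.1f%%; mode class(es): %s%s\n",
              x$n, x$mean,
              paste(sprintf("%g-%g%%", x$mode_class[, "low"],
                            x$mode_class[, "high"]), collapse = ", "),
              if (x$bimodal) " [multimodal]" else ""))
  print(x$histogram)
  invisible(x)
}

#' Transgressive-phenotype test against the best parent
#'
#' For each trait, a one-way analysis of variance across all entries (lines
#' and parents) provides the pooled within-entry mean square; each line is
#' then compared to the best parent (the parent with the larger mean) by
#' t = (line mean - best-parent mean) / (s_pooled sqrt(1/n_line + 1/n_parent))
#' on the ANOVA residual degrees of freedom, one-sided for exceedance. The
#' parents themselves are compared two-sided. No multiple-testing correction
#' is applied by default, matching the classical usage; `bonferroni = TRUE`
#' divides alpha by the number of lines tested.
#'
#' @param traits Data frame with columns `entry`, `trait`, `value`
#'   (replicate measurements; at least 2 replicates somewhere per trait so
#'   the pooled error has residual degrees of freedom).
#' @param parents Character vector of the two parent entry ids.
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Apply a Bonferroni correction to the per-line tests.
#' @return An object of class `transgressive_result`: list with `per_trait`
#'   (data frame: trait, parent means, best parent, parents' two-sided
#'   p-value, pooled SD, residual df, number of transgressive lines) and
#'   `per_line` (data frame of every line x trait comparison with t, p and
#'   the transgressive flag).
#' @export
transgressive_test <- function(traits, parents, alpha = 0.05,
                               bonferroni = FALSE) {
  need <- c("entry", "trait", "value")
  if (!all(need %in% names(traits))) {
    stop("traits needs columns: ", paste(need, collapse = ", "))
  }
  if (length(parents) != 2L || !all(parents %in% traits$entry)) {
    stop("both parents must be present in the trait table")
  }
  per_trait <- list(); per_line <- list()
  for (tr in unique(traits$trait)) {
    d <- traits[traits$trait == tr & !is.na(traits$value), , drop = FALSE]
    ns <- table(d$entry)
    df_res <- nrow(d) - length(ns)
    if (df_res < 1L) {
      warning(sprintf("trait %s skipped: no residual degrees of freedom", tr))
      next
    }
    fit <- stats::aov(value ~ factor(entry), data = d)
    s2 <- sum(stats::residuals(fit)^2) / df_res
    means <- tapply(d$value, d$entry, mean)
    if (s2 <= .Machine$double.eps * max(1, mean(d$value)^2)) {
      warning(sprintf("trait %s: zero within-entry variance", tr))
      s2 <- 0
    }
    pm <- means[parents]
    best <- parents[which.max(pm)]
    se_pp <- sqrt(s2 * (1 / ns[parents[1]] + 1 / ns[parents[2]]))
    p_parents <- if (se_pp > 0) {
      2 * stats::pt(abs(pm[1] - pm[2]) / se_pp, df_res, lower.tail = FALSE)
    } else NA_real_
    lines <- setdiff(names(means), parents)
    alpha_line <- if (bonferroni) alpha / max(length(lines), 1L) else alpha
    res <- lapply(lines, function(ln) {
      se <- sqrt(s2 * (1 / ns[ln] + 1 / ns[best]))
      tstat <- if (se > 0) (means[ln] - means[best]) / se else
        ifelse(means[ln] > means[best], Inf, 0)
      p <- stats::pt(tstat, df_res, lower.tail = FALSE)
      data.frame(trait = tr, line = ln, line_mean = unname(means[ln]),
                 t = unname(tstat), p_one_sided = unname(p),
                 transgressive = !is.na(p) && p < alpha_line,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    per_line[[tr]] <- res
    per_trait[[tr]] <- data.frame(
      trait = tr, mean_parent1 = unname(pm[1]), mean_parent2 = unname(pm[2]),
      best_parent = best, p_parents = unname(p_parents),
      pooled_sd = sqrt(s2), df = df_res,
      n_transgressive = sum(res$transgressive),
      n_lines = nrow(res), stringsAsFactors = FALSE)
  }
  if (length(per_trait) == 0L) stop("no trait could be analysed")
  structure(list(per_trait = do.call(rbind, c(per_trait, make.row.names = FALSE)),
                 per_line = do.call(rbind, c(per_line, make.row.names = FALSE)),
                 parents = parents, alpha = alpha),
            class = "transgressive_result")
}

#' @export
print.transgressive_result <- function(x, ...) {
  cat(sprintf("Transgressive test vs best parent (alpha = %g):\n", x$alpha))
  print(x$per_trait[, c("trait", "mean_parent1", "mean_parent2",
                        "p_parents", "n_transgressive", "n_lines")])
  invisible(x)
}
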