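#' Macrocolinearity comparison of two linkage maps
#'
#' Loci shared by name between two maps are classified as `homeologous` when
#' the locus sits on the declared homeolog of its map-A group in map B, and
#' `non_homeologous` otherwise (the bridge-colour logic of comparative map
#' figures). For every homeologous group pair a Kendall rank-order
#' concordance of the shared homeologous loci is reported (tau = 1 means
#' perfectly conserved marker order). A locus occurring more than once within
#' one map is excluded with a warning.
#'
#' @param map_a,map_b [linkage_map()] objects sharing locus names.
#' @param homeology Named character vector mapping each map-A group label to
#'   its homeologous map-B group; the default is the identity mapping over
#'   map A's groups (the two A genomes share chromosome numbering).
#' @return An object of class `colinearity_table`: list with `table` (per
#'   shared locus: groups, positions, class), `summary` (per map-A group:
#'   shared/homeologous/non-homeologous counts and Kendall tau) and `counts`
#'   (overall totals).
#' @export
compare_maps <- function(map_a, map_b, homeology = NULL) {
  stopifnot(inherits(map_a, "linkage_map"), inherits(map_b, "linkage_map"))
  dup_a <- unique(map_a$locus[duplicated(map_a$locus)])
  dup_b <- unique(map_b$locus[duplicated(map_b$locus)])
  drop <- union(dup_a, dup_b)
  if (length(drop) > 0L) {
    warning("locus name(s) duplicated within a map, excluded: ",
            paste(drop, collapse = ", "))
  }
  a <- map_a[!map_a$locus %in% drop, , drop = FALSE]
  b <- map_b[!map_b$locus %in% drop, , drop = FALSE]
  shared <- intersect(a$locus, b$locus)
  if (length(shared) == 0L) stop("the two maps share no locus name")
  ga <- as.character(unique(a$group))
  if (is.null(homeology)) homeology <- stats::setNames(ga, ga)
  ia <- match(shared, a$locus); ib <- match(shared, b$locus)
  tab <- data.frame(
    locus = shared,
    group_a = as.character(a$group[ia]), position_a = a$position_cM[ia],
    group_b = as.character(b$group[ib]), position_b = b$position_cM[ib],
    stringsAsFactors = FALSE)
  tab$class <- ifelse(!is.na(homeology[tab$group_a]) &
                        homeology[tab$group_a] == tab$group_b,
                      "homeologous", "non_homeologous")
  summ <- do.call(rbind, lapply(ga, function(g) {
    tg <- tab[tab$group_a == g, , drop = FALSE]
    hom <- tg[tg$class == "homeologous", , drop = FALSE]
    tau <- if (nrow(hom) >= 2L) {
      suppressWarnings(stats::cor(hom$position_a, hom$position_b,
                                  method = "kendall"))
    } else NA_real_
    data.frame(group_a = g, group_b = unname(homeology[g]),
               n_shared = nrow(tg), n_homeologous = nrow(hom),
               n_non_homeologous = nrow(tg) - nrow(hom),
               kendall_tau = tau, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ,
                 counts = c(n_shared = nrow(tab),
                            n_homeologous = sum(tab$class == "homeologous"),
                            n_non_homeologous = sum(tab$class == "non_homeologous"))),
            class = "colinearity_table")
}

#' @export
print.colinearity_table <- function(x, ...) {
  cat(sprintf("Macrocolinearity: %d shared loci, %d homeologous, %d non-homeologous\n",
              x$counts["n_shared"], x$counts["n_homeologous"],
              x$counts["n_non_homeologous"]))
  print(x$summary)
  invisible(x)
}
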