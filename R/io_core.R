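#' Construct a linkage map
#'
#' A linkage map is the coordinate backbone of every analysis in this package:
#' an ordered table of marker loci with a linkage-group assignment and a
#' position in centimorgans. Wheat A genomes have seven linkage groups, but any
#' number of group labels is accepted.
#'
#' @param locus Character vector of locus names (unique within the map).
#' @param group Linkage-group labels (integer or character), one per locus.
#' @param position_cM Nonnegative map positions in centimorgans.
#' @return An object of class `linkage_map`: a data frame with columns
#'   `locus`, `group`, `position_cM`, sorted by group and position.
#' @examples
#' m <- linkage_map(c("m1", "m2", "m3"), c(1, 1, 2), c(0, 10, 0))
#' map_total_length(m)
#' @export
linkage_map <- function(locus, group, position_cM) {
  locus <- as.character(locus)
  position_cM <- as.numeric(position_cM)
  if (length(locus) == 0L) stop("linkage map needs at least one locus")
  if (anyDuplicated(locus)) {
    stop("duplicate locus name(s) in map: ",
         paste(unique(locus[duplicated(locus)]), collapse = ", "))
  }
  if (any(!is.finite(position_cM)) || any(position_cM < 0)) {
    stop("map positions must be finite and >= 0")
  }
  m <- data.frame(locus = locus, group = group, position_cM = position_cM,
                  stringsAsFactors = FALSE)
  m <- m[order(m$group, m$position_cM, m$locus), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("linkage_map", "data.frame")
  m
}

#' @export
print.linkage_map <- function(x, ...) {
  gl <- map_group_lengths(x)
  cat(sprintf("Linkage map: %d loci in %d group(s), total %.1f cM\n",
              nrow(x), length(gl), sum(gl)))
  for (g in names(gl)) {
    cat(sprintf("  group %s: %d loci, %.1f cM\n", g, sum(x$group == g), gl[[g]]))
  }
  invisible(x)
}

#' Per-group and total map lengths
#'
#' Group length is the span of its loci (max position minus min position).
#'
#' @param map A [linkage_map()].
#' @return `map_group_lengths`: named numeric vector of spans in cM;
#'   `map_total_length`: their sum; `marker_density`: total length divided by
#'   the number of loci (cM per marker).
#' @export
map_group_lengths <- function(map) {
  stopifnot(inherits(map, "linkage_map"))
  gl <- tapply(map$position_cM, as.character(map$group),
               function(p) max(p) - min(p))
  stats::setNames(as.numeric(gl), names(gl))
}

#' @rdname map_group_lengths
#' @export
map_total_length <- function(map) sum(map_group_lengths(map))

#' @rdname map_group_lengths
#' @export
marker_density <- function(map) map_total_length(map) / nrow(map)

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a linkage map from a delimited file
#'
#' The file must carry columns `locus`, `group` and `position_cM`; the
#' separator (tab or comma) is auto-detected from the header line.
#'
#' @param path Path to a TSV/CSV file.
#' @return A [linkage_map()].
#' @export
read_map <- function(path) {
  sep <- .sniff_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("locus", "group", "position_cM")
  if (!all(need %in% names(d))) {
    stop("map file must have columns: ", paste(need, collapse = ", "))
  }
  linkage_map(d$locus, d$group, d$position_cM)
}

#' Write a linkage map as TSV
#'
#' @param map A [linkage_map()].
#' @param path Output path.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "linkage_map"))
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a dominant-fragment presence/absence matrix
#'
#' Holds calls for dominant (AFLP-type) fragments: `1` present, `0` absent,
#' `NA` missing, together with a per-fragment species-specificity label
#' (`Am_specific`, `Au_specific`, `shared` or `unassigned`).
#'
#' @param calls Integer/numeric matrix (lines x fragments) with values in
#'   \{0, 1, NA\}; dimnames give line and fragment identifiers.
#' @param species Optional character vector of per-fragment labels (recycled
#'   `"unassigned"` if omitted), named by fragment or in column order.
#' @return An object of class `fragment_matrix`: list with elements `calls`
#'   and `species`.
#' @export
fragment_matrix <- function(calls, species = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) rownames(calls) <- paste0("line", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("f", seq_len(ncol(calls)))
  bad <- !(calls %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("fragment calls must be 0, 1 or NA")
  ok_lab <- c("Am_specific", "Au_specific", "shared", "unassigned")
  if (is.null(species)) {
    species <- rep("unassigned", ncol(calls))
  } else if (!is.null(names(species))) {
    species <- unname(species[colnames(calls)])
  }
  species <- as.character(species)
  if (length(species) != ncol(calls) || any(!species %in% ok_lab)) {
    stop("species labels must be one of ", paste(ok_lab, collapse = "/"),
         " for every fragment")
  }
  names(species) <- colnames(calls)
  structure(list(calls = calls, species = species), class = "fragment_matrix")
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat(sprintf("Fragment matrix: %d lines x %d fragments (%d missing calls)\n",
              nrow(x$calls), ncol(x$calls), sum(is.na(x$calls))))
  print(table(species = x$species))
  invisible(x)
}

#' Construct a codominant (SSR-type) genotype matrix
#'
#' Calls are `"RR"` (recurrent-parent homozygote), `"DD"` (donor homozygote),
#' `"RD"` (heterozygote) or `NA` (missing).
#'
#' @param calls Character matrix (lines x loci) with values in
#'   \{"RR","DD","RD", NA\}.
#' @return An object of class `ssr_matrix` wrapping the call matrix.
#' @export
ssr_matrix <- function(calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (is.null(rownames(calls))) rownames(calls) <- paste0("line", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("s", seq_len(ncol(calls)))
  bad <- !(calls %in% c("RR", "DD", "RD", NA_character_))
  if (any(bad)) stop("SSR calls must be RR, DD, RD or NA")
  structure(list(calls = calls), class = "ssr_matrix")
}

#' @export
print.ssr_matrix <- function(x, ...) {
  cat(sprintf("SSR genotype matrix: %d lines x %d loci\n",
              nrow(x$calls), ncol(x$calls)))
  print(table(factor(x$calls, levels = c("RR", "RD", "DD")), useNA = "ifany"))
  invisible(x)
}

#' Default symbol conventions for genotype files
#'
#' @return A list with components `present`, `absent` (dominant files),
#'   `RR`, `DD`, `RD` (codominant files) and `missing` (both).
#' @export
genotype_symbols <- function() {
  list(present = "1", absent = "0",
       RR = "A", DD = "B", RD = "H",
       missing = c("", "NA", "?", "-"))
}

#' Read a genotype matrix from a delimited file
#'
#' First column = line identifier, header row = marker names; the separator is
#' auto-detected. Cell symbols are mapped via `symbols`; unknown symbols are
#' set to missing with a single warning reporting their count (nothing is
#' silently dropped).
#'
#' @param path Path to a TSV/CSV file.
#' @param system `"dominant"` (presence/absence fragments) or `"codominant"`
#'   (SSR-type three-state calls).
#' @param symbols Symbol convention, see [genotype_symbols()].
#' @return A [fragment_matrix()] or [ssr_matrix()].
#' @export
read_genotypes <- function(path, system = c("dominant", "codominant"),
                           symbols = genotype_symbols()) {
  system <- match.arg(system)
  sep <- .sniff_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (nrow(d) == 0L || ncol(d) == 0L) stop("no genotype calls in file: ", path)
  raw <- as.matrix(d)
  out <- matrix(NA_character_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  if (system == "dominant") {
    out[raw %in% symbols$present] <- "1"
    out[raw %in% symbols$absent] <- "0"
  } else {
    out[raw %in% symbols$RR] <- "RR"
    out[raw %in% symbols$DD] <- "DD"
    out[raw %in% symbols$RD] <- "RD"
  }
  known <- !is.na(out) | raw %in% symbols$missing | is.na(raw)
  n_unknown <- sum(!known)
  if (n_unknown > 0L) {
    warning(sprintf("%d unknown symbol(s) mapped to missing", n_unknown))
  }
  if (system == "dominant") {
    fragment_matrix(matrix(as.integer(out), nrow(out), ncol(out),
                           dimnames = dimnames(out)))
  } else {
    ssr_matrix(out)
  }
}

#' Write a genotype matrix as TSV
#'
#' Inverse of [read_genotypes()]: a round trip reproduces the object
#' state-for-state (species labels of a fragment matrix are not stored in the
#' genotype file and must be carried separately).
#'
#' @param m A [fragment_matrix()] or [ssr_matrix()].
#' @param path Output path.
#' @param symbols Symbol convention, see [genotype_symbols()].
#' @export
write_genotypes <- function(m, path, symbols = genotype_symbols()) {
  calls <- m$calls
  if (inherits(m, "fragment_matrix")) {
    out <- matrix(symbols$missing[[1]], nrow(calls), ncol(calls),
                  dimnames = dimnames(calls))
    out[!is.na(calls) & calls == 1L] <- symbols$present[[1]]
    out[!is.na(calls) & calls == 0L] <- symbols$absent[[1]]
  } else if (inherits(m, "ssr_matrix")) {
    out <- matrix(symbols$missing[[1]], nrow(calls), ncol(calls),
                  dimnames = dimnames(calls))
    for (s in c("RR", "DD", "RD")) out[!is.na(calls) & calls == s] <- symbols[[s]][[1]]
  } else stop("m must be a fragment_matrix or ssr_matrix")
  d <- data.frame(line = rownames(out), out, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fertility records
#'
#' Expects columns `female`, `male`, `n_spikelets`, `n_seeds` and optionally
#' `florets_per_spikelet` (default 2, the conventional floret count retained
#' per spikelet in these crosses). Records where seeds exceed
#' florets x spikelets are kept but flagged with a warning.
#'
#' @param path Path to a TSV/CSV file.
#' @return Data frame of fertility records.
#' @export
read_fertility_records <- function(path) {
  sep <- .sniff_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("female", "male", "n_spikelets", "n_seeds")
  if (!all(need %in% names(d))) {
    stop("fertility file must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(d$florets_per_spikelet)) d$florets_per_spikelet <- 2L
  if (any(d$n_spikelets < 0) || any(d$n_seeds < 0)) {
    stop("spikelet and seed counts must be >= 0")
  }
  over <- d$n_seeds > d$florets_per_spikelet * d$n_spikelets
  if (any(over)) {
    warning(sprintf("%d record(s) with more seeds than florets", sum(over)))
  }
  d
}

#' Read a replicated trait table
#'
#' Long format with columns `entry` (line or parent identifier), `trait` and
#' `value` (replicate measurement, mg/kg dry matter by convention).
#'
#' @param path Path to a TSV/CSV file.
#' @return Data frame with columns `entry`, `trait`, `value`.
#' @export
read_trait_table <- function(path) {
  sep <- .sniff_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("entry", "trait", "value")
  if (!all(need %in% names(d))) {
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  }
  d$value <- as.numeric(d$value)
  d
}

#' Bundled synthetic backbone linkage map
#'
#' A 155-locus, 984-cM synthetic map in seven linkage groups emulating the
#' published density of the einkorn SSR backbone (one marker every 6.35 cM).
#' Locus positions are invented (evenly spaced); group lengths were derived
#' from the published per-group coverage arithmetic.
#'
#' @return A [linkage_map()].
#' @export
example_backbone_map <- function() {
  read_map(system.file("extdata", "backbone_map_synthetic.tsv",
                       package = "introgramap", mustWork = TRUE))
}

#' Bundled interspecific cross fertility records
#'
#' Spikelet and seed counts of hand-made T. monococcum x T. urartu crosses
#' (and reciprocals) with definite totals, as published.
#'
#' @return Data frame of fertility records (see [read_fertility_records()]).
#' @export
example_cross_fertility <- function() {
  read_fertility_records(system.file("extdata", "cross_fertility.tsv",
                                     package = "introgramap", mustWork = TRUE))
}
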