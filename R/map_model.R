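# Genetic-map data model, I/O, summary statistics and gap detection.
#
# A genetic map is stored as a data.frame (class "genetic_map") with one row
# per locus and columns locus / marker_type / group / position_cM /
# subgenome, sorted by group then position. Positions are decimal cM.

#' Recognized marker-type categories
#'
#' The eleven marker classes that can appear on the map: EST-derived SSRs
#' (eSSR), genomic SSRs (gSSR), retrotransposon-microsatellite amplified
#' polymorphisms (REMAP), RT (cDNA-derived PCR markers), SRAP, AFLP, SNP,
#' CAPs, InDel, BAC-end and morphological markers.
#'
#' @export
MARKER_TYPES <- c("eSSR", "gSSR", "REMAP", "RT", "SRAP", "AFLP", "SNP",
                  "CAPs", "InDel", "BAC-end", "morphology")

#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (2.5 -> 3, -2.5 -> -3),
#' matching how map statistics are conventionally printed, unlike base
#' \code{round()}'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Subgenome of a linkage-group label
#'
#' Groups labelled "A..." belong to the At subgenome, "D..." to Dt; any
#' other label yields NA (synthetic maps may use arbitrary labels).
#'
#' @param group character vector of group labels.
#' @return character vector in {"At", "Dt", NA}.
#' @export
subgenome_of <- function(group) {
  ifelse(startsWith(group, "A"), "At",
         ifelse(startsWith(group, "D"), "Dt", NA_character_))
}

# Conventional chromosome numbers for tetraploid cotton linkage groups:
# A1..A13 are chromosomes 1..13; the D-subgenome follows the established
# cytogenetic assignment (D1 = Chr15, D2 = Chr14, D3 = Chr17, ...).
.COTTON_CHR <- c(
  A1 = 1, A2 = 2, A3 = 3, A4 = 4, A5 = 5, A6 = 6, A7 = 7, A8 = 8, A9 = 9,
  A10 = 10, A11 = 11, A12 = 12, A13 = 13,
  D1 = 15, D2 = 14, D3 = 17, D4 = 22, D5 = 19, D6 = 25, D7 = 16,
  D8 = 24, D9 = 23, D10 = 20, D11 = 21, D12 = 26, D13 = 18
)

#' Conventional chromosome number of a linkage group
#'
#' Cotton group labels (A1..A13, D1..D13) map to the conventional
#' chromosome numbers used in cytogenetics; any other label falls back to
#' the digits embedded in the label (e.g. "Chr2" -> 2). Labels without
#' digits return NA.
#'
#' @param group character vector of group labels.
#' @return integer vector of chromosome numbers.
#' @export
chromosome_number <- function(group) {
  known <- .COTTON_CHR[group]
  fallback <- suppressWarnings(as.integer(gsub("[^0-9]", "", group)))
  out <- ifelse(is.na(known), fallback, known)
  as.integer(out)
}

#' Construct a genetic map
#'
#' Validates and canonicalizes a table of loci into a \code{genetic_map}:
#' positions must be non-negative, marker types drawn from
#' \code{\link{MARKER_TYPES}}, and (locus, group) pairs unique. Loci are
#' sorted by group and position and annotated with their subgenome.
#'
#' @param df data.frame with columns \code{locus}, \code{marker_type},
#'   \code{group}, \code{position_cM}.
#' @return a \code{genetic_map} (a sorted data.frame with a
#'   \code{subgenome} column added).
#' @export
genetic_map <- function(df) {
  need <- c("locus", "marker_type", "group", "position_cM")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("genetic map is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$locus <- as.character(df$locus)
  df$marker_type <- as.character(df$marker_type)
  df$group <- as.character(df$group)
  pos <- suppressWarnings(as.numeric(df$position_cM))
  bad <- which(is.na(pos) | pos < 0)
  if (length(bad) > 0)
    stop("malformed position_cM at row(s) ", paste(head(bad, 5), collapse = ", "),
         ": positions must be non-negative numbers")
  df$position_cM <- pos
  unknown <- setdiff(unique(df$marker_type), MARKER_TYPES)
  if (length(unknown) > 0)
    stop("unknown marker_type(s): ", paste(unknown, collapse = ", "))
  key <- paste(df$locus, df$group, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (locus, group) row(s): ",
         paste(head(df$locus[duplicated(key)], 5), collapse = ", "))
  df <- df[order(df$group, df$position_cM, df$locus), , drop = FALSE]
  rownames(df) <- NULL
  df$subgenome <- subgenome_of(df$group)
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Read a genetic map from a TSV file
#'
#' Expects a tab-separated table with header columns \code{locus},
#' \code{marker_type}, \code{group}, \code{position_cM}; lines starting
#' with '#' are ignored.
#'
#' @param path file path.
#' @return a \code{\link{genetic_map}}.
#' @export
read_map <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  genetic_map(df)
}

#' Write a genetic map to a TSV file
#'
#' @param map a \code{\link{genetic_map}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_map <- function(map, path) {
  out <- as.data.frame(map)[, c("locus", "marker_type", "group", "position_cM")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map: %d loci in %d linkage group(s)\n",
              nrow(x), length(unique(x$group))))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more loci\n", nrow(x) - 10))
  invisible(x)
}

#' Mean inter-locus distance
#'
#' The mean spacing between adjacent loci: total map length divided by the
#' number of inter-locus intervals, \code{n_loci - n_groups} (each group of
#' n loci contributes n - 1 intervals). Rounded half away from zero.
#'
#' @param total_length total map length in cM.
#' @param n_loci total locus count.
#' @param n_groups number of linkage groups.
#' @param digits decimal places for rounding (default 2).
#' @return mean inter-locus distance in cM.
#' @export
interlocus_mean <- function(total_length, n_loci, n_groups, digits = 2) {
  k <- n_loci - n_groups
  if (k <= 0)
    stop("mean inter-locus distance undefined: no inter-locus intervals ",
         "(all groups singleton)")
  round_half_up(total_length / k, digits)
}

#' Summarize a genetic map
#'
#' Locus counts, lengths and mean inter-locus distances, overall and per
#' linkage group. Group length is max - min position; the mean inter-locus
#' distance divides total length by the number of adjacent-locus intervals
#' (\code{n_loci - n_groups}).
#'
#' @param map a \code{\link{genetic_map}}.
#' @param round_digits decimal places for cM means (default 2).
#' @return a \code{map_summary} list: \code{n_loci}, \code{n_groups},
#'   \code{total_length}, \code{mean_interlocus},
#'   \code{mean_loci_per_group} (rounded to integer), and a
#'   \code{per_group} data.frame with the same statistics per group.
#' @export
summarize_map <- function(map, round_digits = 2) {
  stopifnot(inherits(map, "genetic_map"), nrow(map) > 0)
  sp <- split(map$position_cM, map$group)
  per <- data.frame(
    group = names(sp),
    n_loci = vapply(sp, length, integer(1)),
    length_cM = vapply(sp, function(p) max(p) - min(p), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  per$subgenome <- subgenome_of(per$group)
  per$mean_interlocus <- ifelse(
    per$n_loci > 1,
    round_half_up(per$length_cM / (per$n_loci - 1), round_digits),
    NA_real_)
  n_loci <- sum(per$n_loci)
  n_groups <- nrow(per)
  total_length <- sum(per$length_cM)
  out <- list(
    n_loci = n_loci,
    n_groups = n_groups,
    total_length = total_length,
    mean_interlocus = interlocus_mean(total_length, n_loci, n_groups,
                                      round_digits),
    mean_loci_per_group = as.integer(round_half_up(n_loci / n_groups, 0)),
    per_group = per
  )
  class(out) <- "map_summary"
  out
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf("%d loci in %d linkage groups covering %.2f cM\n",
              x$n_loci, x$n_groups, x$total_length))
  cat(sprintf("mean inter-locus distance: %.2f cM; mean loci/group: %d\n",
              x$mean_interlocus, x$mean_loci_per_group))
  invisible(x)
}

#' Detect large inter-locus gaps
#'
#' Finds all pairs of adjacent loci whose spacing strictly exceeds the
#' threshold (default 10 cM), the conventional cutoff for reporting
#' remaining gaps in a dense map.
#'
#' @param map a \code{\link{genetic_map}}.
#' @param threshold gap size cutoff in cM; gaps are strictly greater.
#' @return data.frame with columns \code{group}, \code{left_locus},
#'   \code{right_locus}, \code{gap_cM}, sorted by group then position.
#' @export
detect_gaps <- function(map, threshold = 10.0) {
  stopifnot(inherits(map, "genetic_map"))
  out <- lapply(split(as.data.frame(map), map$group), function(g) {
    if (nrow(g) < 2) return(NULL)
    d <- diff(g$position_cM)
    i <- which(d > threshold)
    if (length(i) == 0) return(NULL)
    data.frame(group = g$group[i], left_locus = g$locus[i],
               right_locus = g$locus[i + 1], gap_cM = d[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(group = character(), left_locus = character(),
                      right_locus = character(), gap_cM = numeric())
  rownames(out) <- NULL
  out
}
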