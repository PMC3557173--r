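# Chi-square 1:1 segregation testing on BC1 genotypes and scanning for
# segregation distortion regions (SDRs).
#
# BC1 calls are coded 1 (recurrent-parent homozygote), 3 (heterozygote) or
# NA (missing, "-" on disk). Under Mendelian transmission the two classes
# are expected 1:1.

#' Read a BC1 genotype matrix from a TSV file
#'
#' First column is the locus name; remaining columns are one per
#' individual with cells in {1, 3, -}. "-" (or empty) is read as missing.
#'
#' @param path file path.
#' @return integer matrix (loci x individuals, NA = missing) of class
#'   \code{genotype_matrix}, with locus names as rownames.
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  loci <- df[[1]]
  if (anyDuplicated(loci))
    stop("duplicate locus name(s) in genotype matrix: ",
         paste(head(unique(loci[duplicated(loci)]), 5), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m %in% c("-", "", "NA")] <- NA
  bad <- setdiff(unique(m[!is.na(m)]), c("1", "3"))
  if (length(bad) > 0)
    stop("genotype calls must be 1, 3 or '-'; found: ",
         paste(bad, collapse = ", "))
  storage.mode(m) <- "integer"
  rownames(m) <- loci
  genotype_matrix(m)
}

#' Construct a genotype matrix
#'
#' @param m integer matrix, rows = loci (named), columns = individuals,
#'   entries in {1, 3, NA}.
#' @return the matrix with class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  vals <- unique(as.vector(m))
  if (!all(vals %in% c(1L, 3L, NA)))
    stop("genotype codes restricted to {1, 3, NA}")
  if (anyDuplicated(rownames(m))) stop("locus names must be unique")
  class(m) <- c("genotype_matrix", class(m))
  m
}

#' Write a genotype matrix to a TSV file
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  m <- unclass(geno)
  out <- as.data.frame(m, check.names = FALSE)
  out[] <- lapply(out, function(x) ifelse(is.na(x), "-", as.character(x)))
  out <- cbind(locus = rownames(m), out)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Chi-square goodness-of-fit test against 1:1 segregation
#'
#' Pearson chi-square for the Mendelian 1:1 expectation in a BC1
#' population: with e = (n1 + n3)/2, chi2 = (n1 - e)^2/e + (n3 - e)^2/e,
#' one degree of freedom, no continuity correction. Vectorized.
#'
#' @param n1 count(s) of recurrent-parent homozygote calls.
#' @param n3 count(s) of heterozygote calls.
#' @return data.frame with columns \code{chi2} and \code{p}.
#' @export
chi_square_1to1 <- function(n1, n3) {
  n <- n1 + n3
  if (any(n < 1)) stop("untestable locus: n1 + n3 must be >= 1")
  chi2 <- (n1 - n3)^2 / n
  data.frame(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Test every locus for segregation distortion
#'
#' Applies \code{\link{chi_square_1to1}} to each locus of a BC1 genotype
#' matrix (missing calls dropped per locus) and classifies loci with
#' p < alpha by skew direction: toward the recurrent parent when n1 > n3,
#' toward the heterozygote when n3 > n1.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param alpha significance level (default 0.05, uncorrected).
#' @return data.frame with columns \code{locus}, \code{n1}, \code{n3},
#'   \code{chi2}, \code{p}, \code{status} (factor: none /
#'   toward_recurrent / toward_heterozygote).
#' @export
classify_loci <- function(genotypes, alpha = 0.05) {
  stopifnot(is.matrix(genotypes))
  n1 <- rowSums(genotypes == 1L, na.rm = TRUE)
  n3 <- rowSums(genotypes == 3L, na.rm = TRUE)
  if (any(n1 + n3 == 0))
    stop("untestable locus (all calls missing): ",
         paste(head(rownames(genotypes)[n1 + n3 == 0], 5), collapse = ", "))
  ht <- chi_square_1to1(n1, n3)
  status <- rep("none", length(n1))
  status[ht$p < alpha & n1 > n3] <- "toward_recurrent"
  status[ht$p < alpha & n3 > n1] <- "toward_heterozygote"
  data.frame(
    locus = rownames(genotypes), n1 = as.integer(n1), n3 = as.integer(n3),
    chi2 = ht$chi2, p = ht$p,
    status = factor(status,
                    levels = c("none", "toward_recurrent",
                               "toward_heterozygote")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-marker-type distortion summary
#'
#' Aggregates per-locus distortion results by marker type into the
#' conventional report layout: total loci, distorted loci, and the skew
#' split (toward the recurrent parent vs toward the heterozygote), with a
#' Total row.
#'
#' @param results output of \code{\link{classify_loci}}.
#' @param marker_types character vector of marker types, parallel to
#'   \code{results$locus} (or named by locus).
#' @return data.frame with columns \code{marker_type}, \code{total_loci},
#'   \code{distorted}, \code{toward_recurrent}, \code{toward_heterozygote}.
#' @export
marker_type_summary <- function(results, marker_types) {
  if (!is.null(names(marker_types)))
    marker_types <- marker_types[results$locus]
  stopifnot(length(marker_types) == nrow(results))
  types <- intersect(MARKER_TYPES, unique(marker_types))
  rows <- lapply(types, function(ty) {
    r <- results[marker_types == ty, , drop = FALSE]
    data.frame(
      marker_type = ty,
      total_loci = nrow(r),
      distorted = sum(r$status != "none"),
      toward_recurrent = sum(r$status == "toward_recurrent"),
      toward_heterozygote = sum(r$status == "toward_heterozygote"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(
    marker_type = "Total",
    total_loci = sum(out$total_loci),
    distorted = sum(out$distorted),
    toward_recurrent = sum(out$toward_recurrent),
    toward_heterozygote = sum(out$toward_heterozygote),
    stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Scan a map for segregation distortion regions
#'
#' An SDR is a maximal run of at least \code{min_run} consecutive loci (in
#' map order on one linkage group) that are all distorted in the same
#' direction. SDRs are numbered globally in (group, position) order and
#' named "SDR<k>_<chromosome number>" (see
#' \code{\link{chromosome_number}}).
#'
#' @param map a \code{\link{genetic_map}}.
#' @param results output of \code{\link{classify_loci}} covering all
#'   mapped loci.
#' @param min_run minimal run length (default 3).
#' @return data.frame with columns \code{name}, \code{group},
#'   \code{direction}, \code{start_cM}, \code{end_cM}, \code{n_loci},
#'   \code{loci} (comma-joined member names).
#' @export
scan_sdrs <- function(map, results, min_run = 3) {
  stopifnot(inherits(map, "genetic_map"))
  st <- setNames(as.character(results$status), results$locus)
  missing_loci <- setdiff(map$locus, results$locus)
  if (length(missing_loci) > 0)
    stop("distortion results missing for mapped locus/loci: ",
         paste(head(missing_loci, 5), collapse = ", "))
  sdrs <- list()
  for (g in unique(map$group)) {
    gm <- map[map$group == g, , drop = FALSE]
    s <- st[gm$locus]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != "none" & r$lengths >= min_run
    for (i in which(keep)) {
      idx <- starts[i]:ends[i]
      sdrs[[length(sdrs) + 1]] <- data.frame(
        group = g,
        direction = r$values[i],
        start_cM = gm$position_cM[starts[i]],
        end_cM = gm$position_cM[ends[i]],
        n_loci = length(idx),
        loci = paste(gm$locus[idx], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(sdrs) == 0)
    return(data.frame(name = character(), group = character(),
                      direction = character(), start_cM = numeric(),
                      end_cM = numeric(), n_loci = integer(),
                      loci = character()))
  out <- do.call(rbind, sdrs)
  out <- out[order(match(out$group, unique(map$group)), out$start_cM),
             , drop = FALSE]
  out <- cbind(
    name = sprintf("SDR%d_%d", seq_len(nrow(out)),
                   chromosome_number(out$group)),
    out)
  out$name <- as.character(out$name)
  rownames(out) <- NULL
  out
}
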