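# Locus-density binning, cluster / gene-island / retrotransposon-region
# calling, and duplicated-locus (multi-locus marker) analysis.

#' Bin locus density along each linkage group
#'
#' Counts loci in half-open bins [k*w, (k+1)*w) of width \code{width}
#' (default 10 cM). The last bin is closed on the right so a locus at the
#' group maximum is counted once; bins tile [0, group length].
#'
#' @param map a \code{\link{genetic_map}}.
#' @param width bin width in cM (> 0).
#' @return data.frame with columns \code{group}, \code{bin_start},
#'   \code{bin_end}, \code{count}, \code{peak} (logical: bin(s) with the
#'   per-group maximal count).
#' @export
bin_density <- function(map, width = 10.0) {
  stopifnot(inherits(map, "genetic_map"), nrow(map) > 0)
  if (width <= 0) stop("bin width must be > 0")
  out <- lapply(split(map$position_cM, map$group), function(p) {
    n_bins <- max(1L, as.integer(ceiling(max(p) / width - 1e-9)))
    idx <- pmin(floor(p / width), n_bins - 1)  # last bin absorbs the max
    counts <- tabulate(idx + 1L, nbins = n_bins)
    data.frame(bin_start = (seq_len(n_bins) - 1) * width,
               bin_end = seq_len(n_bins) * width,
               count = counts,
               peak = counts == max(counts))
  })
  groups <- rep(names(out), vapply(out, nrow, integer(1)))
  out <- do.call(rbind, out)
  out <- cbind(group = groups, out)
  rownames(out) <- NULL
  out
}

# Maximal index windows [i, j] over sorted positions with span <= window
# and >= min_loci members; overlapping qualifying windows are merged.
.qualifying_runs <- function(pos, min_loci, window) {
  n <- length(pos)
  runs <- list()
  j <- 1
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && pos[j + 1] - pos[i] <= window + 1e-9) j <- j + 1
    if (j - i + 1 >= min_loci) runs[[length(runs) + 1]] <- c(i, j)
  }
  if (length(runs) == 0) return(list())
  # merge overlapping windows into maximal clusters
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], r[2]))
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  merged
}

#' Detect locus clusters, gene islands and retrotransposon-rich regions
#'
#' A cluster is a maximal set of at least \code{min_loci} loci falling
#' within a sliding window of \code{window} cM (default ">= 5 loci/cM");
#' overlapping qualifying windows are merged. Each cluster is classified:
#' \emph{gene_island} if some window of \code{window} cM inside it holds
#' >= \code{min_island} EST-derived (eSSR) loci; \emph{retro_rich} if
#' REMAP loci make up more than \code{retro_fraction} of members;
#' otherwise \emph{generic}.
#'
#' @param map a \code{\link{genetic_map}}.
#' @param min_loci minimal cluster size (default 5).
#' @param window window span in cM (default 1.0).
#' @param min_island minimal eSSR count for a gene island (default 5).
#' @param retro_fraction REMAP share above which a cluster is called
#'   retrotransposon-rich (default 0.5, strict).
#' @return data.frame with columns \code{group}, \code{start_cM},
#'   \code{end_cM}, \code{n_loci}, \code{n_eSSR}, \code{n_REMAP},
#'   \code{kind}, \code{loci}.
#' @export
detect_clusters <- function(map, min_loci = 5, window = 1.0,
                            min_island = 5, retro_fraction = 0.5) {
  stopifnot(inherits(map, "genetic_map"))
  res <- list()
  for (g in unique(map$group)) {
    gm <- map[map$group == g, , drop = FALSE]
    for (r in .qualifying_runs(gm$position_cM, min_loci, window)) {
      idx <- r[1]:r[2]
      types <- gm$marker_type[idx]
      pos <- gm$position_cM[idx]
      n_essr <- sum(types == "eSSR")
      n_remap <- sum(types == "REMAP")
      # gene island: >= min_island eSSR loci within one window span
      epos <- pos[types == "eSSR"]
      island <- FALSE
      if (n_essr >= min_island) {
        for (a in seq_len(length(epos) - min_island + 1)) {
          if (epos[a + min_island - 1] - epos[a] <= window + 1e-9) {
            island <- TRUE
            break
          }
        }
      }
      kind <- if (island) "gene_island"
              else if (n_remap > retro_fraction * length(idx)) "retro_rich"
              else "generic"
      res[[length(res) + 1]] <- data.frame(
        group = g, start_cM = min(pos), end_cM = max(pos),
        n_loci = length(idx), n_eSSR = n_essr, n_REMAP = n_remap,
        kind = kind, loci = paste(gm$locus[idx], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    return(data.frame(group = character(), start_cM = numeric(),
                      end_cM = numeric(), n_loci = integer(),
                      n_eSSR = integer(), n_REMAP = integer(),
                      kind = character(), loci = character()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Homoeologous partner of a cotton linkage group
#'
#' A-subgenome group \code{Ai} pairs with D-subgenome group \code{Di}
#' (shared index). Labels without an A/D prefix and numeric index have no
#' partner (NA).
#'
#' @param group character vector of group labels.
#' @return character vector of partner labels.
#' @export
homoeologous_partner <- function(group) {
  idx <- sub("^[AD]", "", group)
  ok <- grepl("^[AD][0-9]+$", group)
  partner <- ifelse(startsWith(group, "A"), paste0("D", idx),
                    paste0("A", idx))
  ifelse(ok, partner, NA_character_)
}

#' Analyze duplicated loci (multi-locus markers)
#'
#' Markers that map to two or more loci reveal duplication in the
#' allotetraploid genome. This computes the multiplicity histogram
#' (markers mapping to m loci, m >= 2), the duplicated-locus total
#' (sum of m over those markers), and classifies every duplicated locus:
#' \emph{homoeologous} when its marker also hits the homoeologous partner
#' group (Ai <-> Di), else \emph{same_chromosome} when the marker hits the
#' same group again, else \emph{different_nonhomoeologous}.
#'
#' @param map a \code{\link{genetic_map}}.
#' @param marker_to_loci data.frame with columns \code{marker},
#'   \code{locus} (one row per mapped locus of the marker).
#' @return list of class \code{duplication_table}: \code{loci}
#'   (per-duplicated-locus data.frame with the class column),
#'   \code{histogram} (multiplicity -> marker count), and \code{summary}
#'   (totals and percentages to 2 decimals).
#' @export
analyze_duplication <- function(map, marker_to_loci) {
  stopifnot(inherits(map, "genetic_map"),
            all(c("marker", "locus") %in% names(marker_to_loci)))
  unknown <- setdiff(marker_to_loci$locus, map$locus)
  if (length(unknown) > 0)
    stop("marker mapping refers to unknown locus/loci: ",
         paste(head(unknown, 5), collapse = ", "))
  grp <- setNames(map$group, map$locus)
  mt <- marker_to_loci
  mt$group <- grp[mt$locus]
  mult <- table(mt$marker)
  dup_markers <- names(mult)[mult >= 2]
  mt <- mt[mt$marker %in% dup_markers, , drop = FALSE]
  hist_tab <- table(as.integer(mult[dup_markers]))
  histogram <- setNames(as.integer(hist_tab), names(hist_tab))

  cls <- character(nrow(mt))
  if (nrow(mt) > 0) {
    groups_by_marker <- split(mt$group, mt$marker)
    partner <- homoeologous_partner(mt$group)
    for (i in seq_len(nrow(mt))) {
      others <- groups_by_marker[[mt$marker[i]]]
      # remove this locus's own contribution once
      others <- others[-match(mt$group[i], others)]
      cls[i] <- if (!is.na(partner[i]) && partner[i] %in% others)
        "homoeologous"
      else if (mt$group[i] %in% others) "same_chromosome"
      else "different_nonhomoeologous"
    }
  }
  mt$class <- cls
  n_dup_loci <- nrow(mt)
  n_hom <- sum(cls == "homoeologous")
  n_same <- sum(cls == "same_chromosome")
  n_diff <- sum(cls == "different_nonhomoeologous")
  n_nonhom <- n_same + n_diff
  pct <- function(a, b) if (b > 0) round_half_up(100 * a / b, 2) else NA_real_
  out <- list(
    loci = mt[, c("marker", "locus", "group", "class")],
    histogram = histogram,
    summary = list(
      n_markers = length(dup_markers),
      n_duplicated_loci = n_dup_loci,
      n_homoeologous = n_hom,
      n_nonhomoeologous = n_nonhom,
      pct_homoeologous = pct(n_hom, n_dup_loci),
      pct_same_of_nonhom = pct(n_same, n_nonhom),
      pct_different_of_nonhom = pct(n_diff, n_nonhom)
    )
  )
  class(out) <- "duplication_table"
  out
}

#' @export
print.duplication_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%d duplicated loci from %d markers (multiplicity: %s)\n",
              s$n_duplicated_loci, s$n_markers,
              paste(sprintf("%sx:%d", names(x$histogram), x$histogram),
                    collapse = ", ")))
  cat(sprintf("homoeologous bridging: %d loci (%.2f%%); non-homoeologous: %d\n",
              s$n_homoeologous, s$pct_homoeologous, s$n_nonhomoeologous))
  invisible(x)
}

#' Detect reciprocal-translocation signals from duplicated loci
#'
#' For a candidate reciprocal translocation between A-subgenome
#' chromosomes (Ai, Aj), supporting duplicated loci are markers bridging
#' Ai with Dj (the homoeolog of the partner) and, symmetrically, Aj with
#' Di. Counts are marker-level bridge pairs.
#'
#' @param dup a \code{\link{analyze_duplication}} result.
#' @param candidate_pairs list of 2-vectors of A-group labels (default
#'   the cotton A2/A3 and A4/A5 candidates).
#' @return data.frame with columns \code{pair}, \code{n_first_cross}
#'   (Ai <-> Dj), \code{n_second_cross} (Aj <-> Di), \code{n_support}.
#' @export
detect_translocation_signals <- function(dup,
    candidate_pairs = list(c("A2", "A3"), c("A4", "A5"))) {
  stopifnot(inherits(dup, "duplication_table"))
  groups_by_marker <- split(dup$loci$group, dup$loci$marker)
  count_bridge <- function(x, y) {
    sum(vapply(groups_by_marker,
               function(g) (x %in% g) && (y %in% g), logical(1)))
  }
  rows <- lapply(candidate_pairs, function(p) {
    if (length(p) != 2 || any(!grepl("^[AD][0-9]+$", p)))
      stop("candidate pair must be two subgenome group labels: ",
           paste(p, collapse = "/"))
    di <- homoeologous_partner(p[1])
    dj <- homoeologous_partner(p[2])
    n1 <- count_bridge(p[1], dj)   # Ai with homoeolog of Aj
    n2 <- count_bridge(p[2], di)   # Aj with homoeolog of Ai
    data.frame(pair = paste(p, collapse = "/"),
               n_first_cross = n1, n_second_cross = n2,
               n_support = n1 + n2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
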