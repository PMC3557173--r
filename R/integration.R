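# Anchored-sequence clustering, unigene selection, and QTL-gene
# integration by genetic-distance windows.

#' Fiber-quality trait codes
#'
#' FL = fiber length, FS = fiber strength, FF = fiber fineness,
#' FE = fiber elongation, FU = fiber uniformity.
#'
#' @export
QTL_TRAITS <- c("FL", "FS", "FF", "FE", "FU")

#' Read a QTL table
#'
#' Tab-separated with header columns \code{trait}, \code{group},
#' \code{start_cM}, \code{end_cM}, optionally \code{peak_cM} and
#' \code{source}.
#'
#' @param path file path.
#' @return validated data.frame of class \code{qtl_table}.
#' @export
read_qtl <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  qtl_table(df)
}

#' Construct/validate a QTL table
#'
#' @param df data.frame with columns \code{trait} (one of
#'   \code{\link{QTL_TRAITS}}), \code{group}, \code{start_cM},
#'   \code{end_cM}; optional \code{peak_cM}, \code{source}.
#' @return validated data.frame of class \code{qtl_table} with a
#'   \code{qtl_id} column added.
#' @export
qtl_table <- function(df) {
  need <- c("trait", "group", "start_cM", "end_cM")
  stopifnot(all(need %in% names(df)))
  df <- as.data.frame(df)
  bad <- setdiff(unique(df$trait), QTL_TRAITS)
  if (length(bad) > 0)
    stop("unknown trait(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(QTL_TRAITS, collapse = "/"), ")")
  if (any(df$start_cM > df$end_cM))
    stop("QTL intervals must satisfy start_cM <= end_cM")
  if (is.null(df$peak_cM)) df$peak_cM <- NA_real_
  if (is.null(df$source)) df$source <- NA_character_
  if (is.null(df$qtl_id))
    df$qtl_id <- sprintf("q%s_%s_%d", df$trait, df$group,
                         stats::ave(seq_len(nrow(df)),
                                    paste(df$trait, df$group),
                                    FUN = seq_along))
  class(df) <- c("qtl_table", "data.frame")
  df
}

#' Group anchored sequences into per-marker clusters
#'
#' One cluster per marker with at least one in silico PCR hit, carrying
#' all map positions of that marker (multi-locus markers yield
#' multi-position clusters) and its anchored template members.
#'
#' @param anchors an \code{\link{anchor_pool}} result.
#' @param map a \code{\link{genetic_map}}.
#' @param marker_to_loci optional data.frame (\code{marker},
#'   \code{locus}) for markers whose locus names differ from the marker
#'   name; by default a marker maps to the locus of the same name.
#' @return list of class \code{anchor_clusters}: per marker a list with
#'   \code{marker}, \code{positions} (data.frame group/position_cM),
#'   \code{members} (data.frame template/species/kind). Markers with hits
#'   but no mapped locus are collected in attribute \code{unmapped} (with
#'   a warning).
#' @export
build_clusters <- function(anchors, map, marker_to_loci = NULL) {
  stopifnot(inherits(anchors, "anchor_table"), inherits(map, "genetic_map"))
  h <- anchors$hits
  markers <- unique(h$marker)
  if (is.null(marker_to_loci))
    marker_to_loci <- data.frame(marker = map$locus, locus = map$locus,
                                 stringsAsFactors = FALSE)
  pos_by_marker <- split(marker_to_loci$locus, marker_to_loci$marker)
  mappos <- setNames(map$position_cM, map$locus)
  mapgrp <- setNames(map$group, map$locus)
  unmapped <- character(0)
  clusters <- list()
  for (m in markers) {
    loci <- intersect(pos_by_marker[[m]], map$locus)
    # markers absent from the mapping default to the same-name locus
    if (length(loci) == 0 && m %in% map$locus) loci <- m
    if (length(loci) == 0) {
      unmapped <- c(unmapped, m)
      positions <- data.frame(locus = character(), group = character(),
                              position_cM = numeric())
    } else {
      positions <- data.frame(locus = loci, group = unname(mapgrp[loci]),
                              position_cM = unname(mappos[loci]),
                              stringsAsFactors = FALSE)
    }
    hm <- h[h$marker == m, , drop = FALSE]
    members <- unique(hm[, c("template", "species", "kind")])
    rownames(members) <- NULL
    clusters[[m]] <- list(marker = m, positions = positions,
                          members = members)
  }
  if (length(unmapped) > 0)
    warning(length(unmapped), " marker(s) with hits absent from map: ",
            paste(head(unmapped, 5), collapse = ", "))
  attr(clusters, "unmapped") <- unmapped
  class(clusters) <- "anchor_clusters"
  clusters
}

# Longest suffix(a)/prefix(b) overlap of length >= min_overlap with
# mismatch fraction <= 1 - min_identity; 0 if none.
.best_overlap <- function(a, b, min_overlap, min_identity) {
  la <- nchar(a)
  lb <- nchar(b)
  if (min(la, lb) < min_overlap) return(0L)
  for (ov in seq(min(la, lb), min_overlap)) {
    sa <- charToRaw(substr(a, la - ov + 1, la))
    sb <- charToRaw(substr(b, 1, ov))
    if (sum(sa != sb) <= (1 - min_identity) * ov) return(ov)
  }
  0L
}

#' Select a representative unigene for an anchored cluster
#'
#' Greedy assembly of the cluster's member sequences: repeatedly merge
#' the pair with the longest suffix/prefix overlap of at least
#' \code{min_overlap} bp at identity >= \code{min_identity} (bases from
#' the left sequence win inside the overlap), until no merge applies.
#' The representative is the longest resulting sequence; provenance
#' records whether it arose from a merge (\code{merged_consensus}) or is
#' an untouched member (\code{longest_member}).
#'
#' @param seqs named character vector of member sequences (or a list with
#'   \code{$seq}).
#' @param min_overlap minimal overlap in bp (default 40).
#' @param min_identity minimal overlap identity (default 0.95).
#' @return list of class \code{unigene}: \code{seq}, \code{length},
#'   \code{provenance}, \code{n_members}.
#' @export
select_unigene <- function(seqs, min_overlap = 40, min_identity = 0.95) {
  if (is.list(seqs) && !is.null(seqs$seq)) seqs <- seqs$seq
  seqs <- toupper(as.character(seqs))
  stopifnot(length(seqs) >= 1, all(nchar(seqs) > 0))
  n_members <- length(seqs)
  merged_flag <- rep(FALSE, length(seqs))
  repeat {
    n <- length(seqs)
    if (n < 2) break
    best <- c(0L, 0L, 0L)  # ov, i, j
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (min(nchar(seqs[i]), nchar(seqs[j])) < min_overlap) next
      ov <- .best_overlap(seqs[i], seqs[j], min_overlap, min_identity)
      if (ov > best[1]) best <- c(ov, i, j)
    }
    if (best[1] == 0L) break
    i <- best[2]; j <- best[3]; ov <- best[1]
    merged <- paste0(seqs[i], substr(seqs[j], ov + 1, nchar(seqs[j])))
    keep <- setdiff(seq_len(n), c(i, j))
    seqs <- c(seqs[keep], merged)
    merged_flag <- c(merged_flag[keep], TRUE)
  }
  top <- which.max(nchar(seqs))
  out <- list(seq = seqs[top], length = nchar(seqs[top]),
              provenance = if (merged_flag[top]) "merged_consensus"
                           else "longest_member",
              n_members = n_members)
  class(out) <- "unigene"
  out
}

#' @export
print.unigene <- function(x, ...) {
  cat(sprintf("unigene: %d bp (%s) from %d member sequence(s)\n",
              x$length, x$provenance, x$n_members))
  invisible(x)
}

#' Integrate anchored clusters with QTL intervals
#'
#' QTL whose flanking-marker interval is wider than \code{max_interval}
#' (default 20 cM) are excluded. Each retained QTL is assigned every
#' cluster with at least one mapped position inside its closed interval
#' on the same linkage group; each (QTL, cluster) pair counts once. The
#' summary is a per-chromosome matrix of QTL counts by trait plus
#' assigned-gene counts, with At/Dt subtotals and grand totals.
#'
#' @param qtls a \code{\link{qtl_table}}.
#' @param map a \code{\link{genetic_map}} (QTL groups must exist in it).
#' @param clusters an \code{\link{build_clusters}} result.
#' @param max_interval maximal QTL interval width in cM (default 20).
#' @return list of class \code{qtl_integration}: \code{records}
#'   (per retained QTL: qtl_id, trait, group, start, end, n_assigned,
#'   markers, zero-assignment flag), \code{excluded} (qtl_ids filtered by
#'   width), and \code{summary} (Table-2-style data.frame).
#' @export
integrate_qtl <- function(qtls, map, clusters, max_interval = 20.0) {
  stopifnot(inherits(qtls, "data.frame"), inherits(map, "genetic_map"),
            inherits(clusters, "anchor_clusters"))
  bad <- setdiff(unique(qtls$group), unique(map$group))
  if (length(bad) > 0)
    stop("QTL group(s) absent from map: ", paste(bad, collapse = ", "))
  width <- qtls$end_cM - qtls$start_cM
  excluded <- qtls$qtl_id[width > max_interval]
  keep <- qtls[width <= max_interval, , drop = FALSE]

  # flatten cluster positions once
  pos <- do.call(rbind, lapply(clusters, function(cl) {
    if (nrow(cl$positions) == 0) return(NULL)
    data.frame(marker = cl$marker, group = cl$positions$group,
               position_cM = cl$positions$position_cM,
               stringsAsFactors = FALSE)
  }))
  records <- lapply(seq_len(nrow(keep)), function(i) {
    q <- keep[i, ]
    assigned <- character(0)
    if (!is.null(pos)) {
      inq <- pos$group == q$group & pos$position_cM >= q$start_cM &
        pos$position_cM <= q$end_cM
      assigned <- unique(pos$marker[inq])
    }
    data.frame(qtl_id = q$qtl_id, trait = q$trait, group = q$group,
               start_cM = q$start_cM, end_cM = q$end_cM,
               n_assigned = length(assigned),
               markers = paste(assigned, collapse = ","),
               no_gene = length(assigned) == 0,
               stringsAsFactors = FALSE)
  })
  records <- if (length(records) > 0) do.call(rbind, records) else
    data.frame(qtl_id = character(), trait = character(),
               group = character(), start_cM = numeric(),
               end_cM = numeric(), n_assigned = integer(),
               markers = character(), no_gene = logical())
  rownames(records) <- NULL
  out <- list(records = records, excluded = excluded,
              summary = .integration_summary(records))
  class(out) <- "qtl_integration"
  out
}

# Table-2-style layout: rows = chromosomes, trait columns qFE..qFU, QTL
# total and distinct assigned genes, with At/Dt subtotals + grand total.
.integration_summary <- function(records) {
  trait_cols <- paste0("q", c("FE", "FL", "FF", "FS", "FU"))
  groups <- unique(records$group)
  groups <- groups[order(subgenome_of(groups), chromosome_number(groups))]
  row_for <- function(r, label) {
    counts <- vapply(c("FE", "FL", "FF", "FS", "FU"),
                     function(tr) sum(r$trait == tr), integer(1))
    genes <- unique(unlist(strsplit(r$markers[r$markers != ""], ",")))
    df <- data.frame(chromosome = label, t(counts),
                     qtl_total = nrow(r), n_genes = length(genes),
                     stringsAsFactors = FALSE)
    names(df) <- c("chromosome", trait_cols, "qtl_total", "n_genes")
    df
  }
  rows <- lapply(groups, function(g)
    row_for(records[records$group == g, , drop = FALSE], g))
  sub_rows <- lapply(c("At", "Dt"), function(sg) {
    r <- records[!is.na(subgenome_of(records$group)) &
                   subgenome_of(records$group) == sg, , drop = FALSE]
    if (nrow(r) == 0 && !any(subgenome_of(groups) %in% sg)) return(NULL)
    row_for(r, paste0(sg, "_subtotal"))
  })
  out <- do.call(rbind, c(rows, sub_rows, list(row_for(records, "Total"))))
  rownames(out) <- NULL
  out
}

#' @export
print.qtl_integration <- function(x, ...) {
  tot <- x$summary[x$summary$chromosome == "Total", ]
  cat(sprintf(
    "%d QTL retained (%d excluded by interval width), %d ESTs/genes assigned\n",
    tot$qtl_total, length(x$excluded), tot$n_genes))
  invisible(x)
}

#' Cluster QTL by interval overlap
#'
#' Single-linkage grouping of QTL on the same chromosome whose closed
#' intervals overlap; a cluster is multi-trait when its members span two
#' or more traits. Output is independent of input order.
#'
#' @param qtls a \code{\link{qtl_table}}.
#' @return data.frame with columns \code{cluster_id}, \code{group},
#'   \code{start_cM}, \code{end_cM} (union span), \code{n_qtl},
#'   \code{traits}, \code{multi_trait}, \code{members}.
#' @export
cluster_qtl <- function(qtls) {
  stopifnot(inherits(qtls, "data.frame"))
  if (nrow(qtls) == 0)
    return(data.frame(cluster_id = character(), group = character(),
                      start_cM = numeric(), end_cM = numeric(),
                      n_qtl = integer(), traits = character(),
                      multi_trait = logical(), members = character()))
  res <- list()
  for (g in sort(unique(qtls$group))) {
    q <- qtls[qtls$group == g, , drop = FALSE]
    q <- q[order(q$start_cM, q$end_cM, q$qtl_id), , drop = FALSE]
    # single linkage on sorted intervals: extend while next start <= max end
    cl_start <- 1
    cur_end <- q$end_cM[1]
    bounds <- list()
    if (nrow(q) > 1) for (i in 2:nrow(q)) {
      if (q$start_cM[i] <= cur_end) {
        cur_end <- max(cur_end, q$end_cM[i])
      } else {
        bounds[[length(bounds) + 1]] <- c(cl_start, i - 1)
        cl_start <- i
        cur_end <- q$end_cM[i]
      }
    }
    bounds[[length(bounds) + 1]] <- c(cl_start, nrow(q))
    for (b in bounds) {
      idx <- b[1]:b[2]
      traits <- sort(unique(q$trait[idx]))
      res[[length(res) + 1]] <- data.frame(
        group = g, start_cM = min(q$start_cM[idx]),
        end_cM = max(q$end_cM[idx]), n_qtl = length(idx),
        traits = paste(traits, collapse = ","),
        multi_trait = length(traits) >= 2,
        members = paste(sort(q$qtl_id[idx]), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$group, out$start_cM), , drop = FALSE]
  out <- cbind(cluster_id = sprintf("QC%d", seq_len(nrow(out))), out)
  out$cluster_id <- as.character(out$cluster_id)
  rownames(out) <- NULL
  out
}
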