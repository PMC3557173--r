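# In silico PCR: mismatch-bounded primer-site search (pigeonhole seeding +
# Hamming verification), convergent forward-reverse amplicon prediction,
# and X-drop seed-and-extend matching for long (BAC) templates.
#
# Coordinates are 1-based inclusive throughout (the R/IRanges idiom); the
# GFF3 writer therefore emits them unchanged.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a primer-pair table
#'
#' Tab-separated with header columns \code{marker}, \code{forward},
#' \code{reverse}; sequences must be unambiguous A/C/G/T.
#'
#' @param path file path.
#' @return data.frame of class \code{primer_table}.
#' @export
read_primers <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  primer_table(df)
}

#' Construct/validate a primer-pair table
#'
#' @param df data.frame with columns \code{marker}, \code{forward},
#'   \code{reverse}.
#' @return validated data.frame of class \code{primer_table}.
#' @export
primer_table <- function(df) {
  need <- c("marker", "forward", "reverse")
  stopifnot(all(need %in% names(df)))
  df <- as.data.frame(df)[, need]
  df[] <- lapply(df, as.character)
  df$forward <- toupper(df$forward)
  df$reverse <- toupper(df$reverse)
  seqs <- c(df$forward, df$reverse)
  if (any(nchar(seqs) == 0) || any(grepl("[^ACGT]", seqs)))
    stop("primer sequences must be non-empty and restricted to A/C/G/T")
  if (anyDuplicated(df$marker)) stop("marker names must be unique")
  class(df) <- c("primer_table", "data.frame")
  df
}

#' Read a template pool from FASTA
#'
#' Headers carry whitespace-separated tokens after the id, e.g.
#' \code{">EST0001 species=Gh kind=EST"}. Missing tokens default to
#' species NA and kind "EST".
#'
#' @param path FASTA file path.
#' @return data.frame of class \code{template_pool} with columns
#'   \code{id}, \code{species}, \code{kind}, \code{seq}.
#' @export
read_templates <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  grab <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
    out <- rep(NA_character_, length(hdr))
    hit <- grepl(paste0(key, "="), hdr)
    out[hit] <- sub(paste0(key, "="), "", m)
    out
  }
  kind <- grab("kind")
  kind[is.na(kind)] <- "EST"
  template_pool(data.frame(id = id, species = grab("species"), kind = kind,
                           seq = toupper(as.character(ss)),
                           stringsAsFactors = FALSE))
}

#' Construct/validate a template pool
#'
#' @param df data.frame with columns \code{id}, \code{species},
#'   \code{kind} ("EST" or "BAC"), \code{seq} (A/C/G/T/N).
#' @return validated data.frame of class \code{template_pool}.
#' @export
template_pool <- function(df) {
  need <- c("id", "species", "kind", "seq")
  stopifnot(all(need %in% names(df)))
  df <- as.data.frame(df)[, need]
  df$id <- as.character(df$id)
  df$seq <- toupper(as.character(df$seq))
  if (anyDuplicated(df$id)) stop("template ids must be unique")
  if (!all(df$kind %in% c("EST", "BAC")))
    stop("template kind must be EST or BAC")
  if (any(grepl("[^ACGTN]", df$seq)))
    stop("template sequences restricted to A/C/G/T/N")
  class(df) <- c("template_pool", "data.frame")
  df
}

#' Write a template pool to FASTA
#'
#' @param pool a \code{\link{template_pool}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_templates <- function(pool, path) {
  ss <- Biostrings::DNAStringSet(pool$seq)
  names(ss) <- sprintf("%s species=%s kind=%s", pool$id, pool$species,
                       pool$kind)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Split a primer into (max_mismatch + 1) contiguous segments of near-equal
# length. By pigeonhole, any end-to-end alignment with <= max_mismatch
# substitutions matches at least one segment exactly.
.pigeonhole_segments <- function(primer, max_mismatch) {
  L <- nchar(primer)
  m <- max_mismatch + 1
  if (L < m)
    stop("primer shorter than max_mismatch + 1; pigeonhole search needs ",
         m, " non-empty segments")
  base <- L %/% m
  lens <- rep(base, m)
  extra <- L %% m
  if (extra > 0) lens[seq_len(extra)] <- base + 1
  starts <- cumsum(c(1, lens[-m]))
  list(seg = substring(primer, starts, starts + lens - 1), start = starts)
}

# Pool lookup structure: templates joined by "N" so one C-level
# fixed-string scan covers the whole pool. Exact A/C/G/T segments can
# never straddle a junction (they would have to contain the N).
.pool_index <- function(seqs) {
  lens <- nchar(seqs)
  list(big = paste(seqs, collapse = "N"),
       starts = cumsum(c(1L, head(lens, -1L) + 1L)),
       lens = lens)
}

# All end-to-end sites of `primer` on the given strand of each pool
# sequence with Hamming distance <= max_mismatch. Candidate offsets come
# from exact lookup of the pigeonhole segments; verification is a
# vectorized full comparison. Returns data.frame(seq_idx, start
# [1-based], mismatches).
.sites_pool <- function(primer, index, max_mismatch) {
  L <- nchar(primer)
  praw <- charToRaw(primer)
  segs <- .pigeonhole_segments(primer, max_mismatch)
  gcand <- integer(0)
  for (si in seq_along(segs$seg)) {
    g <- gregexpr(segs$seg[si], index$big, fixed = TRUE)[[1]]
    if (g[1] != -1L)
      gcand <- c(gcand, as.integer(g) - segs$start[si] + 1L)
  }
  empty <- data.frame(seq_idx = integer(), start = integer(),
                      mismatches = integer())
  gcand <- gcand[gcand >= 1L]
  if (length(gcand) == 0) return(empty)
  gcand <- sort(unique(gcand))
  i <- findInterval(gcand, index$starts)
  s <- gcand - index$starts[i] + 1L
  ok <- s >= 1L & s + L - 1L <= index$lens[i]
  if (!any(ok)) return(empty)
  gcand <- gcand[ok]; i <- i[ok]; s <- s[ok]
  subs <- substring(index$big, gcand, gcand + L - 1L)
  mat <- matrix(charToRaw(paste(subs, collapse = "")), nrow = L)
  mm <- as.integer(colSums(mat != praw))
  keep <- mm <= max_mismatch
  data.frame(seq_idx = i[keep], start = s[keep], mismatches = mm[keep])
}

.as_seqs <- function(template) {
  if (inherits(template, "template_pool") || is.data.frame(template))
    template$seq
  else as.character(template)
}

#' Find primer binding sites on a template
#'
#' Locates every end-to-end placement of the primer on either strand of
#' the template with at most \code{max_mismatch} substitutions (Hamming
#' distance; template Ns count as mismatches). Candidate sites are seeded
#' by exact lookup of \code{max_mismatch + 1} contiguous primer segments
#' (pigeonhole: a site within the bound must match one segment exactly)
#' and verified by full comparison.
#'
#' @param primer DNA string (A/C/G/T).
#' @param template DNA string, or a one-row \code{\link{template_pool}}.
#' @param max_mismatch maximal substitution count (default 3).
#' @return data.frame with columns \code{start} (1-based position of the
#'   site on the plus strand), \code{strand} ("+": primer matches the plus
#'   strand; "-": its reverse complement does), \code{mismatches}.
#' @export
match_primer_sites <- function(primer, template, max_mismatch = 3) {
  primer <- toupper(primer)
  if (nchar(primer) < max_mismatch + 1)
    stop("primer shorter than max_mismatch + 1; pigeonhole search needs ",
         max_mismatch + 1, " non-empty segments")
  seqs <- .as_seqs(template)
  stopifnot(length(seqs) == 1)
  idx <- .pool_index(seqs)
  plus <- .sites_pool(primer, idx, max_mismatch)
  minus <- .sites_pool(revcomp(primer), idx, max_mismatch)
  out <- rbind(
    data.frame(start = plus$start, strand = rep("+", nrow(plus)),
               mismatches = plus$mismatches),
    data.frame(start = minus$start, strand = rep("-", nrow(minus)),
               mismatches = minus$mismatches))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Convergent amplicons for one primer pair over an indexed template
# pool. Site tables computed once per orientation across the whole pool.
.amplicons_pool <- function(marker, forward, reverse, index, max_mismatch,
                            min_product, max_product) {
  if (min_product > min(max_product))
    stop("min_product must be <= max_product")
  lenF <- nchar(forward)
  lenR <- nchar(reverse)
  fP <- .sites_pool(forward, index, max_mismatch)          # F on plus
  rM <- .sites_pool(revcomp(reverse), index, max_mismatch) # R on minus
  rP <- .sites_pool(reverse, index, max_mismatch)          # R on plus
  fM <- .sites_pool(revcomp(forward), index, max_mismatch) # F on minus
  max_prod <- if (length(max_product) == 1)
    rep(max_product, length(index$lens)) else max_product
  res <- list()
  emit <- function(i, start, end, strand, mmf, mmr) {
    size <- end - start + 1L
    if (size < min_product || size > max_prod[i]) return()
    res[[length(res) + 1]] <<- data.frame(
      seq_idx = i, strand = strand, start = start, end = end,
      product_size = size, mm_forward = mmf, mm_reverse = mmr,
      stringsAsFactors = FALSE)
  }
  # orientation A: forward primer on plus strand, reverse on minus,
  # reverse site downstream (convergent, 3' ends facing inward)
  for (i in intersect(unique(fP$seq_idx), unique(rM$seq_idx))) {
    f <- fP[fP$seq_idx == i, ]
    r <- rM[rM$seq_idx == i, ]
    for (a in seq_len(nrow(f))) for (b in seq_len(nrow(r))) {
      fs <- f$start[a]; rs <- r$start[b]
      if (rs >= fs && rs + lenR - 1L >= fs + lenF - 1L)
        emit(i, fs, rs + lenR - 1L, "+", f$mismatches[a], r$mismatches[b])
    }
  }
  # orientation B: forward primer on minus strand, reverse on plus
  for (i in intersect(unique(fM$seq_idx), unique(rP$seq_idx))) {
    f <- fM[fM$seq_idx == i, ]
    r <- rP[rP$seq_idx == i, ]
    for (a in seq_len(nrow(f))) for (b in seq_len(nrow(r))) {
      fs <- f$start[a]; rs <- r$start[b]
      if (fs >= rs && fs + lenF - 1L >= rs + lenR - 1L)
        emit(i, rs, fs + lenF - 1L, "-", f$mismatches[a], r$mismatches[b])
    }
  }
  if (length(res) == 0)
    return(data.frame(seq_idx = integer(), strand = character(),
                      start = integer(), end = integer(),
                      product_size = integer(), mm_forward = integer(),
                      mm_reverse = integer()))
  out <- do.call(rbind, res)
  out <- unique(out)
  out <- out[order(out$seq_idx, out$start, out$end, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict in silico PCR products on a template
#'
#' Reports every convergent ("FR") placement of a primer pair on the
#' template: the forward primer on one strand and the reverse primer on
#' the opposite strand downstream of it, both within the mismatch bound,
#' with product size (5' end of one primer to the 5' end of the other,
#' inclusive of both) inside [min_product, max_product]. Coordinates are
#' on the template plus strand, 1-based inclusive.
#'
#' @param pair list or one-row data.frame with \code{marker},
#'   \code{forward}, \code{reverse}.
#' @param template DNA string or one-row \code{\link{template_pool}}.
#' @param max_mismatch per-primer substitution bound (default 3).
#' @param min_product,max_product product-size bounds in bp.
#' @return data.frame with columns \code{marker}, \code{strand} (of the
#'   forward primer), \code{start}, \code{end}, \code{product_size},
#'   \code{mm_forward}, \code{mm_reverse}.
#' @export
find_amplicons <- function(pair, template, max_mismatch = 3,
                           min_product = 40, max_product = 5000) {
  seqs <- .as_seqs(template)
  stopifnot(length(seqs) == 1)
  hits <- .amplicons_pool(pair$marker, toupper(pair$forward),
                          toupper(pair$reverse), .pool_index(seqs),
                          max_mismatch, min_product, max_product)
  data.frame(marker = rep(pair$marker, nrow(hits)),
             hits[, c("strand", "start", "end", "product_size",
                      "mm_forward", "mm_reverse")],
             stringsAsFactors = FALSE)
}

#' Anchor a set of primer pairs to a sequence pool
#'
#' Runs \code{\link{find_amplicons}} for every marker against every
#' template and assembles an anchor table: all hits plus amplification
#' bookkeeping (markers with and without products, distinct ESTs and BACs
#' hit, success percentage).
#'
#' @param pairs a \code{\link{primer_table}}.
#' @param pool a \code{\link{template_pool}} (non-empty).
#' @param max_mismatch per-primer substitution bound (default 3).
#' @param min_product minimal product size in bp.
#' @param max_product_est,max_product_bac maximal product size for EST and
#'   BAC templates (BAC inserts admit far larger products).
#' @return object of class \code{anchor_table}: list with \code{hits}
#'   (data.frame marker/template/species/kind/strand/start/end/
#'   product_size/mm_forward/mm_reverse), \code{markers} (all queried
#'   markers) and \code{summary}.
#' @export
anchor_pool <- function(pairs, pool, max_mismatch = 3, min_product = 40,
                        max_product_est = 5000, max_product_bac = 20000) {
  stopifnot(inherits(pairs, "data.frame"))
  if (!is.data.frame(pool) || nrow(pool) == 0)
    stop("template pool is empty")
  max_prod <- ifelse(pool$kind == "BAC", max_product_bac, max_product_est)
  index <- .pool_index(pool$seq)
  res <- vector("list", nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    h <- .amplicons_pool(pairs$marker[j], pairs$forward[j],
                         pairs$reverse[j], index, max_mismatch,
                         min_product, max_prod)
    if (nrow(h) > 0) {
      res[[j]] <- data.frame(
        marker = pairs$marker[j],
        template = pool$id[h$seq_idx],
        species = pool$species[h$seq_idx],
        kind = pool$kind[h$seq_idx],
        h[, c("strand", "start", "end", "product_size", "mm_forward",
              "mm_reverse")],
        stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, res)
  if (is.null(hits))
    hits <- data.frame(marker = character(), template = character(),
                       species = character(), kind = character(),
                       strand = character(), start = integer(),
                       end = integer(), product_size = integer(),
                       mm_forward = integer(), mm_reverse = integer())
  rownames(hits) <- NULL
  n_markers <- nrow(pairs)
  with_hit <- unique(hits$marker)
  out <- list(
    hits = hits,
    markers = pairs$marker,
    summary = list(
      n_markers = n_markers,
      n_with_hit = length(with_hit),
      n_without_hit = n_markers - length(with_hit),
      n_est_hit = length(unique(hits$template[hits$kind == "EST"])),
      n_bac_hit = length(unique(hits$template[hits$kind == "BAC"])),
      success_pct = anchoring_success_pct(length(with_hit), n_markers)
    )
  )
  class(out) <- "anchor_table"
  out
}

#' Amplification success percentage
#'
#' 100 x (markers with at least one product) / (markers screened),
#' rounded half away from zero to one decimal.
#'
#' @param n_success markers with >= 1 predicted product.
#' @param n_total markers screened.
#' @return percentage to 1 decimal.
#' @export
anchoring_success_pct <- function(n_success, n_total) {
  stopifnot(n_total > 0)
  round_half_up(100 * n_success / n_total, 1)
}

#' @export
print.anchor_table <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "%d/%d primer pairs (%.1f%%) amplified products from %d ESTs and %d BACs\n",
    s$n_with_hit, s$n_markers, s$success_pct, s$n_est_hit, s$n_bac_hit))
  invisible(x)
}

#' Compare predicted product sizes across species
#'
#' Markers whose products come from two or more species are classified
#' \code{same_size} when every predicted product size is identical (exact
#' bp equality) and \code{different_size} otherwise — a simple screen for
#' insertion/deletion variation between orthologous amplicons.
#'
#' @param table an \code{\link{anchor_pool}} result.
#' @return data.frame with columns \code{marker}, \code{n_species},
#'   \code{size_class}; attribute \code{summary} carries the class
#'   counts.
#' @export
compare_product_sizes <- function(table) {
  stopifnot(inherits(table, "anchor_table"))
  h <- table$hits[!is.na(table$hits$species), , drop = FALSE]
  sp <- split(h, h$marker)
  rows <- lapply(sp, function(d) {
    ns <- length(unique(d$species))
    if (ns < 2) return(NULL)
    data.frame(marker = d$marker[1], n_species = ns,
               size_class = if (length(unique(d$product_size)) == 1)
                 "same_size" else "different_size",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(marker = character(), n_species = integer(),
                      size_class = character())
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_same = sum(out$size_class == "same_size"),
    n_different = sum(out$size_class == "different_size"))
  out
}

#' Seed-and-extend ungapped matching
#'
#' Finds high-scoring ungapped segment matches between an arbitrary query
#' and a (typically long, BAC-sized) template: every exact k-mer shared by
#' the query (either strand) and the template seeds an ungapped extension
#' in both directions that terminates when the running score drops more
#' than \code{xdrop} below its running maximum. Matches with score >=
#' \code{min_score} are reported; overlapping matches on the same
#' diagonal are collapsed to the best-scoring one.
#'
#' @param query DNA string.
#' @param template DNA string or one-row \code{\link{template_pool}}.
#' @param k seed word size (>= 4, default 12).
#' @param match,mismatch per-base scores (defaults +1 / -2).
#' @param xdrop termination threshold (default 12).
#' @param min_score minimal reported score (default 30).
#' @return data.frame with columns \code{strand}, \code{query_start},
#'   \code{query_end}, \code{template_start}, \code{template_end},
#'   \code{length}, \code{score}, \code{identity} (1-based inclusive;
#'   query coordinates on the original query).
#' @export
seed_extend <- function(query, template, k = 12, match = 1, mismatch = -2,
                        xdrop = 12, min_score = 30) {
  if (k < 4) stop("seed word size k must be >= 4")
  query <- toupper(query)
  tmpl <- toupper(.as_seqs(template))
  stopifnot(length(tmpl) == 1)
  if (nchar(query) < k) stop("query shorter than seed word size")
  res <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    m <- .extend_one_strand(q, tmpl, k, match, mismatch, xdrop, min_score)
    if (nrow(m) > 0) {
      if (strand == "-") {
        nq <- nchar(query)
        qs <- nq - m$query_end + 1L
        qe <- nq - m$query_start + 1L
        m$query_start <- qs
        m$query_end <- qe
      }
      m$strand <- strand
      res[[length(res) + 1]] <- m
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(strand = character(), query_start = integer(),
                      query_end = integer(), template_start = integer(),
                      template_end = integer(), length = integer(),
                      score = numeric(), identity = numeric()))
  out <- out[order(-out$score, out$template_start),
             c("strand", "query_start", "query_end", "template_start",
               "template_end", "length", "score", "identity")]
  rownames(out) <- NULL
  out
}

.extend_one_strand <- function(q, t, k, match, mismatch, xdrop, min_score) {
  nq <- nchar(q)
  nt <- nchar(t)
  empty <- data.frame(query_start = integer(), query_end = integer(),
                      template_start = integer(),
                      template_end = integer(), length = integer(),
                      score = numeric(), identity = numeric())
  if (nq < k || nt < k) return(empty)
  qk <- substring(q, 1:(nq - k + 1), k:nq)
  tk <- substring(t, 1:(nt - k + 1), k:nt)
  qpos_by_kmer <- split(seq_along(qk), qk)
  hit <- match(tk, names(qpos_by_kmer))
  tpos <- which(!is.na(hit))
  if (length(tpos) == 0) return(empty)
  qraw <- charToRaw(q)
  traw <- charToRaw(t)
  seeds <- do.call(rbind, lapply(tpos, function(tp) {
    cbind(q = qpos_by_kmer[[hit[tp]]], t = tp)
  }))
  diags <- seeds[, "t"] - seeds[, "q"]
  out <- list()
  for (d in unique(diags)) {
    qlo <- max(1L, 1L - d)
    qhi <- min(nq, nt - d)
    eq <- qraw[qlo:qhi] == traw[(qlo + d):(qhi + d)]
    s <- ifelse(eq, match, mismatch)
    dseeds <- sort(unique(seeds[diags == d, "q"]))
    found <- list()
    for (q0 in dseeds) {
      # skip seeds inside an already-extended interval on this diagonal
      inside <- FALSE
      for (f in found)
        if (q0 >= f[1] && q0 + k - 1 <= f[2]) { inside <- TRUE; break }
      if (inside) next
      li <- q0 - qlo + 1L          # local index of seed start
      ri <- li + k - 1L            # local index of seed end
      # right extension with X-drop
      best_r <- 0; run <- 0; rend <- ri
      i <- ri + 1L
      while (i <= length(s)) {
        run <- run + s[i]
        if (run > best_r) { best_r <- run; rend <- i }
        if (run < best_r - xdrop) break
        i <- i + 1L
      }
      # left extension with X-drop
      best_l <- 0; run <- 0; lend <- li
      i <- li - 1L
      while (i >= 1L) {
        run <- run + s[i]
        if (run > best_l) { best_l <- run; lend <- i }
        if (run < best_l - xdrop) break
        i <- i - 1L
      }
      score <- k * match + best_r + best_l
      if (score >= min_score) {
        qs <- lend + qlo - 1L
        qe <- rend + qlo - 1L
        found[[length(found) + 1]] <- c(qs, qe, score,
                                        sum(eq[lend:rend]) / (qe - qs + 1))
      }
    }
    # collapse overlapping intervals on this diagonal: keep best score
    if (length(found) > 0) {
      fm <- do.call(rbind, found)
      fm <- fm[order(fm[, 1]), , drop = FALSE]
      keep <- list(fm[1, ])
      if (nrow(fm) > 1) for (r in 2:nrow(fm)) {
        last <- keep[[length(keep)]]
        if (fm[r, 1] <= last[2]) {
          if (fm[r, 3] > last[3]) keep[[length(keep)]] <- fm[r, ]
        } else keep[[length(keep) + 1]] <- fm[r, ]
      }
      for (kk in keep) {
        out[[length(out) + 1]] <- data.frame(
          query_start = as.integer(kk[1]), query_end = as.integer(kk[2]),
          template_start = as.integer(kk[1] + d),
          template_end = as.integer(kk[2] + d),
          length = as.integer(kk[2] - kk[1] + 1),
          score = kk[3], identity = kk[4])
      }
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Write anchor hits as GFF3
#'
#' One \code{PCR_product} feature per hit with attributes marker,
#' mismatches (forward+reverse) and product_size; 1-based inclusive
#' coordinates per the GFF3 convention.
#'
#' @param table an \code{\link{anchor_pool}} result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_anchors_gff <- function(table, path) {
  stopifnot(inherits(table, "anchor_table"))
  h <- table$hits
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(h) > 0) {
    lines <- sprintf(
      "%s\tcottonmap\tPCR_product\t%d\t%d\t.\t%s\t.\tmarker=%s;mismatches=%d;product_size=%d",
      h$template, h$start, h$end, h$strand, h$marker,
      h$mm_forward + h$mm_reverse, h$product_size)
    writeLines(lines, con)
  }
  invisible(path)
}
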