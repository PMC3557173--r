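# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly k positions with different bases
.mutate_test <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  for (i in sample(length(ch), k))
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# Naive full-scan primer-site search: slide the primer over every offset
# of both strands and count mismatches by vectorized byte comparison.
# Deliberately a different algorithm from the pigeonhole engine.
naive_sites <- function(primer, tmpl, max_mm) {
  out <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") primer else revcomp(primer)
    pr <- charToRaw(p)
    tr <- charToRaw(tmpl)
    L <- length(pr)
    n <- length(tr)
    if (n < L) next
    mm <- integer(n - L + 1)
    for (j in seq_len(L)) mm <- mm + as.integer(tr[j:(n - L + j)] != pr[j])
    hit <- which(mm <= max_mm)
    if (length(hit) > 0)
      out[[strand]] <- data.frame(start = hit, strand = strand,
                                  mismatches = mm[hit])
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Exhaustive per-diagonal best-window (max subarray) scan for ungapped
# matching, over both query strands.
diagonal_best_score <- function(query, tmpl, match = 1, mismatch = -2) {
  best <- -Inf
  for (q in c(query, revcomp(query))) {
    qr <- charToRaw(q)
    tr <- charToRaw(tmpl)
    nq <- length(qr)
    nt <- length(tr)
    for (d in (1 - nq):(nt - 1)) {
      qlo <- max(1, 1 - d)
      qhi <- min(nq, nt - d)
      if (qhi < qlo) next
      s <- ifelse(qr[qlo:qhi] == tr[(qlo + d):(qhi + d)], match, mismatch)
      # Kadane
      run <- 0
      for (v in s) {
        run <- max(v, run + v)
        if (run > best) best <- run
      }
    }
  }
  best
}

# Brute-force cluster oracle: enumerate all maximal subranges with
# span <= window and size >= min_loci, then merge overlapping ranges.
brute_clusters <- function(pos, min_loci, window) {
  n <- length(pos)
  ranges <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (pos[j] - pos[i] > window + 1e-9) break
    if (j - i + 1 >= min_loci) {
      maximal <- (i == 1 || pos[j] - pos[i - 1] > window + 1e-9) &&
        (j == n || pos[j + 1] - pos[i] > window + 1e-9)
      if (maximal) ranges[[length(ranges) + 1]] <- c(i, j)
    }
  }
  if (length(ranges) == 0) return(list())
  ranges <- ranges[order(vapply(ranges, `[`, numeric(1), 1))]
  merged <- list(ranges[[1]])
  for (r in ranges[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] <= last[2])
      merged[[length(merged)]] <- c(last[1], max(last[2], r[2]))
    else merged[[length(merged) + 1]] <- r
  }
  merged
}

# all permutations of 1:n (tiny n): insert n into every slot of each
# permutation of 1:(n-1)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) for (i in 0:(n - 1))
    out[[length(out) + 1]] <- append(p, n, after = i)
  out
}

# sequential chain merge with exact suffix/prefix overlaps >= min_overlap;
# -Inf when some consecutive pair has no such overlap
chain_merge_len <- function(frags, min_overlap) {
  s <- frags[1]
  for (f in frags[-1]) {
    la <- nchar(s); lb <- nchar(f)
    ovs <- seq(min(la, lb), min_overlap)
    ok <- FALSE
    for (ov in ovs) {
      if (substr(s, la - ov + 1, la) == substr(f, 1, ov)) {
        s <- paste0(s, substr(f, ov + 1, lb))
        ok <- TRUE
        break
      }
    }
    if (!ok) return(-Inf)
  }
  nchar(s)
}

# quick genetic map from positions on one or more groups
toy_map <- function(pos, group = "Chr2", marker_type = "gSSR",
                    locus = NULL) {
  if (is.null(locus)) locus <- sprintf("%s_L%03d", group, seq_along(pos))
  genetic_map(data.frame(locus = locus, marker_type = marker_type,
                         group = group, position_cM = pos,
                         stringsAsFactors = FALSE))
}

# genotype matrix realizing exact (n1, n3) counts for each locus
geno_from_counts <- function(n1, n3, loci = NULL) {
  n <- max(n1 + n3)
  if (is.null(loci)) loci <- sprintf("L%03d", seq_along(n1))
  m <- t(vapply(seq_along(n1), function(i) {
    c(rep(1L, n1[i]), rep(3L, n3[i]), rep(NA_integer_, n - n1[i] - n3[i]))
  }, integer(n)))
  rownames(m) <- loci
  colnames(m) <- sprintf("I%03d", seq_len(n))
  genotype_matrix(m)
}

# Per-type distorted-locus counts as printed in the study's marker-type
# table; shipped as a plain-text fixture.
table1_fixture <- function() {
  read.delim(system.file("extdata", "distortion_by_type.tsv",
                         package = "cottonmap"),
             check.names = FALSE, stringsAsFactors = FALSE)
}
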