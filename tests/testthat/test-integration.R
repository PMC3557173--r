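# Anchored-cluster building, unigene selection, QTL integration and
# QTL clustering.

make_anchor_table <- function(markers, templates = NULL,
                              species = "Gh", kind = "EST") {
  if (is.null(templates)) templates <- paste0("T_", markers)
  structure(list(
    hits = data.frame(marker = markers, template = templates,
                      species = species, kind = kind, strand = "+",
                      start = 1L, end = 100L, product_size = 100L,
                      mm_forward = 0L, mm_reverse = 0L,
                      stringsAsFactors = FALSE),
    markers = unique(markers), summary = NULL), class = "anchor_table")
}

test_that("cluster building carries map positions and warns on unmapped", {
  m <- toy_map(c(5, 15, 25, 35), group = "A1",
               locus = c("mk1", "mk2", "mk3", "mk4"))
  anchors <- make_anchor_table(c("mk1", "mk1", "mk3", "mk3", "mk3", "mk3"),
                               sprintf("E%d", 1:6))
  cl <- build_clusters(anchors, m)
  expect_length(cl, 2)
  expect_equal(nrow(cl[["mk3"]]$members), 4)
  expect_equal(cl[["mk1"]]$positions$position_cM, 5)
  # cluster count equals distinct markers with >= 1 hit
  expect_equal(length(cl), length(unique(anchors$hits$marker)))

  # multi-locus marker via explicit mapping
  m2l <- data.frame(marker = c("mk1", "mk1"), locus = c("mk1", "mk4"))
  cl2 <- build_clusters(anchors, m, m2l)
  expect_equal(cl2[["mk1"]]$positions$position_cM, c(5, 35))

  # marker with hits but absent from map -> warning, not failure
  anchors2 <- make_anchor_table(c("mk1", "ghost"))
  expect_warning(cl3 <- build_clusters(anchors2, m), "ghost")
  expect_equal(attr(cl3, "unmapped"), "ghost")
})

test_that("unigene selection merges overlaps greedily with fallback", {
  set.seed(17)
  a <- random_dna(300)
  overlap <- substr(a, 251, 300)
  b <- paste0(overlap, random_dna(250))
  u <- select_unigene(c(a, b), min_overlap = 40)
  expect_equal(u$length, 550)
  expect_equal(u$provenance, "merged_consensus")

  # mutually non-overlapping members fall back to the longest
  u2 <- select_unigene(c(random_dna(200), random_dna(350),
                         random_dna(280)))
  expect_equal(u2$length, 350)
  expect_equal(u2$provenance, "longest_member")

  # never shorter than the longest member; bounded by best-order merge
  for (s in 1:8) {
    set.seed(400 + s)
    n <- sample(2:4, 1)
    frags <- character(n)
    backbone <- random_dna(150 * n)
    for (i in seq_len(n))
      frags[i] <- substr(backbone, (i - 1) * 100 + 1, (i - 1) * 100 + 160)
    frags <- sample(frags)
    u <- select_unigene(frags, min_overlap = 40)
    expect_gte(u$length, max(nchar(frags)))
    # exhaustive-ordering oracle: greedy cannot beat the best chain
    best <- max(vapply(
      combinat_perms(n), function(ord) chain_merge_len(frags[ord], 40),
      numeric(1)))
    expect_lte(u$length, best)
    expect_equal(u$length, (n - 1) * 100 + 160)  # tiling case is exact
  }
})

test_that("QTL integration filters, assigns and conserves totals", {
  m <- toy_map(c(5, 15, 25, 45), group = "A1",
               locus = c("mk1", "mk2", "mk3", "mk4"))
  anchors <- make_anchor_table(c("mk1", "mk2", "mk3", "mk4"))
  cl <- build_clusters(anchors, m)
  qtls <- qtl_table(data.frame(
    trait = c("FL", "FS", "FF"), group = "A1",
    start_cM = c(10, 0, 20), end_cM = c(30, 26, 46)))
  res <- integrate_qtl(qtls, m, cl)
  # [10, 30]: positions 15 and 25 inside, 45 outside
  r1 <- res$records[res$records$trait == "FL", ]
  expect_equal(r1$n_assigned, 2)
  expect_setequal(strsplit(r1$markers, ",")[[1]], c("mk2", "mk3"))
  # width 26 > 20 -> excluded
  expect_equal(length(res$excluded), 2)
  expect_equal(nrow(res$records), 1)

  # monotone in max_interval: enlarging never removes an assignment
  res30 <- integrate_qtl(qtls, m, cl, max_interval = 30)
  expect_true(all(res$records$qtl_id %in% res30$records$qtl_id))
  expect_gte(sum(res30$records$n_assigned), sum(res$records$n_assigned))

  expect_error(integrate_qtl(qtl_table(data.frame(
    trait = "FL", group = "ZZ9", start_cM = 0, end_cM = 5)), m, cl),
    "absent from map")
  expect_error(qtl_table(data.frame(trait = "XX", group = "A1",
                                    start_cM = 0, end_cM = 5)),
               "trait")
})

test_that("integration summary has consistent subgenome subtotals", {
  set.seed(88)
  rows <- rbind(
    data.frame(locus = sprintf("a_%d", 1:30), marker_type = "eSSR",
               group = "A2", position_cM = seq(1, 88, by = 3)),
    data.frame(locus = sprintf("d_%d", 1:30), marker_type = "eSSR",
               group = "D7", position_cM = seq(1, 88, by = 3)))
  m <- genetic_map(rows)
  anchors <- make_anchor_table(m$locus)
  cl <- build_clusters(anchors, m)
  qtls <- qtl_table(data.frame(
    trait = sample(QTL_TRAITS, 8, replace = TRUE),
    group = rep(c("A2", "D7"), 4),
    start_cM = rep(c(0, 20, 40, 60), each = 2),
    end_cM = rep(c(15, 35, 55, 75), each = 2)))
  res <- integrate_qtl(qtls, m, cl)
  s <- res$summary
  at <- s[s$chromosome == "At_subtotal", ]
  dt <- s[s$chromosome == "Dt_subtotal", ]
  tot <- s[s$chromosome == "Total", ]
  expect_equal(at$qtl_total + dt$qtl_total, tot$qtl_total)
  expect_equal(at$n_genes + dt$n_genes, tot$n_genes)
  trait_cols <- paste0("q", c("FE", "FL", "FF", "FS", "FU"))
  expect_equal(sum(tot[, trait_cols]), tot$qtl_total)
  # per-chromosome rows sum to the grand total
  chr <- s[!grepl("subtotal|Total", s$chromosome), ]
  expect_equal(sum(chr$qtl_total), tot$qtl_total)
  # every assigned position lies inside its QTL interval
  for (i in seq_len(nrow(res$records))) {
    r <- res$records[i, ]
    if (r$markers == "") next
    mk <- strsplit(r$markers, ",")[[1]]
    pos <- m$position_cM[match(mk, m$locus)]
    expect_true(all(pos >= r$start_cM & pos <= r$end_cM))
  }
})

test_that("QTL clustering is single-linkage and order-invariant", {
  qtls <- qtl_table(data.frame(
    trait = c("FL", "FS", "FF"), group = "D8",
    start_cM = c(0, 8, 30), end_cM = c(10, 20, 40)))
  cl <- cluster_qtl(qtls)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$n_qtl, c(2, 1))
  expect_equal(cl$start_cM[1], 0)
  expect_equal(cl$end_cM[1], 20)
  expect_true(cl$multi_trait[1])

  # multi-trait flag on overlapping different-trait pair
  q2 <- qtl_table(data.frame(trait = c("FL", "FS"), group = "A1",
                             start_cM = c(0, 5), end_cM = c(10, 12)))
  expect_true(cluster_qtl(q2)$multi_trait)

  # permutation invariance
  set.seed(66)
  s3 <- runif(12, 0, 80)
  q3 <- qtl_table(data.frame(
    trait = sample(QTL_TRAITS, 12, replace = TRUE),
    group = sample(c("A1", "D5"), 12, replace = TRUE),
    start_cM = s3, end_cM = s3 + runif(12, 2, 15)))
  ref <- cluster_qtl(q3)
  for (i in 1:5) {
    perm <- q3[sample(nrow(q3)), ]
    got <- cluster_qtl(qtl_table(as.data.frame(perm)))
    expect_equal(got$members, ref$members)
    expect_equal(got$start_cM, ref$start_cM)
  }
})
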