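# In silico PCR: site search, amplicon prediction, pool anchoring,
# product-size comparison and seed-extend matching.

test_that("primer-site search handles exact and bounded-mismatch cases", {
  s <- match_primer_sites("ACGTACGT", "TTACGTACGTTT", max_mismatch = 0)
  plus <- s[s$strand == "+", ]
  expect_equal(plus$start, 3)
  expect_equal(plus$mismatches, 0)

  # 4 substitutions exceed the bound of 3
  primer <- "ACGGTTCAGGATCCATTGCA"
  ch <- strsplit(primer, "")[[1]]
  ch[c(2, 6, 11, 16)] <- c("T", "A", "C", "C")  # all differ from original
  mut <- paste0("TTTT", paste(ch, collapse = ""), "TTTT")
  expect_equal(nrow(match_primer_sites(primer, mut, 3)), 0)
  expect_equal(nrow(match_primer_sites(primer, mut, 4)), 1)

  # N in the template counts as a mismatch
  expect_equal(match_primer_sites("ACGTACGTAC", "TTACGTNCGTACTT",
                                  1)$mismatches, 1)

  expect_error(match_primer_sites("ACG", "ACGTACGT", 3), "pigeonhole")
})

test_that("pigeonhole search equals the naive full scan on random cases", {
  set.seed(42)
  n_combo <- 0
  for (t in 1:20) {
    tmpl <- random_dna(1500)
    for (p in 1:12) {
      primer <- random_dna(20)
      # plant a mutated copy so non-trivial hits exist in most combos
      k <- sample(0:3, 1)
      site <- .mutate_test(primer, k)
      at <- sample(nchar(tmpl) - 20, 1)
      tmpl2 <- paste0(substr(tmpl, 1, at - 1), site,
                      substr(tmpl, at + 20, nchar(tmpl)))
      got <- match_primer_sites(primer, tmpl2, 3)
      want <- naive_sites(primer, tmpl2, 3)
      expect_equal(got, want)
      expect_true(any(got$start == at & got$mismatches == k))
      n_combo <- n_combo + 1
    }
  }
  expect_gte(n_combo, 200)
})

test_that("amplicon prediction: planted product, strand symmetry, bounds", {
  fwd <- "ACGGTTCAGGATCCATTGCA"
  rev <- "TGCCAGTTAACGGATCTTGA"
  pair <- list(marker = "M1", forward = fwd, reverse = rev)
  tmpl <- paste0(fwd, strrep("A", 25), revcomp(rev))
  hit <- find_amplicons(pair, tmpl)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$product_size, 65)
  expect_equal(hit$mm_forward + hit$mm_reverse, 0)

  # strand symmetry: reverse-complemented template, same product size
  hit_rc <- find_amplicons(pair, revcomp(tmpl))
  expect_equal(nrow(hit_rc), 1)
  expect_equal(hit_rc$product_size, 65)
  expect_equal(hit_rc$strand, "-")

  # product-size bounds exclude the hit
  expect_equal(nrow(find_amplicons(pair, tmpl, min_product = 70)), 0)
  expect_equal(nrow(find_amplicons(pair, tmpl, max_product = 60)), 0)
  expect_error(find_amplicons(pair, tmpl, min_product = 100,
                              max_product = 50), "min_product")

  # monotonicity: raising max_mismatch never removes a hit; tightening
  # the product window never adds one
  set.seed(99)
  for (i in 1:10) {
    t2 <- random_dna(800)
    p2 <- list(marker = "x", forward = random_dna(20),
               reverse = random_dna(20))
    t2 <- paste0(t2, p2$forward, random_dna(60), revcomp(p2$reverse),
                 random_dna(50))
    key <- function(h) paste(h$start, h$end, h$strand)
    h0 <- find_amplicons(p2, t2, max_mismatch = 0)
    h3 <- find_amplicons(p2, t2, max_mismatch = 3)
    expect_true(all(key(h0) %in% key(h3)))
    hn <- find_amplicons(p2, t2, min_product = 90, max_product = 110)
    expect_true(all(key(hn) %in% key(find_amplicons(p2, t2))))
  }
})

test_that("pool anchoring bookkeeping decomposes into per-pair calls", {
  set.seed(7)
  # 4 markers; amplicons planted for 2 of them in one template
  pairs <- primer_table(data.frame(
    marker = sprintf("MK%d", 1:4),
    forward = vapply(1:4, function(i) random_dna(20), character(1)),
    reverse = vapply(1:4, function(i) random_dna(20), character(1))))
  tmpl <- paste0(random_dna(50),
                 pairs$forward[1], random_dna(80), revcomp(pairs$reverse[1]),
                 random_dna(50),
                 pairs$forward[2], random_dna(120), revcomp(pairs$reverse[2]),
                 random_dna(50))
  pool <- template_pool(data.frame(id = "T1", species = "Gh",
                                   kind = "EST", seq = tmpl))
  res <- anchor_pool(pairs, pool)
  expect_equal(res$summary$n_with_hit, 2)
  expect_equal(res$summary$n_without_hit, 2)
  expect_equal(res$summary$success_pct, 50.0)

  # decomposition oracle: summary equals independent find_amplicons runs
  per_pair <- vapply(seq_len(4), function(j) {
    nrow(find_amplicons(as.list(pairs[j, ]), tmpl)) > 0
  }, logical(1))
  expect_equal(res$summary$n_with_hit, sum(per_pair))
  expect_equal(sort(unique(res$hits$marker)),
               sort(pairs$marker[per_pair]))

  expect_error(anchor_pool(pairs, pool[0, ]), "empty")
  # printed-arithmetic check on the study-scale counts
  expect_equal(anchoring_success_pct(2111, 2111 + 1213), 63.5)
})

test_that("synthetic pools are recovered at exactly the planted rate", {
  cfg <- sim_config(seed = 31, amplicon_plan = list(
    n_markers = 40, frac_success = 0.635, n_decoys = 10, n_bac = 2,
    template_len = 400))
  sq <- generate_sequences(cfg)
  res <- anchor_pool(sq$primers, sq$pool)
  truth <- sq$truth$markers
  expect_equal(sort(unique(res$hits$marker)),
               sort(truth$marker[truth$success]))
  expect_equal(res$summary$success_pct,
               anchoring_success_pct(sum(truth$success), nrow(truth)))
  # every planted mismatch count respected
  planted <- truth[truth$success, ]
  first_hit <- res$hits[!duplicated(res$hits$marker), ]
  first_hit <- first_hit[match(planted$marker, first_hit$marker), ]
  expect_true(all(first_hit$mm_forward <= 3 & first_hit$mm_reverse <= 3))

  # mismatch-planted site beyond the bound is not recovered
  fwd <- "ACGGTTCAGGATCCATTGCA"
  rev <- "TGCCAGTTAACGGATCTTGA"
  set.seed(4)
  bad_f <- .mutate_test(fwd, 4)
  tmpl <- paste0(bad_f, strrep("A", 60), revcomp(rev))
  expect_equal(nrow(find_amplicons(list(marker = "m", forward = fwd,
                                        reverse = rev), tmpl)), 0)
})

test_that("cross-species product-size comparison recovers planted variants", {
  cfg <- sim_config(seed = 13, amplicon_plan = list(
    n_markers = 30, frac_success = 0.8, n_decoys = 5, n_bac = 0,
    template_len = 400, frac_size_variant = 0.5))
  sq <- generate_sequences(cfg)
  res <- anchor_pool(sq$primers, sq$pool)
  sizes <- compare_product_sizes(res)
  truth <- sq$truth$markers
  truth <- truth[truth$success & !is.na(truth$size_class), ]
  got <- setNames(sizes$size_class, sizes$marker)[truth$marker]
  expect_equal(unname(got), truth$size_class)

  # direct worked examples
  tab <- structure(list(hits = data.frame(
    marker = c("a", "a", "b", "b"),
    template = c("t1", "t2", "t3", "t4"),
    species = c("Gh", "Gr", "Gh", "Gr"),
    kind = "EST", strand = "+", start = 1L,
    end = c(180L, 180L, 180L, 186L),
    product_size = c(180L, 180L, 180L, 186L),
    mm_forward = 0L, mm_reverse = 0L)), class = "anchor_table")
  cmp <- compare_product_sizes(tab)
  expect_equal(setNames(cmp$size_class, cmp$marker),
               c(a = "same_size", b = "different_size"))
})

test_that("seed-extend finds planted blocks and matches the diagonal oracle", {
  set.seed(11)
  block <- random_dna(40)
  query <- paste0(random_dna(30), block, random_dna(30))
  tmpl <- paste0(random_dna(50), block, random_dna(50))
  m <- seed_extend(query, tmpl)
  expect_gte(nrow(m), 1)
  # the planted block plus chance matches in the flanks
  expect_gte(max(m$score), 40)
  expect_equal(max(m$score), diagonal_best_score(query, tmpl))
  expect_equal(m$identity[which.max(m$score)], 1.0)

  # no shared k-mer -> empty
  expect_equal(nrow(seed_extend(strrep("A", 40), strrep("C", 200))), 0)
  expect_error(seed_extend(query, tmpl, k = 3), "k")

  # reverse-strand block is found with the same score
  m_rc <- seed_extend(revcomp(query), tmpl)
  expect_equal(max(m_rc$score), max(m$score))
  expect_equal(m_rc$strand[which.max(m_rc$score)], "-")

  # oracle: reported maximum equals the exhaustive per-diagonal
  # best-window score on planted-block pairs
  for (i in 1:100) {
    set.seed(800 + i)
    core <- random_dna(60)
    q <- paste0(random_dna(20), core, random_dna(20))
    t <- paste0(random_dna(25), core, random_dna(25))
    got <- seed_extend(q, t, min_score = 30)
    expect_equal(max(got$score), diagonal_best_score(q, t))
  }
})
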