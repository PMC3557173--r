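# Density binning, cluster calling, duplication and translocation analysis.

test_that("density bins use half-open intervals and conserve counts", {
  m <- toy_map(0:100)
  d <- bin_density(m, 10)
  expect_equal(nrow(d), 10)
  expect_equal(d$count, c(rep(10, 9), 11))  # last bin absorbs the max
  expect_equal(sum(d$count), 101)

  # all loci at one point
  m0 <- toy_map(rep(0, 7), locus = sprintf("z%d", 1:7))
  d0 <- bin_density(m0, 10)
  expect_equal(nrow(d0), 1)
  expect_equal(d0$count, 7)

  expect_error(bin_density(m, 0), "width")

  # conservation on a random multi-group map
  gm <- generate_map(sim_config(seed = 21, n_groups = 5,
                                loci_per_group = 80))$map
  d <- bin_density(gm)
  counts <- tapply(d$count, d$group, sum)
  expect_equal(as.integer(counts[sort(unique(gm$group))]),
               as.integer(table(gm$group)[sort(unique(gm$group))]))
})

test_that("cluster calling matches worked examples", {
  # six EST-SSR loci spanning 0.57 cM -> one gene island
  pos <- c(106.83, 106.95, 107.05, 107.18, 107.30, 107.40)
  m <- toy_map(pos, group = "A5", marker_type = "eSSR")
  cl <- detect_clusters(m)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$kind, "gene_island")
  expect_equal(cl$n_loci, 6)
  expect_equal(cl$end_cM - cl$start_cM, 0.57)

  # below min_loci: no cluster
  m4 <- toy_map(c(0, 0.1, 0.3, 0.5), marker_type = "eSSR")
  expect_equal(nrow(detect_clusters(m4)), 0)

  # 15 loci within 1 cM, 8 REMAP -> retrotransposon-rich
  m15 <- toy_map(seq(50, 50.9, length.out = 15), group = "D3",
                 marker_type = c(rep("REMAP", 8), rep("gSSR", 7)))
  cl15 <- detect_clusters(m15)
  expect_equal(nrow(cl15), 1)
  expect_equal(cl15$kind, "retro_rich")
  expect_equal(cl15$n_REMAP, 8)
  expect_equal(cl15$n_loci, 15)
})

test_that("cluster calling agrees with the all-subranges brute force", {
  for (s in 1:6) {
    set.seed(300 + s)
    # dense positions so clusters actually occur
    pos <- sort(round(runif(50, 0, 25), 2))
    m <- toy_map(pos, group = "G1")
    got <- detect_clusters(m, min_loci = 4, window = 1.0)
    want <- brute_clusters(pos, 4, 1.0)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$start_cM,
                   vapply(want, function(r) pos[r[1]], numeric(1)))
      expect_equal(got$end_cM,
                   vapply(want, function(r) pos[r[2]], numeric(1)))
    }
  }
})

test_that("duplication accounting reproduces the multiplicity arithmetic", {
  # histogram {2:287, 3:37, 4:2} -> 693 loci from 326 markers, with the
  # homoeolog / same-chromosome / different split planted by the generator
  cfg <- sim_config(seed = 7)
  gm <- generate_map(cfg)
  dup_in <- generate_duplication(gm$map, cfg)
  dup <- analyze_duplication(gm$map, dup_in$marker_to_loci)
  expect_equal(dup$summary$n_markers, 326)
  expect_equal(dup$summary$n_duplicated_loci, 693)
  expect_equal(dup$histogram, c(`2` = 287L, `3` = 37L, `4` = 2L))
  expect_equal(dup$summary$n_homoeologous, dup_in$truth$n_homoeologous)
  expect_equal(dup$summary$n_nonhomoeologous,
               dup_in$truth$n_same_chromosome + dup_in$truth$n_different)
  # 693 loci with 249 non-homoeologous -> 64.07% bridging share
  expect_equal(dup$summary$n_nonhomoeologous, 249)
  expect_equal(dup$summary$pct_homoeologous, 64.07)
  # class percentages partition within rounding
  expect_equal(dup$summary$pct_same_of_nonhom +
                 dup$summary$pct_different_of_nonhom, 100,
               tolerance = 0.011)

  # one marker hitting the same chromosome twice
  m <- toy_map(c(0, 5, 10), group = "A1")
  d2 <- analyze_duplication(m, data.frame(marker = "mk",
                                          locus = m$locus[1:2]))
  expect_equal(unique(d2$loci$class), "same_chromosome")

  expect_error(analyze_duplication(m, data.frame(marker = "mk",
                                                 locus = "nope")),
               "unknown locus")
})

test_that("translocation signals count reciprocal homoeolog bridges", {
  # build a map over the needed groups and a duplication table with
  # planted bridge counts 8 (A3/D2), 7 (A2/D3), 9 (A5/D4), 3 (A4/D5)
  groups <- c("A2", "A3", "A4", "A5", "D2", "D3", "D4", "D5")
  rows <- do.call(rbind, lapply(groups, function(g)
    data.frame(locus = sprintf("%s_%02d", g, 1:12), marker_type = "gSSR",
               group = g, position_cM = seq(0, 55, by = 5))))
  m <- genetic_map(rows)
  plant <- rbind(
    data.frame(a = "A3", b = "D2", n = 8),
    data.frame(a = "A2", b = "D3", n = 7),
    data.frame(a = "A5", b = "D4", n = 9),
    data.frame(a = "A4", b = "D5", n = 3))
  used <- setNames(rep(0, length(groups)), groups)
  m2l <- do.call(rbind, lapply(seq_len(nrow(plant)), function(i) {
    n <- plant$n[i]
    a <- plant$a[i]; b <- plant$b[i]
    out <- data.frame(
      marker = sprintf("T%s%s_%d", a, b, seq_len(n)),
      locus = c(sprintf("%s_%02d", a, used[a] + seq_len(n)),
                sprintf("%s_%02d", b, used[b] + seq_len(n))))
    used[a] <<- used[a] + n
    used[b] <<- used[b] + n
    out
  }))
  dup <- analyze_duplication(m, m2l)
  sig <- detect_translocation_signals(dup)
  expect_equal(sig$n_support[sig$pair == "A2/A3"], 15)
  expect_equal(sig$n_support[sig$pair == "A4/A5"], 12)
  expect_equal(sum(sig$n_support), 27)

  # homoeologous-only table gives zero signal; empty table gives empty
  hom <- data.frame(marker = rep(c("h1", "h2"), each = 2),
                    locus = c("A2_11", "D2_09", "A3_09", "D3_08"))
  sig0 <- detect_translocation_signals(analyze_duplication(m, hom))
  expect_equal(sig0$n_support, c(0, 0))
  empty <- analyze_duplication(m, data.frame(marker = character(),
                                             locus = character()))
  expect_equal(nrow(empty$loci), 0)
  expect_error(detect_translocation_signals(dup, list(c("bad", "A3"))),
               "pair")
})
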