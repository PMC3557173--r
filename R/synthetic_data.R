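# Seeded generators for every pipeline input, with ground-truth manifests
# so detector recovery can be scored exactly.
#
# Defaults mirror the BC1 mapping design the analysis assumes: 26 linkage
# groups (A1-A13, D1-D13) of ~131 loci over ~141 cM each, 138 BC1
# individuals, 1% missing genotype calls, and an anchoring plan in which
# 63.5% of markers carry a planted amplicon.

# Independent per-module streams derived from one global seed, so adding
# a generator never perturbs another's draws. Kept below 2^31.
.module_seed <- function(seed, module) {
  k <- match(module, c("map", "bc1", "seq", "qtl", "dup"))
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

# Marker-type sampling weights (relative frequencies of the 11 classes on
# a dense cotton map).
.TYPE_WEIGHTS <- c(eSSR = 1450, gSSR = 1284, REMAP = 187, RT = 172,
                   SRAP = 127, AFLP = 80, SNP = 73, CAPs = 19, InDel = 12,
                   `BAC-end` = 8, morphology = 2)

#' Simulation configuration
#'
#' Bundles the seed and all generator plans. Every argument has a default
#' reflecting the BC1 study design the pipeline targets; plans are
#' replaced wholesale when supplied.
#'
#' @param seed integer master seed; all generator randomness derives from
#'   it through independent per-module streams.
#' @param n_groups number of linkage groups (default 26; labels A1..A13,
#'   D1..D13 when 26, else G1..Gn).
#' @param loci_per_group loci simulated per group (default 131).
#' @param group_length_cM group length in cM (default 141).
#' @param n_individuals BC1 population size (default 138).
#' @param missing_rate genotype missing-at-random rate (default 0.01).
#' @param distortion_regions data.frame(group, start_cM, end_cM, p3):
#'   heterozygote transmission probability p3 inside each region (0.5
#'   elsewhere = fair). NULL for fair transmission everywhere.
#' @param cluster_plants data.frame(group, center_cM, n_loci, span_cM,
#'   marker_type): locus clusters inserted into the map. NULL for none.
#' @param amplicon_plan list: n_markers, frac_success, primer_len,
#'   template_len, product_range, max_planted_mismatch,
#'   frac_second_species, frac_size_variant, insertion_bp, n_decoys,
#'   n_bac, bac_len, frac_bac.
#' @param qtl_plan data.frame(trait, group, start_cM, end_cM): QTL
#'   intervals to emit. NULL defers to \code{\link{generate_qtl}}
#'   defaults.
#' @param duplication_plan list: n_hom_dup, n_same_dup, n_diff_dup,
#'   n_tri, n_tetra (marker counts by duplication pattern).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_groups = 26,
                       loci_per_group = 131,
                       group_length_cM = 141,
                       n_individuals = 138,
                       missing_rate = 0.01,
                       distortion_regions = NULL,
                       cluster_plants = NULL,
                       amplicon_plan = NULL,
                       qtl_plan = NULL,
                       duplication_plan = NULL) {
  stopifnot(seed == as.integer(seed), n_groups >= 1, loci_per_group >= 2,
            group_length_cM > 0, n_individuals >= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(distortion_regions) &&
      (any(distortion_regions$p3 < 0) || any(distortion_regions$p3 > 1)))
    stop("transmission probability p3 must lie in [0, 1]")
  default_plan <- list(
    n_markers = 1000, frac_success = 0.635, primer_len = 20,
    template_len = 600, product_range = c(100, 400),
    max_planted_mismatch = 3, frac_second_species = 1.0,
    frac_size_variant = 0.639, insertion_bp = 6, n_decoys = 100,
    n_bac = 10, bac_len = 10000, frac_bac = 0.06)
  if (!is.null(amplicon_plan))
    default_plan[names(amplicon_plan)] <- amplicon_plan
  default_dup <- list(n_hom_dup = 181, n_same_dup = 40, n_diff_dup = 66,
                      n_tri = 37, n_tetra = 2)
  if (!is.null(duplication_plan))
    default_dup[names(duplication_plan)] <- duplication_plan
  out <- list(seed = as.integer(seed), n_groups = n_groups,
              loci_per_group = loci_per_group,
              group_length_cM = group_length_cM,
              n_individuals = n_individuals, missing_rate = missing_rate,
              distortion_regions = distortion_regions,
              cluster_plants = cluster_plants,
              amplicon_plan = default_plan, qtl_plan = qtl_plan,
              duplication_plan = default_dup)
  class(out) <- "sim_config"
  out
}

.group_labels <- function(n_groups) {
  if (n_groups == 26) c(paste0("A", 1:13), paste0("D", 1:13))
  else if (n_groups <= 26 && n_groups %% 2 == 0)
    c(paste0("A", seq_len(n_groups / 2)), paste0("D", seq_len(n_groups / 2)))
  else paste0("G", seq_len(n_groups))
}

#' Generate a synthetic genetic map
#'
#' Positions are drawn uniformly over each group, then any planted
#' clusters from \code{cfg$cluster_plants} are inserted. Deterministic
#' under a fixed seed.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list: \code{map} (a \code{\link{genetic_map}}) and
#'   \code{truth} (manifest with planted cluster membership).
#' @export
generate_map <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.module_seed(cfg$seed, "map"))
  labels <- .group_labels(cfg$n_groups)
  rows <- list()
  planted <- list()
  for (g in labels) {
    pos <- sort(runif(cfg$loci_per_group, 0, cfg$group_length_cM))
    type <- sample(names(.TYPE_WEIGHTS), length(pos), replace = TRUE,
                   prob = .TYPE_WEIGHTS)
    flag <- rep(FALSE, length(pos))
    cp <- cfg$cluster_plants
    if (!is.null(cp)) for (i in which(cp$group == g)) {
      lo <- cp$center_cM[i] - cp$span_cM[i] / 2
      hi <- cp$center_cM[i] + cp$span_cM[i] / 2
      if (lo < 0 || hi > cfg$group_length_cM)
        stop("infeasible cluster plant on ", g, ": [", lo, ", ", hi,
             "] outside group length ", cfg$group_length_cM)
      newpos <- sort(runif(cp$n_loci[i], lo, hi))
      pos <- c(pos, newpos)
      type <- c(type, rep(cp$marker_type[i], cp$n_loci[i]))
      flag <- c(flag, rep(TRUE, cp$n_loci[i]))
    }
    ord <- order(pos)
    pos <- pos[ord]; type <- type[ord]; flag <- flag[ord]
    locus <- sprintf("%s_L%03d", g, seq_along(pos))
    rows[[g]] <- data.frame(locus = locus, marker_type = type, group = g,
                            position_cM = round(pos, 2),
                            stringsAsFactors = FALSE)
    if (any(flag))
      planted[[g]] <- data.frame(group = g, locus = locus[flag],
                                 position_cM = round(pos, 2)[flag],
                                 stringsAsFactors = FALSE)
  }
  map_df <- do.call(rbind, rows)
  rownames(map_df) <- NULL
  truth_clusters <- if (length(planted) > 0) {
    tc <- do.call(rbind, planted)
    rownames(tc) <- NULL
    tc
  } else NULL
  list(map = genetic_map(map_df), truth = list(clusters = truth_clusters))
}

#' Generate BC1 genotypes with planted transmission bias
#'
#' Each individual at each locus is heterozygous (code 3) with
#' probability p3 — 0.5 outside distortion regions, region-specific
#' inside — independently across individuals; calls are then masked
#' missing at \code{cfg$missing_rate}.
#'
#' @param map a \code{\link{genetic_map}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return list: \code{genotypes} (a \code{\link{genotype_matrix}}) and
#'   \code{truth} (per-region member loci and expected skew direction).
#' @export
generate_bc1 <- function(map, cfg) {
  stopifnot(inherits(map, "genetic_map"), inherits(cfg, "sim_config"))
  set.seed(.module_seed(cfg$seed, "bc1"))
  n_loci <- nrow(map)
  n_ind <- cfg$n_individuals
  p3 <- rep(0.5, n_loci)
  regions <- cfg$distortion_regions
  truth_regions <- NULL
  if (!is.null(regions)) {
    if (any(regions$p3 < 0 | regions$p3 > 1))
      stop("transmission probability p3 must lie in [0, 1]")
    bad <- setdiff(regions$group, map$group)
    if (length(bad) > 0)
      stop("distortion region on unknown group(s): ",
           paste(bad, collapse = ", "))
    tr <- list()
    for (i in seq_len(nrow(regions))) {
      inr <- map$group == regions$group[i] &
        map$position_cM >= regions$start_cM[i] &
        map$position_cM <= regions$end_cM[i]
      p3[inr] <- regions$p3[i]
      tr[[i]] <- data.frame(
        region = i, group = regions$group[i], p3 = regions$p3[i],
        direction = if (regions$p3[i] > 0.5) "toward_heterozygote"
                    else if (regions$p3[i] < 0.5) "toward_recurrent"
                    else "none",
        n_loci = sum(inr), loci = paste(map$locus[inr], collapse = ","),
        stringsAsFactors = FALSE)
    }
    truth_regions <- do.call(rbind, tr)
  }
  het <- matrix(rbinom(n_loci * n_ind, 1, rep(p3, times = n_ind)),
                nrow = n_loci)
  calls <- matrix(ifelse(het == 1, 3L, 1L), nrow = n_loci)
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(n_loci * n_ind) < cfg$missing_rate,
                   nrow = n_loci)
    calls[miss] <- NA_integer_
  }
  rownames(calls) <- map$locus
  colnames(calls) <- sprintf("BC1_%03d", seq_len(n_ind))
  list(genotypes = genotype_matrix(calls),
       truth = list(regions = truth_regions))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute `k` positions of `s` with different bases
.mutate <- function(s, k) {
  if (k == 0) return(s)
  ch <- strsplit(s, "")[[1]]
  idx <- sample(length(ch), k)
  for (i in idx) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

.plant_amplicon <- function(tmpl, fwd, rev, product_size, mm_f, mm_r) {
  L <- nchar(tmpl)
  lf <- nchar(fwd)
  lr <- nchar(rev)
  stopifnot(product_size >= lf + lr, L >= product_size)
  fstart <- sample(L - product_size + 1, 1)
  fsite <- .mutate(fwd, mm_f)
  rsite <- .mutate(revcomp(rev), mm_r)
  rstart <- fstart + product_size - lr
  tmpl <- paste0(substr(tmpl, 1, fstart - 1), fsite,
                 substr(tmpl, fstart + lf, L))
  tmpl <- paste0(substr(tmpl, 1, rstart - 1), rsite,
                 substr(tmpl, rstart + lr, L))
  list(seq = tmpl, fstart = fstart, rstart = rstart)
}

#' Generate primer pairs and a template pool with planted amplicons
#'
#' Markers designated successful (fraction \code{frac_success} of the
#' plan) get the forward primer and the reverse complement of the reverse
#' primer planted at recorded offsets in a template, with planned
#' substitution counts; a second-species copy may carry an insertion
#' between the primer sites so cross-species product sizes differ by a
#' known offset. Non-designated markers receive no planted site. A
#' fraction of successful markers is additionally planted into long BAC
#' templates.
#'
#' @param cfg a \code{\link{sim_config}} (see \code{amplicon_plan}).
#' @return list: \code{primers} (a \code{\link{primer_table}}),
#'   \code{pool} (a \code{\link{template_pool}}) and \code{truth}
#'   (per-marker manifest: success, planted mismatches, product sizes,
#'   expected size class).
#' @export
generate_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  plan <- cfg$amplicon_plan
  set.seed(.module_seed(cfg$seed, "seq"))
  n <- plan$n_markers
  n_success <- round(plan$frac_success * n)
  lf <- plan$primer_len
  # planted products must fit both primers and the template
  prod_lo <- plan$product_range[1]
  prod_hi <- min(plan$product_range[2], plan$template_len)
  if (prod_lo < 2 * lf || prod_lo > prod_hi)
    stop("template too short for planted product: product range [",
         prod_lo, ", ", prod_hi, "] must admit both primers and fit ",
         "the template")
  markers <- sprintf("MK%04d", seq_len(n))
  fwd <- vapply(seq_len(n), function(i) .random_dna(lf), character(1))
  rev <- vapply(seq_len(n), function(i) .random_dna(lf), character(1))
  success <- c(rep(TRUE, n_success), rep(FALSE, n - n_success))
  templates <- list()
  truth <- list()
  add_template <- function(id, species, kind, seq) {
    templates[[length(templates) + 1]] <<- data.frame(
      id = id, species = species, kind = kind, seq = seq,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    if (!success[i]) {
      truth[[i]] <- data.frame(marker = markers[i], success = FALSE,
                               product_size = NA_integer_,
                               mm_forward = NA_integer_,
                               mm_reverse = NA_integer_,
                               size_class = NA_character_,
                               in_bac = FALSE, stringsAsFactors = FALSE)
      next
    }
    psize <- sample(prod_lo:prod_hi, 1)
    mm_f <- sample(0:plan$max_planted_mismatch, 1)
    mm_r <- sample(0:plan$max_planted_mismatch, 1)
    t1 <- .plant_amplicon(.random_dna(plan$template_len), fwd[i], rev[i],
                          psize, mm_f, mm_r)
    add_template(sprintf("EST%05d", length(templates) + 1), "Gh", "EST",
                 t1$seq)
    size_class <- NA_character_
    if (runif(1) < plan$frac_second_species) {
      variant <- runif(1) < plan$frac_size_variant
      psize2 <- psize + if (variant) plan$insertion_bp else 0L
      t2 <- .plant_amplicon(.random_dna(plan$template_len + psize2 - psize),
                            fwd[i], rev[i], psize2, mm_f, mm_r)
      add_template(sprintf("EST%05d", length(templates) + 1), "Gb", "EST",
                   t2$seq)
      size_class <- if (variant) "different_size" else "same_size"
    }
    in_bac <- runif(1) < plan$frac_bac
    truth[[i]] <- data.frame(marker = markers[i], success = TRUE,
                             product_size = psize, mm_forward = mm_f,
                             mm_reverse = mm_r, size_class = size_class,
                             in_bac = in_bac, stringsAsFactors = FALSE)
  }
  # long BAC templates carrying a subset of successful markers
  bac_markers <- which(success & vapply(truth, function(t) t$in_bac,
                                        logical(1)))
  if (plan$n_bac > 0) {
    per_bac <- split(bac_markers,
                     rep_len(seq_len(plan$n_bac), length(bac_markers)))
    for (b in seq_len(plan$n_bac)) {
      seq <- .random_dna(plan$bac_len)
      for (i in per_bac[[as.character(b)]]) {
        pl <- .plant_amplicon(seq, fwd[i], rev[i],
                              truth[[i]]$product_size,
                              truth[[i]]$mm_forward,
                              truth[[i]]$mm_reverse)
        seq <- pl$seq
      }
      add_template(sprintf("BAC%03d", b), "Gh", "BAC", seq)
    }
  }
  for (d in seq_len(plan$n_decoys))
    add_template(sprintf("DEC%04d", d), sample(c("Gr", "Ga"), 1), "EST",
                 .random_dna(plan$template_len))
  list(primers = primer_table(data.frame(marker = markers, forward = fwd,
                                         reverse = rev,
                                         stringsAsFactors = FALSE)),
       pool = template_pool(do.call(rbind, templates)),
       truth = list(markers = do.call(rbind, truth),
                    n_success = n_success,
                    success_pct = anchoring_success_pct(n_success, n)))
}

#' Generate a QTL table on a map
#'
#' Emits fiber-quality QTL intervals from \code{cfg$qtl_plan}, or a
#' default plan of intervals spread over the first groups with widths
#' 6-18 cM plus two 25-cM intervals that exercise the 20-cM filter.
#'
#' @param map a \code{\link{genetic_map}}.
#' @param cfg a \code{\link{sim_config}}.
#' @param positions optional data.frame(marker, group, position_cM) of
#'   anchored-marker positions; the manifest then records which markers
#'   fall inside each interval.
#' @return list: \code{qtls} (a \code{\link{qtl_table}}) and
#'   \code{truth} (per-QTL width filter flag and contained markers).
#' @export
generate_qtl <- function(map, cfg, positions = NULL) {
  stopifnot(inherits(map, "genetic_map"), inherits(cfg, "sim_config"))
  set.seed(.module_seed(cfg$seed, "qtl"))
  plan <- cfg$qtl_plan
  groups <- unique(map$group)
  glen <- vapply(split(map$position_cM, map$group)[groups], max, numeric(1))
  if (is.null(plan)) {
    n_qtl <- min(20, 4 * length(groups))
    g <- sample(groups, n_qtl, replace = TRUE)
    width <- c(rep(25, 2), runif(n_qtl - 2, 6, 18))[seq_len(n_qtl)]
    start <- vapply(seq_len(n_qtl), function(i)
      runif(1, 0, max(glen[g[i]] - width[i], 0.1)), numeric(1))
    plan <- data.frame(trait = sample(QTL_TRAITS, n_qtl, replace = TRUE),
                       group = g, start_cM = round(start, 2),
                       end_cM = round(start + width, 2),
                       stringsAsFactors = FALSE)
  }
  bad <- setdiff(plan$group, groups)
  if (length(bad) > 0)
    stop("QTL plan names unknown group(s): ", paste(bad, collapse = ", "))
  qtls <- qtl_table(plan)
  truth <- lapply(seq_len(nrow(qtls)), function(i) {
    q <- qtls[i, ]
    contained <- character(0)
    if (!is.null(positions)) {
      inq <- positions$group == q$group &
        positions$position_cM >= q$start_cM &
        positions$position_cM <= q$end_cM
      contained <- unique(positions$marker[inq])
    }
    data.frame(qtl_id = q$qtl_id, width = q$end_cM - q$start_cM,
               passes_filter = (q$end_cM - q$start_cM) <= 20,
               n_contained = length(contained),
               contained = paste(contained, collapse = ","),
               stringsAsFactors = FALSE)
  })
  list(qtls = qtls, truth = list(qtl = do.call(rbind, truth)))
}

#' Generate a duplicated-marker plan on a map
#'
#' Builds a marker-to-loci mapping realizing the configured duplication
#' pattern counts: duplicated markers bridging homoeologous partners
#' (Ai/Di), duplicated markers hitting one group twice, duplicated
#' markers spanning two non-homoeologous groups, triplicated markers
#' (Ai, Di plus a third non-partner group) and tetraplicated markers
#' (Ai, Di, Aj, Dj). Loci are drawn without replacement from the map.
#'
#' @param map a \code{\link{genetic_map}} with A/D group labels.
#' @param cfg a \code{\link{sim_config}} (see \code{duplication_plan}).
#' @return list: \code{marker_to_loci} (data.frame marker/locus) and
#'   \code{truth} (expected multiplicity histogram and locus-class
#'   counts).
#' @export
generate_duplication <- function(map, cfg) {
  stopifnot(inherits(map, "genetic_map"), inherits(cfg, "sim_config"))
  plan <- cfg$duplication_plan
  set.seed(.module_seed(cfg$seed, "dup"))
  agroups <- unique(map$group[startsWith(map$group, "A")])
  idx <- sort(as.integer(sub("^A", "", agroups)))
  idx <- idx[paste0("D", idx) %in% map$group]
  if (length(idx) < 2)
    stop("duplication plan needs a map with >= 2 homoeologous A/D pairs")
  pool <- split(map$locus, map$group)
  draw <- function(g) {
    if (length(pool[[g]]) == 0)
      stop("locus pool exhausted for group ", g)
    l <- sample(pool[[g]], 1)
    pool[[g]] <<- setdiff(pool[[g]], l)
    l
  }
  rows <- list()
  mk <- 0
  emit <- function(groups) {
    mk <<- mk + 1
    for (g in groups)
      rows[[length(rows) + 1]] <<- data.frame(
        marker = sprintf("DUP%04d", mk), locus = draw(g),
        stringsAsFactors = FALSE)
  }
  for (i in seq_len(plan$n_hom_dup)) {
    j <- sample(idx, 1)
    emit(c(paste0("A", j), paste0("D", j)))
  }
  for (i in seq_len(plan$n_same_dup)) {
    g <- sample(c(paste0("A", idx), paste0("D", idx)), 1)
    emit(c(g, g))
  }
  for (i in seq_len(plan$n_diff_dup)) {
    jj <- sample(idx, 2)
    emit(paste0("A", jj))  # two distinct A-groups: non-partner bridge
  }
  for (i in seq_len(plan$n_tri)) {
    jj <- sample(idx, 2)
    emit(c(paste0("A", jj[1]), paste0("D", jj[1]), paste0("A", jj[2])))
  }
  for (i in seq_len(plan$n_tetra)) {
    jj <- sample(idx, 2)
    emit(c(paste0("A", jj[1]), paste0("D", jj[1]),
           paste0("A", jj[2]), paste0("D", jj[2])))
  }
  m2l <- do.call(rbind, rows)
  hist_expect <- c(`2` = plan$n_hom_dup + plan$n_same_dup + plan$n_diff_dup,
                   `3` = plan$n_tri, `4` = plan$n_tetra)
  hist_expect <- hist_expect[hist_expect > 0]
  list(marker_to_loci = m2l,
       truth = list(
         histogram = hist_expect,
         n_markers = sum(hist_expect),
         n_duplicated_loci = sum(as.integer(names(hist_expect)) *
                                   hist_expect),
         n_homoeologous = 2 * plan$n_hom_dup + 2 * plan$n_tri +
           4 * plan$n_tetra,
         n_same_chromosome = 2 * plan$n_same_dup,
         n_different = 2 * plan$n_diff_dup + plan$n_tri))
}
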