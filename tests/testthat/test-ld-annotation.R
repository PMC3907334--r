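test_that("pairwise r2 matches direct haplotype-table arithmetic", {
  # counts AB=40, Ab=10, aB=10, ab=40: D = 0.4 - 0.25 = 0.15, r2 = 0.36
  H <- haplotypes_from_counts(40, 10, 10, 40)
  p <- panel_from_matrix(H)
  expect_equal(pairwise_r2(p, "v001", "v002"), 0.36)
  expect_equal(pairwise_r2(p, "v002", "v001"), 0.36)  # symmetric
  # identical columns: r2 = 1
  p2 <- panel_from_matrix(cbind(H[, 1], H[, 1]))
  expect_equal(pairwise_r2(p2, "v001", "v002"), 1.0)
})

test_that("monomorphic variants give an undefined-LD error", {
  H <- cbind(c(1L, 1L, 1L, 1L), c(0L, 1L, 0L, 1L))
  p <- panel_from_matrix(H)
  expect_error(pairwise_r2(p, "v001", "v002"), "monomorphic")
})

test_that("pairwise r2 equals the brute-force oracle on random panels", {
  set.seed(42)
  for (rep in 1:25) {
    n_hap <- 2 * sample(10:60, 1)
    n_var <- sample(3:10, 1)
    H <- matrix(rbinom(n_hap * n_var, 1L, runif(1, 0.2, 0.8)), n_hap, n_var)
    poly <- colSums(H) > 0 & colSums(H) < n_hap
    if (sum(poly) < 2) next
    H <- H[, poly, drop = FALSE]
    p <- panel_from_matrix(H)
    ids <- p$variants$id
    ij <- sample(length(ids), 2)
    expect_equal(pairwise_r2(p, ids[ij[1]], ids[ij[2]]),
                 brute_force_r2(H[, ij[1]], H[, ij[2]]),
                 tolerance = 1e-12)
  }
})

test_that("correlated-SNP discovery respects the window and r2 cutoff", {
  # 5 variants, positions 1000..5000; v1 = index; v2 identical (perfect
  # proxy); v4 identical but outside the window; v3, v5 independent noise
  set.seed(1)
  base <- rbinom(200, 1, 0.4)
  noise1 <- rbinom(200, 1, 0.4)
  noise2 <- rbinom(200, 1, 0.4)
  H <- cbind(base, base, noise1, base, noise2)
  p <- panel_from_matrix(H)
  corr <- find_correlated_snps(list(EUR = p), "v001", window = 4000,
                               r2_min = 0.5)
  expect_true(all(c("v001", "v002") %in% corr$id))
  expect_false("v004" %in% corr$id)  # r2 = 1 but beyond +/- 2 kb
  expect_true(corr$is_index[corr$id == "v001"])
  expect_equal(corr$r2_EUR[corr$id == "v002"], 1.0)
})

test_that("correlated-SNP discovery equals a brute-force all-pairs scan", {
  gs <- genome_spec("chr1", 1e6)
  p <- simulate_haplotype_panel(gs, 150, 30, 1e5, 0.8, seed = 20)
  idx <- "snp0015"
  corr <- find_correlated_snps(list(POP = p), idx, window = 4e5,
                               r2_min = 0.5)
  v <- p$variants
  ipos <- v$pos[v$id == idx]
  expected <- v$id[vapply(seq_len(nrow(v)), function(j) {
    if (abs(v$pos[j] - ipos) > 2e5) return(FALSE)
    if (v$id[j] == idx) return(TRUE)
    brute_force_r2(p$haplotypes[, idx], p$haplotypes[, v$id[j]]) >= 0.5
  }, logical(1))]
  expect_setequal(corr$id, expected)
})

test_that("correlated-SNP output is invariant to variant ordering", {
  gs <- genome_spec("chr1", 1e6)
  p <- simulate_haplotype_panel(gs, 100, 20, 1e5, 0.8, seed = 21)
  perm <- sample(20)
  p_shuf <- haplotype_panel(p$haplotypes[, perm], p$variants[perm, ],
                            p$samples, p$population)
  a <- find_correlated_snps(list(POP = p), "snp0010", window = 4e5)
  b <- find_correlated_snps(list(POP = p_shuf), "snp0010", window = 4e5)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("population intersection tiers follow both thresholds", {
  corr <- data.frame(
    index_id = "i", id = c("s1", "s2", "s3"), chrom = "chr1",
    pos = 1:3, ref = "A", alt = "G",
    r2_AFR = c(0.9, 0.9, 0.6), r2_EUR = c(0.85, 0.3, 0.55),
    is_index = FALSE, stringsAsFactors = FALSE
  )
  out <- intersect_populations(corr, c("AFR", "EUR"))
  expect_equal(as.character(out$tier), c("shared_high", "single", "shared"))
  expect_error(intersect_populations(corr, c("AFR", "ASN")), "ASN")
})

test_that("dual-population proxies match the planted truth", {
  gs <- genome_spec("chr1", 5e6)
  tp <- simulate_two_population_panels(gs, 60, 0.5, seed = 22,
                                       n_samples = 200, n_pairs = 15)
  shared <- vapply(seq_len(nrow(tp$truth)), function(k) {
    idx <- tp$truth$index_id[k]
    corr <- find_correlated_snps(tp$panels, idx, window = 10e6,
                                 r2_min = 0.5)
    corr <- intersect_populations(corr, c("popA", "popB"))
    tp$truth$proxy_id[k] %in% corr$id[corr$tier >= "shared"]
  }, logical(1))
  expect_equal(shared, tp$truth$dual)
})

test_that("biofeature membership equals a linear-scan oracle", {
  gs <- genome_spec("chr1", 1e6)
  tracks <- generate_biofeature_tracks(gs, c("dnase", "h3k27ac", "ctcf"),
                                       density = 30, seed = 23)
  set.seed(24)
  snps <- data.frame(id = sprintf("s%02d", 1:50), chrom = "chr1",
                     pos = sample.int(1e6, 50), stringsAsFactors = FALSE)
  ann <- annotate_biofeatures(snps, tracks)
  for (i in seq_len(nrow(snps))) {
    expected <- names(tracks)[vapply(tracks, function(gr) {
      any(GenomicRanges::start(gr) <= snps$pos[i] &
            GenomicRanges::end(gr) >= snps$pos[i])
    }, logical(1))]
    expect_setequal(ann$memberships[[i]], expected)
  }
})

test_that("a SNP at a BED interval end is not a member (half-open)", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tpeak1\t0\t.", f)  # covers 1-based 101..200
  track <- list(peak = read_bed(f))
  snps <- data.frame(id = c("in", "at_end", "past"), chrom = "chr1",
                     pos = c(200L, 201L, 250L), stringsAsFactors = FALSE)
  ann <- annotate_biofeatures(snps, track)
  expect_equal(ann$n_biofeatures, c(1L, 0L, 0L))
})

test_that("functional classification applies the precedence rule", {
  tss <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10000, 50000), width = 1),
    strand = c("+", "-")
  )
  gene_tracks <- list(
    tss = tss,
    coding_exon = GenomicRanges::GRanges("chr1",
                                         IRanges::IRanges(30000, 31000)),
    utr3 = GenomicRanges::GRanges("chr1", IRanges::IRanges(40000, 41000)),
    utr5 = GenomicRanges::GRanges("chr1", IRanges::IRanges(0, 1)),
    mir_target = GenomicRanges::GRanges("chr1",
                                        IRanges::IRanges(40500, 40600))
  )
  chrom_tracks <- list(
    h3k27ac = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(c(9000, 29000, 40000, 60000),
                               c(12000, 32000, 42000, 61000))
    )
  )
  snps <- data.frame(
    id = c("prom_plus", "prom_minus", "exon_and_peak", "mir", "enh_only",
           "naked"),
    chrom = "chr1",
    # promoter windows: + strand TSS 10000 -> [9000, 10100];
    # - strand TSS 50000 -> [49900, 51000]
    pos = c(9500L, 50400L, 30500L, 40550L, 60500L, 80000L),
    stringsAsFactors = FALSE
  )
  ann <- annotate_biofeatures(snps, chrom_tracks)
  cls <- classify_functional(ann, gene_tracks)
  expect_equal(
    as.character(cls$class),
    c("promoter", "promoter", "coding_exon", "mir_utr", "enhancer",
      "unclassified")
  )
  # strand matters: +500 of a + strand TSS is outside [-1000, +100]
  snps2 <- data.frame(id = "downstream", chrom = "chr1", pos = 10500L,
                      stringsAsFactors = FALSE)
  cls2 <- classify_functional(annotate_biofeatures(snps2, chrom_tracks),
                              gene_tracks)
  expect_false(as.character(cls2$class) == "promoter")
  # classes partition the set: one class per SNP, counts sum to total
  expect_equal(sum(table(cls$class)), nrow(cls))
  # strandless TSS rejected
  gene_tracks$tss <- GenomicRanges::GRanges("chr1",
                                            IRanges::IRanges(10000, 10000))
  expect_error(classify_functional(ann, gene_tracks), "strand")
})

test_that("locus merging takes the transitive closure of both link rules", {
  # A and B: r2 = 1 (identical columns); B and C share >= 3 proxies but
  # r2(A, C) and r2(B, C) are low; D is isolated
  set.seed(25)
  base <- rbinom(300, 1, 0.5)
  other <- rbinom(300, 1, 0.5)
  lone <- rbinom(300, 1, 0.5)
  H <- cbind(base, base, other, lone)
  p <- panel_from_matrix(H)
  indexes <- p$variants[, c("id", "chrom", "pos")]
  shared <- sprintf("px%d", 1:3)
  corr_tables <- list(
    v001 = data.frame(id = c("v001", "a1")),
    v002 = data.frame(id = c("v002", shared)),
    v003 = data.frame(id = c("v003", shared)),
    v004 = data.frame(id = c("v004", "d1"))
  )
  loci <- merge_loci(indexes, corr_tables, list(POP = p),
                     merge_r2 = 0.5, shared_min = 3)
  locus_of <- setNames(loci$locus, loci$index_id)
  expect_equal(unname(locus_of["v001"]), unname(locus_of["v002"]))
  expect_equal(unname(locus_of["v002"]), unname(locus_of["v003"]))
  expect_false(locus_of["v004"] == locus_of["v001"])
  expect_equal(length(unique(loci$locus)), 2)
  # each index in exactly one locus
  expect_equal(anyDuplicated(loci$index_id), 0L)
})

test_that("two uncorrelated indexes with no shared proxies stay separate", {
  set.seed(26)
  H <- cbind(rbinom(200, 1, 0.5), rbinom(200, 1, 0.5))
  p <- panel_from_matrix(H)
  indexes <- p$variants[, c("id", "chrom", "pos")]
  corr_tables <- list(v001 = data.frame(id = "v001"),
                      v002 = data.frame(id = "v002"))
  loci <- merge_loci(indexes, corr_tables, list(POP = p))
  expect_equal(length(unique(loci$locus)), 2)
})

test_that("biofeature matrix clustering is deterministic and oracle-consistent", {
  m <- rbind(
    s1 = c(1L, 1L, 0L, 0L),
    s2 = c(1L, 1L, 0L, 0L),   # identical to s1: distance 0, merged first
    s3 = c(0L, 0L, 1L, 1L),   # disjoint from s1: distance 1
    s4 = c(0L, 1L, 1L, 0L),
    s5 = c(1L, 0L, 0L, 1L),
    s6 = c(0L, 0L, 0L, 1L)
  )
  colnames(m) <- c("t1", "t2", "t3", "t4")
  res <- cluster_matrix(m)
  expect_equal(res$row_hclust$height[1], 0)
  first_pair <- rownames(m)[sort(-res$row_hclust$merge[1, ])]
  expect_setequal(first_pair, c("s1", "s2"))
  d <- as.matrix(riskenhancer:::.jaccard_dist(m))
  expect_equal(d["s1", "s3"], 1)
  expect_equal(d["s1", "s2"], 0)
  # independent distance oracle
  if (requireNamespace("vegan", quietly = TRUE)) {
    dv <- as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
    expect_equal(unname(as.matrix(d)), unname(dv), tolerance = 1e-12)
  }
  # naive O(n^3) average-linkage agglomeration oracle on merge heights
  naive_heights <- local({
    dm <- as.matrix(riskenhancer:::.jaccard_dist(m))
    groups <- as.list(rownames(m))
    heights <- numeric(0)
    while (length(groups) > 1) {
      best <- c(NA, NA)
      bestd <- Inf
      for (i in seq_along(groups)) {
        for (j in seq_len(i - 1)) {
          dd <- mean(dm[groups[[i]], groups[[j]]])
          if (dd < bestd) {
            bestd <- dd
            best <- c(i, j)
          }
        }
      }
      heights <- c(heights, bestd)
      groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[1]]])
      groups[[best[1]]] <- NULL
    }
    heights
  })
  expect_equal(res$row_hclust$height, naive_heights, tolerance = 1e-12)
  # input order does not change the result
  perm <- c(4, 1, 6, 2, 5, 3)
  res2 <- cluster_matrix(m[perm, ])
  expect_equal(res2$row_order, res$row_order)
  expect_error(cluster_matrix(matrix(0L, 3, 3,
                                     dimnames = list(letters[1:3],
                                                     LETTERS[1:3]))),
               "all-zero")
})
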