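.snp_granges <- function(snps) {
  GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
}

.check_track <- function(gr, nm) {
  if (!methods::is(gr, "GRanges")) {
    stop_bad_arg("track '", nm, "' is not a GRanges")
  }
  if (length(gr) && any(GenomicRanges::width(gr) < 1L)) {
    stop_bad_arg("track '", nm, "' has malformed intervals (end <= start)")
  }
  gr
}

#' Annotate SNPs with chromatin biofeature memberships
#'
#' Adds, for each SNP, the set of biofeature tracks whose intervals
#' contain its position.  Tracks are 1-based closed `GRanges` in memory;
#' BED files read through [read_bed()] follow the half-open BED
#' convention, so a SNP at a BED interval's end coordinate is not a
#' member.  SNPs in no track are retained with an empty membership (they
#' classify as `unclassified` downstream).
#'
#' @param snps Data frame with at least `id`, `chrom`, `pos` (1-based).
#' @param tracks Named list of `GRanges` biofeature tracks.
#' @return `snps` with list-column `memberships` and integer column
#'   `n_biofeatures`.
#' @export
annotate_biofeatures <- function(snps, tracks) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stop_bad_arg("tracks must be a named list")
  }
  gr_snps <- .snp_granges(snps)
  member <- matrix(FALSE, nrow(snps), length(tracks),
                   dimnames = list(snps$id, names(tracks)))
  for (nm in names(tracks)) {
    gr <- .check_track(tracks[[nm]], nm)
    member[, nm] <- IRanges::overlapsAny(gr_snps, gr)
  }
  snps$memberships <- lapply(seq_len(nrow(snps)), function(i) {
    names(tracks)[member[i, ]]
  })
  snps$n_biofeatures <- vapply(snps$memberships, length, integer(1))
  snps
}

#' Classify annotated SNPs by putative functional category
#'
#' Assigns each SNP one class under an explicit precedence rule:
#' `coding_exon` (in a coding exon) beats `mir_utr` (in a microRNA target
#' site within a 5' or 3' UTR) beats `promoter` (within the strand-aware
#' window -1000 bp to +100 bp around a transcription start site) beats
#' `enhancer` (any chromatin biofeature membership and nothing above);
#' SNPs matching nothing are `unclassified`.  A multi-category SNP is
#' counted once, under its highest class, so class counts partition the
#' classified set; the full membership list is preserved.
#'
#' @param annotated Output of [annotate_biofeatures()].
#' @param gene_tracks Named list of `GRanges`: `tss` (strand required),
#'   `coding_exon`, `utr3`, `utr5`, `mir_target`.
#' @param promoter_window Length-2 vector, bp relative to the TSS
#'   (default `c(-1000, 100)`), applied strand-aware.
#' @return `annotated` with a `class` factor column.
#' @export
classify_functional <- function(annotated, gene_tracks,
                                promoter_window = c(-1000, 100)) {
  need <- c("tss", "coding_exon", "utr3", "utr5", "mir_target")
  missing_tr <- setdiff(need, names(gene_tracks))
  if (length(missing_tr)) {
    stop_bad_arg("gene_tracks missing: ", paste(missing_tr, collapse = ", "))
  }
  tss <- gene_tracks$tss
  if (length(tss) && any(as.character(GenomicRanges::strand(tss)) == "*")) {
    stop_bad_arg("tss track must carry strand for promoter windows")
  }
  promoters <- GenomicRanges::promoters(
    tss, upstream = -promoter_window[1], downstream = promoter_window[2] + 1L
  )
  gr_snps <- .snp_granges(annotated)
  in_exon <- IRanges::overlapsAny(gr_snps, gene_tracks$coding_exon)
  in_utr <- IRanges::overlapsAny(gr_snps, gene_tracks$utr3) |
    IRanges::overlapsAny(gr_snps, gene_tracks$utr5)
  in_mir <- IRanges::overlapsAny(gr_snps, gene_tracks$mir_target) & in_utr
  in_prom <- IRanges::overlapsAny(gr_snps, promoters)
  in_enh <- annotated$n_biofeatures > 0L
  cls <- rep("unclassified", nrow(annotated))
  cls[in_enh] <- "enhancer"
  cls[in_prom] <- "promoter"
  cls[in_mir] <- "mir_utr"
  cls[in_exon] <- "coding_exon"
  annotated$class <- factor(
    cls, levels = c("coding_exon", "mir_utr", "promoter", "enhancer",
                    "unclassified")
  )
  annotated
}

# Minimal union-find with path compression.
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
.uf_union <- function(parent, i, j) {
  ri <- .uf_find(parent, i)
  rj <- .uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

#' Merge index SNPs into risk loci
#'
#' Groups GWAS index SNPs into loci by transitive closure: two indexes
#' merge if their pairwise r-squared reaches `merge_r2` in any population
#' whose panel holds both, or if they share at least `shared_min`
#' correlated SNPs.  Loci are numbered in genomic order of their leftmost
#' index SNP; every index SNP lands in exactly one locus.
#'
#' @param indexes Data frame of index SNPs (`id`, `chrom`, `pos`).
#' @param corr_tables Named list (by index id) of
#'   [find_correlated_snps()] outputs.
#' @param panels Named list of [haplotype_panel()] by population.
#' @param merge_r2 Pairwise r-squared threshold (default 0.5).
#' @param shared_min Shared correlated-SNP count threshold (default 3).
#' @return Data frame with `locus`, `index_id`, and a list-column
#'   `members` of the locus's merged correlated-SNP ids.
#' @export
merge_loci <- function(indexes, corr_tables, panels, merge_r2 = 0.5,
                       shared_min = 3L) {
  n <- nrow(indexes)
  if (!all(indexes$id %in% names(corr_tables))) {
    stop_bad_arg("corr_tables must cover every index SNP")
  }
  proxies <- lapply(indexes$id, function(id) corr_tables[[id]]$id)
  parent <- .uf_new(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      linked <- FALSE
      for (pop in names(panels)) {
        pv <- panels[[pop]]$variants$id
        if (all(c(indexes$id[i], indexes$id[j]) %in% pv)) {
          r2 <- tryCatch(
            pairwise_r2(panels[[pop]], indexes$id[i], indexes$id[j]),
            error = function(e) NA_real_
          )
          if (!is.na(r2) && r2 >= merge_r2) linked <- TRUE
        }
      }
      if (!linked &&
          length(intersect(proxies[[i]], proxies[[j]])) >= shared_min) {
        linked <- TRUE
      }
      if (linked) parent <- .uf_union(parent, i, j)
    }
  }
  root <- vapply(seq_len(n), function(i) .uf_find(parent, i), integer(1))
  groups <- split(seq_len(n), root)
  # number loci by genomic order of the leftmost member
  ord <- order(vapply(groups, function(g) {
    min(indexes$pos[g])
  }, numeric(1)))
  groups <- groups[ord]
  out <- do.call(rbind, lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    data.frame(locus = k, index_id = indexes$id[g], stringsAsFactors = FALSE)
  }))
  out$members <- lapply(out$locus, function(k) {
    g <- groups[[k]]
    sort(unique(unlist(proxies[g])))
  })
  out
}

#' SNP-by-biofeature incidence matrix
#'
#' @param annotated Output of [annotate_biofeatures()].
#' @return Binary integer matrix, SNP ids as rows, track names as columns.
#' @export
snp_biofeature_matrix <- function(annotated) {
  tracks <- sort(unique(unlist(annotated$memberships)))
  m <- matrix(0L, nrow(annotated), length(tracks),
              dimnames = list(annotated$id, tracks))
  for (i in seq_len(nrow(annotated))) {
    m[i, annotated$memberships[[i]]] <- 1L
  }
  m
}

.jaccard_dist <- function(m) {
  # pairwise Jaccard distance between rows of a binary matrix
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  union <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 0
  as.dist(d)
}

#' Cluster the SNP-by-biofeature matrix
#'
#' Agglomerative clustering of rows (SNPs) and columns (biofeatures) with
#' Jaccard distance and average linkage.  Rows and columns are sorted by
#' label before clustering so the result is deterministic regardless of
#' input order.
#'
#' @param m Binary matrix from [snp_biofeature_matrix()]; needs at least
#'   two rows and two columns and at least one nonzero entry.
#' @return List with `row_hclust`, `col_hclust`, `row_order`,
#'   `col_order` (label vectors) and the reordered `matrix`.
#' @export
cluster_matrix <- function(m) {
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop_bad_arg("need at least 2 SNPs and 2 tracks to cluster")
  }
  if (all(m == 0L)) stop_bad_arg("all-zero matrix cannot be clustered")
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  row_hc <- hclust(.jaccard_dist(m), method = "average")
  col_hc <- hclust(.jaccard_dist(t(m)), method = "average")
  list(
    row_hclust = row_hc, col_hclust = col_hc,
    row_order = rownames(m)[row_hc$order],
    col_order = colnames(m)[col_hc$order],
    matrix = m[row_hc$order, col_hc$order, drop = FALSE]
  )
}
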