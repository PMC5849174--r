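# Pairwise r2 between SNP dosages, LD blocks as connected components, and
# block pruning that keeps the most strongly associated SNP per block.

#' Pairwise r-squared matrix
#'
#' Composite (genotype-dosage) linkage disequilibrium: the square of the
#' Pearson correlation between dosage vectors over samples with non-missing
#' calls at both SNPs. Phase-free and deterministic; it equals haplotype-based
#' r2 exactly when phase is unambiguous. A SNP monomorphic within a pairwise
#' complete subset yields `NA` for that pair.
#'
#' @param gm a [genotype_matrix()].
#' @param snp_ids optional subset of SNPs (default: all).
#' @return List of class `ld_matrix`: `snp_ids`, `r2` (symmetric, unit
#'   diagonal for polymorphic SNPs) and `n_pairs_used`.
#' @export
ld_matrix <- function(gm, snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- gm$snps$snp_id
  gm <- subset_genotypes(gm, snps = snp_ids)
  d <- gm$dosage
  storage.mode(d) <- "double"
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  r2 <- r^2
  poly <- apply(d, 2, function(v) length(unique(v[!is.na(v)])) > 1)
  diag(r2)[poly] <- 1
  npairs <- crossprod(!is.na(d))
  dimnames(r2) <- dimnames(npairs) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = r2, n_pairs_used = npairs),
            class = "ld_matrix")
}

#' r-squared between two SNPs
#' @param gm a [genotype_matrix()].
#' @param snp_a,snp_b SNP ids.
#' @return r2 in [0, 1], or `NA` if either SNP is monomorphic in the
#'   pairwise-complete subset.
#' @export
pairwise_r2 <- function(gm, snp_a, snp_b) {
  ld <- ld_matrix(gm, snp_ids = c(snp_a, snp_b))
  unname(ld$r2[snp_a, snp_b])
}

#' Partition SNPs into LD blocks
#'
#' A block is a connected component of the graph whose edges join SNP pairs
#' with r2 at or above the threshold (r2 >= 0.5 is treated as moderate to
#' strong LD). Connectivity is transitive, so a chain a-b, b-c forms one
#' block even if a and c are themselves below threshold. Singletons are
#' blocks of size one; `NA` entries contribute no edge.
#'
#' @param ld an [ld_matrix()].
#' @param threshold minimum r2 for an edge (default 0.5).
#' @return Named integer vector: block id per SNP.
#' @export
ld_blocks <- function(ld, threshold = 0.5) {
  stopifnot(inherits(ld, "ld_matrix"))
  adj <- ld$r2 >= threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), ld$snp_ids)
}

#' Prune SNPs by LD, keeping the strongest association per block
#'
#' Within every LD block, exactly one SNP is kept: the one with the smallest
#' association p-value, ties broken by larger |log OR|, then by genomic
#' position (chromosome, then position, ascending). All removals are logged
#' with the retained SNP named.
#'
#' @param candidates association table (rows of [run_association()]) for the
#'   SNPs to prune; all must be present in `ld`.
#' @param ld an [ld_matrix()] covering the candidates.
#' @param manifest a [snp_manifest()] supplying chromosome/position for
#'   tie-breaking.
#' @param threshold r2 threshold defining blocks (default 0.5).
#' @return List with `kept` (SNP ids, input order) and `log` (data.frame:
#'   removed_snp, block_id, kept_snp, r2_to_kept).
#' @export
prune_by_ld <- function(candidates, ld, manifest, threshold = 0.5) {
  ids <- candidates$snp_id
  if (!all(ids %in% ld$snp_ids)) {
    stop("candidates missing from LD matrix: ",
         paste(setdiff(ids, ld$snp_ids), collapse = ", "))
  }
  sub <- ld_matrix_subset(ld, ids)
  blocks <- ld_blocks(sub, threshold = threshold)
  mi <- match(ids, manifest$snp_id)
  ord <- data.frame(
    snp_id = ids, block = blocks[ids],
    p = candidates$p, absbeta = abs(candidates$beta),
    chrom = manifest$chrom[mi], pos = manifest$pos[mi],
    stringsAsFactors = FALSE
  )
  kept <- character(0)
  log_rows <- list()
  for (b in sort(unique(ord$block))) {
    members <- ord[ord$block == b, , drop = FALSE]
    o <- order(members$p, -members$absbeta, members$chrom, members$pos)
    winner <- members$snp_id[o[1]]
    kept <- c(kept, winner)
    losers <- setdiff(members$snp_id, winner)
    if (length(losers)) {
      log_rows[[length(log_rows) + 1]] <- data.frame(
        removed_snp = losers, block_id = b, kept_snp = winner,
        r2_to_kept = sub$r2[losers, winner], stringsAsFactors = FALSE
      )
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(removed_snp = character(), block_id = integer(),
               kept_snp = character(), r2_to_kept = numeric(),
               stringsAsFactors = FALSE)
  rownames(log) <- NULL
  list(kept = ids[ids %in% kept], log = log)
}

ld_matrix_subset <- function(ld, snp_ids) {
  structure(list(snp_ids = snp_ids,
                 r2 = ld$r2[snp_ids, snp_ids, drop = FALSE],
                 n_pairs_used = ld$n_pairs_used[snp_ids, snp_ids,
                                                drop = FALSE]),
            class = "ld_matrix")
}
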