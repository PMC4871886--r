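LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

split_lineage <- function(lineage) {
  trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
}

#' Remove OTUs whose lineage contains an excluded rank label
#'
#' Drops multicellular or otherwise out-of-scope organisms (e.g.
#' Archaeplastida, Metazoa, Amoebozoa, Fungi) by case-insensitive whole-rank
#' match against the lineage string, so that only protists remain.
#'
#' @param table an [otu_table()]
#' @param excluded_lineages character vector of rank labels to exclude
#' @return filtered `otu_table`
#' @export
clean_protist_table <- function(table, excluded_lineages) {
  if (!length(excluded_lineages)) return(table)
  excl <- tolower(excluded_lineages)
  hit <- vapply(table$lineages, function(l) any(tolower(split_lineage(l)) %in% excl),
                logical(1))
  if (any(hit)) {
    mg_log("community", "removed %d OTU(s) matching excluded lineages: %s",
           sum(hit), paste(utils::head(rownames(table$counts)[hit], 10), collapse = ", "))
  }
  if (all(hit)) mg_warn("community", "all OTUs removed by lineage exclusion")
  table$counts <- table$counts[!hit, , drop = FALSE]
  table$lineages <- table$lineages[!hit]
  table
}

#' Multiple rarefaction of an OTU table
#'
#' Each sample is subsampled without replacement to exactly `depth` reads,
#' `repeats` times; the returned counts are the per-OTU means over repeats,
#' rounded half-up to integers. Column sums after rounding stay within
#' `repeats` reads of the target depth.
#'
#' @param table an [otu_table()]
#' @param depth target reads per sample (must not exceed any sample total)
#' @param repeats number of rarefaction draws to average
#' @param seed RNG seed (mandatory, for reproducibility)
#' @return rarefied `otu_table`
#' @export
rarefy <- function(table, depth, repeats = 100, seed) {
  if (missing(seed)) stopf("rarefy requires an explicit seed")
  if (repeats < 1) stopf("repeats must be >= 1")
  totals <- colSums(table$counts)
  short <- totals < depth
  if (any(short)) {
    stopf("depth %d exceeds total reads of sample '%s' (%d)",
          depth, names(totals)[short][1], totals[short][1])
  }
  n_otu <- nrow(table$counts)
  acc <- matrix(0, n_otu, ncol(table$counts), dimnames = dimnames(table$counts))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (r in seq_len(repeats)) {
    for (j in seq_len(ncol(acc))) {
      pool <- rep.int(seq_len(n_otu), table$counts[, j])
      take <- if (depth > 0) pool[sample.int(length(pool), depth)] else integer(0)
      acc[, j] <- acc[, j] + tabulate(take, nbins = n_otu)
    }
  }
  out <- round_half_up(acc / repeats)
  storage.mode(out) <- "integer"
  mg_log("community", "rarefied %d samples to depth %d (%d repeats)",
         ncol(acc), depth, repeats)
  table$counts <- out
  table
}

# save/restore global RNG state so seeded operations do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Keep only OTUs present in every replicate of every group
#'
#' The shared-OTU filter: an OTU is retained only when its count is
#' positive in every sample of every listed group (e.g. all three T0
#' replicates, all T24 controls and all T24 treatments).
#'
#' @param table an [otu_table()]
#' @param groups named list mapping group name to the sample ids it contains
#' @return filtered `otu_table`
#' @export
shared_otu_filter <- function(table, groups) {
  if (!length(groups)) stopf("at least one group required")
  for (g in names(groups)) {
    if (!length(groups[[g]])) stopf("group '%s' is empty", g)
    missing <- setdiff(groups[[g]], colnames(table$counts))
    if (length(missing)) stopf("group '%s' names unknown sample(s): %s",
                               g, paste(missing, collapse = ", "))
  }
  all_samples <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_samples)) stopf("each sample must belong to exactly one group")
  keep <- rowSums(table$counts[, all_samples, drop = FALSE] > 0) == length(all_samples)
  mg_log("community", "shared-OTU filter kept %d of %d OTUs", sum(keep), length(keep))
  table$counts <- table$counts[keep, , drop = FALSE]
  table$lineages <- table$lineages[keep]
  table
}

#' Relative-abundance community profiles at a taxonomic rank
#'
#' Counts are aggregated by the lineage label at `level` (unresolvable
#' lineages become "Unclassified"), converted to percentages of the sample
#' total, and categories below `threshold` percent in every sample are
#' lumped into 'Others'. Columns sum to 100.
#'
#' @param table an [otu_table()]
#' @param level rank to aggregate at: index (1 = domain) or one of
#'   "domain", "phylum", "class", "order", "family", "genus"
#' @param threshold percent RA below which (in all samples) a category is
#'   lumped into 'Others'
#' @return matrix of class `community_profile` (categories x samples, RA %)
#' @export
relative_abundance_profile <- function(table, level = "phylum", threshold = 1.0) {
  if (is.character(level)) {
    level <- match(match.arg(level, LINEAGE_RANKS), LINEAGE_RANKS)
  }
  labels <- vapply(table$lineages, function(l) {
    parts <- split_lineage(l)
    if (length(parts) >= level && nzchar(parts[level])) parts[level] else "Unclassified"
  }, character(1))
  totals <- colSums(table$counts)
  if (any(totals == 0)) {
    stopf("sample '%s' has zero total reads", names(totals)[totals == 0][1])
  }
  agg <- rowsum(table$counts, group = labels)
  ra <- sweep(agg, 2, totals, "/") * 100
  low <- apply(ra, 1, max) < threshold
  if (any(low)) {
    others <- colSums(ra[low, , drop = FALSE])
    ra <- ra[!low, , drop = FALSE]
    ra <- rbind(ra, Others = others)
  }
  ord <- order(-rowMeans(ra))
  if ("Others" %in% rownames(ra)) {
    ord <- c(setdiff(ord, which(rownames(ra) == "Others")), which(rownames(ra) == "Others"))
  }
  ra <- ra[ord, , drop = FALSE]
  class(ra) <- c("community_profile", class(ra))
  ra
}

#' Bray-Curtis similarity matrix
#'
#' `S(x, y) = 100 * (1 - sum|xi - yi| / sum(xi + yi))`, computed between all
#' columns of an abundance or relative-abundance matrix.
#'
#' @param x numeric matrix, categories x samples (a `community_profile`
#'   works directly)
#' @return matrix of class `similarity_matrix` (percent, diagonal 100)
#' @export
bray_curtis <- function(x) {
  x <- unclass(x)
  if (ncol(x) < 2) stopf("need >= 2 samples")
  n <- ncol(x)
  s <- matrix(100, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(x[, i] + x[, j])
      if (denom == 0) stopf("samples '%s' and '%s' are both all-zero",
                            colnames(x)[i], colnames(x)[j])
      s[i, j] <- s[j, i] <- 100 * (1 - sum(abs(x[, i] - x[, j])) / denom)
    }
  }
  class(s) <- c("similarity_matrix", class(s))
  s
}

#' Group-average (UPGMA) hierarchical clustering of a similarity matrix
#'
#' Agglomerates on dissimilarity (100 - similarity) with unweighted
#' group-average linkage. Ties are broken deterministically in favour of the
#' pair whose lexicographically smallest member label sorts first. Merge
#' levels are recorded as similarity percent and are monotone non-increasing.
#'
#' @param sim a [bray_curtis()] similarity matrix
#' @return object of class `upgma_dendrogram`: `merges` data.frame
#'   (cluster indices as in [stats::hclust()] and similarity %), `labels`,
#'   and an `hclust` member for interoperability
#' @export
upgma <- function(sim) {
  labels <- colnames(sim)
  n <- length(labels)
  d <- 100 - unclass(sim)
  diag(d) <- NA
  # active cluster bookkeeping
  members <- as.list(seq_len(n))         # leaf indices per active cluster
  ids <- -seq_len(n)                     # hclust coding: negative = leaf
  minlab <- labels                       # lexicographic tie-break key
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(max(n - 1, 0))) {
    m <- length(members)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        dij <- d[i, j]
        lab <- sort(c(minlab[i], minlab[j]))
        cand <- list(i = i, j = j, d = dij, lab = lab)
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (lab[1] < best$lab[1] || (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- best$d
    # group-average update
    newrow <- rep(NA_real_, m)
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      newrow[k] <- (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    }
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], NA))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    minlab <- c(minlab[keep], min(minlab[c(i, j)]))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    ids <- c(ids[keep], step)
  }
  hc <- structure(list(merge = merge, height = height,
                       order = hclust_order(merge, n), labels = labels,
                       method = "average", call = match.call(),
                       dist.method = "bray-curtis dissimilarity"),
                  class = "hclust")
  res <- list(
    merges = data.frame(a = merge[, 1], b = merge[, 2],
                        similarity = 100 - height),
    labels = labels,
    hclust = hc
  )
  class(res) <- "upgma_dendrogram"
  res
}

# leaf ordering for an hclust merge matrix (left-to-right tree traversal)
hclust_order <- function(merge, n) {
  if (n == 1) return(1L)
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("<upgma_dendrogram> %d leaves; merge similarities: %s\n",
              length(x$labels), paste(sprintf("%.1f", x$merges$similarity), collapse = ", ")))
  invisible(x)
}

#' Serialize a UPGMA dendrogram to Newick text
#'
#' Branch lengths follow from the merge levels of the ultrametric tree
#' (node height = dissimilarity / 2).
#'
#' @param dend an [upgma()] result
#' @param path optional file to write to
#' @return the Newick string, invisibly when written to file
#' @export
write_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# all distinct permutations of a label multiset, as a matrix (n x P)
multiset_permutations <- function(labels) {
  rec <- function(remaining) {
    if (length(remaining) == 1) return(matrix(remaining, 1, 1))
    out <- NULL
    for (u in unique(remaining)) {
      idx <- match(u, remaining)
      sub <- rec(remaining[-idx])
      out <- cbind(out, rbind(matrix(u, 1, ncol(sub)), sub))
    }
    out
  }
  rec(sort(labels))
}

count_distinct_labelings <- function(labels) {
  tab <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based permutation test of group separation on a
#' similarity matrix. With ranks taken on the dissimilarities (average-rank
#' ties), `R = (mean between-group rank - mean within-group rank) /
#' (N(N-1)/4)`; R near 1 means all within-group pairs are more similar than
#' any between-group pair, R near 0 means no separation. The p-value is
#' one-sided (large R): exhaustive over all distinct label permutations when
#' there are no more of them than `n_permutations`, otherwise estimated from
#' `n_permutations` sampled permutations as
#' `(1 + #{R_perm >= R_obs}) / (1 + n_permutations)`.
#'
#' @param sim a [bray_curtis()] similarity matrix
#' @param labels group label per sample (>= 2 groups, each of size >= 2)
#' @param n_permutations permutation budget
#' @param seed RNG seed for sampled permutations
#' @return object of class `anosim_result` with `r_statistic`, `p_value`,
#'   `n_permutations`, `method`, `group_labels`
#' @export
anosim <- function(sim, labels, n_permutations = 999, seed = 1) {
  n <- ncol(sim)
  if (length(labels) != n) stopf("one label per sample required")
  tab <- table(labels)
  if (length(tab) < 2) stopf("need >= 2 groups")
  if (any(tab < 2)) stopf("group '%s' has fewer than 2 samples", names(tab)[tab < 2][1])
  d <- 100 - unclass(sim)
  pair_i <- pair_j <- integer(0)
  for (i in seq_len(n - 1)) {
    pair_i <- c(pair_i, rep.int(i, n - i))
    pair_j <- c(pair_j, (i + 1):n)
  }
  r <- rank(d[cbind(pair_i, pair_j)])  # average-rank ties
  M <- length(r)
  denom <- n * (n - 1) / 4
  r_stat <- function(lab_matrix) {
    within <- lab_matrix[pair_i, , drop = FALSE] == lab_matrix[pair_j, , drop = FALSE]
    rw <- colSums(r * within) / colSums(within)
    rb <- colSums(r * !within) / colSums(!within)
    (rb - rw) / denom
  }
  labels <- as.character(labels)
  r_obs <- r_stat(matrix(labels, ncol = 1))

  n_distinct <- count_distinct_labelings(labels)
  if (n_distinct <= n_permutations) {
    perms <- multiset_permutations(labels)
    r_all <- r_stat(perms)
    p <- sum(r_all >= r_obs - 1e-12) / ncol(perms)
    method <- "exhaustive"
    n_used <- ncol(perms)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    perms <- vapply(seq_len(n_permutations), function(i) sample(labels), character(n))
    r_all <- r_stat(perms)
    p <- (1 + sum(r_all >= r_obs - 1e-12)) / (1 + n_permutations)
    method <- "sampled"
    n_used <- n_permutations
  }
  res <- list(r_statistic = unname(r_obs), p_value = p,
              n_permutations = n_used, method = method,
              group_labels = names(tab))
  class(res) <- "anosim_result"
  res
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("<anosim> R = %.3f, p = %.4g (%s, %d permutations; groups: %s)\n",
              x$r_statistic, x$p_value, x$method, x$n_permutations,
              paste(x$group_labels, collapse = ", ")))
  invisible(x)
}

#' Mann-Whitney U test (exact for small samples)
#'
#' U from rank sums with average-rank ties. The two-sided p-value is exact
#' by enumeration of all arrangements when `m + n <= 16`
#' (`p = 2 * min(P(U <= u), P(U >= u))`, capped at 1), and a tie-corrected
#' normal approximation with continuity correction otherwise.
#'
#' @param x,y numeric samples (non-empty)
#' @return list with `U` (statistic of the first sample), `p_value`, `method`
#' @export
mann_whitney <- function(x, y) {
  m <- length(x); n <- length(y)
  if (!m || !n) stopf("both samples must be non-empty")
  N <- m + n
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (N <= 16) {
    combs <- utils::combn(N, m)
    us <- colSums(matrix(r[combs], nrow = m)) - m * (m + 1) / 2
    p_le <- mean(us <= U + 1e-9)
    p_ge <- mean(us >= U - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- m * n / 2
    ties <- table(r)
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  list(U = unname(U), p_value = p, method = method)
}

#' Write a similarity matrix to TSV
#' @param sim similarity matrix
#' @param path output TSV
#' @export
write_similarity <- function(sim, path) {
  df <- data.frame(sample_id = rownames(sim),
                   apply(unclass(sim), 2, format_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write community profiles to TSV
#' @param profile a `community_profile` matrix
#' @param path output TSV
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(category = rownames(profile),
                   apply(unclass(profile), 2, format_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
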