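#' Clustering thresholds for ensemble merging
#'
#' Per-genotyper calls are clustered against the input (anchor) variant
#' set with class-specific rules: SVs (> 50 bp or INV/DUP by type) cluster
#' when their positional difference is below `sv_pos_tol` (strict) and
#' their length-difference ratio is below `sv_len_ratio` (strict, relative
#' to the anchor length); indels use `indel_pos_tol` with the same ratio
#' rule; SNPs require exact positional matching (`snp_pos_tol = 0`).
#'
#' @param sv_pos_tol bp, strict upper bound on SV start-position difference.
#' @param sv_len_ratio fraction, strict upper bound on
#'   `|len_call - len_anchor| / |len_anchor|`.
#' @param indel_pos_tol bp, strict upper bound for indels.
#' @param snp_pos_tol bp, inclusive bound for SNPs (0 = exact match).
#' @return a `cluster_thresholds` list.
#' @export
cluster_thresholds <- function(sv_pos_tol = 200, sv_len_ratio = 0.25,
                               indel_pos_tol = 10, snp_pos_tol = 0) {
  stopifnot(sv_pos_tol >= 0, sv_len_ratio >= 0, indel_pos_tol >= 0,
            snp_pos_tol >= 0)
  structure(list(sv_pos_tol = sv_pos_tol, sv_len_ratio = sv_len_ratio,
                 indel_pos_tol = indel_pos_tol, snp_pos_tol = snp_pos_tol),
            class = "cluster_thresholds")
}

# length used in the ratio rule: allele-length magnitude for sequence
# indels/SVs, reference span for inversions and duplications (an inversion
# has signed length 0)
effective_length <- function(records) {
  ifelse(records$sv_type %in% c("INV", "DUP"),
         records$end - records$pos + 1L, abs(records$length))
}

rbind_outputs <- function(outputs) {
  if (is.data.frame(outputs)) return(outputs)
  keep <- c("chrom", "pos", "ref", "alt", "var_class", "sv_type", "length",
            "end", "a1", "a2", "gq", "dp", "source")
  do.call(rbind, lapply(outputs, function(x) x[, keep, drop = FALSE]))
}

#' Cluster per-genotyper calls against the anchor variant set
#'
#' Every cluster is anchored on one input variant (the population/graph
#' variant whose coordinates define the cluster); each call is assigned to
#' at most one anchor of the same variant class (and the same SV type for
#' SVs) satisfying the position and length-ratio thresholds. Among several
#' admissible anchors the nearest by start position wins, ties broken by
#' smaller length difference, then by lower anchor position. Each
#' genotyper contributes at most one call per anchor (the best-matching
#' one); all other calls are returned unassigned.
#'
#' @param anchors variant table of input variants (deduplicated; sorted
#'   internally).
#' @param outputs a single variant table with a `source` column, or a list
#'   of per-genotyper variant tables.
#' @param thresholds a [cluster_thresholds()].
#' @return a list with `anchors` (sorted, with `anchor_id`), `assignments`
#'   (calls with an `anchor_id` column, `NA` when unassigned) and
#'   `unassigned` (the subset of calls with no anchor).
#' @export
cluster_calls <- function(anchors, outputs, thresholds = cluster_thresholds()) {
  stopifnot(inherits(thresholds, "cluster_thresholds"))
  anchors <- sort_variants(anchors)
  anchors$anchor_id <- seq_len(nrow(anchors))
  rownames(anchors) <- NULL
  calls <- rbind_outputs(outputs)
  n <- nrow(calls)
  calls$anchor_id <- rep(NA_integer_, n)
  if (n == 0L || nrow(anchors) == 0L) {
    return(list(anchors = anchors, assignments = calls,
                unassigned = calls))
  }
  a_elen <- effective_length(anchors)
  c_elen <- effective_length(calls)
  grp_key <- function(x) paste(x$chrom, x$var_class,
                               ifelse(x$var_class == "SV", x$sv_type, "-"))
  a_groups <- split(seq_len(nrow(anchors)), grp_key(anchors))
  ck <- grp_key(calls)

  pos_diff <- len_diff <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ai <- a_groups[[ck[i]]]
    if (is.null(ai)) next
    d <- abs(anchors$pos[ai] - calls$pos[i])
    tol_ok <- switch(calls$var_class[i],
                     SNP = d <= thresholds$snp_pos_tol,
                     INDEL = d < thresholds$indel_pos_tol,
                     SV = d < thresholds$sv_pos_tol)
    ld <- abs(c_elen[i] - a_elen[ai])
    if (calls$var_class[i] != "SNP") {
      ratio_ok <- ifelse(a_elen[ai] == 0, c_elen[i] == 0,
                         ld / a_elen[ai] < thresholds$sv_len_ratio)
      tol_ok <- tol_ok & ratio_ok
    }
    cand <- ai[tol_ok]
    if (length(cand) == 0L) next
    d <- d[tol_ok]; ld <- ld[tol_ok]
    best <- order(d, ld, anchors$pos[cand])[1]
    calls$anchor_id[i] <- anchors$anchor_id[cand[best]]
    pos_diff[i] <- d[best]; len_diff[i] <- ld[best]
  }
  # one call per genotyper per node: keep the best-matching call
  key <- paste(calls$source, calls$anchor_id)
  assigned <- which(!is.na(calls$anchor_id))
  if (length(assigned) > 1L) {
    ord <- assigned[order(pos_diff[assigned], len_diff[assigned], assigned)]
    dup <- ord[duplicated(key[ord])]
    calls$anchor_id[dup] <- NA_integer_
  }
  rownames(calls) <- NULL
  list(anchors = anchors, assignments = calls,
       unassigned = calls[is.na(calls$anchor_id), , drop = FALSE])
}

#' Build the variant graph from clustered calls
#'
#' Nodes are the anchor variants, each holding the co-clustered calls from
#' every genotyper; anchors sharing a `(chrom, pos)` coordinate lie on the
#' same branch. Iteration order is genomic.
#'
#' @param clustered output of [cluster_calls()].
#' @return a `variant_graph`: list with `nodes` (anchor table with
#'   `anchor_id` and `branch`), `calls` (assigned calls only).
#' @export
build_variant_graph <- function(clustered) {
  nodes <- clustered$anchors
  branch_key <- paste(nodes$chrom, nodes$pos)
  nodes$branch <- match(branch_key, unique(branch_key))
  calls <- clustered$assignments
  calls <- calls[!is.na(calls$anchor_id), , drop = FALSE]
  structure(list(nodes = nodes, calls = calls), class = "variant_graph")
}

#' @export
print.variant_graph <- function(x, ...) {
  cat("Variant graph: ", nrow(x$nodes), " nodes, ",
      length(unique(x$nodes$branch)), " branches, ",
      nrow(x$calls), " genotyper calls\n", sep = "")
  invisible(x)
}

#' Z-score normalization of per-genotyper read depths
#'
#' Different genotypers report depths on different scales, so depths are
#' made comparable by per-tool Z-scores: `D' = (D - mu) / sigma`, with
#' `mu` the mean and `sigma` the population standard deviation
#' (`sqrt(sum((D_i - mu)^2) / N)`) over all `N` depth-bearing calls of
#' that tool. A tool with zero depth spread (`sigma = 0`) gets `D' = 0`
#' for all calls; calls without a DP value get `D' = NA`.
#'
#' @param outputs a variant table with `source` and `dp` columns, or a
#'   list of per-genotyper tables.
#' @return a list with `stats` (data.frame `tool, mu, sigma, n`) and
#'   `calls` (the input with a `dprime` column appended).
#' @export
normalize_depths <- function(outputs) {
  calls <- rbind_outputs(outputs)
  calls$dprime <- rep(NA_real_, nrow(calls))
  tools <- unique(calls$source)
  stats_list <- list()
  for (tool in tools) {
    idx <- which(calls$source == tool & !is.na(calls$dp))
    if (length(idx) == 0L) next
    d <- calls$dp[idx]
    mu <- mean(d)
    sigma <- sqrt(sum((d - mu)^2) / length(d))
    calls$dprime[idx] <- if (sigma > 0) (d - mu) / sigma else 0
    stats_list[[tool]] <- data.frame(tool = tool, mu = mu, sigma = sigma,
                                     n = length(d), stringsAsFactors = FALSE)
  }
  stats <- if (length(stats_list)) do.call(rbind, stats_list)
           else data.frame(tool = character(), mu = numeric(),
                           sigma = numeric(), n = integer())
  rownames(stats) <- NULL
  list(stats = stats, calls = calls)
}

# shared consensus engine: genotype supported by most genotypers;
# ties (and the all-singleton SV case) resolved by the smallest |D'|;
# missing genotypes never contribute support
consensus_genotype <- function(a1, a2, dprime, small) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]; dprime <- dprime[ok]
  if (length(a1) == 0L) return(NULL)
  key <- paste0(a1, "/", a2)
  tab <- table(key)
  mx <- max(tab)
  if (small && mx < 2L) return(NULL)  # no genotype supported by > 1 tool
  if (!small && mx == 1L) {
    # all genotype frequencies equal 1: smallest normalized absolute depth
    score <- abs(dprime)
    score[is.na(score)] <- Inf
    best <- order(score, key)[1]
    chosen <- key[best]
  } else {
    cand <- names(tab)[tab == mx]
    if (length(cand) == 1L) {
      chosen <- cand
    } else {
      best_abs <- vapply(cand, function(g) {
        s <- abs(dprime[key == g])
        if (all(is.na(s))) Inf else min(s, na.rm = TRUE)
      }, numeric(1))
      chosen <- cand[order(best_abs, cand)][1]
    }
  }
  sup <- which(key == chosen)
  alleles <- as.integer(strsplit(chosen, "/", fixed = TRUE)[[1]])
  list(a1 = alleles[1], a2 = alleles[2], support = length(sup), idx = sup)
}

#' Consensus genotype for a small-variant node
#'
#' SNPs and indels take the genotype supported by most genotypers; when no
#' genotype is supported by more than one genotyper the variant is skipped
#' (`NULL`). Ties among equally supported genotypes are resolved by the
#' smallest absolute normalized depth among their supporting calls.
#'
#' @param node data.frame of the node's calls with columns `a1, a2,
#'   dprime` (and optionally `source`).
#' @return `NULL` (skipped) or a list `a1, a2, support, idx`.
#' @export
consensus_small <- function(node) {
  consensus_genotype(node$a1, node$a2, node$dprime, small = TRUE)
}

#' Consensus genotype for an SV node
#'
#' The genotype supported by most genotypers wins; when all genotype
#' frequencies are equal to 1, the genotype of the call with the smallest
#' absolute normalized depth is taken. A node with no (non-missing) calls
#' is skipped.
#'
#' @inheritParams consensus_small
#' @return `NULL` (skipped) or a list `a1, a2, support, idx`.
#' @export
consensus_sv <- function(node) {
  consensus_genotype(node$a1, node$a2, node$dprime, small = FALSE)
}

#' Merge genotyper outputs into consensus calls
#'
#' End-to-end ensemble merge: cluster every genotyper's calls against the
#' anchor (input) variants, build the variant graph, Z-score-normalize
#' per-tool depths, and emit one consensus genotype per anchor. Output
#' records carry the anchor's coordinates and alleles (the input variant
#' defines the true coordinates of its cluster), the consensus GT, the
#' supporting-tool list and the support count.
#'
#' @param anchors variant table of input variants.
#' @param outputs list of per-genotyper variant tables (each with its
#'   `source` set), or one combined table.
#' @param thresholds a [cluster_thresholds()].
#' @return a variant table with extra columns `tools` (comma-separated)
#'   and `support`; anchors whose node was skipped are absent.
#' @export
merge_genotyper_outputs <- function(anchors, outputs,
                                    thresholds = cluster_thresholds()) {
  clustered <- cluster_calls(anchors, outputs, thresholds)
  norm <- normalize_depths(clustered$assignments)
  graph <- build_variant_graph(
    list(anchors = clustered$anchors, assignments = norm$calls))
  calls_by_anchor <- split(seq_len(nrow(graph$calls)),
                           graph$calls$anchor_id)
  nodes <- graph$nodes
  keep <- logical(nrow(nodes))
  a1 <- a2 <- rep(NA_integer_, nrow(nodes))
  tools <- character(nrow(nodes))
  support <- integer(nrow(nodes))
  for (j in seq_len(nrow(nodes))) {
    idx <- calls_by_anchor[[as.character(nodes$anchor_id[j])]]
    if (is.null(idx)) next
    node <- graph$calls[idx, , drop = FALSE]
    res <- if (nodes$var_class[j] == "SV") consensus_sv(node)
           else consensus_small(node)
    if (is.null(res)) next
    keep[j] <- TRUE
    a1[j] <- res$a1; a2[j] <- res$a2
    support[j] <- res$support
    tools[j] <- paste(sort(node$source[res$idx]), collapse = ",")
  }
  out <- nodes[keep, c("chrom", "pos", "ref", "alt", "var_class", "sv_type",
                       "length", "end"), drop = FALSE]
  out$a1 <- a1[keep]; out$a2 <- a2[keep]
  out$gq <- NA_real_; out$dp <- NA_real_
  out$source <- "ensemble"
  out$tools <- tools[keep]
  out$support <- support[keep]
  out <- sort_variants(out)
  rownames(out) <- NULL
  out
}
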