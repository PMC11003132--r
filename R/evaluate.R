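#' Benchmark matching rule
#'
#' An SV call is a correct *presence* when both its start and end
#' breakpoints lie within `sv_bp_tol` of the true positions (inclusive)
#' and its size differs from the true size by at most
#' `sv_size_tol * |true length|` (inclusive). An indel needs a position
#' difference strictly below `indel_pos_tol`; a SNP needs an exact
#' position and allele match. A call whose genotype also equals the truth
#' is a correct *genotype*.
#'
#' @param sv_bp_tol bp, inclusive breakpoint tolerance for SVs.
#' @param sv_size_tol fraction, inclusive size tolerance for SVs.
#' @param indel_pos_tol bp, strict position tolerance for indels.
#' @param snp_exact logical; SNPs require exact position + allele match.
#' @param indel_size_rule logical; when `TRUE`, indels must additionally
#'   pass the SV size-ratio test (off by default: indel presence is
#'   position + class only).
#' @return a `match_rule` list.
#' @export
match_rule <- function(sv_bp_tol = 200, sv_size_tol = 0.25,
                       indel_pos_tol = 10, snp_exact = TRUE,
                       indel_size_rule = FALSE) {
  stopifnot(sv_bp_tol >= 0, sv_size_tol >= 0, indel_pos_tol >= 0)
  structure(list(sv_bp_tol = sv_bp_tol, sv_size_tol = sv_size_tol,
                 indel_pos_tol = indel_pos_tol, snp_exact = isTRUE(snp_exact),
                 indel_size_rule = isTRUE(indel_size_rule)),
            class = "match_rule")
}

# vectorized presence test of one call against many truth rows (or vice
# versa); inputs are aligned vectors
presence_ok <- function(c_chrom, c_pos, c_end, c_len, c_class, c_svt,
                        c_ref, c_alt,
                        t_chrom, t_pos, t_end, t_len, t_class, t_svt,
                        t_ref, t_alt, rule) {
  ok <- c_chrom == t_chrom & c_class == t_class
  sv <- ok & c_class == "SV"
  ok[sv] <- c_svt[sv] == t_svt[sv] &
    abs(c_pos[sv] - t_pos[sv]) <= rule$sv_bp_tol &
    abs(c_end[sv] - t_end[sv]) <= rule$sv_bp_tol &
    abs(c_len[sv] - t_len[sv]) <= rule$sv_size_tol * abs(t_len[sv])
  ind <- ok & c_class == "INDEL"
  ind_ok <- abs(c_pos[ind] - t_pos[ind]) < rule$indel_pos_tol
  if (rule$indel_size_rule) {
    ind_ok <- ind_ok &
      abs(c_len[ind] - t_len[ind]) <= rule$sv_size_tol * abs(t_len[ind])
  }
  ok[ind] <- ind_ok
  snp <- ok & c_class == "SNP"
  ok[snp] <- if (rule$snp_exact) {
    c_pos[snp] == t_pos[snp] & c_ref[snp] == t_ref[snp] &
      c_alt[snp] == t_alt[snp]
  } else abs(c_pos[snp] - t_pos[snp]) <= 0
  ok
}

#' Match one call against one truth variant
#'
#' @param call,truth single-row variant tables (same chromosome expected;
#'   a different chromosome or class is simply no match).
#' @param rule a [match_rule()].
#' @return `"NO_MATCH"`, `"PRESENCE"` (position/size match only) or
#'   `"GENOTYPE"` (presence plus genotype agreement).
#' @export
match_variant <- function(call, truth, rule = match_rule()) {
  ok <- presence_ok(call$chrom, call$pos, call$end, call$length,
                    call$var_class, call$sv_type, call$ref, call$alt,
                    truth$chrom, truth$pos, truth$end, truth$length,
                    truth$var_class, truth$sv_type, truth$ref, truth$alt,
                    rule)
  if (!ok) return("NO_MATCH")
  if (genotype_equal(call$a1, call$a2, truth$a1, truth$a2)) "GENOTYPE"
  else "PRESENCE"
}

metric_row <- function(class, level, stratum, tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  data.frame(class = class, level = level, stratum = stratum,
             tp = tp, fp = fp, fn = fn,
             precision = precision, recall = recall, f = f,
             stringsAsFactors = FALSE)
}

# greedy nearest-first 1-to-1 pairing of calls to truth within one class
pair_class <- function(calls, truth, ci, ti, rule) {
  pairs <- NULL
  if (length(ci) > 0L && length(ti) > 0L) {
    grid <- expand.grid(c_ = ci, t_ = ti)
    ok <- presence_ok(calls$chrom[grid$c_], calls$pos[grid$c_],
                      calls$end[grid$c_], calls$length[grid$c_],
                      calls$var_class[grid$c_], calls$sv_type[grid$c_],
                      calls$ref[grid$c_], calls$alt[grid$c_],
                      truth$chrom[grid$t_], truth$pos[grid$t_],
                      truth$end[grid$t_], truth$length[grid$t_],
                      truth$var_class[grid$t_], truth$sv_type[grid$t_],
                      truth$ref[grid$t_], truth$alt[grid$t_], rule)
    grid <- grid[ok, , drop = FALSE]
    if (nrow(grid) > 0L) {
      d <- abs(calls$pos[grid$c_] - truth$pos[grid$t_])
      ld <- abs(calls$length[grid$c_] - truth$length[grid$t_])
      ord <- order(d, ld, truth$pos[grid$t_], calls$pos[grid$c_])
      used_c <- used_t <- integer(0)
      sel <- logical(nrow(grid))
      for (k in ord) {
        if (grid$c_[k] %in% used_c || grid$t_[k] %in% used_t) next
        sel[k] <- TRUE
        used_c <- c(used_c, grid$c_[k])
        used_t <- c(used_t, grid$t_[k])
      }
      pairs <- grid[sel, , drop = FALSE]
    }
  }
  if (is.null(pairs)) pairs <- data.frame(c_ = integer(), t_ = integer())
  pairs$gt_match <- genotype_equal(calls$a1[pairs$c_], calls$a2[pairs$c_],
                                   truth$a1[pairs$t_], truth$a2[pairs$t_])
  pairs
}

#' Evaluate calls against a truth set
#'
#' Pairs calls with truth variants 1-to-1 (greedy nearest-first within the
#' matching tolerances, per class), then reports TP/FP/FN, precision,
#' recall and F-score at two levels: *presence* (position/size match) and
#' *genotype* (presence plus genotype agreement). Metrics are reported per
#' class (SNP, INDEL, DEL, INS, INV, DUP) and pooled (`ALL`).
#'
#' @param calls,truth variant tables (deduplicated).
#' @param rule a [match_rule()].
#' @return an `eval_report`: list with `metrics` (data.frame
#'   `class, level, stratum, tp, fp, fn, precision, recall, f`) and
#'   `pairs` (matched index pairs with `gt_match`).
#' @export
evaluate_calls <- function(calls, truth, rule = match_rule()) {
  c_cls <- eval_class(calls)
  t_cls <- eval_class(truth)
  classes <- sort(unique(c(c_cls, t_cls)))
  pairs_all <- NULL
  rows <- list()
  for (cl in classes) {
    ci <- which(c_cls == cl)
    ti <- which(t_cls == cl)
    p <- pair_class(calls, truth, ci, ti, rule)
    pairs_all <- rbind(pairs_all, p)
    tp_p <- nrow(p)
    tp_g <- sum(p$gt_match)
    rows[[length(rows) + 1L]] <- rbind(
      metric_row(cl, "presence", "overall", tp_p, length(ci) - tp_p,
                 length(ti) - tp_p),
      metric_row(cl, "genotype", "overall", tp_g, length(ci) - tp_g,
                 length(ti) - tp_g))
  }
  tp_p <- if (is.null(pairs_all)) 0L else nrow(pairs_all)
  tp_g <- if (is.null(pairs_all)) 0L else sum(pairs_all$gt_match)
  rows[[length(rows) + 1L]] <- rbind(
    metric_row("ALL", "presence", "overall", tp_p, nrow(calls) - tp_p,
               nrow(truth) - tp_p),
    metric_row("ALL", "genotype", "overall", tp_g, nrow(calls) - tp_g,
               nrow(truth) - tp_g))
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  if (is.null(pairs_all)) pairs_all <- data.frame(c_ = integer(),
                                                  t_ = integer(),
                                                  gt_match = logical())
  structure(list(metrics = metrics, pairs = pairs_all,
                 n_calls = nrow(calls), n_truth = nrow(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation: ", x$n_calls, " calls vs ", x$n_truth,
      " truth variants\n", sep = "")
  print(x$metrics[x$metrics$stratum == "overall", ], row.names = FALSE,
        digits = 4)
  invisible(x)
}

#' Precision-recall curve over a quality-score sweep
#'
#' Re-evaluates the call set at every distinct score threshold: at
#' threshold `t` only calls with score `>= t` are kept. The score is GQ,
#' with DP substituting when GQ is absent (or DP directly). The loosest
#' point (minimum threshold) equals the unfiltered [evaluate_calls()]
#' metrics; recall is non-increasing as the threshold rises.
#'
#' @param calls,truth variant tables.
#' @param rule a [match_rule()].
#' @param score `"GQ"` (DP substituting where GQ is `NA`) or `"DP"`.
#' @param level `"genotype"` or `"presence"` metrics at each threshold.
#' @return data.frame `threshold, precision, recall, n_calls`, ordered by
#'   ascending threshold; zero rows when no call carries a score.
#' @export
pr_curve <- function(calls, truth, rule = match_rule(),
                     score = c("GQ", "DP"), level = c("genotype", "presence")) {
  score <- match.arg(score)
  level <- match.arg(level)
  s <- if (score == "GQ") ifelse(is.na(calls$gq), calls$dp, calls$gq)
       else calls$dp
  keep <- !is.na(s)
  calls <- calls[keep, , drop = FALSE]
  s <- s[keep]
  if (length(s) == 0L) {
    return(data.frame(threshold = numeric(), precision = numeric(),
                      recall = numeric(), n_calls = integer()))
  }
  thresholds <- sort(unique(s))
  rows <- lapply(thresholds, function(t) {
    sub <- calls[s >= t, , drop = FALSE]
    rep <- evaluate_calls(sub, truth, rule)
    m <- rep$metrics
    m <- m[m$class == "ALL" & m$level == level, ]
    data.frame(threshold = t, precision = m$precision, recall = m$recall,
               n_calls = nrow(sub))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a BED3 file of genomic intervals
#'
#' Standard BED semantics: 0-based, half-open `[start, end)` intervals.
#'
#' @param path path to a tab-separated BED file (first three columns used).
#' @return data.frame `chrom, start, end`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end",
                                         paste0("x", 4:12))[1:3],
                           fill = TRUE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  bed
}

in_bed <- function(chrom, pos, bed) {
  # pos is 1-based; BED is 0-based half-open
  hit <- logical(length(pos))
  for (ch in unique(bed$chrom)) {
    b <- bed[bed$chrom == ch, , drop = FALSE]
    i <- which(chrom == ch)
    for (k in i) {
      hit[k] <- any(b$start < pos[k] & pos[k] <= b$end)
    }
  }
  hit
}

assign_strata <- function(records, strata) {
  if (is.numeric(strata)) {
    breaks <- sort(unique(c(-Inf, strata, Inf)))
    labs <- paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")")
    labs[1] <- paste0("(-Inf,", breaks[2], ")")
    idx <- findInterval(records$length, breaks)
    labs[idx]
  } else {
    stopifnot(is.list(strata), !is.null(names(strata)))
    out <- rep("non-repeat", nrow(records))
    for (nm in rev(names(strata))) {  # first-listed wins on overlap
      hit <- in_bed(records$chrom, records$pos, strata[[nm]])
      out[hit] <- nm
    }
    out
  }
}

#' Stratified evaluation by variant length or genomic regions
#'
#' Each truth variant is assigned to exactly one stratum: its signed
#' length bin (half-open `[a, b)` bins from a numeric break vector), or
#' the first BED set overlapping its position (with a `"non-repeat"`
#' fallback). TPs and FNs are counted in the truth variant's stratum;
#' unmatched (FP) calls are attributed to the stratum of their own length
#' or position, so per-stratum counts sum to the overall counts.
#'
#' @param calls,truth variant tables.
#' @param rule a [match_rule()].
#' @param strata either a numeric vector of length-bin breakpoints or a
#'   named list of BED data.frames (`chrom, start, end`, 0-based
#'   half-open; see [read_bed()]).
#' @return an `eval_report` whose `metrics` hold one `(stratum, level)`
#'   row set per stratum (class `ALL`), plus the overall rows.
#' @export
stratified_evaluate <- function(calls, truth, rule = match_rule(), strata) {
  if (is.list(strata) && !is.data.frame(strata)) {
    ov <- overlapping_bed_sets(strata)
    if (length(ov)) {
      warning("overlapping BED sets (first-listed wins): ",
              paste(ov, collapse = ", "))
    }
  }
  base <- evaluate_calls(calls, truth, rule)
  t_str <- assign_strata(truth, strata)
  c_str <- assign_strata(calls, strata)
  matched_c <- base$pairs$c_
  rows <- list()
  for (st in sort(unique(c(t_str, c_str)))) {
    ti <- which(t_str == st)
    p <- base$pairs[base$pairs$t_ %in% ti, , drop = FALSE]
    tp_p <- nrow(p); tp_g <- sum(p$gt_match)
    fp_calls <- setdiff(which(c_str == st), matched_c)
    rows[[length(rows) + 1L]] <- rbind(
      metric_row("ALL", "presence", st, tp_p, length(fp_calls),
                 length(ti) - tp_p),
      metric_row("ALL", "genotype", st,
                 tp_g, length(fp_calls) + (tp_p - tp_g), length(ti) - tp_g))
  }
  metrics <- rbind(base$metrics, do.call(rbind, rows))
  rownames(metrics) <- NULL
  structure(list(metrics = metrics, pairs = base$pairs,
                 n_calls = nrow(calls), n_truth = nrow(truth)),
            class = "eval_report")
}

overlapping_bed_sets <- function(strata) {
  nms <- names(strata)
  hits <- character(0)
  if (length(nms) < 2) return(hits)
  for (i in seq_along(nms)[-1]) {
    for (j in seq_len(i - 1)) {
      a <- strata[[i]]; b <- strata[[j]]
      for (ch in intersect(a$chrom, b$chrom)) {
        ai <- a[a$chrom == ch, ]; bi <- b[b$chrom == ch, ]
        if (any(outer(ai$start, bi$end, `<`) & outer(ai$end, bi$start, `>`))) {
          hits <- c(hits, paste(nms[j], nms[i], sep = "/"))
        }
      }
    }
  }
  unique(hits)
}

#' Write an evaluation report as a tab-separated table
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  utils::write.table(report$metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
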