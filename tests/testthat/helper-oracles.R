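# Independent reference implementations used to cross-check the package's
# clustering, pairing and consensus logic, plus random-instance generators.
# These deliberately re-derive every rule from first principles (naive
# all-pairs scans, augmenting-path matching) rather than calling package
# internals.

# --- minimal variant-table builder for hand-made fixtures ----------------
vt <- function(chrom, pos, class, len, sv_type = NULL, a1 = 0L, a2 = 1L,
               gq = NA_real_, dp = NA_real_, source = NA_character_,
               ref = NULL, alt = NULL) {
  n <- length(pos)
  chrom <- rep_len(chrom, n); class <- rep_len(class, n)
  len <- rep_len(as.integer(len), n)
  if (is.null(sv_type)) {
    sv_type <- ifelse(class != "SV", "NONE", ifelse(len >= 0, "INS", "DEL"))
  } else sv_type <- rep_len(sv_type, n)
  # synthesize allele strings consistent with class/length
  mk <- function(i) {
    if (class[i] == "SNP") return(c("A", "T"))
    if (sv_type[i] == "INV") {
      s <- strrep("A", max(1L, abs(len[i])))
      return(c(s, strrep("T", nchar(s))))
    }
    if (sv_type[i] == "DUP") {
      s <- strrep("A", max(1L, abs(len[i])))
      return(c(s, strrep("A", 2L * nchar(s))))
    }
    if (len[i] < 0) return(c(strrep("A", 1L - len[i]), "A"))
    c("A", strrep("T", 1L + len[i]))
  }
  al <- vapply(seq_len(n), mk, character(2))
  if (is.null(ref)) ref <- al[1, ]
  if (is.null(alt)) alt <- al[2, ]
  d <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                  var_class = class, sv_type = sv_type, length = len,
                  end = as.integer(ifelse(sv_type %in% c("DEL", "INV", "DUP"),
                                          pos + nchar(ref) - 1L, pos)),
                  a1 = rep_len(as.integer(a1), n),
                  a2 = rep_len(as.integer(a2), n),
                  gq = rep_len(as.numeric(gq), n),
                  dp = rep_len(as.numeric(dp), n),
                  source = rep_len(as.character(source), n),
                  stringsAsFactors = FALSE)
  d
}

# one consensus node's calls as a data.frame (NULL genotype = missing)
node_df <- function(gts, dprime = NA_real_, source = NULL) {
  if (length(gts) == 0L) {
    return(data.frame(a1 = integer(), a2 = integer(), dprime = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  }
  a <- t(vapply(gts, function(g) if (is.null(g)) c(NA_integer_, NA_integer_)
                else sort(as.integer(g)), integer(2)))
  data.frame(a1 = a[, 1], a2 = a[, 2],
             dprime = rep_len(as.numeric(dprime), length(gts)),
             source = if (is.null(source)) paste0("tool", seq_along(gts))
                      else source,
             stringsAsFactors = FALSE)
}

# a truth/call deletion pair for matching-rule checks
del_pair <- function(t_pos, t_len, c_pos, c_len, t_gt = c(0L, 1L),
                     c_gt = c(0L, 1L)) {
  truth <- vt("chr1", t_pos, "SV", -abs(t_len), sv_type = "DEL",
              a1 = t_gt[1], a2 = t_gt[2])
  call <- vt("chr1", c_pos, "SV", -abs(c_len), sv_type = "DEL",
             a1 = c_gt[1], a2 = c_gt[2])
  list(truth = truth, call = call)
}

# --- brute-force clustering oracle ---------------------------------------
# Scores every (anchor, call) pair against the thresholds, picks the
# nearest admissible anchor (ties: length difference, anchor position),
# then enforces one call per tool per anchor. Returns the anchor_id vector.
oracle_cluster <- function(anchors, calls, th = cluster_thresholds()) {
  anchors <- sort_variants(anchors)
  anchors$anchor_id <- seq_len(nrow(anchors))
  elen <- function(x) ifelse(x$sv_type %in% c("INV", "DUP"),
                             x$end - x$pos + 1L, abs(x$length))
  ae <- elen(anchors); ce <- elen(calls)
  n <- nrow(calls)
  aid <- rep(NA_integer_, n)
  pd <- ld <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    comp <- anchors$chrom == calls$chrom[i] &
      anchors$var_class == calls$var_class[i] &
      (calls$var_class[i] != "SV" | anchors$sv_type == calls$sv_type[i])
    d <- abs(anchors$pos - calls$pos[i])
    pos_ok <- if (calls$var_class[i] == "SNP") d <= th$snp_pos_tol
      else if (calls$var_class[i] == "INDEL") d < th$indel_pos_tol
      else d < th$sv_pos_tol
    ratio_ok <- rep(TRUE, nrow(anchors))
    if (calls$var_class[i] != "SNP") {
      ratio_ok <- ifelse(ae == 0, ce[i] == 0, abs(ce[i] - ae) / ae < th$sv_len_ratio)
    }
    cand <- which(comp & pos_ok & ratio_ok)
    if (!length(cand)) next
    o <- cand[order(d[cand], abs(ce[i] - ae[cand]), anchors$pos[cand])[1]]
    aid[i] <- anchors$anchor_id[o]
    pd[i] <- d[o]; ld[i] <- abs(ce[i] - ae[o])
  }
  # one call per (tool, anchor): best by distance, length diff, input order
  for (key in unique(paste(calls$source, aid)[!is.na(aid)])) {
    members <- which(paste(calls$source, aid) == key & !is.na(aid))
    if (length(members) > 1L) {
      best <- members[order(pd[members], ld[members], members)[1]]
      aid[setdiff(members, best)] <- NA_integer_
    }
  }
  aid
}

# random clustering instance: anchors plus jittered/spurious calls
random_cluster_instance <- function(n_anchors, n_tools = 3) {
  classes <- sample(c("SNP", "INDEL", "SV"), n_anchors, replace = TRUE,
                    prob = c(0.4, 0.3, 0.3))
  len <- ifelse(classes == "SNP", 0L,
         ifelse(classes == "INDEL", sample(c(-1, 1), n_anchors, TRUE) *
                  sample(1:49, n_anchors, TRUE),
                sample(c(-1, 1), n_anchors, TRUE) * sample(50:400, n_anchors, TRUE)))
  svt <- ifelse(classes != "SV", "NONE",
                sample(c("INS", "DEL", "INV", "DUP"), n_anchors, TRUE))
  len[svt %in% c("INV")] <- 0L
  len[svt %in% c("DUP")] <- abs(len[svt %in% c("DUP")])
  anchors <- vt(sample(c("chr1", "chr2"), n_anchors, TRUE),
                sample(1:50000, n_anchors), classes, len, sv_type = svt)
  anchors <- anchors[!duplicated(anchors[, c("chrom", "pos", "ref", "alt")]), ]
  calls <- NULL
  for (t in seq_len(n_tools)) {
    idx <- which(runif(nrow(anchors)) < 0.8)
    if (length(idx)) {
      cc <- anchors[idx, ]
      jit <- ifelse(cc$var_class == "SV", sample(-300:300, length(idx), TRUE),
             ifelse(cc$var_class == "INDEL", sample(-12:12, length(idx), TRUE),
                    sample(-1:1, length(idx), TRUE)))
      cc$pos <- pmax(1L, cc$pos + jit)
      grow <- ifelse(cc$var_class == "SV",
                     round(cc$length * runif(length(idx), -0.4, 0.4)), 0L)
      cc$length <- as.integer(cc$length + grow)
      cc$end <- as.integer(ifelse(cc$sv_type %in% c("DEL", "INV", "DUP"),
                                  cc$pos + abs(cc$length), cc$pos))
      cc$source <- paste0("tool", t)
      calls <- rbind(calls, cc)
    }
    extra <- vt("chr1", sample(1:50000, 5), "SNP", 0L,
                source = paste0("tool", t))
    calls <- rbind(calls, extra)
  }
  rownames(calls) <- NULL
  list(anchors = anchors, calls = calls)
}

# --- maximum-cardinality 1-to-1 matching oracle (Kuhn's algorithm) -------
# admissibility recomputed from the matching rule's definition
oracle_admissible <- function(call, truth, rule) {
  if (call$chrom != truth$chrom) return(FALSE)
  cc <- if (call$var_class == "SV") call$sv_type else call$var_class
  tc <- if (truth$var_class == "SV") truth$sv_type else truth$var_class
  if (cc != tc) return(FALSE)
  if (call$var_class == "SV") {
    abs(call$pos - truth$pos) <= rule$sv_bp_tol &&
      abs(call$end - truth$end) <= rule$sv_bp_tol &&
      abs(call$length - truth$length) <= rule$sv_size_tol * abs(truth$length)
  } else if (call$var_class == "INDEL") {
    abs(call$pos - truth$pos) < rule$indel_pos_tol
  } else {
    call$pos == truth$pos && call$ref == truth$ref && call$alt == truth$alt
  }
}

oracle_max_matching <- function(calls, truth, rule = match_rule()) {
  nc <- nrow(calls); nt <- nrow(truth)
  adj <- matrix(FALSE, nc, nt)
  for (i in seq_len(nc)) for (j in seq_len(nt)) {
    adj[i, j] <- oracle_admissible(calls[i, ], truth[j, ], rule)
  }
  match_t <- rep(0L, nt)
  try_kuhn <- function(i, seen) {
    for (j in which(adj[i, ])) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_t[j] == 0L || Recall(match_t[j], seen)) {
        match_t[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  size <- 0L
  for (i in seq_len(nc)) {
    if (try_kuhn(i, rep(FALSE, nt))) size <- size + 1L
  }
  size
}

# --- consensus oracle ----------------------------------------------------
# Direct transcription of the consensus rules: most-supported genotype;
# small variants skipped unless some genotype has support >= 2; SVs with
# all frequencies 1 take the smallest |D'|; ties among equally supported
# genotypes resolved by the smallest |D'| (missing D' loses), then lexical.
oracle_consensus <- function(gts, dprime, small) {
  keep <- !vapply(gts, is.null, logical(1))
  gts <- gts[keep]; dprime <- dprime[keep]
  if (!length(gts)) return(NULL)
  key <- vapply(gts, function(g) paste(sort(g), collapse = "/"), character(1))
  counts <- table(key)
  mx <- max(counts)
  if (small && mx < 2) return(NULL)
  pick_by_depth <- function(cands) {
    best <- vapply(cands, function(g) {
      s <- abs(dprime[key == g]); s[is.na(s)] <- Inf
      min(s)
    }, numeric(1))
    cands[order(best, cands)][1]
  }
  if (!small && mx == 1) {
    s <- abs(dprime); s[is.na(s)] <- Inf
    chosen <- key[order(s, key)][1]
  } else {
    cands <- names(counts)[counts == mx]
    chosen <- if (length(cands) == 1) cands else pick_by_depth(cands)
  }
  as.integer(strsplit(chosen, "/")[[1]])
}

# fast spaced truth/call fixture built directly from variant tables (no
# haplotype application), for high-repetition evaluator properties
light_eval_instance <- function(n = 20) {
  classes <- sample(c("SNP", "INDEL", "DEL", "INS"), n, replace = TRUE)
  len <- ifelse(classes == "SNP", 0L,
         ifelse(classes == "INDEL", sample(1:49, n, TRUE) * sample(c(-1L, 1L), n, TRUE),
         ifelse(classes == "DEL", -sample(50:400, n, TRUE),
                sample(50:400, n, TRUE))))
  truth <- vt("chr1", seq_len(n) * 1500L, ifelse(classes %in% c("DEL", "INS"),
                                                 "SV", classes), len,
              a1 = sample(0:1, n, TRUE), a2 = 1L)
  keep <- runif(n) > 0.15
  calls <- truth[keep, , drop = FALSE]
  m <- nrow(calls)
  sv <- calls$var_class == "SV"
  calls$pos <- calls$pos + ifelse(sv, sample(-250:250, m, TRUE), 0L)
  calls$end <- as.integer(ifelse(calls$sv_type %in% c("DEL", "INV", "DUP"),
                                 calls$pos + abs(calls$length), calls$pos))
  flip <- runif(m) < 0.15
  calls$a1[flip] <- 1L - calls$a1[flip]
  calls$gq <- round(runif(m, 5, 60))
  calls$dp <- round(runif(m, 5, 50))
  g <- normalize_gt_pair_local(calls$a1, calls$a2)
  calls$a1 <- g$a1; calls$a2 <- g$a2
  list(truth = truth, calls = calls)
}

normalize_gt_pair_local <- function(a1, a2) {
  swap <- !is.na(a1) & a1 > a2
  t <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- t
  list(a1 = a1, a2 = a2)
}

# spaced random truth/call fixtures for evaluator properties
random_eval_instance <- function(n = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- make_reference(1, 1e5, seed = sample.int(1e6, 1))
  sp <- spike_variants(ref, spike_config(
    counts = c(SNP = n, INDEL = ceiling(n / 2), DEL = ceiling(n / 4),
               INS = ceiling(n / 4), INV = 2, DUP = 2),
    seed = sample.int(1e6, 1)))
  prof <- error_profile("t1", fn_rate = 0.15, genotype_error_rate = 0.1,
                        breakpoint_jitter_sd = 4, length_jitter_sd = 4)
  calls <- simulate_outputs(sp$truth, list(prof), reference = ref,
                            seed = sample.int(1e6, 1))[[1]]
  list(truth = sp$truth, calls = calls)
}

metric <- function(report, cls, lvl, col, stratum = "overall") {
  m <- report$metrics
  m[m$class == cls & m$level == lvl & m$stratum == stratum, col]
}
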