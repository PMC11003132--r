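test_that("clustering applies the class-specific position and ratio thresholds", {
  anchor <- vt("chr1", 1000, "SV", -100L, sv_type = "DEL")
  near <- vt("chr1", 1080, "SV", -110L, sv_type = "DEL", source = "t1")
  out <- cluster_calls(anchor, near)
  expect_equal(out$assignments$anchor_id, 1L)

  long <- vt("chr1", 1000, "SV", -160L, sv_type = "DEL", source = "t1")
  out2 <- cluster_calls(anchor, long)
  expect_true(is.na(out2$assignments$anchor_id))  # ratio 0.60 >= 0.25

  snp_a <- vt("chr1", 500, "SNP", 0L)
  snp_c <- vt("chr1", 501, "SNP", 0L, source = "t1")
  expect_true(is.na(cluster_calls(snp_a, snp_c)$assignments$anchor_id))
  expect_equal(cluster_calls(snp_a, vt("chr1", 500, "SNP", 0L, source = "t1")
               )$assignments$anchor_id, 1L)
})

test_that("position tolerances are strict for SVs and indels", {
  anchor <- vt("chr1", 1000, "SV", -100L, sv_type = "DEL")
  at199 <- vt("chr1", 1199, "SV", -100L, sv_type = "DEL", source = "t")
  at200 <- vt("chr1", 1200, "SV", -100L, sv_type = "DEL", source = "t")
  expect_false(is.na(cluster_calls(anchor, at199)$assignments$anchor_id))
  expect_true(is.na(cluster_calls(anchor, at200)$assignments$anchor_id))
  ind <- vt("chr1", 1000, "INDEL", 5L)
  at9 <- vt("chr1", 1009, "INDEL", 5L, source = "t")
  at10 <- vt("chr1", 1010, "INDEL", 5L, source = "t")
  expect_false(is.na(cluster_calls(ind, at9)$assignments$anchor_id))
  expect_true(is.na(cluster_calls(ind, at10)$assignments$anchor_id))
})

test_that("among admissible anchors the nearest wins", {
  anchors <- rbind(vt("chr1", 1000, "SV", -100L, sv_type = "DEL"),
                   vt("chr1", 1150, "SV", -100L, sv_type = "DEL"))
  call <- vt("chr1", 1090, "SV", -100L, sv_type = "DEL", source = "t1")
  out <- cluster_calls(anchors, call)
  chosen <- out$anchors$pos[match(out$assignments$anchor_id,
                                  out$anchors$anchor_id)]
  expect_equal(chosen, 1150L)  # |1090-1150| = 60 < |1090-1000| = 90
})

test_that("each genotyper contributes at most one call per node", {
  anchor <- vt("chr1", 1000, "SV", -100L, sv_type = "DEL")
  calls <- rbind(vt("chr1", 1010, "SV", -100L, sv_type = "DEL", source = "t1"),
                 vt("chr1", 1050, "SV", -100L, sv_type = "DEL", source = "t1"),
                 vt("chr1", 1050, "SV", -100L, sv_type = "DEL", source = "t2"))
  out <- cluster_calls(anchor, calls)
  assigned <- out$assignments[!is.na(out$assignments$anchor_id), ]
  expect_equal(nrow(assigned), 2)
  expect_equal(sort(assigned$source), c("t1", "t2"))
  expect_equal(assigned$pos[assigned$source == "t1"], 1010L)  # nearest kept
  expect_equal(nrow(out$unassigned), 1)
})

test_that("cluster assignments equal the brute-force all-pairs matcher", {
  set.seed(101)
  for (i in 1:20) {
    inst <- random_cluster_instance(sample(20:120, 1))
    got <- cluster_calls(inst$anchors, inst$calls)$assignments$anchor_id
    want <- oracle_cluster(inst$anchors, inst$calls)
    expect_identical(got, want)
  }
})

test_that("the variant graph groups same-position anchors on one branch", {
  a <- vt("chr1", 1000, "SNP", 0L); a$alt <- "T"
  b <- vt("chr1", 1000, "SNP", 0L); b$alt <- "G"
  c <- vt("chr1", 2000, "SNP", 0L)
  g <- build_variant_graph(cluster_calls(rbind(a, b, c), a[0, ]))
  expect_equal(nrow(g$nodes), 3)
  expect_equal(length(unique(g$nodes$branch)), 2)
  expect_equal(g$nodes$branch[1], g$nodes$branch[2])

  empty <- build_variant_graph(cluster_calls(a[0, ], a[0, ]))
  expect_equal(nrow(empty$nodes), 0)

  set.seed(3)
  rnd <- vt(sample(c("chr1", "chr2"), 100, TRUE), sample(1:1e5, 100),
            "SNP", 0L)
  g2 <- build_variant_graph(cluster_calls(rnd, a[0, ]))
  expect_equal(order(g2$nodes$chrom, g2$nodes$pos), seq_len(nrow(g2$nodes)))
})

test_that("depth normalization evaluates the Z-score equations exactly", {
  calls <- vt("chr1", c(100, 200, 300), "SNP", 0L, dp = c(5, 10, 15),
              source = "t1")
  out <- normalize_depths(calls)
  expect_equal(out$stats$mu, 10)
  expect_equal(out$stats$sigma, sqrt(50 / 3))     # population SD, divisor N
  expect_equal(out$calls$dprime, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
})

test_that("degenerate and missing depths are handled", {
  flat <- vt("chr1", c(1, 2, 3) * 100, "SNP", 0L, dp = 7, source = "t1")
  expect_equal(normalize_depths(flat)$calls$dprime, c(0, 0, 0))
  mix <- rbind(vt("chr1", 100, "SNP", 0L, dp = 5, source = "t1"),
               vt("chr1", 200, "SNP", 0L, dp = NA, source = "t1"),
               vt("chr1", 300, "SNP", 0L, dp = NA, source = "t2"))
  out <- normalize_depths(mix)
  expect_equal(out$stats$tool, "t1")   # t2 has no depth-bearing calls
  expect_true(is.na(out$calls$dprime[out$calls$source == "t2"]))
})

test_that("per-tool normalized depths have mean 0 and unit population SD", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    calls <- vt("chr1", seq_len(n) * 1000, "SNP", 0L,
                dp = round(runif(n, 3, 80)), source = sample(c("a", "b"), n, TRUE))
    out <- normalize_depths(calls)
    for (tool in out$stats$tool) {
      if (out$stats$sigma[out$stats$tool == tool] == 0) next
      d <- out$calls$dprime[out$calls$source == tool]
      expect_lt(abs(mean(d)), 1e-9)
      expect_lt(abs(sqrt(mean((d - mean(d))^2)) - 1), 1e-9)
    }
  }
})

test_that("small-variant consensus takes the majority and skips single support", {
  expect_equal(consensus_small(node_df(list(c(0, 1), c(0, 1), c(1, 1))))[c("a1", "a2", "support")],
               list(a1 = 0L, a2 = 1L, support = 2L))
  expect_null(consensus_small(node_df(list(c(0, 1)))))
  # unordered equality gives 0/1 and 1/0 joint support 2
  expect_equal(consensus_small(node_df(list(c(0, 1), c(1, 0))))$support, 2L)
})

test_that("SV consensus uses majority, then smallest |D'| when all frequencies are 1", {
  maj <- consensus_sv(node_df(list(c(0, 1), c(0, 1), c(1, 1)),
                              dprime = c(0.9, -0.1, 0)))
  expect_equal(c(maj$a1, maj$a2), c(0L, 1L))
  tie <- consensus_sv(node_df(list(c(0, 1), c(1, 1)), dprime = c(0.5, -0.2)))
  expect_equal(c(tie$a1, tie$a2), c(1L, 1L))   # |-0.2| < |0.5|
  expect_null(consensus_sv(node_df(list())))
  # a call without D' loses the depth tie-break to one that has it
  tie2 <- consensus_sv(node_df(list(c(0, 1), c(1, 1)), dprime = c(NA, 1.7)))
  expect_equal(c(tie2$a1, tie2$a2), c(1L, 1L))
})

test_that("consensus matches an independent rule transcription exhaustively", {
  gt_space <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L), NULL)  # NULL = missing
  for (K in 2:4) {
    idx <- do.call(expand.grid, rep(list(1:4), K))
    dprime <- c(0.5, -0.2, 0.9, 0.1)[1:K]
    for (r in seq_len(nrow(idx))) {
      gts <- gt_space[as.integer(idx[r, ])]
      node <- node_df(gts, dprime = dprime)
      for (small in c(TRUE, FALSE)) {
        got <- if (small) consensus_small(node) else consensus_sv(node)
        want <- oracle_consensus(gts, dprime, small)
        if (is.null(want)) {
          expect_null(got)
        } else {
          expect_equal(c(got$a1, got$a2), want)
        }
        # determinism
        got2 <- if (small) consensus_small(node) else consensus_sv(node)
        expect_identical(got, got2)
      }
    }
  }
})

test_that("a strict majority genotype wins regardless of depths", {
  set.seed(31)
  for (i in 1:50) {
    K <- sample(3:5, 1)
    maj <- sample(list(c(0L, 1L), c(1L, 1L), c(0L, 0L)), 1)[[1]]
    k_maj <- ceiling(K / 2) + 1
    gts <- c(rep(list(maj), min(k_maj, K)),
             lapply(seq_len(max(0, K - k_maj)), function(j)
               sample(list(c(0L, 0L), c(0L, 1L), c(1L, 1L)), 1)[[1]]))
    node <- node_df(gts, dprime = rnorm(length(gts)))
    for (fun in list(consensus_small, consensus_sv)) {
      res <- fun(node)
      expect_equal(c(res$a1, res$a2), sort(maj))
    }
  }
})

test_that("unanimous genotypers reproduce their input through the merge", {
  ref <- make_reference(1, 1e5, seed = 41)
  sp <- spike_variants(ref, spike_config(
    counts = c(SNP = 20, INDEL = 10, DEL = 8, INS = 8, INV = 2, DUP = 2),
    seed = 41))
  outs <- lapply(paste0("tool", 1:3), function(t) {
    x <- sp$truth; x$source <- t; x$dp <- 30; x
  })
  merged <- merge_genotyper_outputs(sp$truth, outs)
  expect_equal(nrow(merged), 50)
  expect_equal(merged$a1, sp$truth$a1)
  expect_equal(merged$a2, sp$truth$a2)
  expect_true(all(merged$support == 3))
  expect_true(all(merged$tools == "tool1,tool2,tool3"))
})

test_that("small variants called by a single tool are skipped, SVs are kept", {
  anchor_snp <- vt("chr1", 500, "SNP", 0L)
  anchor_sv <- vt("chr1", 5000, "SV", -100L, sv_type = "DEL")
  calls <- rbind(vt("chr1", 500, "SNP", 0L, source = "t1", dp = 10),
                 vt("chr1", 5000, "SV", -100L, sv_type = "DEL",
                    source = "t1", dp = 10))
  merged <- merge_genotyper_outputs(rbind(anchor_snp, anchor_sv), calls)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$var_class, "SV")
  expect_equal(merged$support, 1L)
})

test_that("a shifted deletion call is counted at the anchor's coordinates", {
  anchor <- vt("chr1", 1000, "SV", -100L, sv_type = "DEL", a1 = 0L, a2 = 1L)
  calls <- rbind(
    vt("chr1", 1080, "SV", -100L, sv_type = "DEL", a1 = 1L, a2 = 1L,
       source = "t1", dp = 20),
    vt("chr1", 1000, "SV", -100L, sv_type = "DEL", a1 = 1L, a2 = 1L,
       source = "t2", dp = 25))
  merged <- merge_genotyper_outputs(anchor, calls)
  expect_equal(merged$pos, 1000L)
  expect_equal(merged$ref, anchor$ref)
  expect_equal(c(merged$a1, merged$a2), c(1L, 1L))
  expect_equal(merged$support, 2L)
})

test_that("re-merging the merged output as a single tool is idempotent for SVs", {
  ref <- make_reference(1, 1e5, seed = 43)
  sp <- spike_variants(ref, spike_config(
    counts = c(SNP = 15, INDEL = 8, DEL = 8, INS = 8, INV = 3, DUP = 3),
    seed = 43))
  profs <- lapply(1:3, function(i) error_profile(paste0("t", i),
                                                 fn_rate = 0.05,
                                                 genotype_error_rate = 0.05))
  outs <- simulate_outputs(sp$truth, profs, reference = ref, seed = 5)
  merged <- merge_genotyper_outputs(sp$truth, outs)
  again_in <- merged; again_in$source <- "ensemble"
  again <- merge_genotyper_outputs(merged, again_in)
  sv1 <- merged[merged$var_class == "SV", c("chrom", "pos", "a1", "a2")]
  sv2 <- again[again$var_class == "SV", c("chrom", "pos", "a1", "a2")]
  rownames(sv1) <- rownames(sv2) <- NULL
  expect_identical(sv1, sv2)
  expect_equal(nrow(again[again$var_class != "SV", ]), 0)  # single-tool skip
})

test_that("an ensemble of three error-prone genotypers beats the per-tool error rate", {
  set.seed(47)
  n <- 1000
  anchors <- vt("chr1", seq_len(n) * 1000L, "SNP", 0L,
                a1 = rep(0L, n), a2 = rep(1L, n))
  for (e in c(0.1, 0.2, 0.3)) {
    outs <- lapply(1:3, function(t) {
      x <- anchors
      err <- runif(n) < e
      for (k in which(err)) {
        alt <- Filter(function(g) !(g[1] == x$a1[k] && g[2] == x$a2[k]),
                      list(c(0L, 0L), c(0L, 1L), c(1L, 1L)))
        g <- alt[[sample.int(2, 1)]]
        x$a1[k] <- g[1]; x$a2[k] <- g[2]
      }
      x$source <- paste0("t", t); x$dp <- 30
      x
    })
    merged <- merge_genotyper_outputs(anchors, outs)
    wrong <- sum(!genotype_equal(merged$a1, merged$a2, 0L, 1L)) +
      (n - nrow(merged))  # skipped variants count against the ensemble
    expect_lt(wrong / n, e)
  }
})
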