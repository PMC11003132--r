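#' Configuration for spiking variants into a reference
#'
#' Defines the truth set of a synthetic benchmark: how many variants of
#' each class to place, their size ranges, the heterozygous fraction, and
#' the minimum spacing between events. Defaults give a mixed SNP/indel/SV
#' truth set on the scale used throughout the package's tests.
#'
#' @param counts named integer vector over
#'   `SNP, INDEL, DEL, INS, INV, DUP` (missing names count 0).
#' @param het_fraction probability that a spiked variant is heterozygous
#'   (placed on one random haplotype); otherwise homozygous on both.
#' @param indel_size,sv_size length-2 integer ranges (bp) for indel and SV
#'   event sizes; indels must stay within 1-49 bp, SVs start at 50 bp.
#' @param min_spacing minimum bp between the reference spans of
#'   neighbouring events, keeping clusters unambiguous.
#' @param seed integer seed; every placement decision derives from it.
#' @return a `spike_config` list.
#' @export
spike_config <- function(counts = c(SNP = 100, INDEL = 40, DEL = 20,
                                    INS = 20, INV = 10, DUP = 10),
                         het_fraction = 0.5,
                         indel_size = c(1, 49), sv_size = c(50, 500),
                         min_spacing = 300, seed = 1L) {
  full <- c(SNP = 0L, INDEL = 0L, DEL = 0L, INS = 0L, INV = 0L, DUP = 0L)
  full[names(counts)] <- as.integer(counts)
  stopifnot(all(full >= 0), het_fraction >= 0, het_fraction <= 1,
            indel_size[1] >= 1, indel_size[2] <= 49,
            sv_size[1] >= 50, min_spacing >= 0)
  structure(list(counts = full, het_fraction = het_fraction,
                 indel_size = indel_size, sv_size = sv_size,
                 min_spacing = min_spacing, seed = as.integer(seed)),
            class = "spike_config")
}

#' Generate a random reference genome
#'
#' Uniform random A/C/G/T sequences, deterministic under the seed.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths integer vector (recycled) of chromosome lengths in bp,
#'   each at least 10 kb.
#' @param seed integer seed.
#' @return named character vector (`chr1`, `chr2`, ...).
#' @export
make_reference <- function(n_chrom = 1L, lengths = 1e5, seed = 1L) {
  lengths <- rep_len(as.integer(lengths), n_chrom)
  stopifnot(all(lengths >= 1e4))
  set.seed(seed)
  seqs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  stats::setNames(seqs, paste0("chr", seq_len(n_chrom)))
}

#' Write reference sequences to FASTA
#' @param reference named character vector of sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*", "", names(x))
  stats::setNames(toupper(as.character(x)), names(x))
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Spike a truth set of variants into a reference
#'
#' Places exactly the requested number of variants per class at random,
#' non-overlapping positions (at least `min_spacing` bp apart), assigns
#' each a heterozygous (one random haplotype) or homozygous genotype, and
#' applies them to produce the two haplotype sequences. Deletions remove
#' the span (VCF padding-base representation), insertions add novel
#' random sequence, inversions reverse-complement the span, duplications
#' tandem-duplicate it.
#'
#' @param reference named character vector of reference sequences.
#' @param config a [spike_config()].
#' @return a list with `truth` (variant table with an extra `hap` column:
#'   0 = both haplotypes, 1/2 = heterozygous carrier), `haplotypes`
#'   (list of two named character vectors) and `reference`.
#' @export
spike_variants <- function(reference, config = spike_config()) {
  stopifnot(inherits(config, "spike_config"))
  reference <- as_reference(reference)
  set.seed(config$seed)
  counts <- config$counts
  n_total <- sum(counts)
  classes <- rep(names(counts), counts)

  # event sizes and reference spans per class (resample guards against
  # sample()'s scalar expansion when a size range is a single value)
  resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  sv_len <- function(n) if (n) resample(config$sv_size[1]:config$sv_size[2], n)
                        else integer(0)
  size <- integer(n_total)
  size[classes == "SNP"] <- 1L
  ind <- which(classes == "INDEL")
  if (length(ind)) {
    size[ind] <- resample(config$indel_size[1]:config$indel_size[2],
                          length(ind))
  }
  for (cl in c("DEL", "INS", "INV", "DUP")) {
    i <- which(classes == cl)
    size[i] <- sv_len(length(i))
  }
  # indels are half insertions, half deletions
  indel_is_del <- rep(FALSE, n_total)
  indel_is_del[ind] <- sample(c(TRUE, FALSE), length(ind), replace = TRUE)

  span <- ifelse(classes %in% c("SNP"), 1L,
          ifelse(classes == "INS", 1L,
          ifelse(classes == "DEL", size + 1L,
          ifelse(classes == "INDEL", ifelse(indel_is_del, size + 1L, 1L),
                 size))))  # INV/DUP span = size

  # distribute events over chromosomes proportional to length
  chrom_len <- nchar(reference)
  chrom_of <- sample(names(reference), n_total, replace = TRUE,
                     prob = chrom_len / sum(chrom_len))
  pos <- integer(n_total)
  for (ch in names(reference)) {
    i <- which(chrom_of == ch)
    if (!length(i)) next
    i <- i[sample.int(length(i))]  # random genomic order of classes
    need <- sum(span[i]) + (length(i) + 1L) * config$min_spacing
    if (need > chrom_len[[ch]]) {
      worst <- names(sort(tapply(span[i], classes[i], sum),
                          decreasing = TRUE))[1]
      stop("infeasible packing on ", ch, ": requested ", worst,
           " variants (largest span share) exceed the chromosome length")
    }
    slack <- chrom_len[[ch]] - need
    cuts <- sort(stats::runif(length(i), 0, slack))
    gaps <- diff(c(0, cuts))
    cur <- 1L
    for (k in seq_along(i)) {
      cur <- cur + as.integer(gaps[k]) + config$min_spacing
      pos[i[k]] <- cur
      cur <- cur + span[i[k]]
    }
  }

  ref_al <- alt_al <- character(n_total)
  hint <- rep(NA_character_, n_total)
  for (k in seq_len(n_total)) {
    ch <- chrom_of[k]; p <- pos[k]; L <- size[k]
    base <- substr(reference[[ch]], p, p)
    if (classes[k] == "SNP") {
      ref_al[k] <- base
      alt_al[k] <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    } else if (classes[k] == "INDEL" && !indel_is_del[k] ||
               classes[k] == "INS") {
      ref_al[k] <- base
      alt_al[k] <- paste0(base, rand_seq(L))
      if (classes[k] == "INS") hint[k] <- "INS"
    } else if (classes[k] == "INDEL" || classes[k] == "DEL") {
      ref_al[k] <- substr(reference[[ch]], p, p + L)
      alt_al[k] <- base
      if (classes[k] == "DEL") hint[k] <- "DEL"
    } else if (classes[k] == "INV") {
      ref_al[k] <- substr(reference[[ch]], p, p + L - 1L)
      alt_al[k] <- revcomp(ref_al[k])
      hint[k] <- "INV"
    } else { # DUP
      ref_al[k] <- substr(reference[[ch]], p, p + L - 1L)
      alt_al[k] <- paste0(ref_al[k], ref_al[k])
      hint[k] <- "DUP"
    }
  }

  het <- stats::runif(n_total) < config$het_fraction
  hap <- ifelse(het, sample(1:2, n_total, replace = TRUE), 0L)
  a1 <- ifelse(het, 0L, 1L)
  truth <- variant_table(chrom_of, pos, ref_al, alt_al,
                         a1 = a1, a2 = 1L, sv_type_hint = hint)
  truth$hap <- hap
  truth <- sort_variants(truth)
  rownames(truth) <- NULL

  haplotypes <- lapply(1:2, function(h) {
    seqs <- reference
    carried <- truth[truth$hap == 0L | truth$hap == h, , drop = FALSE]
    for (ch in unique(carried$chrom)) {
      v <- carried[carried$chrom == ch, , drop = FALSE]
      v <- v[order(-v$pos), , drop = FALSE]  # apply right-to-left
      s <- seqs[[ch]]
      for (k in seq_len(nrow(v))) {
        s <- paste0(substr(s, 1, v$pos[k] - 1L), v$alt[k],
                    substr(s, v$pos[k] + nchar(v$ref[k]), nchar(s)))
      }
      seqs[[ch]] <- s
    }
    seqs
  })
  names(haplotypes) <- c("hap1", "hap2")
  list(truth = truth, haplotypes = haplotypes, reference = reference)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Error profile of an emulated genotyper
#'
#' Controls the noise a synthetic genotyper applies to the truth set:
#' missed calls, genotype errors, breakpoint/length jitter on SVs, and
#' the DP/GQ distributions that make threshold sweeps informative
#' (correct calls draw GQ around `gq_correct_mean`, erroneous ones around
#' `gq_error_mean`).
#'
#' @param tool genotyper identifier string.
#' @param fn_rate probability a truth variant is missed entirely.
#' @param genotype_error_rate probability a reported genotype is wrong.
#' @param breakpoint_jitter_sd bp, SD of the rounded Gaussian shift added
#'   to SV start positions.
#' @param length_jitter_sd bp, SD of the rounded Gaussian perturbation of
#'   SV event sizes.
#' @param depth_mean,depth_sd reads; per-call DP is
#'   `max(1, round(N(depth_mean, depth_sd)))`.
#' @param gq_correct_mean,gq_error_mean Phred-like GQ centres for correct
#'   and erroneous genotype calls (SD 10, clamped to `[0, 99]`).
#' @param seed optional integer; when `NULL`, [simulate_outputs()] derives
#'   a per-tool seed from its own seed so streams are independent.
#' @return an `error_profile` list.
#' @export
error_profile <- function(tool, fn_rate = 0.1, genotype_error_rate = 0.05,
                          breakpoint_jitter_sd = 5, length_jitter_sd = 5,
                          depth_mean = 30, depth_sd = 6,
                          gq_correct_mean = 50, gq_error_mean = 15,
                          seed = NULL) {
  stopifnot(fn_rate >= 0, fn_rate <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            breakpoint_jitter_sd >= 0, length_jitter_sd >= 0)
  structure(list(tool = tool, fn_rate = fn_rate,
                 genotype_error_rate = genotype_error_rate,
                 breakpoint_jitter_sd = breakpoint_jitter_sd,
                 length_jitter_sd = length_jitter_sd,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 gq_correct_mean = gq_correct_mean,
                 gq_error_mean = gq_error_mean, seed = seed),
            class = "error_profile")
}

GT_SPACE <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))

#' Emulate noisy genotyper outputs from a truth set
#'
#' For each error profile, each truth variant is dropped with probability
#' `fn_rate`; surviving calls keep the true genotype with probability
#' `1 - genotype_error_rate` and otherwise draw a different genotype from
#' `{0/0, 0/1, 1/1}`. SV start positions and event sizes receive rounded
#' zero-mean Gaussian jitter (the VCF representation is rebuilt so POS,
#' alleles and END stay mutually consistent); DP and GQ are drawn from the
#' profile's distributions. Deterministic under the seeds; each tool has
#' its own stream, so adding a tool never perturbs earlier ones.
#'
#' @param truth truth variant table (from [spike_variants()]).
#' @param profiles list of [error_profile()]s.
#' @param reference optional reference (named character vector); when
#'   supplied, jittered deletion/inversion/duplication REF alleles are
#'   re-extracted from it, otherwise novel random bases stand in.
#' @param seed base seed used to derive per-tool seeds for profiles
#'   without their own.
#' @return named list of per-tool variant tables (`source` set).
#' @export
simulate_outputs <- function(truth, profiles, reference = NULL, seed = 1L) {
  stopifnot(length(profiles) > 0)
  out <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    stopifnot(inherits(p, "error_profile"))
    set.seed(p$seed %||% (as.integer(seed) + 7919L * i))
    out[[p$tool]] <- simulate_one_tool(truth, p, reference)
  }
  out
}

simulate_one_tool <- function(truth, p, reference) {
  n <- nrow(truth)
  keep <- stats::runif(n) >= p$fn_rate
  v <- truth[keep, c("chrom", "pos", "ref", "alt", "var_class", "sv_type",
                     "length", "end", "a1", "a2", "gq", "dp"), drop = FALSE]
  m <- nrow(v)
  if (m == 0L) {
    v$source <- character(0)
    return(v)
  }
  # genotype errors
  err <- stats::runif(m) < p$genotype_error_rate
  for (k in which(err)) {
    alts <- Filter(function(g) !(g[1] == v$a1[k] && g[2] == v$a2[k]), GT_SPACE)
    g <- alts[[sample.int(length(alts), 1)]]
    v$a1[k] <- g[1]; v$a2[k] <- g[2]
  }
  # breakpoint and length jitter on SVs
  sv <- which(v$var_class == "SV")
  if (length(sv)) {
    shift <- as.integer(round(stats::rnorm(length(sv), 0, p$breakpoint_jitter_sd)))
    dlen <- as.integer(round(stats::rnorm(length(sv), 0, p$length_jitter_sd)))
    for (j in seq_along(sv)) {
      k <- sv[j]
      if (shift[j] == 0L && dlen[j] == 0L) next  # unperturbed: keep alleles
      v$pos[k] <- max(2L, v$pos[k] + shift[j])
      sz <- switch(v$sv_type[k],
                   INS = nchar(v$alt[k]) - 1L,
                   DEL = nchar(v$ref[k]) - 1L,
                   nchar(v$ref[k]))           # INV/DUP span
      sz <- max(2L, sz + dlen[j])
      from_ref <- function(nch) {
        if (is.null(reference)) return(NULL)
        s <- substr(reference[[v$chrom[k]]], v$pos[k], v$pos[k] + nch - 1L)
        if (nchar(s) == nch) s else NULL
      }
      if (v$sv_type[k] == "INS") {
        pad <- from_ref(1L) %||% substr(v$ref[k], 1, 1)
        v$ref[k] <- pad
        v$alt[k] <- paste0(pad, rand_seq(sz))
      } else if (v$sv_type[k] == "DEL") {
        span <- from_ref(sz + 1L)
        if (is.null(span)) span <- paste0(substr(v$ref[k], 1, 1), rand_seq(sz))
        v$ref[k] <- span
        v$alt[k] <- substr(span, 1, 1)
      } else if (v$sv_type[k] == "INV") {
        span <- from_ref(sz) %||% rand_seq(sz)
        v$ref[k] <- span
        v$alt[k] <- revcomp(span)
      } else { # DUP
        span <- from_ref(sz) %||% rand_seq(sz)
        v$ref[k] <- span
        v$alt[k] <- paste0(span, span)
      }
      v$length[k] <- nchar(v$alt[k]) - nchar(v$ref[k])
      v$end[k] <- variant_end(v$pos[k], v$ref[k], v$sv_type[k])
    }
  }
  v$dp <- pmax(1, round(stats::rnorm(m, p$depth_mean, p$depth_sd)))
  gq_centre <- ifelse(err, p$gq_error_mean, p$gq_correct_mean)
  v$gq <- pmin(99, pmax(0, round(stats::rnorm(m, gq_centre, 10))))
  v$source <- p$tool
  rownames(v) <- NULL
  v
}
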