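#' Population VCF filter settings
#'
#' By default filtering is disabled and variants pass through untouched;
#' enabling it retains variants with minor allele frequency at least
#' `min_maf` and missing rate at most `max_missing_rate` (both inclusive
#' on the keep side).
#'
#' @param min_maf minimum minor allele frequency, in `[0, 0.5]`.
#' @param max_missing_rate maximum fraction of samples with a missing
#'   genotype, in `[0, 1]`.
#' @param enabled logical; `FALSE` (default) disables filtering entirely.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_maf = 0, max_missing_rate = 1, enabled = FALSE) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            max_missing_rate >= 0, max_missing_rate <= 1)
  structure(list(min_maf = min_maf, max_missing_rate = max_missing_rate,
                 enabled = isTRUE(enabled)),
            class = "filter_config")
}

#' Minor allele frequency of a site
#'
#' Computed over the alleles of non-missing genotypes only: with ALT
#' frequency `p` among non-missing alleles, MAF is `min(p, 1 - p)`.
#'
#' @param gt a two-column integer matrix of allele indices, one row per
#'   sample (`NA` row = missing genotype).
#' @return MAF in `[0, 0.5]`, or `NA` when every genotype is missing.
#' @examples
#' compute_maf(rbind(c(0, 0), c(0, 1), c(1, 1), c(NA, NA)))  # 0.5
#' @export
compute_maf <- function(gt) {
  gt <- as.matrix(gt)
  ok <- !is.na(gt[, 1]) & !is.na(gt[, 2])
  if (!any(ok)) return(NA_real_)
  alleles <- c(gt[ok, 1], gt[ok, 2])
  p <- mean(alleles != 0)
  min(p, 1 - p)
}

#' Missing-genotype rate of a site
#' @inheritParams compute_maf
#' @return fraction of samples with a missing genotype.
#' @export
compute_missing_rate <- function(gt) {
  gt <- as.matrix(gt)
  if (nrow(gt) == 0L) stop("missing rate needs at least one genotype")
  mean(is.na(gt[, 1]) | is.na(gt[, 2]))
}

#' Reformat a variant table against a reference
#'
#' The "convert" step of the pipeline: symbolic ALT alleles (`<DEL>`,
#' `<INV>`, `<DUP>`) carrying an `END` coordinate are resolved to explicit
#' sequences from the reference (a deletion becomes the full deleted span
#' as REF with its first base as ALT; an inversion's ALT is the
#' reverse-complemented span; a tandem duplication's ALT is the doubled
#' span). Records whose alleles still contain characters outside
#' `{A,C,G,T,N}` after upper-casing are dropped and logged, as are
#' unresolvable symbolic records; byte-identical duplicates (same
#' chrom/pos/ref/alt) collapse to one.
#'
#' @param records a variant table (possibly holding symbolic ALTs from
#'   [read_vcf()]).
#' @param reference named character vector (or `Biostrings::DNAStringSet`)
#'   of reference sequences covering every chromosome in `records`.
#' @return a list with `records` (the cleaned table, sorted) and
#'   `rejected` (a data.frame `chrom, pos, alt, reason`).
#' @export
reformat_vcf <- function(records, reference) {
  reference <- as_reference(reference)
  missing_chr <- setdiff(unique(records$chrom), names(reference))
  if (length(missing_chr) > 0) {
    stop("chromosome(s) absent from reference: ",
         paste(missing_chr, collapse = ", "))
  }
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  records$ref <- toupper(records$ref)
  sym <- grepl("^<", records$alt)
  records$alt[!sym] <- toupper(records$alt[!sym])

  for (i in which(sym)) {
    typ <- records$sv_type[i]
    if (!typ %in% c("DEL", "INV", "DUP") || is.na(records$end[i]) ||
        records$end[i] < records$pos[i]) {
      reason[i] <- "unresolvable symbolic allele"
      next
    }
    span <- substr_ref(reference, records$chrom[i], records$pos[i], records$end[i])
    if (typ == "DEL") {
      records$ref[i] <- span
      records$alt[i] <- substr(span, 1, 1)
    } else if (typ == "INV") {
      records$ref[i] <- span
      records$alt[i] <- revcomp(span)
    } else { # DUP
      records$ref[i] <- span
      records$alt[i] <- paste0(span, span)
    }
    cls <- classify_variant(records$ref[i], records$alt[i], typ)
    records$var_class[i] <- cls$var_class
    records$sv_type[i] <- cls$sv_type
    records$length[i] <- cls$length
    records$end[i] <- variant_end(records$pos[i], records$ref[i], typ)
  }

  bad_chr <- is.na(reason) &
    (grepl("[^ACGTN]", records$ref) | grepl("[^ACGTN]", records$alt) |
       nchar(records$ref) == 0L | nchar(records$alt) == 0L)
  reason[bad_chr] <- "non-ACGTN characters in alleles"

  keep <- is.na(reason)
  rejected <- data.frame(chrom = records$chrom[!keep], pos = records$pos[!keep],
                         alt = records$alt[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  out <- records[keep, , drop = FALSE]
  dup <- duplicated(out[, c("chrom", "pos", "ref", "alt")])
  out <- sort_variants(out[!dup, , drop = FALSE])
  rownames(out) <- NULL
  list(records = out, rejected = rejected)
}

as_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  toupper(reference)
}

substr_ref <- function(reference, chrom, start, end) {
  seq <- reference[[chrom]]
  if (end > nchar(seq)) stop("coordinates beyond end of ", chrom)
  substr(seq, start, end)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Filter a population variant table by MAF and missing rate
#'
#' With a disabled config (the default) the input is returned unchanged.
#' Otherwise a record is retained when its MAF is at least
#' `config$min_maf` and its missing rate is at most
#' `config$max_missing_rate`; sites where every genotype is missing have
#' undefined MAF and fail any MAF threshold.
#'
#' @param records a multi-sample variant table with a `genotypes`
#'   list-column (from [read_vcf()]).
#' @param config a [filter_config()].
#' @return a list with `retained`, `removed` (variant tables) and `counts`
#'   (named integer vector `input, retained, removed`).
#' @export
filter_population_vcf <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(records)
  if (!config$enabled) {
    return(list(retained = records, removed = records[0, , drop = FALSE],
                counts = c(input = n, retained = n, removed = 0L)))
  }
  maf <- vapply(records$genotypes, compute_maf, numeric(1))
  miss <- vapply(records$genotypes, compute_missing_rate, numeric(1))
  keep <- !is.na(maf) & maf >= config$min_maf & miss <= config$max_missing_rate
  list(retained = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       counts = c(input = n, retained = sum(keep), removed = sum(!keep)))
}
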