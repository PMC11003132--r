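#' @keywords internal
"_PACKAGE"

# Variant class boundaries (bp): indels span 1-49 bp, SVs >= 50 bp.
SV_MIN_LEN <- 50L

VAR_CLASSES <- c("SNP", "INDEL", "SV")
SV_TYPES <- c("INS", "DEL", "INV", "DUP", "NONE")

#' Construct a variant table
#'
#' The central container of the package: one row per biallelic variant call.
#' Coordinates are 1-based VCF convention; `length` is the signed allele
#' length difference (alt minus ref); `end` is the last affected reference
#' base (`pos` for SNPs and insertions, `pos + nchar(ref) - 1` for
#' deletions, inversions and duplications). Genotypes are stored as the two
#' allele indices `a1 <= a2` (0 = REF, 1 = ALT), both `NA` when the call is
#' missing.
#'
#' @param chrom character, sequence names.
#' @param pos integer, 1-based positions of the first REF base.
#' @param ref,alt character, explicit allele sequences (biallelic).
#' @param a1,a2 integer allele indices (0/1), `NA` for missing genotypes.
#' @param gq numeric genotype quality (Phred-like), `NA` when absent.
#' @param dp numeric read depth at the site, `NA` when absent.
#' @param source character genotyper identifier, `NA` when not applicable.
#' @param sv_type_hint optional character vector of symbolic-type hints
#'   (`"INS"`, `"DEL"`, `"INV"`, `"DUP"`) forcing SV classification
#'   regardless of allele length.
#' @param end optional integer end coordinates (used for symbolic records
#'   whose REF does not span the event); recomputed from `ref` otherwise.
#' @return a `data.frame` with columns `chrom, pos, ref, alt, var_class,
#'   sv_type, length, end, a1, a2, gq, dp, source`.
#' @examples
#' variant_table("chr1", 100, "A", "T", a1 = 0, a2 = 1)
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          a1 = NA_integer_, a2 = NA_integer_,
                          gq = NA_real_, dp = NA_real_,
                          source = NA_character_,
                          sv_type_hint = NULL, end = NULL) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      var_class = character(), sv_type = character(),
                      length = integer(), end = integer(),
                      a1 = integer(), a2 = integer(),
                      gq = numeric(), dp = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  }
  cls <- classify_variant(ref, alt, sv_type_hint)
  gt <- normalize_gt_pair(rep_len(as.integer(a1), n), rep_len(as.integer(a2), n))
  out <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    ref = as.character(ref), alt = as.character(alt),
                    var_class = cls$var_class, sv_type = cls$sv_type,
                    length = cls$length, end = 0L,
                    a1 = gt$a1, a2 = gt$a2,
                    gq = rep_len(as.numeric(gq), n),
                    dp = rep_len(as.numeric(dp), n),
                    source = rep_len(as.character(source), n),
                    stringsAsFactors = FALSE)
  out$end <- variant_end(out$pos, out$ref, out$sv_type)
  if (!is.null(end)) {
    hint <- rep_len(as.integer(end), n)
    out$end <- as.integer(ifelse(is.na(hint), out$end, hint))
  }
  stopifnot(all(out$pos >= 1L))
  out
}

variant_end <- function(pos, ref, sv_type) {
  as.integer(ifelse(sv_type %in% c("DEL", "INV", "DUP"),
                    pos + nchar(ref) - 1L, pos))
}

#' Classify alleles into SNP / indel / SV
#'
#' Applies the size-based taxonomy used throughout the package: a
#' single-base substitution is a SNP; an allele length difference of
#' 1-49 bp is an indel; 50 bp or more is an SV (insertion if positive,
#' deletion if negative). Inversions and duplications are SVs by type
#' regardless of length (an inversion has signed length 0), so a
#' `sv_type_hint` of `"INV"` or `"DUP"` forces class SV.
#'
#' @param ref,alt character vectors of explicit allele sequences.
#' @param sv_type_hint optional character vector (`NA` or one of
#'   `"INS"`, `"DEL"`, `"INV"`, `"DUP"`) recycled along `ref`.
#' @return a `data.frame` with columns `var_class`, `sv_type`, `length`
#'   (signed, `nchar(alt) - nchar(ref)`).
#' @examples
#' classify_variant("A", "T")                    # SNP
#' classify_variant("A", strrep("T", 50))        # INDEL, +49
#' classify_variant("A", paste0("A", strrep("T", 50)))  # SV INS, +50
#' @export
classify_variant <- function(ref, alt, sv_type_hint = NULL) {
  n <- length(ref)
  ref <- as.character(ref); alt <- as.character(alt)
  hint <- if (is.null(sv_type_hint)) rep(NA_character_, n)
          else rep_len(as.character(sv_type_hint), n)
  hint[!is.na(hint) & hint == "NONE"] <- NA_character_
  bad <- (is.na(ref) | is.na(alt) | nchar(ref) == 0L | nchar(alt) == 0L) & is.na(hint)
  if (any(bad)) {
    stop("malformed record: empty allele without an SV type hint at index ",
         which(bad)[1], call. = FALSE)
  }
  len <- nchar(alt) - nchar(ref)
  var_class <- rep(NA_character_, n)
  sv_type <- rep("NONE", n)

  forced <- !is.na(hint) & hint %in% c("INV", "DUP")
  var_class[forced] <- "SV"
  sv_type[forced] <- hint[forced]

  rest <- !forced
  snp <- rest & len == 0L & nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  var_class[snp] <- "SNP"
  indel <- rest & abs(len) >= 1L & abs(len) < SV_MIN_LEN
  var_class[indel] <- "INDEL"
  sv <- rest & abs(len) >= SV_MIN_LEN
  var_class[sv] <- "SV"
  sv_type[sv & len > 0L] <- "INS"
  sv_type[sv & len < 0L] <- "DEL"
  # explicit INS/DEL hints refine sv_type but never shrink the class
  refine <- rest & !is.na(hint) & var_class %in% "SV"
  sv_type[refine] <- hint[refine]

  unclassed <- is.na(var_class)
  if (any(unclassed)) {
    stop("malformed record: balanced multi-base substitution (MNP) or ",
         "identical alleles at index ", which(unclassed)[1], call. = FALSE)
  }
  data.frame(var_class = var_class, sv_type = sv_type, length = as.integer(len),
             stringsAsFactors = FALSE)
}

# canonical unordered storage: a1 <= a2, both NA when missing
normalize_gt_pair <- function(a1, a2) {
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  swap <- !miss & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  list(a1 = a1, a2 = a2)
}

#' Unordered genotype equality
#'
#' Two diploid genotypes are equal when their allele multisets agree:
#' 0/1 equals 1/0. A missing genotype never equals anything, including
#' another missing genotype.
#'
#' @param a1,a2 allele indices of the first genotype (`NA` = missing).
#' @param b1,b2 allele indices of the second genotype.
#' @return logical vector.
#' @examples
#' genotype_equal(0, 1, 1, 0)  # TRUE
#' genotype_equal(NA, NA, 0, 0)  # FALSE
#' @export
genotype_equal <- function(a1, a2, b1, b2) {
  ga <- normalize_gt_pair(as.integer(a1), as.integer(a2))
  gb <- normalize_gt_pair(as.integer(b1), as.integer(b2))
  ok <- !is.na(ga$a1) & !is.na(gb$a1)
  ok & ga$a1 == gb$a1 & ga$a2 == gb$a2
}

#' Parse VCF GT strings into allele-index pairs
#'
#' Accepts `/` or `|` separators (phase is ignored), promotes haploid calls
#' to homozygous diploid, and treats half-missing calls (`./1`) as missing.
#'
#' @param gt character vector of GT strings (`"0/1"`, `"1|0"`, `"."`, ...).
#' @return a list with integer vectors `a1`, `a2` (`NA` = missing).
#' @export
parse_gt <- function(gt) {
  gt <- as.character(gt)
  parts <- strsplit(gt, "[/|]")
  one <- function(p) {
    if (length(p) == 0L || anyNA(p) || any(p == "" | p == ".")) {
      return(c(NA_integer_, NA_integer_))  # missing or half-missing
    }
    v <- suppressWarnings(as.integer(p))
    if (any(is.na(v))) return(c(NA_integer_, NA_integer_))
    if (length(v) == 1L) v <- c(v, v)  # haploid -> homozygous diploid
    sort(v[1:2])
  }
  m <- vapply(parts, one, integer(2))
  miss <- is.na(gt)
  a1 <- m[1, ]; a2 <- m[2, ]
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  list(a1 = a1, a2 = a2)
}

format_gt <- function(a1, a2) {
  ifelse(is.na(a1), "./.", paste0(a1, "/", a2))
}

#' Genomic sort order for a variant table
#' @param records a variant table.
#' @return the table sorted by `(chrom, pos)`.
#' @export
sort_variants <- function(records) {
  records[order(records$chrom, records$pos, records$end, records$alt), ,
          drop = FALSE]
}

#' Read a VCF file into a variant table
#'
#' Multiallelic records are split into biallelic rows: for the row carrying
#' ALT *k*, sample alleles equal to *k* map to 1 and all other alleles
#' (REF or another ALT) map to 0. Symbolic ALTs (`<DEL>`, `<INS>`, `<INV>`,
#' `<DUP>`) are retained verbatim with their `INFO/END` coordinate so that
#' [reformat_vcf()] can resolve them against a reference; other records get
#' `end` recomputed from the REF span. Phase separators are ignored,
#' haploid genotypes are promoted to homozygous diploid, and half-missing
#' genotypes count as missing.
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @param sample for multi-sample files, the sample (name or index) whose
#'   GT/GQ/DP populate the scalar columns; defaults to the first. All
#'   samples' genotypes are kept in the `genotypes` list-column (one
#'   two-column allele-index matrix per record) for cohort-level filters.
#' @param source genotyper identifier stored in the `source` column.
#' @return a variant table (see [variant_table()]) with an extra
#'   `genotypes` list-column, sorted by `(chrom, pos)`.
#' @export
read_vcf <- function(path, sample = 1L, source = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) return(variant_table())
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  info <- fix[, "INFO"]
  end_info <- suppressWarnings(as.integer(sub(".*END=([0-9]+).*", "\\1",
                 ifelse(grepl("(^|;)END=[0-9]+", info), info, NA))))
  svtype_info <- ifelse(grepl("(^|;)SVTYPE=", info),
                        sub(".*SVTYPE=([A-Za-z]+).*", "\\1", info), NA)

  has_gt <- ncol(v@gt) > 1L
  gt_mat <- gq_mat <- dp_mat <- NULL
  if (has_gt) {
    gt_mat <- vcfR::extract.gt(v, element = "GT")
    gq_mat <- try_extract_numeric(v, "GQ")
    dp_mat <- try_extract_numeric(v, "DP")
    if (is.character(sample)) {
      si <- match(sample, colnames(gt_mat))
      if (is.na(si)) stop("sample '", sample, "' not found in ", path)
    } else si <- as.integer(sample)
  }

  rec_idx <- rep(seq_len(n), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  ref <- toupper(fix[rec_idx, "REF"])
  alt <- toupper(unlist(alts, use.names = FALSE))
  chrom <- fix[rec_idx, "CHROM"]
  pos <- as.integer(fix[rec_idx, "POS"])

  sym <- grepl("^<", alt)
  hint <- rep(NA_character_, length(alt))
  hint[sym] <- sub("^<([A-Za-z:]+)>$", "\\1", alt[sym])
  hint[sym] <- sub(":.*", "", hint[sym])
  hint[sym & !hint %in% c("INS", "DEL", "INV", "DUP")] <- NA
  nonsym_hint <- !sym & !is.na(svtype_info[rec_idx]) &
    svtype_info[rec_idx] %in% c("INV", "DUP")
  hint[nonsym_hint] <- svtype_info[rec_idx][nonsym_hint]
  alt_store <- alt

  gt_all <- vector("list", length(alt))
  a1 <- a2 <- rep(NA_integer_, length(alt))
  gq <- dp <- rep(NA_real_, length(alt))
  if (has_gt) {
    for (k in seq_along(alt)) {
      i <- rec_idx[k]; ak <- alt_idx[k]
      p <- parse_gt(gt_mat[i, ])
      # remap: allele == this ALT -> 1, anything else -> 0
      m1 <- ifelse(is.na(p$a1), NA_integer_, as.integer(p$a1 == ak))
      m2 <- ifelse(is.na(p$a2), NA_integer_, as.integer(p$a2 == ak))
      gmat <- cbind(a1 = pmin(m1, m2), a2 = pmax(m1, m2))
      gt_all[[k]] <- gmat
      a1[k] <- gmat[si, 1]; a2[k] <- gmat[si, 2]
      if (!is.null(gq_mat)) gq[k] <- gq_mat[i, si]
      if (!is.null(dp_mat)) dp[k] <- dp_mat[i, si]
    }
  } else {
    gt_all <- rep(list(cbind(a1 = NA_integer_, a2 = NA_integer_)[0, , drop = FALSE]),
                  length(alt))
  }

  # balanced multi-base substitutions fit none of the SNP/indel/SV classes;
  # drop them up front with a warning
  mnp <- !sym & nchar(ref) == nchar(alt) & nchar(ref) > 1L &
    !(hint %in% c("INV", "DUP") & !is.na(hint))
  if (any(mnp)) {
    warning(sum(mnp), " balanced multi-base substitution(s) (MNP) dropped")
    keep_row <- !mnp
    rec_idx <- rec_idx[keep_row]; alt_idx <- alt_idx[keep_row]
    ref <- ref[keep_row]; alt <- alt[keep_row]; alt_store <- alt_store[keep_row]
    chrom <- chrom[keep_row]; pos <- pos[keep_row]
    sym <- sym[keep_row]; hint <- hint[keep_row]
    gt_all <- gt_all[keep_row]
    a1 <- a1[keep_row]; a2 <- a2[keep_row]
    gq <- gq[keep_row]; dp <- dp[keep_row]
  }

  # symbolic ALTs bypass allele-based classification: class/length come
  # from the symbol and INFO/END, pending resolution by reformat_vcf()
  alt_cls <- alt_store
  ref[sym & nchar(ref) == 0L] <- "N"
  alt_cls[sym] <- ifelse(substr(ref[sym], 1, 1) == "N", "A", "N")
  out <- variant_table(chrom, pos, ref, alt_cls, a1, a2, gq, dp,
                       source = source, sv_type_hint = hint,
                       end = end_info[rec_idx])
  out$alt <- alt_store
  if (any(sym)) {
    out$end[sym & is.na(end_info[rec_idx])] <- NA_integer_
    sv_end <- out$end[sym]
    sv_pos <- out$pos[sym]
    span <- sv_end - sv_pos + 1L
    out$var_class[sym] <- "SV"
    typ <- hint[sym]
    typ[is.na(typ)] <- "NONE"
    out$sv_type[sym] <- typ
    out$length[sym] <- ifelse(typ == "DEL", -(sv_end - sv_pos),
                       ifelse(typ == "DUP", span,
                       ifelse(typ == "INV", 0L, NA_integer_)))
  }
  out$genotypes <- I(gt_all)
  out <- sort_variants(out)
  rownames(out) <- NULL
  out
}

try_extract_numeric <- function(v, el) {
  fmt <- v@gt[, "FORMAT"]
  if (!any(grepl(paste0("(^|:)", el, "(:|$)"), fmt))) return(NULL)
  suppressWarnings(vcfR::extract.gt(v, element = el, as.numeric = TRUE))
}

#' Write a variant table to a VCF file
#'
#' Emits a minimal single-sample VCF 4.2 with FORMAT `GT:GQ:DP`. The merge
#' pipeline's provenance columns, when present, are written as INFO keys
#' `TOOLS` (comma-separated genotyper list) and `SUPPORT` (supporting-tool
#' count). Records are sorted by `(chrom, pos)` before writing.
#'
#' @param records a variant table.
#' @param path output path (plain text; use a `.gz` connection upstream if
#'   compression is needed).
#' @param sample_name sample column header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_name = "SAMPLE") {
  records <- sort_variants(records)
  n <- nrow(records)
  info_parts <- vector("list", n)
  sv <- records$var_class == "SV"
  info <- character(n)
  for (i in seq_len(n)) {
    p <- character(0)
    if (sv[i]) p <- c(p, paste0("SVTYPE=", records$sv_type[i]),
                      paste0("END=", records$end[i]))
    if (!is.null(records$tools)) p <- c(p, paste0("TOOLS=", records$tools[i]))
    if (!is.null(records$support)) p <- c(p, paste0("SUPPORT=", records$support[i]))
    info[i] <- if (length(p)) paste(p, collapse = ";") else "."
  }
  fmt_num <- function(x) ifelse(is.na(x), ".",
                                formatC(x, format = "g", digits = 6))
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", "PASS", info, "GT:GQ:DP",
                paste(format_gt(records$a1, records$a2),
                      fmt_num(records$gq), fmt_num(records$dp), sep = ":"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ensemblevar",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=TOOLS,Number=.,Type=String,Description=\"Genotypers supporting the consensus call\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Number of genotypers supporting the consensus genotype\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Evaluation/consensus class of each record
#'
#' SNP and INDEL pass through; SVs are reported by their type
#' (DEL/INS/INV/DUP) so metrics can be stratified the way SV benchmarks
#' are reported.
#' @param records a variant table.
#' @return character vector.
#' @export
eval_class <- function(records) {
  ifelse(records$var_class == "SV", records$sv_type, records$var_class)
}
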