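#' Sequencing-run context for genotyper selection
#'
#' @param genome_size reference genome size in bp.
#' @param read_length sequencing read length in bp.
#' @param depth sequencing depth of the sample, in fold coverage.
#' @param long_reads logical; `TRUE` for long-read (PacBio/ONT) data.
#' @param mode `"fast"` or `"precise"`; only affects whether Paragraph is
#'   used for all variants or SVs only.
#' @return a `run_context` list.
#' @export
run_context <- function(genome_size, read_length, depth,
                        long_reads = FALSE, mode = c("fast", "precise")) {
  mode <- match.arg(mode)
  stopifnot(genome_size > 0, read_length > 0, depth >= 0)
  structure(list(genome_size = genome_size, read_length = read_length,
                 depth = depth, long_reads = isTRUE(long_reads), mode = mode),
            class = "run_context")
}

#' Select the genotyper panel for a run
#'
#' Deterministic decision rules driven by genome size, read length,
#' sequencing depth and data type:
#'
#' * long reads: GraphAligner aligns reads to the graph and vg genotypes
#'   downstream; no short-read tool is considered.
#' * BayesTyper genotypes SNPs, indels and SVs in every short-read run.
#' * Paragraph genotypes SVs only in fast mode (it writes three files per
#'   variant, so including small variants is I/O-prohibitive) and all
#'   variant types in precise mode.
#' * vg giraffe is used when the genome exceeds 1 Gb (1e9 bp, strict),
#'   vg map otherwise.
#' * GraphTyper2 is added when read length exceeds 130 bp *and* depth
#'   exceeds 5x (both strict).
#' * PanGenie is added when depth is below 5x *or* read length is below
#'   130 bp (both strict). At exactly 130 bp / 5x neither conditional tool
#'   fires and the plan holds the unconditional tools only.
#'
#' @param ctx a [run_context()].
#' @return a `genotyping_plan`: list with `tools` (data.frame of `tool`,
#'   `scope` in `{all-variants, sv-only}`) and the originating context.
#' @examples
#' select_genotypers(run_context(2.3e9, 150, 30))
#' @export
select_genotypers <- function(ctx) {
  stopifnot(inherits(ctx, "run_context"))
  if (ctx$long_reads) {
    tools <- data.frame(tool = c("GraphAligner", "vg"),
                        scope = "all-variants", stringsAsFactors = FALSE)
  } else {
    tool <- c("BayesTyper")
    scope <- c("all-variants")
    tool <- c(tool, "Paragraph")
    scope <- c(scope, if (ctx$mode == "fast") "sv-only" else "all-variants")
    tool <- c(tool, if (ctx$genome_size > 1e9) "vg giraffe" else "vg map")
    scope <- c(scope, "all-variants")
    if (ctx$read_length > 130 && ctx$depth > 5) {
      tool <- c(tool, "GraphTyper2"); scope <- c(scope, "all-variants")
    }
    if (ctx$depth < 5 || ctx$read_length < 130) {
      tool <- c(tool, "PanGenie"); scope <- c(scope, "all-variants")
    }
    tools <- data.frame(tool = tool, scope = scope, stringsAsFactors = FALSE)
  }
  structure(list(tools = tools, context = ctx), class = "genotyping_plan")
}

#' @export
print.genotyping_plan <- function(x, ...) {
  cat("Genotyping plan (", if (x$context$long_reads) "long reads"
      else paste0("short reads, ", x$context$mode, " mode"), "):\n", sep = "")
  for (i in seq_len(nrow(x$tools))) {
    cat("  ", x$tools$tool[i], " [", x$tools$scope[i], "]\n", sep = "")
  }
  invisible(x)
}

#' Read-subsampling fraction for a target depth
#'
#' Read mapping against a genome graph dominates runtime, so genotyping
#' runs on a subsample of the reads at a target depth (default 15x). The
#' fraction is `target_depth * genome_size / total_bases`, capped at 1 --
#' data below the target depth is never up-sampled.
#'
#' @param total_bases total sequenced bases (bp) available for the sample.
#' @param genome_size reference genome size (bp).
#' @param target_depth target fold coverage after subsampling.
#' @return fraction in `(0, 1]`.
#' @examples
#' subsample_fraction(4.05e9, 135e6)  # 30x data, 15x target -> 0.5
#' @export
subsample_fraction <- function(total_bases, genome_size, target_depth = 15) {
  stopifnot(genome_size > 0, target_depth > 0)
  if (total_bases <= 0) stop("total_bases must be positive")
  min(1, target_depth * genome_size / total_bases)
}
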