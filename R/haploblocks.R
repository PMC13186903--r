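#' Partition a SNP map into haplotype blocks
#'
#' Splits each chromosome's markers into ordered, non-overlapping blocks of
#' exactly `block_size` consecutive SNPs, subject to two constraints: the
#' block span (last minus first position) must be strictly less than
#' `max_span_bp`, and every gap between adjacent block members strictly less
#' than `max_gap_bp`.  Defaults follow the 4-SNP / <150 kb / <50 kb
#' haplotype-block definition used to compute allele-sharing distances,
#' trading off the number of SNPs captured per block against the
#' recombination probability within it.
#'
#' The partition is built by a single deterministic left-to-right scan per
#' chromosome: a candidate run grows marker by marker; a marker joins iff its
#' gap to the previous run member is < `max_gap_bp` and the resulting span is
#' < `max_span_bp`; once the run holds `block_size` markers the block is
#' emitted and a fresh run starts at the next marker; when a marker cannot
#' join, the run restarts at that marker and any never-emitted run members
#' become unassigned.  Markers left in short trailing runs are unassigned,
#' never merged into undersized blocks.
#'
#' @param map SNP map tibble (`marker`, `chrom`, `pos`), sorted by
#'   (chromosome, position).
#' @param block_size Markers per block (>= 2).  Default 4.
#' @param max_span_bp Strict upper bound on block span in bp.  Default 150000.
#' @param max_gap_bp Strict upper bound on adjacent within-block gaps in bp.
#'   Default 50000.
#' @return A `block_partition`: list with `blocks` (tibble: `block_id`,
#'   `chrom`, `start`, `end`, `markers` list-column of row indices into `map`)
#'   and `unassigned` (integer vector of map row indices), plus the parameters
#'   as attributes.
#' @examples
#' map <- tibble::tibble(marker = paste0("m", 1:4), chrom = "1",
#'                       pos = c(1000L, 20000L, 40000L, 60000L))
#' partition_blocks(map)$blocks
#' @export
partition_blocks <- function(map, block_size = 4L, max_span_bp = 150000L,
                             max_gap_bp = 50000L) {
  validate_snp_map(map)
  if (block_size < 2L) stop("block_size must be >= 2")
  if (max_span_bp < max_gap_bp) stop("max_span_bp must be >= max_gap_bp")
  if (is.unsorted(order(map$chrom, map$pos)) ||
      !identical(order(map$chrom, map$pos), seq_len(nrow(map)))) {
    stop("map must be sorted by (chrom, pos)")
  }
  blocks <- list()
  unassigned <- integer(0)
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    pos <- map$pos[idx]
    run <- integer(0)
    for (k in seq_along(idx)) {
      joins <- length(run) == 0L ||
        ((pos[k] - pos[run[length(run)]]) < max_gap_bp &&
         (pos[k] - pos[run[1L]]) < max_span_bp)
      if (joins) {
        run <- c(run, k)
      } else {
        unassigned <- c(unassigned, idx[run])
        run <- k
      }
      if (length(run) == block_size) {
        blocks[[length(blocks) + 1L]] <- list(
          chrom = chr,
          start = pos[run[1L]],
          end = pos[run[block_size]],
          markers = idx[run]
        )
        run <- integer(0)
      }
    }
    unassigned <- c(unassigned, idx[run])
  }
  block_tbl <- if (length(blocks) == 0L) {
    tibble::tibble(block_id = character(), chrom = character(),
                   start = integer(), end = integer(), n_markers = integer(),
                   markers = list())
  } else {
    tibble::tibble(
      block_id = sprintf("block_%04d", seq_along(blocks)),
      chrom = vapply(blocks, `[[`, character(1L), "chrom"),
      start = vapply(blocks, function(b) as.integer(b$start), integer(1L)),
      end = vapply(blocks, function(b) as.integer(b$end), integer(1L)),
      n_markers = block_size,
      markers = lapply(blocks, `[[`, "markers")
    )
  }
  out <- list(blocks = block_tbl, unassigned = sort(unassigned))
  attr(out, "block_size") <- block_size
  attr(out, "max_span_bp") <- max_span_bp
  attr(out, "max_gap_bp") <- max_gap_bp
  attr(out, "n_markers") <- nrow(map)
  class(out) <- "block_partition"
  out
}

#' @export
print.block_partition <- function(x, ...) {
  cat("Haplotype-block partition:", nrow(x$blocks), "blocks of",
      attr(x, "block_size"), "SNPs;", length(x$unassigned),
      "of", attr(x, "n_markers"), "markers unassigned\n")
  invisible(x)
}

#' Summarise block coverage of a SNP map
#'
#' @param partition A `block_partition` from [partition_blocks()].
#' @param map The SNP map the partition was derived from.
#' @return A list with `n_blocks`, `fraction_assigned`, `per_chrom` (tibble of
#'   per-chromosome block counts) and `span_bp` / `gap_bp` min/median/max
#'   tibbles.
#' @export
block_coverage_stats <- function(partition, map) {
  stopifnot(inherits(partition, "block_partition"))
  if (attr(partition, "n_markers") != nrow(map)) {
    stop("partition was derived from a map of different length")
  }
  n_assigned <- sum(partition$blocks$n_markers)
  if (length(partition$unassigned) + n_assigned != nrow(map)) {
    stop("partition does not cover the supplied map")
  }
  spans <- partition$blocks$end - partition$blocks$start
  gaps <- unlist(lapply(partition$blocks$markers, function(m) diff(map$pos[m])))
  stat3 <- function(v) {
    if (length(v) == 0L) {
      tibble::tibble(min = NA_real_, median = NA_real_, max = NA_real_)
    } else {
      tibble::tibble(min = min(v), median = stats::median(v), max = max(v))
    }
  }
  list(
    n_blocks = nrow(partition$blocks),
    fraction_assigned = if (nrow(map) == 0L) 0 else n_assigned / nrow(map),
    per_chrom = dplyr::count(partition$blocks, .data$chrom, name = "n_blocks"),
    span_bp = stat3(spans),
    gap_bp = stat3(gaps)
  )
}

#' Export blocks as BED intervals
#'
#' Writes the block partition in BED-like 0-based half-open coordinates
#' (chromosome, start-1, end, block id); internal coordinates stay 1-based
#' inclusive.
#'
#' @param partition A `block_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
blocks_to_bed <- function(partition, path) {
  stopifnot(inherits(partition, "block_partition"))
  b <- partition$blocks
  readr::write_tsv(
    tibble::tibble(chrom = b$chrom, start = b$start - 1L, end = b$end,
                   name = b$block_id),
    path, col_names = FALSE
  )
  invisible(path)
}
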