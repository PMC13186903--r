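#' Allele sharing between two animals over one block
#'
#' Per-marker sharing is the identity-by-state fraction of the two unphased
#' diploid genotypes: `1 - |a - b| / 2` on dosage codes, so identical
#' genotypes share 1, opposite homozygotes share 0, and a homozygote vs a
#' heterozygote shares 0.5.  Block sharing is the mean over the block's
#' markers, and is `NA` (undefined) if any entry of either vector is missing
#' — blocks contribute to a pair only when fully observed in both animals.
#'
#' @param g_i,g_j Equal-length dosage vectors (one block) with entries
#'   0/1/2/`NA`.
#' @return Sharing in `[0, 1]`, or `NA` if either vector has a missing entry.
#' @examples
#' pair_block_sharing(c(1, 1, 1, 1), c(2, 2, 2, 2))  # 0.5
#' @export
pair_block_sharing <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) stop("block vectors differ in length")
  if (anyNA(g_i) || anyNA(g_j)) return(NA_real_)
  mean(1 - abs(g_i - g_j) / 2)
}

#' Haplotype-block allele-sharing distance matrix
#'
#' Computes the pairwise allele-sharing distance (ASD) between all animals:
#' `d(i, j) = 1 -` mean block sharing over all blocks where
#' [pair_block_sharing()] is defined for the pair.  Missing data are handled
#' by whole-block pairwise deletion; the fraction of usable blocks is
#' returned per pair and pairs falling below `min_valid_fraction` raise an
#' error rather than silently degrading.
#'
#' The statistic is unphased, genotype-level IBS sharing averaged first
#' within blocks and then across blocks.  It is symmetric, zero on the
#' diagonal, bounded in `[0, 1]`, and invariant to flipping the dosage
#' orientation (`x -> 2 - x`) at any subset of markers; it need not satisfy
#' the triangle inequality.
#'
#' @param genotypes Animals x markers dosage matrix (>= 2 animals).
#' @param partition A `block_partition` over the matching map.
#' @param min_valid_fraction Minimum fraction of blocks that must be usable
#'   for every pair.  Default 0.5.
#' @return An `asd_dist` object: list with `distance` (symmetric matrix),
#'   `valid_block_fraction` (matrix), and `n_blocks`.
#' @export
asd_matrix <- function(genotypes, partition, min_valid_fraction = 0.5) {
  stopifnot(inherits(partition, "block_partition"))
  n <- nrow(genotypes)
  if (n < 2L) stop("need at least 2 animals")
  if (attr(partition, "n_markers") != ncol(genotypes)) {
    stop("partition was derived from a map of different length")
  }
  n_blocks <- nrow(partition$blocks)
  if (n_blocks == 0L) stop("empty block partition: no blocks to compare")
  ids <- rownames(genotypes)
  share_sum <- matrix(0, n, n)
  share_cnt <- matrix(0L, n, n)
  for (b in seq_len(n_blocks)) {
    idx <- partition$blocks$markers[[b]]
    x <- genotypes[, idx, drop = FALSE]
    ok <- rowSums(is.na(x)) == 0L     # animals fully observed on this block
    if (sum(ok) < 2L) next
    xs <- x[ok, , drop = FALSE]
    s <- matrix(1, sum(ok), sum(ok))
    for (m in seq_along(idx)) {
      s <- s - abs(outer(xs[, m], xs[, m], `-`)) / (2 * length(idx))
    }
    share_sum[ok, ok] <- share_sum[ok, ok] + s
    share_cnt[ok, ok] <- share_cnt[ok, ok] + 1L
  }
  if (any(share_cnt[upper.tri(share_cnt)] == 0L)) {
    bad <- which(share_cnt == 0L & upper.tri(share_cnt), arr.ind = TRUE)
    stop("no usable blocks for pair(s): ",
         paste(ids[bad[, 1L]], ids[bad[, 2L]], sep = "/", collapse = ", "))
  }
  valid_frac <- share_cnt / n_blocks
  low <- valid_frac < min_valid_fraction & upper.tri(valid_frac)
  if (any(low)) {
    bad <- which(low, arr.ind = TRUE)
    stop("valid-block fraction below ", min_valid_fraction, " for pair(s): ",
         paste(ids[bad[, 1L]], ids[bad[, 2L]], sep = "/", collapse = ", "))
  }
  d <- 1 - share_sum / share_cnt
  d <- (d + t(d)) / 2              # symmetrise away rounding noise
  diag(d) <- 0
  d[d < 0] <- 0
  dimnames(d) <- dimnames(valid_frac) <- list(ids, ids)
  structure(
    list(distance = d, valid_block_fraction = valid_frac, n_blocks = n_blocks),
    class = "asd_dist"
  )
}

#' @export
print.asd_dist <- function(x, ...) {
  cat("Allele-sharing distance matrix:", nrow(x$distance), "animals,",
      x$n_blocks, "blocks\n")
  off <- x$distance[upper.tri(x$distance)]
  cat(sprintf("  distances: min %.4f, median %.4f, max %.4f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

#' Tidy pairwise distances
#'
#' @param x An `asd_dist` object.
#' @param ... Unused.
#' @return Tibble with one row per unordered animal pair: `id1`, `id2`,
#'   `distance`, `valid_block_fraction`.
#' @method tidy asd_dist
#' @export
tidy.asd_dist <- function(x, ...) {
  ut <- which(upper.tri(x$distance), arr.ind = TRUE)
  tibble::tibble(
    id1 = rownames(x$distance)[ut[, 1L]],
    id2 = colnames(x$distance)[ut[, 2L]],
    distance = x$distance[ut],
    valid_block_fraction = x$valid_block_fraction[ut]
  )
}

#' Heatmap of an allele-sharing distance matrix
#'
#' Rows and columns are ordered by the UPGMA dendrogram leaf order so related
#' animals cluster along the diagonal, mirroring the clustered-heatmap view
#' used to read off genetic backgrounds (low distance = close relationship).
#'
#' @param object An `asd_dist` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot asd_dist
#' @export
autoplot.asd_dist <- function(object, ...) {
  ord <- leaf_order(upgma(object))
  df <- tidyr::expand_grid(id1 = ord, id2 = ord) |>
    dplyr::mutate(distance = object$distance[cbind(.data$id1, .data$id2)],
                  id1 = factor(.data$id1, levels = ord),
                  id2 = factor(.data$id2, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$id1, .data$id2, fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b",
                                 name = "ASD") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
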