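# Small in-code fixtures shared across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

tiny_map <- function(pos, chrom = "1") {
  tibble::tibble(marker = sprintf("m%02d", seq_along(pos)),
                 chrom = rep(chrom, length.out = length(pos)),
                 pos = as.integer(pos))
}

tiny_genotypes <- function(values, ids = NULL, markers = NULL) {
  g <- as.matrix(values)
  rownames(g) <- ids %||% sprintf("a%02d", seq_len(nrow(g)))
  colnames(g) <- markers %||% sprintf("m%02d", seq_len(ncol(g)))
  g
}

# map with every marker in one 4-SNP block (tight spacing)
blocky_map <- function(n_markers, gap = 10000L, chrom = "1") {
  tiny_map(seq(1L, by = gap, length.out = n_markers), chrom = chrom)
}

random_map <- function(n, max_gap = 80000L, n_chrom = 2L) {
  chrom <- sort(sample(sprintf("c%d", seq_len(n_chrom)), n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(idx) {
    cumsum(sample.int(max_gap, length(idx), replace = TRUE))
  }), use.names = FALSE)
  tibble::tibble(marker = sprintf("m%03d", seq_len(n)), chrom = chrom,
                 pos = as.integer(pos))
}

random_distance_matrix <- function(n, ids = NULL) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.05, 1)
  d <- d + t(d)
  ids <- ids %||% sprintf("s%02d", seq_len(n))
  dimnames(d) <- list(ids, ids)
  d
}

# independent reference for the greedy block scan (deliberately plain)
reference_block_scan <- function(map, block_size = 4L, max_span_bp = 150000L,
                                 max_gap_bp = 50000L) {
  blocks <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    run <- integer(0)
    for (i in idx) {
      ok <- length(run) == 0L ||
        (map$pos[i] - map$pos[run[length(run)]] < max_gap_bp &&
           map$pos[i] - map$pos[run[1]] < max_span_bp)
      if (ok) run <- c(run, i) else run <- i
      if (length(run) == block_size) {
        blocks[[length(blocks) + 1]] <- run
        run <- integer(0)
      }
    }
  }
  blocks
}

# brute-force UPGMA used as the clustering oracle: recomputes all pairwise
# cluster averages from the original matrix at every step
reference_upgma <- function(d) {
  ids <- rownames(d)
  clusters <- as.list(ids)
  heights <- c()
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (avg < best_d - 1e-12 ||
            (abs(avg - best_d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, key = key); best_d <- avg
        }
      }
    }
    heights <- c(heights, best_d / 2)
    merges[[length(merges) + 1]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# leaf sets merged at each step of an upgma_tree, sorted, for comparison
upgma_merge_sets <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1)
  get_m <- function(code) if (code < 0) tree$labels[-code] else members[[code]]
  out <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    members[[s]] <- c(get_m(tree$merge[s, 1]), get_m(tree$merge[s, 2]))
    out[[s]] <- sort(members[[s]])
  }
  out
}

small_cohort_config <- function(seed, ...) {
  cohort_config(n_snps = 600L, n_chrom = 3L, n_ref_a = 12L, n_ref_b = 12L,
                design = tibble::tibble(
                  alpha = c(0.8, 0.8, 0.2, 0.2),
                  treatment = c("CONTROL", "IHF", "CONTROL", "IHF"),
                  n = c(6L, 6L, 6L, 6L)
                ),
                seed = seed, ...)
}
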