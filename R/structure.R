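#' Classical (Torgerson) multidimensional scaling of a distance matrix
#'
#' Projects the allele-sharing distance matrix onto `dims` axes by
#' eigendecomposition of the double-centred squared-distance matrix.  Axes
#' whose eigenvalues are non-positive carry no Euclidean information and are
#' zero-filled (and reported), never clipped silently into coordinates.  Each
#' retained axis is oriented so that the reference-panel-A centroid
#' coordinate is non-negative (first animal non-negative when no panels are
#' given), making plots reproducible.
#'
#' @param dm An `asd_dist` object or a symmetric labelled distance matrix.
#' @param dims Number of output axes.  Default 2 (the plane).
#' @param labels Optional `panel_labels`; used only for the sign convention.
#' @return An `asd_mds` object: list with `coordinates` (tibble: `id`,
#'   `axis1` ... `axisk`), `eigenvalues` (all, non-increasing), `stress` (sum
#'   of squared residuals between embedded and input distances), and
#'   `n_negative_axes` (requested axes without positive eigenvalue).
#' @export
classical_mds <- function(dm, dims = 2L, labels = NULL) {
  d <- if (inherits(dm, "asd_dist")) dm$distance else as.matrix(dm)
  n <- nrow(d)
  if (dims < 1L) stop("dims must be >= 1")
  if (dims > n) stop("dims (", dims, ") exceeds animal count (", n, ")")
  fit <- stats::cmdscale(stats::as.dist(d), k = min(dims, n - 1L), eig = TRUE)
  pts <- fit$points
  coords <- matrix(0, n, dims, dimnames = list(rownames(d), NULL))
  k_avail <- ncol(pts)
  if (k_avail > 0L) coords[, seq_len(k_avail)] <- pts[, seq_len(k_avail)]
  # axes whose eigenvalue is zero to numerical precision carry no signal;
  # zero them rather than keep eigensolver dust
  tol <- max(fit$eig, 0) * 1e-9
  degenerate <- which(fit$eig[seq_len(dims)] <= tol)
  coords[, degenerate] <- 0
  n_negative <- dims - min(k_avail, sum(fit$eig[seq_len(min(dims, n))] > 1e-12))
  # sign convention: REF_A centroid (or first animal) non-negative per axis
  ref_rows <- if (!is.null(labels)) {
    which(rownames(d) %in% labels$id[labels$role == "REF_A"])
  } else integer(0)
  if (length(ref_rows) == 0L) ref_rows <- 1L
  for (j in seq_len(dims)) {
    if (mean(coords[ref_rows, j]) < 0) coords[, j] <- -coords[, j]
  }
  emb <- as.matrix(stats::dist(coords))
  stress <- sum((emb - d)^2) / 2
  out <- list(
    coordinates = tibble::tibble(id = rownames(d)) |>
      dplyr::bind_cols(tibble::as_tibble(coords, .name_repair = ~ paste0("axis", seq_len(dims)))),
    eigenvalues = sort(fit$eig, decreasing = TRUE),
    stress = stress,
    n_negative_axes = max(0L, n_negative)
  )
  class(out) <- "asd_mds"
  out
}

#' @export
print.asd_mds <- function(x, ...) {
  cat("Classical MDS embedding:", nrow(x$coordinates), "animals,",
      ncol(x$coordinates) - 1L, "axes; stress =", signif(x$stress, 4), "\n")
  invisible(x)
}

#' @method tidy asd_mds
#' @export
tidy.asd_mds <- function(x, ...) x$coordinates

#' @method glance asd_mds
#' @export
glance.asd_mds <- function(x, ...) {
  k <- ncol(x$coordinates) - 1L
  tot <- sum(abs(x$eigenvalues))
  tibble::tibble(
    n = nrow(x$coordinates),
    dims = k,
    stress = x$stress,
    prop_variance = if (tot > 0) sum(pmax(x$eigenvalues[seq_len(k)], 0)) / tot else NA_real_,
    n_negative_eigenvalues = sum(x$eigenvalues < 0),
    n_negative_axes = x$n_negative_axes
  )
}

#' Plot an MDS embedding
#'
#' @param object An `asd_mds` object.
#' @param labels Optional `panel_labels` to colour points by role/breed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot asd_mds
#' @export
autoplot.asd_mds <- function(object, labels = NULL, ...) {
  df <- object$coordinates
  if (!is.null(labels)) {
    role_name <- c(
      REF_A = paste0(attr(labels, "breed_a"), " (reference)"),
      REF_B = paste0(attr(labels, "breed_b"), " (reference)"),
      EXPERIMENTAL = "Experimental"
    )
    df <- dplyr::left_join(df, labels, by = "id") |>
      dplyr::mutate(group = role_name[.data$role])
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2,
                                          colour = .data$group))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2))
  }
  p + ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "MDS axis 1", y = "MDS axis 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' UPGMA hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with size-weighted average linkage: at each step
#' the closest pair of clusters merges into a node whose height is half the
#' merge distance, and distances to the new cluster are the size-weighted
#' means of its members' distances.  Ties in the closest pair are broken
#' deterministically by the lexicographically smallest pair of smallest
#' member-leaf labels, so dendrograms and heatmap orderings are
#' byte-reproducible.
#'
#' @param dm An `asd_dist` object or symmetric labelled distance matrix.
#' @return An `upgma_tree`: list with `merge` (hclust-style, negative =
#'   leaf), `height` (node heights, merge distance / 2), `labels`.
#' @export
upgma <- function(dm) {
  d <- if (inherits(dm, "asd_dist")) dm$distance else as.matrix(dm)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 animals")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  labels <- rownames(d)
  # active clusters: list of (hclust code, size, min leaf label)
  code <- -seq_len(n)
  size <- rep(1L, n)
  minlab <- labels
  dd <- d
  diag(dd) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(size)
    best <- NULL
    best_d <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        dij <- dd[i, j]
        if (dij < best_d - 1e-12) {
          best <- c(i, j); best_d <- dij
        } else if (abs(dij - best_d) <= 1e-12 && !is.null(best)) {
          key_new <- sort(c(minlab[i], minlab[j]))
          key_old <- sort(c(minlab[best[1L]], minlab[best[2L]]))
          if (key_new[1L] < key_old[1L] ||
              (key_new[1L] == key_old[1L] && key_new[2L] < key_old[2L])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- best_d / 2
    new_size <- size[i] + size[j]
    new_row <- (size[i] * dd[i, ] + size[j] * dd[j, ]) / new_size
    keep <- setdiff(seq_len(m), c(i, j))
    dd <- rbind(cbind(dd[keep, keep, drop = FALSE], new_row[keep]),
                c(new_row[keep], Inf))
    code <- c(code[keep], step)
    size <- c(size[keep], new_size)
    minlab <- c(minlab[keep], min(minlab[c(i, j)]))
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree:", length(x$labels), "leaves; root height",
      signif(x$height[length(x$height)], 4), "\n")
  invisible(x)
}

#' @method tidy upgma_tree
#' @export
tidy.upgma_tree <- function(x, ...) {
  tibble::tibble(
    node = seq_along(x$height),
    left = x$merge[, 1L],
    right = x$merge[, 2L],
    height = x$height
  )
}

#' Cophenetic distance implied by a UPGMA tree
#'
#' Leaf-to-leaf distance is twice the height of the most recent common
#' ancestor, i.e. the merge distance at which the two leaves first share a
#' cluster.  For an ultrametric input this reproduces the input matrix
#' exactly.
#'
#' @param tree An `upgma_tree`.
#' @return A labelled symmetric matrix.
#' @export
upgma_cophenetic <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1L)
  coph <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  get_members <- function(code) {
    if (code < 0L) -code else members[[code]]
  }
  for (step in seq_len(n - 1L)) {
    left <- get_members(tree$merge[step, 1L])
    right <- get_members(tree$merge[step, 2L])
    coph[left, right] <- coph[right, left] <- 2 * tree$height[step]
    members[[step]] <- c(left, right)
  }
  coph
}

#' Deterministic dendrogram leaf order
#'
#' Left-to-right leaf traversal of the UPGMA tree: at each internal node the
#' child containing the lexicographically smallest leaf goes left.  The
#' result is independent of the input animal order and defines the heatmap
#' row/column ordering.
#'
#' @param tree An `upgma_tree`.
#' @return Character vector of animal ids.
#' @export
leaf_order <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- length(tree$labels)
  walk <- function(code) {
    if (code < 0L) return(tree$labels[-code])
    left <- walk(tree$merge[code, 1L])
    right <- walk(tree$merge[code, 2L])
    if (min(left) <= min(right)) c(left, right) else c(right, left)
  }
  walk(n - 1L)
}

#' Convert a UPGMA tree to an ape phylogeny / write Newick
#'
#' Branch lengths are height differences, so leaf-to-root path length equals
#' the root height (half the deepest merge distance).
#'
#' @param tree An `upgma_tree`.
#' @return An [ape::phylo] object.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  # hclust stores merge distances; ape::as.phylo.hclust halves them to node
  # heights, which matches this tree's height = distance / 2 convention
  hc <- structure(
    list(merge = tree$merge, height = tree$height * 2, labels = tree$labels,
         order = match(leaf_order(tree), tree$labels),
         method = "average"),
    class = "hclust"
  )
  ape::as.phylo(hc)
}

#' @param path Output path for the Newick file.
#' @rdname as_phylo
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(as_phylo(tree), file = path)
  invisible(path)
}

#' Assign experimental animals a breed-dominance label
#'
#' For each experimental animal the mean allele-sharing distance to the two
#' purebred reference panels is computed (the animal itself is never a panel
#' member) and summarised as a dominance score
#' `(d_B - d_A) / (d_A + d_B)` in `[-1, 1]`: positive scores mean the animal
#' is closer to panel A.  Labels are `A_DOMINANT` when `score > tie_band`,
#' `B_DOMINANT` when `score < -tie_band`, and `UNASSIGNED` inside the tie
#' band (including an exact tie at 0).
#'
#' @param dm An `asd_dist` object or symmetric labelled distance matrix
#'   containing both panels and all experimental animals.
#' @param labels A `panel_labels` object; both reference roles must be
#'   non-empty.
#' @param tie_band Half-width of the unassigned band on the score scale.
#'   Default 0 (only exact ties are unassigned).
#' @return A `breed_assignment` tibble: `id`, `d_A`, `d_B`, `score`, `label`,
#'   plus breed-name attributes.
#' @export
assign_breed <- function(dm, labels, tie_band = 0) {
  d <- if (inherits(dm, "asd_dist")) dm$distance else as.matrix(dm)
  stopifnot(tie_band >= 0, tie_band < 1)
  ref_a <- labels$id[labels$role == "REF_A"]
  ref_b <- labels$id[labels$role == "REF_B"]
  exp_ids <- labels$id[labels$role == "EXPERIMENTAL"]
  if (length(ref_a) == 0L || length(ref_b) == 0L) {
    stop("both reference panels must be non-empty")
  }
  missing_ids <- setdiff(c(ref_a, ref_b, exp_ids), rownames(d))
  if (length(missing_ids) > 0L) {
    stop("animals absent from the distance matrix: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  }
  d_a <- rowMeans(d[exp_ids, ref_a, drop = FALSE])
  d_b <- rowMeans(d[exp_ids, ref_b, drop = FALSE])
  denom <- d_a + d_b
  score <- ifelse(denom > 0, (d_b - d_a) / denom, 0)
  label <- dplyr::case_when(
    score > tie_band ~ "A_DOMINANT",
    score < -tie_band ~ "B_DOMINANT",
    .default = "UNASSIGNED"
  )
  out <- tibble::tibble(id = exp_ids, d_A = unname(d_a), d_B = unname(d_b),
                        score = unname(score), label = label)
  attr(out, "breed_a") <- attr(labels, "breed_a")
  attr(out, "breed_b") <- attr(labels, "breed_b")
  attr(out, "tie_band") <- tie_band
  class(out) <- c("breed_assignment", class(out))
  out
}

#' Plot breed-dominance scores
#'
#' @param object A `breed_assignment`.
#' @param ... Unused.
#' @return A ggplot object: animals ranked by dominance score, coloured by
#'   label, with the tie band shaded.
#' @method autoplot breed_assignment
#' @export
autoplot.breed_assignment <- function(object, ...) {
  tb <- attr(object, "tie_band") %||% 0
  df <- dplyr::arrange(tibble::as_tibble(object), .data$score) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$score, colour = .data$label)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = -tb, ymax = tb,
                      alpha = 0.15, fill = "grey50") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Animal (ranked)",
      y = sprintf("Dominance score (+: %s, -: %s)",
                  attr(object, "breed_a") %||% "A",
                  attr(object, "breed_b") %||% "B"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
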