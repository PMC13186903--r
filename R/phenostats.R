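# Exact-test machinery: enumeration index matrices are cached per (n1, n2)
# so repeated stratified contrasts at the same group sizes stay fast.
.hs_cache <- new.env(parent = emptyenv())

combn_cache <- function(n, k) {
  key <- paste0("C", n, "_", k)
  if (is.null(.hs_cache[[key]])) .hs_cache[[key]] <- utils::combn(n, k)
  .hs_cache[[key]]
}

stat_result <- function(method, statistic, p_value, n1, n2, mode,
                        estimate = NA_real_) {
  tibble::tibble(method = method, statistic = statistic, estimate = estimate,
                 p_value = p_value, n1 = n1, n2 = n2, mode = mode)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples,
#' using midranks so ties are handled throughout.  In exact mode the null
#' distribution of U is obtained by complete enumeration of all
#' `choose(n1 + n2, n1)` assignments of the pooled midranks to the first
#' group, and the two-sided p-value is the probability of a U at least as far
#' from its null mean `n1 * n2 / 2` as the observed one.  Approximate mode
#' uses the normal approximation with tie correction and a 0.5 continuity
#' correction.  `auto` picks exact when `n1 + n2 <= 20`.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"approximate"`.
#' @return A one-row tibble: `method`, `statistic` (U of the first sample),
#'   `p_value`, `n1`, `n2`, `mode`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approximate")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
  if (mode == "auto") mode <- if (n1 + n2 <= 20L) "exact" else "approximate"
  r <- rank(c(x, y))                       # midranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (mode == "exact") {
    idx <- combn_cache(n1 + n2, n1)
    rank_sums <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rank_sums - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    n <- n1 + n2
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  stat_result("Mann-Whitney U", u_obs, p, n1, n2, mode)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by enumeration of the conditional (hypergeometric)
#' distribution given the margins: all tables whose probability does not
#' exceed that of the observed table (within a relative tolerance of 1e-7
#' for ties) contribute.  The sample odds ratio is reported; a zero
#' off-diagonal cell yields `Inf` or 0, which is flagged in the result mode.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A one-row tibble with the odds ratio as `estimate`.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p_value  # 34/70
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  a <- table[1L, 1L]
  m1 <- sum(table[1L, ]); m2 <- sum(table[2L, ])  # row margins
  k <- sum(table[, 1L])                           # first-column margin
  n_tot <- m1 + m2
  if (n_tot == 0L) stop("at least one margin must be positive")
  lo <- max(0L, k - m2); hi <- min(k, m1)
  if (lo == hi) {
    p <- 1  # margins fix the table completely
  } else {
    probs <- stats::dhyper(lo:hi, m1, m2, k)
    p_obs <- stats::dhyper(a, m1, m2, k)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  or <- (table[1L, 1L] * table[2L, 2L]) / (table[1L, 2L] * table[2L, 1L])
  mode <- if (any(table == 0)) "exact (0-cell odds ratio)" else "exact"
  stat_result("Fisher exact", NA_real_, p, m1, m2, mode, estimate = or)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Equal-length numeric samples (n >= 3, both with positive
#'   variance).
#' @return A one-row tibble with `estimate` = r and the two-sided p-value
#'   from the t transform on n - 2 degrees of freedom.
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length samples with n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in a sample")
  ct <- stats::cor.test(x, y, method = "pearson")
  stat_result("Pearson correlation", unname(ct$statistic), ct$p.value,
              length(x), length(y), "approximate", estimate = unname(ct$estimate))
}

#' Per-animal fibrosis summaries and heterogeneity
#'
#' Summarises per-image fibrosis percentages for the left and right atrium of
#' one animal: the regional mean, the "fibrosis difference" heterogeneity
#' statistic (max minus min across images, the spread measure correlated
#' with AF burden), and the per-image standard deviation as an alternative
#' heterogeneity measure.
#'
#' @param la_values,ra_values Per-image fibrosis percentages (>= 2 images per
#'   region; ten per region is the expected design).
#' @return A tibble with one row per region: `region`, `n_images`, `mean`,
#'   `difference`, `sd`.
#' @export
fibrosis_heterogeneity <- function(la_values, ra_values) {
  one <- function(v, region) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) stop("need at least 2 images per region (", region, ")")
    if (any(v < 0 | v > 100)) stop("fibrosis percentages must lie in [0, 100]")
    tibble::tibble(region = region, n_images = length(v), mean = mean(v),
                   difference = max(v) - min(v), sd = stats::sd(v))
  }
  dplyr::bind_rows(one(la_values, "LA"), one(ra_values, "RA"))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Normalises each sample's target-gene Ct to its reference-gene Ct
#' (`dct = ct - ct_ref`), centres on the control-group mean delta-Ct
#' (`ddct = dct - mean(dct[control])`), and reports the fold change
#' `2^(-ddct)`.  By construction the control group's mean delta-delta-Ct is
#' 0, and adding any constant to all Ct values of a sample (target and
#' reference together) leaves the folds unchanged.
#'
#' @param ct Target-gene Ct per sample.
#' @param ct_ref Reference-gene (e.g. ACTB) Ct per sample; must be complete.
#' @param group Group label per sample.
#' @param control_label The label identifying the control group (non-empty).
#' @return A tibble: `group`, `delta_ct`, `delta_delta_ct`, `fold_change`,
#'   one row per sample in input order.
#' @export
ddct_fold_change <- function(ct, ct_ref, group, control_label) {
  if (length(ct) != length(ct_ref) || length(ct) != length(group)) {
    stop("ct, ct_ref and group must have equal length")
  }
  if (anyNA(ct_ref)) stop("reference Ct missing for ",
                          sum(is.na(ct_ref)), " sample(s)")
  ctrl <- group == control_label & !is.na(ct)
  if (!any(ctrl)) stop("control group '", control_label, "' is empty")
  dct <- ct - ct_ref
  ddct <- dct - mean(dct[ctrl])
  tibble::tibble(group = group, delta_ct = dct, delta_delta_ct = ddct,
                 fold_change = 2^(-ddct))
}

#' Atrial-fibrillation inducibility endpoints
#'
#' An induced AF episode is one lasting strictly longer than `episode_min_s`
#' seconds (the default 10 s mirrors the definition of AF as an arrhythmic
#' episode with irregular RR intervals lasting longer than 10 s).  Two
#' complementary endpoints are derived per animal: whether any episode
#' crossed the threshold (animal-level inducibility) and the fraction of
#' burst stimulations that induced such an episode (stimulation-level
#' vulnerability).
#'
#' @param episodes Tibble with columns `id`, `duration_s` (one row per AF
#'   episode; animals without episodes may be absent).
#' @param stimulations Tibble with columns `id`, `n_stimulations`.
#' @param episode_min_s Strict duration threshold in seconds.  Default 10.
#' @return A tibble keyed by `id`: `n_stimulations`, `n_episodes`,
#'   `n_inducing` (episodes over threshold), `inducible` (logical),
#'   `fraction_inducing`.
#' @export
af_endpoints <- function(episodes, stimulations, episode_min_s = 10) {
  stopifnot(all(c("id", "duration_s") %in% names(episodes)),
            all(c("id", "n_stimulations") %in% names(stimulations)))
  if (any(episodes$duration_s < 0, na.rm = TRUE)) {
    stop("episode durations must be non-negative")
  }
  per_animal <- episodes |>
    dplyr::summarise(
      n_episodes = dplyr::n(),
      n_inducing = sum(.data$duration_s > episode_min_s),
      .by = "id"
    )
  out <- stimulations |>
    dplyr::left_join(per_animal, by = "id") |>
    tidyr::replace_na(list(n_episodes = 0L, n_inducing = 0L)) |>
    dplyr::mutate(
      inducible = .data$n_inducing > 0L,
      fraction_inducing = .data$n_inducing / .data$n_stimulations
    )
  short <- out$n_stimulations < out$n_episodes
  if (any(short)) {
    stop("animal ", out$id[short][1L],
         " has more AF episodes than burst stimulations")
  }
  out
}

# Group contrast helpers --------------------------------------------------

sem <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2L) return(NA_real_)
  stats::sd(v) / sqrt(length(v))
}

contrast_continuous <- function(values1, values2) {
  v1 <- values1[!is.na(values1)]; v2 <- values2[!is.na(values2)]
  if (length(v1) == 0L || length(v2) == 0L) {
    return(tibble::tibble(n1 = length(v1), mean1 = NA_real_, sem1 = NA_real_,
                          n2 = length(v2), mean2 = NA_real_, sem2 = NA_real_,
                          test = "Mann-Whitney U", p_value = NA_real_))
  }
  res <- mann_whitney_u(v1, v2)
  tibble::tibble(n1 = length(v1), mean1 = mean(v1), sem1 = sem(v1),
                 n2 = length(v2), mean2 = mean(v2), sem2 = sem(v2),
                 test = "Mann-Whitney U", p_value = res$p_value)
}

contrast_binary <- function(hits1, total1, hits2, total2) {
  if (total1 == 0L || total2 == 0L) {
    return(tibble::tibble(n1 = total1, mean1 = NA_real_, sem1 = NA_real_,
                          n2 = total2, mean2 = NA_real_, sem2 = NA_real_,
                          test = "Fisher exact", p_value = NA_real_))
  }
  tab <- matrix(c(hits1, total1 - hits1, hits2, total2 - hits2), 2L,
                byrow = TRUE)
  res <- fisher_exact_2x2(tab)
  tibble::tibble(n1 = total1, mean1 = 100 * hits1 / total1, sem1 = NA_real_,
                 n2 = total2, mean2 = 100 * hits2 / total2, sem2 = NA_real_,
                 test = "Fisher exact", p_value = res$p_value)
}
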