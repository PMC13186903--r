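#' Genotype-stratified phenotype report
#'
#' Re-analyses the phenotype table with the genetic background taken into
#' account.  Experimental animals are split into the four design cells
#' (breed A / breed B crossed with control / IHF, breed labels taken from
#' the assignment) and the report computes:
#'
#' * within-breed IHF-vs-control contrasts for every continuous variable
#'   (ejection fraction, pressures, AERP/AVERP/SNRT per drive cycle length,
#'   per-region mean fibrosis and fibrosis difference, per-gene/tissue qPCR
#'   expression) via the exact Mann-Whitney U test;
#' * the same contrasts between the two IHF groups (cross-breed);
#' * AF inducibility at the animal level (inducible animals vs not) and at
#'   the stimulation level (pooled inducing vs non-inducing stimulations),
#'   both via Fisher's exact test — stimulation-level pooling ignores
#'   within-animal clustering, which is flagged in the caveats;
#' * Pearson correlation of the per-animal AF episode count with the
#'   fibrosis difference (per region), within each breed's IHF group.
#'
#' qPCR contrasts are tested on delta-Ct values (target minus reference
#' gene); reported group means are fold changes relative to the
#' breed-matched control group (delta-delta-Ct method).  Every cell carries
#' mean, SEM, group sizes and the raw two-sided p-value; no multiplicity
#' correction is applied, which the report caveats state.  Contrasts with an
#' empty cell are reported with `NA` p-values, never dropped as errors.
#'
#' @param pheno A `phenotype_table` covering the experimental animals.
#' @param assignment A `breed_assignment` (or a tibble with `id`, `label`).
#'   `UNASSIGNED` animals are excluded and counted.
#' @param reference_gene Reference gene for delta-Ct normalisation.
#'   Default `"ACTB"`.
#' @param episode_min_s Strict AF episode duration threshold (s).  Default 10.
#' @param alpha Significance threshold used to flag rows.  Default 0.05.
#' @return A `stratified_report`: tibble with columns `section`,
#'   `comparison`, `variable`, `qualifier`, `group1`, `group2`, `n1`,
#'   `mean1`, `sem1`, `n2`, `mean2`, `sem2`, `test`, `estimate`, `p_value`,
#'   `significant`; attributes `caveats`, `n_unassigned`, `groups` (the four
#'   design cells with sizes), `alpha`.
#' @export
stratified_report <- function(pheno, assignment, reference_gene = "ACTB",
                              episode_min_s = 10, alpha = 0.05) {
  stopifnot(inherits(pheno, "phenotype_table"))
  breed_a <- attr(assignment, "breed_a") %||% "A"
  breed_b <- attr(assignment, "breed_b") %||% "B"
  lab <- tibble::as_tibble(assignment)[, c("id", "label")]
  missing_lab <- setdiff(unique(pheno$id), lab$id)
  if (length(missing_lab) > 0L) {
    stop("phenotype animals without a breed assignment: ",
         paste(utils::head(missing_lab, 5L), collapse = ", "))
  }
  n_unassigned <- sum(lab$label == "UNASSIGNED" & lab$id %in% pheno$id)
  pt <- dplyr::inner_join(tibble::as_tibble(pheno), lab, by = "id") |>
    dplyr::filter(.data$label != "UNASSIGNED") |>
    dplyr::mutate(breed = ifelse(.data$label == "A_DOMINANT", breed_a, breed_b))

  animals <- dplyr::distinct(pt, .data$id, .data$breed, .data$treatment)
  groups <- animals |>
    dplyr::count(.data$breed, .data$treatment, name = "n") |>
    dplyr::arrange(match(.data$breed, c(breed_a, breed_b)), .data$treatment)

  # ---- per-animal derived values -----------------------------------------
  simple <- pt |>
    dplyr::filter(.data$variable %in% c("ef", "lv_sys", "lvedp", "pcwp", "pa",
                                        "rv", "ra")) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .by = c("id", "breed", "treatment", "variable")) |>
    dplyr::mutate(qualifier = NA_character_)

  ep <- pt |>
    dplyr::filter(.data$variable %in% c("aerp", "averp", "snrt_bcl")) |>
    dplyr::mutate(value = .data$value,
                  qualifier = paste0(.data$cycle_length_ms, " ms")) |>
    dplyr::select("id", "breed", "treatment", "variable", "qualifier", "value")

  fib <- pt |>
    dplyr::filter(.data$variable == "fibrosis") |>
    dplyr::summarise(
      mean_fibrosis = mean(.data$value),
      fibrosis_difference = max(.data$value) - min(.data$value),
      .by = c("id", "breed", "treatment", "region")
    )
  fib_long <- dplyr::bind_rows(
    fib |> dplyr::transmute(.data$id, .data$breed, .data$treatment,
                            variable = "fibrosis_mean",
                            qualifier = .data$region,
                            value = .data$mean_fibrosis),
    fib |> dplyr::transmute(.data$id, .data$breed, .data$treatment,
                            variable = "fibrosis_difference",
                            qualifier = .data$region,
                            value = .data$fibrosis_difference)
  )

  # qPCR: delta-Ct per animal/gene/tissue; tests run on delta-Ct
  ct <- pt |> dplyr::filter(.data$variable == "ct")
  dct_long <- NULL
  if (nrow(ct) > 0L) {
    ref <- ct |>
      dplyr::filter(.data$gene == reference_gene) |>
      dplyr::select("id", "tissue", ref_ct = "value")
    dct_long <- ct |>
      dplyr::filter(.data$gene != reference_gene) |>
      dplyr::inner_join(ref, by = c("id", "tissue")) |>
      dplyr::mutate(variable = "expression",
                    qualifier = paste0(.data$gene, " (", .data$tissue, ")"),
                    value = .data$value - .data$ref_ct) |>
      dplyr::select("id", "breed", "treatment", "variable", "qualifier", "value")
  }

  continuous <- dplyr::bind_rows(simple, ep, fib_long, dct_long)

  # AF endpoints per animal
  af <- pt |> dplyr::filter(.data$variable == "af_episode_duration_s")
  af_tbl <- NULL
  if (nrow(af) > 0L) {
    af_tbl <- af |>
      dplyr::summarise(
        n_stimulations = dplyr::n(),
        n_inducing = sum(.data$value > episode_min_s),
        n_episodes = sum(.data$value > 0),
        .by = c("id", "breed", "treatment")
      ) |>
      dplyr::mutate(inducible = .data$n_inducing > 0L)
  }

  rows <- list()
  add <- function(section, comparison, variable, qualifier, g1, g2, cc) {
    rows[[length(rows) + 1L]] <<- dplyr::bind_cols(
      tibble::tibble(section = section, comparison = comparison,
                     variable = variable,
                     qualifier = qualifier %||% NA_character_,
                     group1 = g1, group2 = g2),
      cc
    )
  }

  contrast_set <- function(section, comparison, df1, df2, g1, g2) {
    vars <- dplyr::distinct(
      dplyr::bind_rows(df1, df2), .data$variable, .data$qualifier
    )
    for (r in seq_len(nrow(vars))) {
      vv <- vars$variable[r]; qq <- vars$qualifier[r]
      pick <- function(df) {
        df$value[df$variable == vv &
                   (is.na(qq) & is.na(df$qualifier) |
                      (!is.na(qq) & !is.na(df$qualifier) & df$qualifier == qq))]
      }
      v1 <- pick(df1); v2 <- pick(df2)
      cc <- contrast_continuous(v1, v2)
      if (vv == "expression") {
        # express group means as fold changes vs group2 (baseline) mean
        base <- mean(v2[!is.na(v2)])
        if (is.finite(base)) {
          cc$mean1 <- mean(2^(-(v1[!is.na(v1)] - base)))
          cc$sem1 <- sem(2^(-(v1[!is.na(v1)] - base)))
          cc$mean2 <- mean(2^(-(v2[!is.na(v2)] - base)))
          cc$sem2 <- sem(2^(-(v2[!is.na(v2)] - base)))
        }
      }
      add(section, comparison, vv, qq, g1, g2, cc)
    }
  }

  for (br in c(breed_a, breed_b)) {
    df_ihf <- continuous |> dplyr::filter(.data$breed == br, .data$treatment == "IHF")
    df_ctl <- continuous |> dplyr::filter(.data$breed == br, .data$treatment == "CONTROL")
    contrast_set("within-breed", paste0(br, ": IHF vs control"),
                 df_ihf, df_ctl, paste(br, "IHF"), paste(br, "control"))
  }
  df_a <- continuous |> dplyr::filter(.data$breed == breed_a, .data$treatment == "IHF")
  df_b <- continuous |> dplyr::filter(.data$breed == breed_b, .data$treatment == "IHF")
  contrast_set("cross-breed", paste0(breed_a, " IHF vs ", breed_b, " IHF"),
               df_a, df_b, paste(breed_a, "IHF"), paste(breed_b, "IHF"))

  if (!is.null(af_tbl)) {
    af_contrast <- function(section, comparison, s1, s2, g1, g2) {
      cc_animal <- contrast_binary(sum(s1$inducible), nrow(s1),
                                   sum(s2$inducible), nrow(s2))
      add(section, comparison, "af_inducible_animals", "per animal",
          g1, g2, cc_animal)
      cc_stim <- contrast_binary(sum(s1$n_inducing), sum(s1$n_stimulations),
                                 sum(s2$n_inducing), sum(s2$n_stimulations))
      add(section, comparison, "af_inducing_stimulations", "per stimulation",
          g1, g2, cc_stim)
    }
    for (br in c(breed_a, breed_b)) {
      s_ihf <- af_tbl |> dplyr::filter(.data$breed == br, .data$treatment == "IHF")
      s_ctl <- af_tbl |> dplyr::filter(.data$breed == br, .data$treatment == "CONTROL")
      if (nrow(s_ihf) > 0L && nrow(s_ctl) > 0L) {
        af_contrast("within-breed", paste0(br, ": IHF vs control"),
                    s_ihf, s_ctl, paste(br, "IHF"), paste(br, "control"))
      }
    }
    s_a <- af_tbl |> dplyr::filter(.data$breed == breed_a, .data$treatment == "IHF")
    s_b <- af_tbl |> dplyr::filter(.data$breed == breed_b, .data$treatment == "IHF")
    if (nrow(s_a) > 0L && nrow(s_b) > 0L) {
      af_contrast("cross-breed", paste0(breed_a, " IHF vs ", breed_b, " IHF"),
                  s_a, s_b, paste(breed_a, "IHF"), paste(breed_b, "IHF"))
    }

    # AF episode count vs fibrosis difference, per breed, IHF animals
    if (nrow(fib) > 0L) {
      ep_counts <- af_tbl |> dplyr::select("id", "breed", "treatment", "n_inducing")
      for (br in c(breed_a, breed_b)) {
        for (reg in sort(unique(fib$region))) {
          sub <- fib |>
            dplyr::filter(.data$breed == br, .data$treatment == "IHF",
                          .data$region == reg) |>
            dplyr::inner_join(ep_counts, by = c("id", "breed", "treatment"))
          cc <- tryCatch({
            res <- pearson_corr(sub$fibrosis_difference, sub$n_inducing)
            tibble::tibble(n1 = res$n1, mean1 = NA_real_, sem1 = NA_real_,
                           n2 = res$n2, mean2 = NA_real_, sem2 = NA_real_,
                           test = res$method, estimate = res$estimate,
                           p_value = res$p_value)
          }, error = function(e) {
            tibble::tibble(n1 = nrow(sub), mean1 = NA_real_, sem1 = NA_real_,
                           n2 = nrow(sub), mean2 = NA_real_, sem2 = NA_real_,
                           test = "Pearson correlation", estimate = NA_real_,
                           p_value = NA_real_)
          })
          add("correlation", paste0(br, " IHF"),
              "af_episodes_vs_fibrosis_difference", reg,
              paste(br, "IHF"), paste(br, "IHF"), cc)
        }
      }
    }
  }

  out <- dplyr::bind_rows(rows)
  if (!"estimate" %in% names(out)) out$estimate <- NA_real_
  out <- out |>
    dplyr::mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha)
  attr(out, "caveats") <- c(
    "Raw two-sided p-values; no correction for multiple comparisons was applied.",
    "Stimulation-level Fisher tests pool stimulations across animals and ignore within-animal clustering.",
    paste0("Significance threshold: p < ", alpha, ".")
  )
  attr(out, "n_unassigned") <- n_unassigned
  attr(out, "groups") <- groups
  attr(out, "alpha") <- alpha
  class(out) <- c("stratified_report", class(out))
  out
}

#' @export
print.stratified_report <- function(x, ...) {
  g <- attr(x, "groups")
  cat("Genotype-stratified phenotype report\n")
  cat("Groups:", paste(sprintf("%s %s (n = %d)", g$breed,
                               tolower(g$treatment), g$n), collapse = ", "), "\n")
  if (attr(x, "n_unassigned") > 0L) {
    cat("Excluded (unassigned background):", attr(x, "n_unassigned"), "\n")
  }
  for (cv in attr(x, "caveats")) cat("Note:", cv, "\n")
  cat("\n")
  df <- tibble::as_tibble(x) |>
    dplyr::mutate(
      cell1 = sprintf("%.3g +/- %.2g (n=%d)", .data$mean1, .data$sem1, .data$n1),
      cell2 = sprintf("%.3g +/- %.2g (n=%d)", .data$mean2, .data$sem2, .data$n2),
      p = ifelse(is.na(.data$p_value), "NA",
                 ifelse(.data$p_value < 0.001, "<0.001",
                        sprintf("%.3f", .data$p_value))),
      sig = ifelse(.data$significant, "*", "")
    )
  print(df[, c("comparison", "variable", "qualifier", "cell1", "cell2", "p", "sig")],
        n = Inf)
  invisible(x)
}

#' @method glance stratified_report
#' @export
glance.stratified_report <- function(x, ...) {
  tibble::tibble(
    n_contrasts = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_significant = sum(x$significant),
    n_unassigned = attr(x, "n_unassigned"),
    alpha = attr(x, "alpha")
  )
}

#' Write a stratified report
#'
#' Writes the machine-readable TSV and a human-readable text rendering with
#' group sizes and caveats in the header.
#'
#' @param report A `stratified_report`.
#' @param path Output TSV path; the text rendering goes to `path` with a
#'   `.txt` extension appended.
#' @return `path`, invisibly.
#' @export
write_stratified_report <- function(report, path) {
  readr::write_tsv(tibble::as_tibble(report), path)
  txt <- paste0(path, ".txt")
  con <- file(txt, open = "wt")
  on.exit(close(con))
  sink(con)
  print(report)
  sink()
  invisible(path)
}
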