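#' Configuration for a synthetic two-breed cohort
#'
#' Defines the study conditions the generator emulates: two founder breeds
#' diverged under a Balding-Nichols model, purebred reference panels, admixed
#' experimental animals in a breed-by-treatment design, and phenotypes whose
#' effects are restricted the way the stratified analysis expects (fibrosis
#' increase and profibrotic gene shifts in breed A under IHF, atrial ERP
#' shortening in breed B under IHF, AF inducibility elevated under IHF in
#' both breeds).
#'
#' Defaults mirror the study layout: 46,298 autosomal SNPs on 18
#' chromosomes with ~50 kb mean spacing, reference panels of 49 (breed A,
#' Pietrain) and 38 (breed B, German Landrace), and 40 experimental animals
#' in four cells — breed-A control (n = 10), breed-A IHF (n = 15), breed-B
#' control (n = 8), breed-B IHF (n = 7) — with admixture 0.8 / 0.2 toward
#' breed A.
#'
#' @param n_snps Number of autosomal SNPs.
#' @param n_chrom Number of chromosomes the SNPs are spread over.
#' @param mean_gap_bp Mean inter-marker gap (exponential), bp.
#' @param fst Balding-Nichols divergence parameter in (0, 1).
#' @param n_ref_a,n_ref_b Reference panel sizes.
#' @param design Tibble with columns `alpha` (admixture toward breed A),
#'   `treatment` (`CONTROL`/`IHF`) and `n` (animals per cell).
#' @param missing_rate Genotype missingness rate.
#' @param fibrosis_effect Breed-A-by-IHF fibrosis increase, percentage
#'   points on the per-animal mean.
#' @param fibrosis_sd,fibrosis_image_sd Between-animal and within-animal
#'   (per-image) fibrosis SDs, percentage points.
#' @param aerp_effect Breed-B-by-IHF AERP shortening, ms, applied at every
#'   drive cycle length.
#' @param af_rates Named per-stimulation AF induction probabilities for the
#'   four cells (`A_CONTROL`, `A_IHF`, `B_CONTROL`, `B_IHF`).
#' @param n_stimulations Burst stimulations per animal.
#' @param dct_shifts Tibble (`gene`, `tissue`, `breed` in `c("A","B")`,
#'   `shift`) of delta-Ct shifts applied to IHF animals; negative = higher
#'   expression.  `NULL` uses the built-in profile (see
#'   [default_dct_shifts()]).
#' @param ct_sd Per-measurement Ct noise SD (cycles).
#' @param seed Mandatory integer seed; the whole cohort is drawn from this
#'   single seeded generator.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_snps = 46298L,
                          n_chrom = 18L,
                          mean_gap_bp = 50000,
                          fst = 0.10,
                          n_ref_a = 49L,
                          n_ref_b = 38L,
                          design = tibble::tibble(
                            alpha = c(0.8, 0.8, 0.2, 0.2),
                            treatment = c("CONTROL", "IHF", "CONTROL", "IHF"),
                            n = c(10L, 15L, 8L, 7L)
                          ),
                          missing_rate = 0.01,
                          fibrosis_effect = 6,
                          fibrosis_sd = 2,
                          fibrosis_image_sd = 2,
                          aerp_effect = 40,
                          af_rates = c(A_CONTROL = 0.02, A_IHF = 0.32,
                                       B_CONTROL = 0.10, B_IHF = 0.30),
                          n_stimulations = 10L,
                          dct_shifts = NULL,
                          ct_sd = 0.5,
                          seed) {
  if (missing(seed)) stop("a seed is mandatory for the synthetic cohort")
  stopifnot(n_snps > 0L, n_chrom > 0L, mean_gap_bp > 0, fst > 0, fst < 1,
            n_ref_a > 0L, n_ref_b > 0L, missing_rate >= 0, missing_rate < 1,
            all(af_rates >= 0 & af_rates <= 1),
            all(design$alpha >= 0 & design$alpha <= 1), all(design$n > 0L),
            n_stimulations > 0L)
  if (is.null(dct_shifts)) dct_shifts <- default_dct_shifts()
  structure(
    list(n_snps = as.integer(n_snps), n_chrom = as.integer(n_chrom),
         mean_gap_bp = mean_gap_bp, fst = fst,
         n_ref_a = as.integer(n_ref_a), n_ref_b = as.integer(n_ref_b),
         design = design, missing_rate = missing_rate,
         fibrosis_effect = fibrosis_effect, fibrosis_sd = fibrosis_sd,
         fibrosis_image_sd = fibrosis_image_sd, aerp_effect = aerp_effect,
         af_rates = af_rates, n_stimulations = as.integer(n_stimulations),
         dct_shifts = dct_shifts, ct_sd = ct_sd, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Built-in delta-Ct shift profile
#'
#' IHF-only expression shifts (delta-Ct cycles; -1 means a 2-fold increase)
#' following the observed pattern: in breed A, FN and JNK1 up in the left
#' atrium with a smaller upward trend of ECM/profibrotic genes in the right
#' atrium; in breed B, MMP2/FSP1/TGFB/JNK1 down in the left atrium and
#' COL1A1/TGFB/JNK1 down in the right atrium.
#'
#' @return A tibble with columns `gene`, `tissue`, `breed`, `shift`.
#' @export
default_dct_shifts <- function() {
  dplyr::bind_rows(
    tibble::tibble(gene = c("FN", "JNK1"), tissue = "LA", breed = "A",
                   shift = -1),
    tibble::tibble(gene = c("FN", "MMP2", "CCN2", "TGFB", "JNK1"),
                   tissue = "RA", breed = "A", shift = -0.4),
    tibble::tibble(gene = c("MMP2", "FSP1", "TGFB", "JNK1"), tissue = "LA",
                   breed = "B", shift = 1),
    tibble::tibble(gene = c("COL1A1", "TGFB", "JNK1"), tissue = "RA",
                   breed = "B", shift = 1)
  )
}

qpcr_gene_panel <- function() {
  c("COL1A1", "FN", "MMP2", "ACTA2", "FSP1", "CCN2", "TGFB", "JNK1", "cJUN")
}

#' Simulate per-breed allele frequencies
#'
#' Balding-Nichols divergence: the ancestral frequency of each marker is
#' drawn from Uniform(0.1, 0.9), and each breed's frequency independently
#' from Beta(p(1-F)/F, (1-p)(1-F)/F), so F controls the expected
#' between-breed differentiation.  Draws come from the current RNG state;
#' seed via [simulate_cohort()] or `set.seed()`.
#'
#' @param cfg A `cohort_config`.
#' @return A tibble: `ancestral`, `freq_a`, `freq_b`, one row per marker.
#' @export
simulate_breed_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  m <- cfg$n_snps
  p <- stats::runif(m, 0.1, 0.9)
  shape <- (1 - cfg$fst) / cfg$fst
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  tibble::tibble(
    ancestral = p,
    freq_a = clamp(stats::rbeta(m, p * shape, (1 - p) * shape)),
    freq_b = clamp(stats::rbeta(m, p * shape, (1 - p) * shape))
  )
}

#' Simulate genotypes, map and panel labels
#'
#' Reference animals draw dosages Binomial(2, breed frequency) per marker.
#' An experimental animal with admixture `alpha` draws each of its two
#' allele copies as a Bernoulli trial on the mixture frequency
#' `alpha * freq_a + (1 - alpha) * freq_b` (allele-level admixture,
#' independent copies).  Marker positions are drawn per chromosome with
#' exponential gaps of the configured mean, then sorted; entries are masked
#' missing at the configured rate.
#'
#' @param freqs Output of [simulate_breed_frequencies()].
#' @param cfg The `cohort_config`.
#' @return A list: `genotypes`, `map`, `labels` (a `panel_labels`), `truth`
#'   (tibble of experimental ids with `alpha`, `breed`, `treatment`).
#' @export
simulate_genotypes <- function(freqs, cfg) {
  stopifnot(inherits(cfg, "cohort_config"), nrow(freqs) == cfg$n_snps)
  m <- cfg$n_snps
  per_chrom <- diff(round(seq(0, m, length.out = cfg$n_chrom + 1L)))
  map <- dplyr::bind_rows(lapply(seq_len(cfg$n_chrom), function(ch) {
    k <- per_chrom[ch]
    if (k == 0L) return(NULL)
    gaps <- pmax(1, round(stats::rexp(k, 1 / cfg$mean_gap_bp)))
    tibble::tibble(chrom = sprintf("%02d", ch), pos = as.integer(cumsum(gaps)))
  }))
  map$marker <- sprintf("snp%06d", seq_len(nrow(map)))
  map <- map[, c("marker", "chrom", "pos")]

  ids_a <- sprintf("PI_%02d", seq_len(cfg$n_ref_a))
  ids_b <- sprintf("LR_%02d", seq_len(cfg$n_ref_b))
  truth <- cfg$design |>
    tidyr::uncount(.data$n) |>
    dplyr::mutate(
      id = sprintf("EXP_%02d", dplyr::row_number()),
      breed = ifelse(.data$alpha >= 0.5, "A", "B")
    ) |>
    dplyr::select("id", "alpha", "breed", "treatment")
  n_exp <- nrow(truth)

  draw_panel <- function(n, fr) {
    matrix(stats::rbinom(n * length(fr), 2L, rep(fr, each = n)), nrow = n)
  }
  g_a <- draw_panel(cfg$n_ref_a, freqs$freq_a)
  g_b <- draw_panel(cfg$n_ref_b, freqs$freq_b)
  mix <- outer(truth$alpha, freqs$freq_a) +
    outer(1 - truth$alpha, freqs$freq_b)
  g_e <- matrix(stats::rbinom(n_exp * m, 2L, as.vector(mix)), nrow = n_exp)
  g <- rbind(g_a, g_b, g_e)
  rownames(g) <- c(ids_a, ids_b, truth$id)
  colnames(g) <- map$marker
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(g)) < cfg$missing_rate
    g[mask] <- NA_real_
  }
  list(
    genotypes = g,
    map = map,
    labels = panel_labels(ids_a, ids_b, truth$id),
    truth = truth
  )
}

#' Simulate the phenotype table
#'
#' Generates the long-format phenotype table for the experimental animals
#' given their (true majority) breed and treatment: ejection fraction and
#' pressures with an IHF effect in both breeds, AERP shortened by
#' `aerp_effect` ms at every drive cycle length in breed-B IHF animals only,
#' per-image atrial fibrosis raised by `fibrosis_effect` percentage points
#' in breed-A IHF animals only, per-stimulation AF induction as Bernoulli
#' draws at the cell rate (induced episodes last 15 s, i.e. past the 10-s
#' threshold; non-induced stimulations record 0), and qPCR Ct values with
#' the configured delta-Ct shifts plus a per-sample baseline shift common to
#' target and reference gene (which the delta-delta-Ct analysis cancels).
#'
#' @param truth Tibble with `id`, `breed` (`"A"`/`"B"`), `treatment`.
#' @param cfg The `cohort_config`.
#' @return A `phenotype_table`.
#' @export
simulate_phenotypes <- function(truth, cfg) {
  stopifnot(inherits(cfg, "cohort_config"),
            all(c("id", "breed", "treatment") %in% names(truth)))
  n <- nrow(truth)
  ihf <- truth$treatment == "IHF"
  a_ihf <- ihf & truth$breed == "A"
  b_ihf <- ihf & truth$breed == "B"
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  clamp01 <- function(x) pmin(pmax(x, 0), 100)

  wide <- function(variable, value, ...) {
    tibble::tibble(id = truth$id, treatment = truth$treatment,
                   variable = variable, value = value, ...)
  }
  add(wide("ef", clamp01(stats::rnorm(n, 60 - 25 * ihf, 5))))
  add(wide("lv_sys", stats::rnorm(n, 95, 8)))
  add(wide("lvedp", pmax(0, stats::rnorm(n, 8 + 8 * ihf, 3))))
  add(wide("pcwp", pmax(0, stats::rnorm(n, 8 + 6 * ihf, 3))))
  add(wide("pa", stats::rnorm(n, 22, 4)))
  add(wide("rv", stats::rnorm(n, 28, 4)))
  add(wide("ra", pmax(0, stats::rnorm(n, 5 + 3 * b_ihf, 2))))
  for (cl in c(500, 450, 400, 350, 300, 250)) {
    base <- 185 + (cl - 250) / 10
    add(wide("aerp", stats::rnorm(n, base - cfg$aerp_effect * b_ihf, 20),
             cycle_length_ms = cl))
    add(wide("averp", stats::rnorm(n, 170 + (cl - 250) / 5, 25),
             cycle_length_ms = cl))
  }
  for (cl in c(500, 450, 400)) {
    add(wide("snrt_bcl", pmax(50, stats::rnorm(n, 140, 25)),
             cycle_length_ms = cl))
  }
  for (region in c("LA", "RA")) {
    animal_mean <- stats::rnorm(n, 5 + cfg$fibrosis_effect * a_ihf,
                                cfg$fibrosis_sd)
    for (img in 1:10) {
      add(wide("fibrosis",
               clamp01(stats::rnorm(n, animal_mean, cfg$fibrosis_image_sd)),
               region = region, image = img))
    }
  }
  cell <- paste0(truth$breed, "_", truth$treatment)
  rate <- cfg$af_rates[cell]
  for (s in seq_len(cfg$n_stimulations)) {
    add(wide("af_episode_duration_s",
             15 * stats::rbinom(n, 1L, rate), stim = s))
  }
  shifts <- cfg$dct_shifts
  for (tis in c("LA", "RA")) {
    sample_shift <- stats::rnorm(n, 0, 1)   # common to all Cts of a sample
    add(wide("ct", 18 + sample_shift + stats::rnorm(n, 0, cfg$ct_sd),
             gene = "ACTB", tissue = tis))
    for (gn in qpcr_gene_panel()) {
      sh <- shifts$shift[shifts$gene == gn & shifts$tissue == tis]
      names(sh) <- shifts$breed[shifts$gene == gn & shifts$tissue == tis]
      eff <- ifelse(ihf, dplyr::coalesce(unname(sh[truth$breed]), 0), 0)
      add(wide("ct", 18 + sample_shift + 5 + eff +
                 stats::rnorm(n, 0, cfg$ct_sd),
               gene = gn, tissue = tis))
    }
  }
  phenotype_table(dplyr::bind_rows(rows))
}

#' Simulate a complete synthetic cohort
#'
#' Seeds the generator once from `cfg$seed` and draws, in order, breed
#' allele frequencies, genotypes/map/labels, and the phenotype table, so a
#' fixed seed yields a byte-identical cohort.
#'
#' @param cfg A `cohort_config`.
#' @return A list: `genotypes`, `map`, `labels`, `truth`, `phenotypes`,
#'   `frequencies`, `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  freqs <- simulate_breed_frequencies(cfg)
  geno <- simulate_genotypes(freqs, cfg)
  pheno <- simulate_phenotypes(geno$truth, cfg)
  list(genotypes = geno$genotypes, map = geno$map, labels = geno$labels,
       truth = geno$truth, phenotypes = pheno, frequencies = freqs,
       config = cfg)
}

#' Hudson-type Fst between the two reference panels
#'
#' Ratio-of-averages Hudson estimator on panel allele frequencies computed
#' from dosages, used as a diagnostic that the realised divergence of a
#' simulated (or real) pair of panels matches expectation.
#'
#' @param genotypes Dosage matrix containing both panels.
#' @param labels A `panel_labels`.
#' @return A single Fst estimate.
#' @export
hudson_fst <- function(genotypes, labels) {
  ids_a <- intersect(labels$id[labels$role == "REF_A"], rownames(genotypes))
  ids_b <- intersect(labels$id[labels$role == "REF_B"], rownames(genotypes))
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    stop("need at least 2 animals per panel")
  }
  pa <- colMeans(genotypes[ids_a, , drop = FALSE], na.rm = TRUE) / 2
  pb <- colMeans(genotypes[ids_b, , drop = FALSE], na.rm = TRUE) / 2
  na <- colSums(!is.na(genotypes[ids_a, , drop = FALSE])) * 2
  nb <- colSums(!is.na(genotypes[ids_b, , drop = FALSE])) * 2
  ok <- na > 1 & nb > 1 & !is.na(pa) & !is.na(pb)
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  sum(num[ok]) / sum(den[ok])
}
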