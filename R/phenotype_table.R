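#' Long-format phenotype table
#'
#' The phenotype table is a long tibble with one measurement per row, keyed
#' by animal id and treatment arm, with qualifier columns that are `NA`
#' where they do not apply:
#'
#' \describe{
#'   \item{`id`}{animal id}
#'   \item{`treatment`}{`CONTROL` or `IHF`}
#'   \item{`variable`}{measurement name, see below}
#'   \item{`cycle_length_ms`}{pacing drive cycle length for `aerp`, `averp`,
#'     `snrt_bcl`}
#'   \item{`region`}{`LA` or `RA` for `fibrosis`}
#'   \item{`image`}{image index within a region for `fibrosis`}
#'   \item{`gene`, `tissue`}{for `ct` rows (reference gene included)}
#'   \item{`stim`}{burst-stimulation index for `af_episode_duration_s`}
#'   \item{`value`}{the measurement}
#' }
#'
#' Recognised variables: `ef` (ejection fraction, %), pressures in mmHg
#' (`lv_sys`, `lvedp`, `pcwp`, `pa`, `rv`, `ra`), `aerp` / `averp` (ms) and
#' `snrt_bcl` (% of basic cycle length) at drive cycle lengths from
#' \{500, 450, 400, 350, 300, 250\} ms, `fibrosis` (% per image),
#' `af_episode_duration_s` (seconds per burst stimulation; 0 = no episode),
#' and `ct` (qPCR cycle threshold per gene per tissue).
#'
#' @param data A data frame with the columns above (missing qualifier
#'   columns are added as `NA`).
#' @return The validated tibble, classed `phenotype_table`.
#' @export
phenotype_table <- function(data) {
  needed <- c("id", "treatment", "variable", "value")
  if (!all(needed %in% names(data))) {
    stop("phenotype table needs columns: ", paste(needed, collapse = ", "))
  }
  quals <- c("cycle_length_ms", "region", "image", "gene", "tissue", "stim")
  for (q in quals) if (!q %in% names(data)) data[[q]] <- NA
  out <- tibble::as_tibble(data)[, c(needed[1:3], quals, "value")]
  validate_phenotype_table(out)
  class(out) <- c("phenotype_table", class(out))
  out
}

validate_phenotype_table <- function(pt) {
  bad_trt <- setdiff(unique(pt$treatment), c("CONTROL", "IHF"))
  if (length(bad_trt) > 0L) stop("unknown treatment label: ", bad_trt[1L])
  pct <- pt$value[pt$variable %in% c("ef", "fibrosis")]
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    stop("ef / fibrosis percentages must lie in [0, 100]")
  }
  dur <- pt$value[pt$variable == "af_episode_duration_s"]
  if (any(dur < 0, na.rm = TRUE)) stop("episode durations must be >= 0")
  ct <- pt$value[pt$variable == "ct"]
  if (any(ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  cl <- pt$cycle_length_ms[pt$variable %in% c("aerp", "averp", "snrt_bcl")]
  bad_cl <- setdiff(unique(cl[!is.na(cl)]), c(500, 450, 400, 350, 300, 250))
  if (length(bad_cl) > 0L) {
    stop("cycle length not in the fixed pacing set: ", bad_cl[1L])
  }
  invisible(pt)
}

#' Read / write a phenotype table
#'
#' @param path TSV path.
#' @return [read_phenotype_table()] returns a `phenotype_table`;
#'   [write_phenotype_table()] returns `path` invisibly.
#' @export
read_phenotype_table <- function(path) {
  phenotype_table(readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), treatment = readr::col_character(),
    variable = readr::col_character(), cycle_length_ms = readr::col_double(),
    region = readr::col_character(), image = readr::col_integer(),
    gene = readr::col_character(), tissue = readr::col_character(),
    stim = readr::col_integer(), value = readr::col_double()
  )))
}

#' @param pt A `phenotype_table`.
#' @rdname read_phenotype_table
#' @export
write_phenotype_table <- function(pt, path) {
  readr::write_tsv(tibble::as_tibble(pt), path)
  invisible(path)
}
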