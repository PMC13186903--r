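#' Read a genotype matrix and SNP map
#'
#' Reads allele-dosage genotypes and the accompanying marker map in one of two
#' text dialects and returns them ordered by genomic position.
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`"tsv"`}{Genotype file: header row of marker ids, first column
#'     `id`, cells coded `0`/`1`/`2`/`NA` (copies of the B allele).  Map file:
#'     TSV with columns `marker`, `chrom`, `pos`.}
#'   \item{`"plink_text"`}{PLINK text `.ped`/`.map`: the `.ped` is
#'     space-delimited with six leading columns (family id, animal id, father,
#'     mother, sex, phenotype) followed by two allele columns per marker, with
#'     `0` meaning a missing allele; the `.map` has columns chromosome,
#'     marker id, genetic position, base-pair position.}
#' }
#'
#' For `plink_text`, alleles are converted to dosages deterministically: at
#' each marker the B allele is the lexicographically larger allele observed,
#' and the dosage is the number of B-allele copies (0, 1 or 2).  A genotype
#' with either allele missing is coded `NA`.  The per-marker A/B alleles are
#' recorded in the returned map (`allele_a`, `allele_b`) so the coding is
#' reproducible and the file can be written back.
#'
#' @param genotype_path Path to the genotype file (`.ped` for `plink_text`).
#' @param map_path Path to the marker map (`.map` for `plink_text`).
#' @param dialect `"tsv"` or `"plink_text"`.
#' @return A list with elements `genotypes` (numeric matrix, animals x
#'   markers, row/column names set, entries 0/1/2/`NA`) and `map` (tibble with
#'   columns `marker`, `chrom`, `pos`, plus `allele_a`/`allele_b` for
#'   `plink_text`), columns ordered by (chromosome, position).
#' @examples
#' paths <- tempfile(c("g", "m"))
#' writeLines(c("id\tm1\tm2", "a1\t0\t2", "a2\t1\tNA"), paths[1])
#' writeLines(c("marker\tchrom\tpos", "m1\t1\t100", "m2\t1\t200"), paths[2])
#' g <- read_genotypes(paths[1], paths[2], dialect = "tsv")
#' g$genotypes
#' @export
read_genotypes <- function(genotype_path, map_path, dialect = c("tsv", "plink_text")) {
  dialect <- match.arg(dialect)
  if (!file.exists(genotype_path)) stop("genotype file not found: ", genotype_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  out <- switch(dialect,
    tsv = read_genotypes_tsv(genotype_path, map_path),
    plink_text = read_genotypes_ped(genotype_path, map_path)
  )
  validate_snp_map(out$map)
  validate_genotype_matrix(out$genotypes, out$map)
  out
}

read_genotypes_tsv <- function(genotype_path, map_path) {
  lines <- readLines(genotype_path)
  if (length(lines) < 2L) stop("genotype TSV needs a header and at least one animal row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- length(fields[[1L]])
  ragged <- which(lengths(fields) != n_col)
  if (length(ragged) > 0L) {
    stop("ragged row in ", genotype_path, " at line ", ragged[1L],
         ": expected ", n_col, " fields, found ", length(fields[[ragged[1L]]]))
  }
  markers <- fields[[1L]][-1L]
  if (anyDuplicated(markers)) {
    stop("duplicated marker id in genotype header: ",
         markers[duplicated(markers)][1L])
  }
  ids <- vapply(fields[-1L], `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) stop("duplicated animal id: ", ids[duplicated(ids)][1L])
  cells <- t(vapply(fields[-1L], function(f) f[-1L], character(length(markers))))
  if (length(markers) == 1L) cells <- matrix(cells, ncol = 1L)
  bad <- !(cells %in% c("0", "1", "2", "NA", ""))
  if (any(bad)) {
    stop("coding error: genotype cell '", cells[bad][1L],
         "' is not one of 0/1/2/NA")
  }
  g <- matrix(suppressWarnings(as.numeric(cells)), nrow = length(ids),
              dimnames = list(ids, markers))
  map <- readr::read_tsv(map_path, col_types = readr::cols(
    marker = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_integer()
  ))
  order_genotypes(g, map)
}

read_genotypes_ped <- function(ped_path, map_path) {
  map_raw <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map_raw) < 4L) stop("PLINK .map needs 4 columns (chrom, marker, cM, pos)")
  map <- tibble::tibble(
    marker = map_raw[[2L]],
    chrom = map_raw[[1L]],
    pos = as.integer(map_raw[[4L]])
  )
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty .ped file: ", ped_path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_expect <- 6L + 2L * m
  ragged <- which(lengths(fields) != n_expect)
  if (length(ragged) > 0L) {
    stop("ragged row in ", ped_path, " at line ", ragged[1L], ": expected ",
         n_expect, " fields, found ", length(fields[[ragged[1L]]]))
  }
  ids <- vapply(fields, `[[`, character(1L), 2L)
  if (anyDuplicated(ids)) stop("duplicated animal id: ", ids[duplicated(ids)][1L])
  allele_block <- t(vapply(fields, function(f) f[-(1:6)], character(2L * m)))
  if (m * 2L == 1L) allele_block <- matrix(allele_block, ncol = 1L)
  a1 <- allele_block[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- allele_block[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  g <- matrix(NA_real_, nrow = length(ids), ncol = m, dimnames = list(ids, map$marker))
  allele_a <- allele_b <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(unique(obs[obs != "0"]))
    if (any(nchar(alleles) != 1L | !grepl("^[A-Za-z]$", alleles))) {
      stop("coding error at marker ", map$marker[j], ": unknown allele symbol '",
           alleles[nchar(alleles) != 1L | !grepl("^[A-Za-z]$", alleles)][1L], "'")
    }
    if (length(alleles) > 2L) {
      stop("coding error at marker ", map$marker[j], ": more than 2 alleles observed")
    }
    if (length(alleles) == 0L) next  # fully missing marker; stays NA
    b <- alleles[length(alleles)]                 # lexicographically larger
    a <- if (length(alleles) == 2L) alleles[1L] else alleles[1L]
    allele_a[j] <- a
    allele_b[j] <- b
    miss <- a1[, j] == "0" | a2[, j] == "0"
    g[, j] <- (a1[, j] == b) + (a2[, j] == b)
    g[miss, j] <- NA_real_
  }
  if (anyDuplicated(map$marker)) {
    stop("duplicated marker id in map: ", map$marker[duplicated(map$marker)][1L])
  }
  map$allele_a <- allele_a
  map$allele_b <- allele_b
  order_genotypes(g, map)
}

order_genotypes <- function(g, map) {
  if (anyDuplicated(map$marker)) {
    stop("duplicated marker id in map: ", map$marker[duplicated(map$marker)][1L])
  }
  if (!setequal(colnames(g), map$marker)) {
    stop("genotype columns and map markers disagree")
  }
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  list(genotypes = g[, map$marker, drop = FALSE], map = map)
}

validate_snp_map <- function(map) {
  stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
  if (any(map$pos < 1L, na.rm = TRUE)) stop("map positions must be positive (1-based)")
  dup <- map |>
    dplyr::summarise(d = anyDuplicated(.data$pos) > 0L, .by = "chrom") |>
    dplyr::filter(.data$d)
  if (nrow(dup) > 0L) {
    stop("duplicate positions on chromosome ", dup$chrom[1L])
  }
  invisible(map)
}

validate_genotype_matrix <- function(g, map) {
  if (ncol(g) != nrow(map)) stop("genotype columns != map length")
  vals <- g[!is.na(g)]
  if (!all(vals %in% c(0, 1, 2))) stop("genotype entries must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(g))) stop("animal ids not unique")
  invisible(g)
}

#' Write genotypes back to disk
#'
#' Inverse of [read_genotypes()]: writes the genotype matrix and map in the
#' requested dialect so that reading the files back reproduces the input.
#' For `plink_text` the map must carry `allele_a`/`allele_b` columns (as
#' produced by reading a `.ped`, or supplied by the caller); dosage d is
#' expanded to d copies of the B allele and 2-d copies of the A allele.
#'
#' @param genotypes Animals x markers dosage matrix.
#' @param map SNP map tibble matching the matrix columns.
#' @param genotype_path,map_path Output paths.
#' @param dialect `"tsv"` or `"plink_text"`.
#' @return The genotype path, invisibly.
#' @export
write_genotypes <- function(genotypes, map, genotype_path, map_path,
                            dialect = c("tsv", "plink_text")) {
  dialect <- match.arg(dialect)
  validate_genotype_matrix(genotypes, map)
  if (dialect == "tsv") {
    cells <- ifelse(is.na(genotypes), "NA", as.character(genotypes))
    lines <- c(
      paste(c("id", colnames(genotypes)), collapse = "\t"),
      vapply(seq_len(nrow(genotypes)), function(i) {
        paste(c(rownames(genotypes)[i], cells[i, ]), collapse = "\t")
      }, character(1L))
    )
    writeLines(lines, genotype_path)
    readr::write_tsv(map[, c("marker", "chrom", "pos")], map_path)
  } else {
    if (!all(c("allele_a", "allele_b") %in% names(map))) {
      stop("plink_text output needs allele_a/allele_b columns in the map")
    }
    a <- ifelse(is.na(map$allele_a), "0", map$allele_a)
    b <- ifelse(is.na(map$allele_b), "0", map$allele_b)
    rows <- vapply(seq_len(nrow(genotypes)), function(i) {
      d <- genotypes[i, ]
      first <- ifelse(is.na(d), "0", ifelse(d >= 1, b, a))
      second <- ifelse(is.na(d), "0", ifelse(d == 2, b, a))
      paste(c(rownames(genotypes)[i], rownames(genotypes)[i], "0", "0", "0", "-9",
              as.vector(rbind(first, second))), collapse = " ")
    }, character(1L))
    writeLines(rows, genotype_path)
    writeLines(paste(map$chrom, map$marker, 0, map$pos), map_path)
  }
  invisible(genotype_path)
}

#' Filter to informative SNPs
#'
#' Applies the array-QC filter that defines the "informative" marker set:
#' minor-allele frequency and call rate are computed over all animals and
#' markers failing either threshold are dropped.  The filter is idempotent.
#'
#' @param genotypes Animals x markers dosage matrix (0/1/2/`NA`).
#' @param map Matching SNP map tibble.
#' @param maf_min Minimum minor-allele frequency, in `[0, 0.5)`.  Default 0.01.
#' @param call_rate_min Minimum per-marker call rate, in `(0, 1]`.  Default 0.90.
#' @return A list with `genotypes` and `map` restricted to retained markers and
#'   `report`, a tibble counting markers removed per criterion (a marker
#'   failing both is counted under both; `n_removed` counts it once).
#' @export
filter_informative <- function(genotypes, map, maf_min = 0.01, call_rate_min = 0.90) {
  stopifnot(maf_min >= 0, maf_min < 0.5, call_rate_min > 0, call_rate_min <= 1)
  validate_genotype_matrix(genotypes, map)
  call_rate <- colMeans(!is.na(genotypes))
  f_b <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(f_b, 1 - f_b)
  maf[is.nan(maf)] <- 0  # fully missing marker: uninformative
  fail_cr <- call_rate < call_rate_min
  fail_maf <- maf < maf_min
  keep <- !(fail_cr | fail_maf)
  if (!any(keep)) {
    stop("all ", ncol(genotypes), " markers removed by the informative-SNP ",
         "filter; lower maf_min (", maf_min, ") or call_rate_min (",
         call_rate_min, ")")
  }
  report <- tibble::tibble(
    n_input = ncol(genotypes),
    n_retained = sum(keep),
    n_removed = sum(!keep),
    n_low_maf = sum(fail_maf),
    n_low_call_rate = sum(fail_cr),
    maf_min = maf_min,
    call_rate_min = call_rate_min
  )
  list(
    genotypes = genotypes[, keep, drop = FALSE],
    map = map[keep, , drop = FALSE],
    report = report
  )
}

#' Write and read a labelled distance matrix
#'
#' The on-disk format is a square tab-separated matrix with animal ids as the
#' header and first column; values are printed with enough digits that a
#' read-back reproduces them to at least 12 decimal places.
#'
#' @param dm Symmetric numeric matrix with identical row/column names, or an
#'   `asd_dist` object (its distance component is written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  if (inherits(dm, "asd_dist")) dm <- dm$distance
  if (!is.matrix(dm) || nrow(dm) == 0L) stop("empty or invalid distance matrix")
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (is.null(rownames(dm)) || is.null(colnames(dm))) stop("distance matrix must be labelled")
  lines <- c(
    paste(c("id", colnames(dm)), collapse = "\t"),
    vapply(seq_len(nrow(dm)), function(i) {
      paste(c(rownames(dm)[i], sprintf("%.15g", dm[i, ])), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                         check.names = FALSE)
  as.matrix(x)
}

#' Construct or read reference-panel labels
#'
#' Panel labels attach a role to each animal: member of reference panel A,
#' member of reference panel B, or experimental animal to be assigned.  Breed
#' names (e.g. Pietrain / German Landrace) ride along as attributes used in
#' reports and plots.
#'
#' @param ref_a,ref_b,experimental Character vectors of animal ids.
#' @param breed_a,breed_b Display names for the two reference breeds.
#' @return A tibble with columns `id` and `role` (one of `REF_A`, `REF_B`,
#'   `EXPERIMENTAL`), classed `panel_labels`, with `breed_a`/`breed_b`
#'   attributes.
#' @export
panel_labels <- function(ref_a, ref_b, experimental,
                         breed_a = "Pietrain", breed_b = "Landrace") {
  ids <- c(ref_a, ref_b, experimental)
  if (anyDuplicated(ids)) stop("an animal id appears in more than one role")
  out <- tibble::tibble(
    id = ids,
    role = rep(c("REF_A", "REF_B", "EXPERIMENTAL"),
               c(length(ref_a), length(ref_b), length(experimental)))
  )
  attr(out, "breed_a") <- breed_a
  attr(out, "breed_b") <- breed_b
  class(out) <- c("panel_labels", class(out))
  out
}

#' @param path Two-column TSV (`id`, `role`) to read labels from.
#' @rdname panel_labels
#' @export
read_panel_labels <- function(path, breed_a = "Pietrain", breed_b = "Landrace") {
  x <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), role = readr::col_character()
  ))
  bad <- setdiff(unique(x$role), c("REF_A", "REF_B", "EXPERIMENTAL"))
  if (length(bad) > 0L) stop("unknown panel role: ", bad[1L])
  panel_labels(
    ref_a = x$id[x$role == "REF_A"],
    ref_b = x$id[x$role == "REF_B"],
    experimental = x$id[x$role == "EXPERIMENTAL"],
    breed_a = breed_a, breed_b = breed_b
  )
}
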