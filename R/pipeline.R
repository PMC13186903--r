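#' Configure a stratification pipeline run
#'
#' Exactly one input source must be given: either a synthetic
#' [cohort_config()] or paths to real genotype/map/panel/phenotype files.
#'
#' @param synthetic A `cohort_config`, or `NULL` when reading real files.
#' @param genotype_path,map_path,panel_path,phenotype_path Input files for a
#'   real-data run (`dialect` selects the genotype format).
#' @param dialect Genotype dialect for real input, `"tsv"` or `"plink_text"`.
#' @param out_dir Output directory (created if needed).
#' @param maf_min,call_rate_min Informative-SNP filter thresholds.
#' @param block_size,max_span_bp,max_gap_bp Haplotype-block parameters.
#' @param min_valid_fraction Minimum per-pair usable-block fraction.
#' @param tie_band Breed-assignment tie band.
#' @param episode_min_s AF episode duration threshold (s).
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = NULL,
                       genotype_path = NULL, map_path = NULL,
                       panel_path = NULL, phenotype_path = NULL,
                       dialect = "tsv",
                       out_dir,
                       maf_min = 0.01, call_rate_min = 0.90,
                       block_size = 4L, max_span_bp = 150000L,
                       max_gap_bp = 50000L,
                       min_valid_fraction = 0.5,
                       tie_band = 0,
                       episode_min_s = 10) {
  real <- !is.null(genotype_path) || !is.null(map_path) ||
    !is.null(panel_path) || !is.null(phenotype_path)
  if (is.null(synthetic) && !real) {
    stop("provide either a synthetic cohort_config or input paths")
  }
  if (!is.null(synthetic) && real) {
    stop("provide exactly one of: synthetic config, real input paths")
  }
  if (real && (is.null(genotype_path) || is.null(map_path) ||
               is.null(panel_path) || is.null(phenotype_path))) {
    stop("a real-data run needs genotype, map, panel and phenotype paths")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "cohort_config"))
  structure(
    list(synthetic = synthetic, genotype_path = genotype_path,
         map_path = map_path, panel_path = panel_path,
         phenotype_path = phenotype_path, dialect = dialect,
         out_dir = out_dir, maf_min = maf_min,
         call_rate_min = call_rate_min, block_size = as.integer(block_size),
         max_span_bp = max_span_bp, max_gap_bp = max_gap_bp,
         min_valid_fraction = min_valid_fraction, tie_band = tie_band,
         episode_min_s = episode_min_s),
    class = "run_config"
  )
}

#' Run the full stratification pipeline
#'
#' Chains the stages end to end and writes every artifact as plain text to
#' the configured output directory, in order: the informative-SNP filter
#' report, the block partition (BED) with coverage statistics, the
#' allele-sharing distance matrix with per-pair valid-block fractions, the
#' MDS embedding, the UPGMA tree (Newick), the breed assignment, and the
#' stratified phenotype report.  A `manifest.json` records the
#' configuration, the seed, and an MD5 content hash of every artifact, so
#' reruns with the same configuration and seed are verifiably byte-identical.
#' A failing stage writes a `FAILED` marker naming the stage and rethrows;
#' artifacts already written are retained.
#'
#' @param config A `run_config`.
#' @return A list with the in-memory results (`filter_report`, `partition`,
#'   `coverage`, `asd`, `mds`, `tree`, `assignment`, `report`, `manifest`),
#'   invisibly usable for further analysis.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir, c(
    filter_report = "filter_report.tsv", blocks = "blocks.bed",
    coverage = "block_coverage.json", distance = "distance_matrix.tsv",
    valid = "valid_block_fractions.tsv", embedding = "embedding.tsv",
    tree = "tree.nwk", assignment = "assignment.tsv",
    report = "stratified_report.tsv", manifest = "manifest.json"
  ))
  names(paths) <- c("filter_report", "blocks", "coverage", "distance",
                    "valid", "embedding", "tree", "assignment", "report",
                    "manifest")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  failed_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)

  inputs <- stage("input", {
    if (!is.null(config$synthetic)) {
      simulate_cohort(config$synthetic)
    } else {
      gm <- read_genotypes(config$genotype_path, config$map_path,
                           dialect = config$dialect)
      list(genotypes = gm$genotypes, map = gm$map,
           labels = read_panel_labels(config$panel_path),
           phenotypes = read_phenotype_table(config$phenotype_path))
    }
  })

  filtered <- stage("filter", {
    res <- filter_informative(inputs$genotypes, inputs$map,
                              maf_min = config$maf_min,
                              call_rate_min = config$call_rate_min)
    readr::write_tsv(res$report, paths[["filter_report"]])
    res
  })

  partition <- stage("blocks", {
    bp <- partition_blocks(filtered$map, block_size = config$block_size,
                           max_span_bp = config$max_span_bp,
                           max_gap_bp = config$max_gap_bp)
    blocks_to_bed(bp, paths[["blocks"]])
    bp
  })
  coverage <- stage("blocks", {
    cov <- block_coverage_stats(partition, filtered$map)
    jsonlite::write_json(cov, paths[["coverage"]], auto_unbox = TRUE,
                         digits = NA)
    cov
  })

  dm <- stage("asd", {
    dm <- asd_matrix(filtered$genotypes, partition,
                     min_valid_fraction = config$min_valid_fraction)
    write_distance_matrix(dm$distance, paths[["distance"]])
    write_distance_matrix(dm$valid_block_fraction, paths[["valid"]])
    dm
  })

  mds <- stage("mds", {
    emb <- classical_mds(dm, dims = 2L, labels = inputs$labels)
    readr::write_tsv(emb$coordinates, paths[["embedding"]])
    emb
  })

  tree <- stage("upgma", {
    tr <- upgma(dm)
    write_newick(tr, paths[["tree"]])
    tr
  })

  assignment <- stage("assign", {
    ba <- assign_breed(dm, inputs$labels, tie_band = config$tie_band)
    readr::write_tsv(tibble::as_tibble(ba), paths[["assignment"]])
    ba
  })

  report <- stage("stats", {
    rep <- stratified_report(inputs$phenotypes, assignment,
                             episode_min_s = config$episode_min_s)
    write_stratified_report(rep, paths[["report"]])
    rep
  })

  manifest <- stage("manifest", {
    artifact_paths <- paths[names(paths) != "manifest"]
    artifact_paths <- c(artifact_paths, report_txt = paste0(paths[["report"]], ".txt"))
    hashes <- tools::md5sum(sort(unname(artifact_paths)))
    names(hashes) <- basename(names(hashes))
    cfg_json <- unclass(config)
    cfg_json$out_dir <- NULL   # location is not part of the run's identity
    cfg_json$synthetic <- if (!is.null(config$synthetic)) {
      unclass(config$synthetic)
    }
    man <- list(
      config = cfg_json,
      seed = if (!is.null(config$synthetic)) config$synthetic$seed else NA,
      artifacts = as.list(hashes)
    )
    jsonlite::write_json(man, paths[["manifest"]], auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    man
  })

  invisible(list(inputs = inputs, filter_report = filtered$report,
                 partition = partition, coverage = coverage, asd = dm,
                 mds = mds, tree = tree, assignment = assignment,
                 report = report, manifest = manifest, paths = paths))
}
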