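#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end run: input paths (or simulation
#' sizes when no inputs are given), mass-matching settings, the spatial
#' co-localization threshold, the enrichment test and adjustment, and the
#' single random seed that drives every stochastic step.
#'
#' @param out_dir Output directory (created if missing).
#' @param compositions Optional CSV/TSV path with a `composition` column;
#'   when `NULL`, a synthetic table of `n_glycans` rows is generated.
#' @param peaks Optional CSV/TSV path with an `mz` column; when given, peaks
#'   are matched against the composition table.
#' @param assignments Optional CSV/TSV path with `glycan`, `composition`,
#'   `region` columns; when `NULL`, a toy spatial experiment (masks + ion
#'   images) is simulated and regions are recovered by co-localization.
#' @param n_glycans Number of synthetic glycans when simulating.
#' @param class_mix Target class proportions for the synthetic table; the
#'   default mirrors a lung-like profile dominated by complex fucosylated
#'   species with a substantial high-mannose component.
#' @param regions Region names for the simulated spatial experiment.
#' @param adducts Adduct symbols for mass matching.
#' @param tol_ppm Match tolerance in ppm.
#' @param threshold Co-localization assignment threshold in `(0, 1]`.
#' @param noise_sd Ion-image noise level for the simulated spatial path.
#' @param enrichment_test Test feeding the reported q-values.
#' @param adjust Multiple-testing adjustment.
#' @param seed Integer seed; every stochastic stage derives from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            compositions = NULL,
                            peaks = NULL,
                            assignments = NULL,
                            n_glycans = 60,
                            class_mix = c(HIGH_MANNOSE = 0.15,
                                          PAUCI_MANNOSE = 0.05,
                                          HYBRID = 0.10,
                                          COMPLEX = 0.20,
                                          FUCOSYLATED = 0.20,
                                          MULTI_FUCOSYLATED = 0.10,
                                          SIALYLATED = 0.10,
                                          TETRA_ANTENNARY = 0.10),
                            regions = c("adventitia", "submucosal_gland",
                                        "cartilage", "parenchyma"),
                            adducts = "Na",
                            tol_ppm = 2,
                            threshold = 0.5,
                            noise_sd = 0.05,
                            enrichment_test = c("fisher", "ease", "binomial"),
                            adjust = c("BH", "bonferroni"),
                            seed = 1L) {
  cfg <- list(
    out_dir = out_dir, compositions = compositions, peaks = peaks,
    assignments = assignments, n_glycans = n_glycans, class_mix = class_mix,
    regions = regions, adducts = adducts, tol_ppm = tol_ppm,
    threshold = threshold, noise_sd = noise_sd,
    enrichment_test = match.arg(enrichment_test),
    adjust = match.arg(adjust), seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from JSON or YAML
#'
#' @param path Path to a `.json` or `.yml`/`.yaml` file whose keys match the
#'   arguments of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$class_mix)) raw$class_mix <- unlist(raw$class_mix)
  do.call(pipeline_config, raw)
}

#' Run the full mining pipeline
#'
#' Executes the stages of a compositional glycomics analysis in order:
#' obtain a composition table (read or simulate), optionally match an
#' observed peak list, classify every composition, assign glycans to regions
#' (from a provided table or a simulated spatial experiment), summarize
#' classes per region, and test each region's glycan set for term
#' enrichment. Writes tidy CSV outputs plus a JSON run manifest to
#' `config$out_dir`. A failure in any stage removes the partial outputs and
#' aborts with a stage-named message. Reruns under the same seed produce
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()] or path readable by
#'   [read_pipeline_config()].
#' @return (Invisibly) a named list of the written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config or a path to one")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    .write_csv(df, p)
    written <<- c(written, p)
    p
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      unlink(written)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  comp_tab <- stage("compositions", {
    if (is.null(config$compositions)) {
      generate_fixture_compositions(config$n_glycans, config$class_mix,
                                    seed = config$seed)
    } else {
      read_glycan_table(config$compositions)
    }
  })
  emit(comp_tab, "compositions.csv")

  if (!is.null(config$peaks)) {
    stage("match", {
      pk <- read_glycan_table_peaks(config$peaks)
      matches <- match_mz(pk$mz, as.list(unique(comp_tab$composition)),
                          adducts = config$adducts, tol_ppm = config$tol_ppm)
      emit(matches, "matches.csv")
    })
  }

  classes <- stage("classify", {
    cbind(glycan = comp_tab$glycan,
          classify_compositions(comp_tab$composition))
  })
  emit(classes, "classes.csv")

  assignment <- stage("regions", {
    if (!is.null(config$assignments)) {
      df <- read_glycan_table(config$assignments)
      region_assignment(df)
    } else {
      # simulated spatial experiment: intend 1-2 regions per glycan, render
      # noisy ion images, then recover membership by co-localization
      intended <- .with_seed(config$seed + 1L, {
        do.call(rbind, lapply(comp_tab$glycan, function(g) {
          k <- sample(1:2, 1)
          data.frame(glycan = g,
                     region = sample(config$regions, k),
                     stringsAsFactors = FALSE)
        }))
      })
      masks <- make_region_masks(regions = config$regions)
      imgs <- generate_fixture_images(masks, intended,
                                      noise_sd = config$noise_sd,
                                      seed = config$seed + 2L)
      compositions <- structure(comp_tab$composition, names = comp_tab$glycan)
      assign_regions(imgs, masks, threshold = config$threshold,
                     compositions = compositions)
    }
  })
  emit(as.data.frame(assignment), "region_assignments.csv")

  summary <- stage("summarize", summarize_regions(assignment))
  emit(summary$counts, "region_summary.csv")
  emit(summary$totals, "region_totals.csv")

  enr <- stage("enrich", {
    comps <- structure(as.list(comp_tab$composition), names = comp_tab$glycan)
    ont <- ontology_terms(comps)
    universe <- comp_tab$glycan
    per_region <- lapply(sort(unique(as.character(assignment$region))),
                         function(r) {
      q <- unique(assignment$glycan[assignment$region == r])
      if (length(q) == 0) return(NULL)
      res <- term_enrichment(q, universe, ont$index,
                             adjust = config$adjust,
                             adjust_test = config$enrichment_test)
      cbind(region = r, res)
    })
    do.call(rbind, per_region)
  })
  emit(enr, "enrichment.csv")

  manifest <- list(
    package = "glycomine",
    version = as.character(utils::packageVersion("glycomine")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "out_dir")],
    outputs = basename(written)
  )
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  written <- c(written, mpath)
  invisible(structure(as.list(written), names = basename(written)))
}

# peak lists share the delimited reader but require an mz column
read_glycan_table_peaks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"mz" %in% names(df)) stop("missing required column 'mz' in ", path)
  df
}
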