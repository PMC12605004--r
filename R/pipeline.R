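#' Load and validate a pipeline configuration
#'
#' @param config a YAML file path or an already-parsed list. Recognized
#'   top-level keys: `seed`, `output_dir`, `stages` (subset of simulate,
#'   preprocess, differential, correlate, enrich, network, diffuse, classify,
#'   cohort_table), `simulate` (arguments for [synthetic_config()]),
#'   `inputs` (paths: proteins, metabolites, metadata, annotations),
#'   `preprocess` (log_transform, max_missing_frac, na_tokens), and
#'   per-stage parameter blocks (`differential`, `correlate`, `enrich`,
#'   `network`, `diffuse`, `classify`).
#' @return validated config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("simulate", "preprocess", "differential", "correlate", "enrich",
             "network", "diffuse", "classify", "cohort_table")
  if (is.null(config$stages)) stop("config must list `stages`")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$output_dir)) stop("config must set `output_dir`")
  if (!"simulate" %in% config$stages && is.null(config$inputs)) {
    stop("config needs either a `simulate` stanza in stages or `inputs` paths")
  }
  config
}

.prov_header <- function(config, stage) {
  sprintf("# omninet %s | stage=%s | seed=%s | config_sha=%s",
          as.character(utils::packageVersion("omninet")), stage, config$seed,
          substr(digest_config(config), 1, 12))
}

#' Stable hash of a configuration (for provenance headers)
#' @param config list.
#' @return character sha-like hash (serialization-based).
#' @export
digest_config <- function(config) {
  config$output_dir <- NULL  # hash the analysis choices, not the disk layout
  raw <- as.integer(serialize(config, NULL, version = 2))
  # two rolling polynomial hashes over the serialized payload; no external
  # digest dependency, exact in double arithmetic
  h1 <- 0; h2 <- 0
  for (b in raw) {
    h1 <- (h1 * 31 + b) %% 16777213
    h2 <- (h2 * 131 + b) %% 16777199
  }
  sprintf("%06x%06x%06x", h1, h2, length(raw) %% 16777216)
}

.write_stage_tsv <- function(df, path, config, stage) {
  con <- file(path, "w")
  writeLines(.prov_header(config, stage), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the pipeline stages of a configuration
#'
#' Stages run in dependency order: a data stage (`simulate`, or `preprocess`
#' over the `inputs` paths) feeds every analysis stage; `diffuse` requires
#' `network`. A missing upstream stage is an error naming the stage to run
#' first. Every output file starts with a provenance header (package
#' version, stage, seed, config hash) and a manifest JSON records the config
#' echo, seeds and outputs. Identical config + seed reruns are idempotent
#' (manifests byte-identical modulo the timestamp field).
#'
#' @param config YAML path or list (see [pipeline_config()]).
#' @return invisibly, the in-memory state (data, results, output paths).
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  st <- list(outputs = list())
  need <- function(what, stage, provider) {
    if (is.null(st[[what]])) {
      stop("stage '", stage, "' needs output of stage '", provider,
           "'; run it first")
    }
  }
  order_ <- c("simulate", "preprocess", "differential", "correlate", "enrich",
              "network", "diffuse", "classify", "cohort_table")
  stages <- config$stages
  # simulate feeds preprocess with in-memory raw blocks
  if ("simulate" %in% stages) stages <- union(stages, "preprocess")
  for (stage in intersect(order_, stages)) {
    st <- switch(stage,
      simulate = {
        args <- config$simulate %||% list()
        if (!is.null(args$planted)) {
          args$planted <- as.data.frame(lapply(args$planted, unlist),
                                        stringsAsFactors = FALSE)
        }
        args$seed <- args$seed %||% config$seed
        cohort <- generate_cohort(do.call(synthetic_config, args))
        paths <- write_cohort(cohort, file.path(config$output_dir, "cohort"))
        st$raw <- cohort; st$outputs$simulate <- unlist(paths)
        st
      },
      preprocess = {
        pp <- config$preprocess %||% list()
        if (is.null(st$raw)) {
          inp <- config$inputs
          st$raw <- list(
            proteins = load_feature_table(
              inp$proteins, "protein",
              exclusion_list = inp$exclusion_list,
              na_tokens = pp$na_tokens %||% c("", "NA", "NaN", "nan")),
            metabolites = load_feature_table(
              inp$metabolites, "metabolite",
              na_tokens = pp$na_tokens %||% c("", "NA", "NaN", "nan")),
            meta = load_sample_metadata(inp$metadata))
        }
        met <- scale_and_impute(
          filter_by_missingness(st$raw$metabolites,
                                max_frac = pp$max_missing_frac %||% 0.20))
        prot <- st$raw$proteins
        if (isTRUE(pp$log_transform %||% TRUE)) {
          prot <- log_transform(prot)
          met$log_transformed <- TRUE  # keep blocks mergeable; metabolites stay on the scaled-imputed scale
        }
        st$data <- merge_omics(prot, met)
        st$meta <- st$raw$meta
        st$outputs$preprocess <- .write_stage_tsv(
          data.frame(sample_id = sample_ids(st$data), st$data$values,
                     check.names = FALSE),
          file.path(config$output_dir, "preprocessed.tsv"), config, stage)
        st
      },
      differential = {
        need("data", stage, "preprocess")
        a <- config$differential %||% list()
        comps <- a$comparison %||% c("ACPA_NEG_vs_CTRL", "ACPA_POS_vs_CTRL")
        res <- do.call(rbind, lapply(comps, function(cm) {
          differential_features(st$data, st$meta, cm,
                                p_thr = a$p %||% 0.01, d_thr = a$d %||% 0.5)
        }))
        st$differential <- res
        st$outputs$differential <- .write_stage_tsv(
          res, file.path(config$output_dir, "differential.tsv"), config, stage)
        st
      },
      correlate = {
        need("data", stage, "preprocess")
        a <- config$correlate %||% list()
        res <- do.call(rbind, lapply(a$markers %||% c("esr", "crp", "das28crp"),
                                     function(mk) {
          spearman_by_subgroup(st$data, st$meta, mk)
        }))
        st$correlate <- res
        st$outputs$correlate <- .write_stage_tsv(
          res, file.path(config$output_dir, "correlations.tsv"), config, stage)
        st
      },
      enrich = {
        need("differential", stage, "differential")
        a <- config$enrich %||% list()
        ann <- if (!is.null(config$inputs$annotations)) {
          read_annotations(config$inputs$annotations, feature_ids(st$data))
        } else pathway_annotations(st$data, a$level %||% "sub_pathway")
        hits <- st$differential$feature_id[st$differential$passes_relaxed]
        res <- fisher_enrichment(unique(hits), ann, mode = a$mode %||% "standard",
                                 alpha = a$alpha %||% 0.05)
        st$enrich <- res
        st$outputs$enrich <- .write_stage_tsv(
          res, file.path(config$output_dir, "enrichment.tsv"), config, stage)
        st
      },
      network = {
        need("data", stage, "preprocess")
        a <- config$network %||% list()
        st$network <- infer_network(
          st$data, st$meta,
          alpha_grid = a$alpha_grid %||% c(0.1, 0.5, 0.9),
          n_cv = a$n_cv %||% 10, seed = config$seed,
          merge = a$merge %||% "union")
        tabs <- network_tables(st$network)
        st$outputs$network <- .write_stage_tsv(
          tabs$edges, file.path(config$output_dir, "network_edges.tsv"),
          config, stage)
        st
      },
      diffuse = {
        need("network", stage, "network")
        a <- config$diffuse %||% list()
        seeds <- igraph::V(st$network)$name[
          igraph::V(st$network)$kind == "phenotype"]
        rk <- rwr(st$network, seeds, r = a$restart %||% 0.5,
                  tol = a$tol %||% 1e-4)
        st$ranking <- rk
        st$subnetwork <- top_n_features(st$network, rk, N = a$top_n %||% 50)
        st$outputs$diffuse <- .write_stage_tsv(
          st$subnetwork$nodes, file.path(config$output_dir, "top_features.tsv"),
          config, stage)
        st
      },
      classify = {
        need("data", stage, "preprocess")
        a <- config$classify %||% list()
        res <- run_task(st$data, st$meta,
                        task = a$task %||% "RA_vs_CTRL",
                        modality = a$modality %||% "multi",
                        selector = a$selector %||% "network_rwr",
                        n_grid = unlist(a$n_grid %||%
                                          c(10, 20, 30, 40, 50, 75, 100, 150,
                                            200, Inf)),
                        k = a$k %||% 5, cv_seed = config$seed)
        st$classify <- res
        st$outputs$classify <- .write_stage_tsv(
          res$per_fold, file.path(config$output_dir, "cv_metrics.tsv"),
          config, stage)
        st
      },
      cohort_table = {
        need("meta", stage, "preprocess")
        res <- cohort_table(st$meta)
        st$cohort_table <- res
        st$outputs$cohort_table <- .write_stage_tsv(
          res, file.path(config$output_dir, "cohort_table.tsv"), config, stage)
        st
      })
  }
  manifest <- list(package = "omninet",
                   version = as.character(utils::packageVersion("omninet")),
                   seed = config$seed,
                   config_sha = digest_config(config),
                   config = config[setdiff(names(config), "output_dir")],
                   outputs = lapply(st$outputs, function(p) {
                     h <- tools::md5sum(unname(unlist(p)))
                     stats::setNames(as.list(unname(h)), basename(names(h)))
                   }),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
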