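# Configuration-driven end-to-end runner tying all stages together.

#' Pipeline configuration
#'
#' Assembles the full parameter set of the workflow. The defaults are the
#' published analysis settings: soft power 15, minimum module size 100,
#' dendrogram cut height 0.99, DEG q < 0.01, module-overrepresentation
#' q < 0.1, top-15% hubs, between-sex marker screen at 45 dpf with
#' p < 0.05 and up to 40 markers per module, enrichment q < 0.1. All
#' thresholds are strict inequalities.
#'
#' @param ... Overrides of the defaults listed above.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    beta = 15L,
    min_module_size = 100L,
    detect_cut_height = 0.99,
    min_mean_tpm = 1,
    deg_q = 0.01,
    deg_transform = "log2p1",
    qvalue_method = "storey",
    module_q = 0.1,
    hub_fraction = 0.15,
    marker_timepoint = 45,
    marker_alpha = 0.05,
    marker_top_n = 40L,
    enrichment_q = 0.1,
    cluster_k = 3L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' @param path YAML file of key-value overrides (keys as in
#'   [pipeline_config()]).
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.write_stage <- function(df, out_dir, name) {
  if (is.null(out_dir) || is.null(df)) return(invisible(NULL))
  path <- file.path(out_dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full gonadal-development co-expression pipeline
#'
#' Executes, in order: expressed-gene filtering, signed network construction
#' (Spearman correlation, soft-thresholded adjacency, topological overlap),
#' module detection, per-gene ANOVA with q-value FDR, module DEG
#' overrepresentation, intramodular connectivity and hub ranking, module
#' eigengenes and archetype classification, optional term enrichment of the
#' related modules, the sex-timing procedure (marker selection, sample
#' clustering, early-sample sex assignment), and the global sample PCA.
#' The analysis itself is deterministic; `config$seed` governs only
#' simulated inputs, so identical config plus inputs reproduce identical
#' outputs.
#'
#' @param expr Gene-by-sample TPM matrix. If `NULL`, a synthetic dataset is
#'   generated with [simulate_expression()] under `config$seed`.
#' @param design Sample design matching `expr` (defaults to
#'   [gonad_design()] when simulating).
#' @param config A [pipeline_config()].
#' @param annotation Optional named term -> genes list for enrichment of
#'   related modules.
#' @param out_dir Optional output directory; when given, every stage writes
#'   its table there, plus the resolved config (`config.yaml`) and a run
#'   manifest (`manifest.json`). On a stage failure a `FAILED` marker names
#'   the failing stage and partial outputs are retained.
#' @return List with all stage results: `expression`, `design`, `modules`,
#'   `soft_power_fit`, `degs` (per-gene table), `overrepresentation`,
#'   `kin`, `hubs`, `eigengenes`, `archetypes`, `enrichment`, `markers`,
#'   `sex_timing`, `pca`, `manifest`.
#' @export
run_pipeline <- function(expr = NULL, design = NULL,
                         config = pipeline_config(),
                         annotation = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  stage <- "input"
  res <- list()
  on_fail <- function(e) {
    if (!is.null(out_dir))
      writeLines(paste("stage:", stage), file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  tryCatch({
    if (is.null(expr)) {
      ds <- simulate_expression(design = if (is.null(design)) gonad_design()
                                         else design,
                                seed = config$seed)
      expr <- ds$expression
      design <- ds$design
      res$truth <- ds$truth
    }
    stopifnot(is.matrix(expr), !is.null(design))

    stage <- "expression_filter"
    expr <- suppressMessages(
      filter_expressed_genes(expr, design, config$min_mean_tpm))

    stage <- "network_build"
    s <- spearman_correlation(log2(expr + 1))
    a <- signed_adjacency(s, config$beta)
    res$soft_power_fit <- scale_free_fit(rowSums(a))
    tom <- topological_overlap(a)
    modules <- detect_modules(tom$diss, config$min_module_size,
                              config$detect_cut_height)
    res$modules <- modules
    .write_stage(data.frame(gene = names(modules), module = unname(modules)),
                 out_dir, "modules.tsv")

    stage <- "differential"
    degs <- differential_expression(expr, design,
                                    transform = config$deg_transform,
                                    method = config$qvalue_method,
                                    q_threshold = config$deg_q)
    res$degs <- degs
    deg_set <- call_degs(degs[, c("gene", "q_value")], config$deg_q)
    .write_stage(degs, out_dir, "degs.tsv")

    stage <- "module_characterization"
    res$overrepresentation <- module_overrepresentation(
      modules, deg_set$genes, rownames(expr), config$module_q)
    .write_stage(res$overrepresentation, out_dir, "module_enrichment.tsv")
    assigned <- any(modules != "unassigned")
    if (assigned) {
      res$kin <- intramodular_connectivity(a, modules)
      res$hubs <- select_hubs(res$kin, modules, config$hub_fraction)
      egl <- suppressWarnings(module_eigengene(expr, modules))
      res$eigengenes <- egl
      res$archetypes <- classify_archetype(egl$eigengenes, design)
      .write_stage(res$hubs, out_dir, "hubs.tsv")
      .write_stage(res$archetypes, out_dir, "archetypes.tsv")
      if (!is.null(annotation)) {
        related <- res$overrepresentation$module[
          res$overrepresentation$is_related]
        res$enrichment <- lapply(setNames(nm = related), function(m) {
          term_enrichment(names(modules)[modules == m], annotation,
                          rownames(expr), config$enrichment_q)
        })
      }
    }

    stage <- "sex_timing"
    res$markers <- character(0)
    res$sex_timing <- NULL
    if (assigned &&
        any(res$archetypes$archetype == "male_specific") &&
        any(res$archetypes$archetype == "female_specific")) {
      res$markers <- select_sex_markers(res$hubs, expr, design,
                                        res$archetypes,
                                        config$marker_timepoint,
                                        config$marker_alpha,
                                        config$marker_top_n)
      if (length(res$markers)) {
        cl <- cluster_samples(expr[res$markers, , drop = FALSE],
                              config$cluster_k)
        res$sex_timing <- assign_early_sex(cl, design)
        .write_stage(res$sex_timing$sample_calls, out_dir,
                     "sex_assignments.tsv")
        .write_stage(res$sex_timing$ratios, out_dir, "sex_timing_ratios.tsv")
      }
    }

    stage <- "sample_pca"
    res$pca <- suppressWarnings(sample_pca(expr))

    stage <- "manifest"
    res$expression <- expr
    res$design <- design
    res$manifest <- list(
      package_version = as.character(utils::packageVersion("gonadnet")),
      parameters = unclass(config),
      n_genes = nrow(expr),
      n_samples = ncol(expr),
      n_modules = length(setdiff(unique(modules), "unassigned")),
      n_degs = deg_set$n,
      n_related_modules = sum(res$overrepresentation$is_related),
      n_markers = length(res$markers)
    )
    if (!is.null(out_dir)) {
      yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
      jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    res
  }, error = on_fail)
}
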