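#' Pipeline run configuration
#'
#' All tunables with their defaults; where the underlying procedure has a
#' canonical parameterization (summit expansion 50 bp, minimum 3 sites,
#' eta 0.1, 2000 sweeps, 3 seeds, z cutoff 1, group cutoff 0.5, match
#' threshold 0.5, 200 permutations) the defaults equal it.
#'
#' @param expand_bp summit expansion half-width.
#' @param min_sites minimum sites per region (also reused for usage
#'   calls).
#' @param eta topic-Dirichlet hyperparameter.
#' @param max_iter Gibbs sweeps.
#' @param seeds multistart seeds.
#' @param z_cut z-score cutoff for participation/driver/usage calls.
#' @param group_cutoff module-group tree-cut height.
#' @param match_threshold module matching correlation threshold.
#' @param n_perm permutations for the PPI test.
#' @param usage_z_axis margin of the usage z-score (see
#'   [call_module_usage()]).
#' @param rf_trees,rf_seeds random-forest settings.
#' @return a `tfmod_config` list.
#' @export
tfmod_config <- function(expand_bp = 50L, min_sites = 3L, eta = 0.1,
                         max_iter = 2000L, seeds = c(1L, 2L, 3L),
                         z_cut = 1, group_cutoff = 0.5,
                         match_threshold = 0.5, n_perm = 200L,
                         usage_z_axis = "region",
                         rf_trees = 500L, rf_seeds = 1:5) {
  structure(as.list(environment()), class = "tfmod_config")
}

#' Run the full module-discovery pipeline
#'
#' Stages: blacklist filtering, co-binding region construction, region-TF
#' matrix, HDP multistart fit, output extraction, and the analysis layer
#' (participation, main drivers, region-module matrix, usage calls,
#' multi-module census, module groups, PCA).  All declared outputs are
#' written as TSV/BED under `out_dir` together with a manifest recording
#' parameters and files; a stage failure aborts with the stage name.
#'
#' @param calls pooled [binding_calls()].
#' @param out_dir output directory (created).
#' @param config a [tfmod_config()].
#' @param blacklist optional blacklist intervals (`chrom`,`start`,`end`).
#' @return invisibly, a list with the in-memory objects (`regions`,
#'   `matrix`, `fit`, `module_tf`, `assignments`, `drivers`, `usage`, ...)
#'   and `files` (the manifest paths).
#' @export
run_pipeline <- function(calls, out_dir, config = tfmod_config(),
                         blacklist = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) {
    path <- file.path(out_dir, name)
    files[[name]] <<- path
    path
  }

  calls <- stage("filter", {
    if (is.null(calls) || nrow(calls) == 0) stop("no input calls")
    filter_blacklist(calls, blacklist)
  })
  regions <- stage("regions", {
    build_cobinding_regions(calls, config$expand_bp, config$min_sites)
  })
  write_regions_bed(regions, out("regions.bed"))
  m <- stage("matrix", {
    mm <- build_region_tf_matrix(regions)
    if (nrow(mm) == 0) stop("no co-binding regions retained")
    mm
  })
  write_matrix_tsv(m, out("region_tf_matrix.tsv"), "region_id")

  corpus <- stage("corpus", corpus_from_matrix(m))
  fit <- stage("fit", {
    fit_hdp_multistart(corpus, seeds = config$seeds, eta = config$eta,
                       max_iter = config$max_iter)
  })
  write.table(fit$runs, out("hdp_runs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  traces <- do.call(cbind, fit$traces)
  colnames(traces) <- paste0("seed_", fit$runs$seed, "_init_",
                             fit$runs$init)
  write.table(data.frame(iteration = seq_len(nrow(traces)), traces),
              out("loglik_trace.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  outputs <- stage("extract", extract_outputs(fit, corpus))
  write_matrix_tsv(outputs$module_tf, out("module_tf_matrix.tsv"),
                   "module")
  write.table(outputs$assignments, out("assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  analysis <- stage("analyze", {
    mtm <- outputs$module_tf
    drivers <- call_main_drivers(mtm, config$z_cut)
    rmm <- region_module_matrix(outputs$assignments, nrow(mtm))
    usage <- call_module_usage(rmm, config$min_sites, config$z_cut,
                               axis = config$usage_z_axis)
    list(participation = call_participation(mtm, config$z_cut),
         drivers = drivers, rmm = rmm, usage = usage,
         census = multi_module_census(usage),
         groups = if (nrow(mtm) >= 2) group_modules(mtm,
                                                    config$group_cutoff)
                  else NULL,
         pca = pca_modules(mtm))
  })
  write_matrix_tsv(analysis$participation * 1L,
                   out("participation.tsv"), "module")
  write.table(data.frame(module = names(analysis$drivers$labels),
                         label = analysis$drivers$labels),
              out("module_labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_matrix_tsv(analysis$rmm, out("region_module_matrix.tsv"),
                   "region_id")
  write_matrix_tsv(analysis$usage * 1L, out("module_usage.tsv"),
                   "region_id")
  write.table(data.frame(n_modules = names(analysis$census),
                         n_regions = analysis$census),
              out("multi_module_census.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(analysis$groups)) {
    write.table(data.frame(module = names(analysis$groups$groups),
                           group = analysis$groups$groups),
                out("module_groups.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_matrix_tsv(analysis$pca$loadings, out("pca_loadings.tsv"),
                   "module")
  write.table(data.frame(component = seq_along(analysis$pca$var_explained),
                         var_explained = analysis$pca$var_explained),
              out("pca_variance.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # manifest last: every declared file must exist and be non-empty
  manifest <- data.frame(
    file = names(files), path = unname(unlist(files)),
    stringsAsFactors = FALSE)
  missing <- !file.exists(manifest$path) | file.size(manifest$path) == 0
  if (any(missing)) {
    stop("declared output missing or empty: ",
         paste(manifest$file[missing], collapse = ", "))
  }
  params <- vapply(config, function(v) paste(v, collapse = ","), "")
  writeLines(c("# tfmodules pipeline manifest",
               paste0("# param\t", names(params), "\t", params),
               paste0(manifest$file, "\t", manifest$path)),
             file.path(out_dir, "manifest.tsv"))

  invisible(list(regions = regions, matrix = m, corpus = corpus,
                 fit = fit, module_tf = outputs$module_tf,
                 assignments = outputs$assignments, analysis = analysis,
                 files = files, out_dir = out_dir))
}
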