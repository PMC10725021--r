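# Study-level orchestration: descriptives -> per-domain networks -> domain
# screening -> integrated networks -> covariate-adjusted variants ->
# centrality/pathways -> stability, with a JSON manifest of everything
# written.

#' Configure a full network study
#'
#' @param data_path,spec_path Delimited cohort file and variable-spec
#'   config ([read_dataset()]); mutually exclusive with `generator`.
#' @param generator A [generator_config()] used to simulate the cohort
#'   when no input files are given.
#' @param out_dir Output directory (created if absent).
#' @param est_config An [estimation_config()].
#' @param stab_config A [stability_config()], or `NULL` to skip the
#'   stability stage.
#' @param npn Nonparanormal rule applied before estimation: `"skewed"`
#'   (default), `"all"`, `"none"`.
#' @param symptom_community Community label of the insomnia symptom items
#'   (default `"ISI"`).
#' @param total_name Name for the symptom total-score node in the
#'   total-score integrated network (default `"ISI"`).
#' @param covariates Covariate node names for the adjusted networks
#'   (default `c("HAMD14", "medication")`); set `NULL` to skip.
#' @param edge_ci_boot Resamples for edge-weight CIs (0 skips; default 0 —
#'   the stability stage is the expensive part and is controlled by
#'   `stab_config`).
#' @param delim Data-file delimiter.
#' @return An object of class `psychnet_studycfg`.
#' @export
study_config <- function(data_path = NULL, spec_path = NULL,
                         generator = NULL, out_dir = "psychnet-study",
                         est_config = estimation_config(),
                         stab_config = NULL,
                         npn = c("skewed", "all", "none"),
                         symptom_community = "ISI",
                         total_name = "ISI",
                         covariates = c("HAMD14", "medication"),
                         edge_ci_boot = 0, delim = ",") {
  npn <- match.arg(npn)
  if (is.null(generator) && (is.null(data_path) || is.null(spec_path)))
    stop("either data_path + spec_path or a generator config is required",
         call. = FALSE)
  structure(
    list(data_path = data_path, spec_path = spec_path,
         generator = generator, out_dir = out_dir,
         est_config = est_config, stab_config = stab_config, npn = npn,
         symptom_community = symptom_community, total_name = total_name,
         covariates = covariates, edge_ci_boot = edge_ci_boot,
         delim = delim),
    class = "psychnet_studycfg")
}

#' Run the full study pipeline
#'
#' Executes, in order: cohort loading (or simulation), descriptive
#' statistics, the symptom-only network, one network per psychosocial
#' domain (symptoms + that domain), domain screening (a domain is retained
#' only if at least one of its nodes shares an edge with a symptom node),
#' the integrated total-score and item-level networks over the retained
#' domains, covariate-adjusted variants, centrality/bridge tables,
#' shortest-pathway summaries, and (when configured) case-dropping
#' bootstrap stability and edge-weight CIs. Every artifact is written
#' under `out_dir` and recorded, with an MD5 hash, in `manifest.json`.
#' A stage failure writes the manifest with a `FAILED` marker and aborts
#' with the stage name.
#'
#' @param config A [study_config()].
#' @return The manifest, invisibly (class `psychnet_manifest`).
#' @export
run_study <- function(config) {
  if (!inherits(config, "psychnet_studycfg"))
    stop("config must come from study_config()", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("psychnet")),
    seed = if (!is.null(config$generator)) config$generator$seed else NULL,
    npn = config$npn,
    gamma = config$est_config$gamma,
    rule = config$est_config$rule,
    stages = list(), artifacts = list(), hashes = list(),
    status = "RUNNING")
  t_all <- proc.time()[["elapsed"]]
  out <- function(name) file.path(config$out_dir, name)
  record <- function(stage, files, t0) {
    manifest$stages[[stage]] <<- list(
      status = "OK", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    for (f in files) {
      manifest$artifacts[[basename(f)]] <<- f
      manifest$hashes[[basename(f)]] <<- unname(tools::md5sum(f))
    }
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(expr, error = function(e) e)
    if (inherits(files, "error")) {
      manifest$stages[[name]] <<- list(status = "FAILED",
                                       error = conditionMessage(files))
      manifest$status <<- "FAILED"
      write_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(files),
           call. = FALSE)
    }
    record(name, files, t0)
  }

  data <- NULL; networks <- list()
  stage("load", {
    data <- if (!is.null(config$generator))
      generate_cohort(config$generator)$dataset
    else
      read_dataset(config$data_path, config$spec_path, delim = config$delim)
    f <- out("cohort.csv")
    write_dataset(data, f)
    write_variable_spec(data$specs, out("spec.yaml"))
    c(f, out("spec.yaml"))
  })

  stage("descriptives", {
    desc <- summarize_cohort(data)
    f1 <- write_tsv_table(desc$numeric, out("descriptives_numeric.tsv"))
    fs <- f1
    if (!is.null(desc$categorical))
      fs <- c(fs, write_tsv_table(desc$categorical,
                                  out("descriptives_categorical.tsv")))
    fs
  })

  comms <- spec_communities(data)
  nms <- spec_names(data)
  sym <- config$symptom_community
  sym_vars <- nms[comms == sym]
  domain_labels <- setdiff(unique(comms), c(sym, "COVARIATE", "HAMD"))
  tdata <- NULL
  stage("transform", {
    tdata <- npn_transform(data, rule = config$npn)$transformed
    character(0)
  })

  fit_and_write <- function(vars, label, covars = NULL) {
    sub <- subset_cohort(tdata, c(vars, covars))
    net <- if (is.null(covars)) estimate_network(sub, config$est_config)
           else estimate_with_covariates(sub, covars, config$est_config)
    f1 <- out(paste0("network_", label, ".tsv"))
    write_network(net, f1)
    f2 <- write_tsv_table(centrality(net),
                          out(paste0("centrality_", label, ".tsv")))
    networks[[label]] <<- net
    c(f1, network_sidecar_path(f1), f2)
  }

  stage("symptom_network", fit_and_write(sym_vars, "insomnia_only"))
  for (dom in domain_labels) {
    local({
      d <- dom
      stage(paste0("domain_network_", d),
            fit_and_write(c(sym_vars, nms[comms == d]),
                          paste0("insomnia_", d)))
    })
  }

  retained <- character(0)
  stage("screening", {
    domnets <- networks[paste0("insomnia_", domain_labels)]
    retained <- select_domains(domnets, symptom_community = sym)
    f <- out("screening.tsv")
    write_tsv_table(
      data.frame(domain = domain_labels,
                 retained = domain_labels %in% retained), f)
    f
  })

  ret_vars <- nms[comms %in% retained]
  total_data <- NULL
  stage("integrated_total", {
    total_data <- npn_transform(
      with_total_score(data, sym_vars, config$total_name,
                       community = sym),
      rule = config$npn)$transformed
    sub <- subset_cohort(total_data, c(config$total_name, ret_vars))
    net <- estimate_network(sub, config$est_config)
    networks[["integrated_total"]] <- net
    f1 <- out("network_integrated_total.tsv")
    write_network(net, f1)
    f2 <- write_tsv_table(centrality(net),
                          out("centrality_integrated_total.tsv"))
    c(f1, network_sidecar_path(f1), f2)
  })
  stage("integrated_items",
        fit_and_write(c(sym_vars, ret_vars), "integrated_items"))

  if (!is.null(config$covariates)) {
    stage("covariate_networks", {
      fs <- fit_and_write(c(sym_vars, ret_vars), "integrated_items_cov",
                          covars = config$covariates)
      sub <- subset_cohort(total_data,
                           c(config$total_name, ret_vars,
                             config$covariates))
      net <- estimate_with_covariates(sub, config$covariates,
                                      config$est_config)
      networks[["integrated_total_cov"]] <- net
      f1 <- out("network_integrated_total_cov.tsv")
      write_network(net, f1)
      c(fs, f1, network_sidecar_path(f1))
    })
  }

  stage("pathways", {
    net <- networks[["integrated_items"]]
    pw <- pathway_subnetwork(net,
                             sources = intersect(net$nodes, ret_vars),
                             targets = intersect(net$nodes, sym_vars))
    f1 <- write_tsv_table(pw$edges, out("pathway_edges.tsv"))
    f2 <- write_tsv_table(
      data.frame(intermediary = if (length(pw$intermediaries))
        pw$intermediaries else character(0)),
      out("pathway_intermediaries.tsv"))
    c(f1, f2)
  })

  if (!is.null(config$stab_config)) {
    stage("stability", {
      sub <- subset_cohort(tdata, c(sym_vars, ret_vars))
      st <- case_drop_bootstrap(sub, config$est_config, config$stab_config)
      f1 <- write_tsv_table(
        data.frame(index = names(st$cs), cs = unname(st$cs)),
        out("stability_cs.tsv"))
      fs <- f1
      for (i in names(st$correlations)) {
        f <- out(paste0("stability_correlations_", i, ".tsv"))
        write_tsv_table(as.data.frame(st$correlations[[i]]), f)
        fs <- c(fs, f)
      }
      fs
    })
  }
  if (config$edge_ci_boot > 0) {
    stage("edge_ci", {
      sub <- subset_cohort(tdata, c(sym_vars, ret_vars))
      ci <- edge_ci_bootstrap(sub, config$est_config,
                              n_boot = config$edge_ci_boot,
                              seed = config$stab_config$seed %||% 1)
      write_tsv_table(ci$edges, out("edge_ci.tsv"))
    })
  }

  manifest$retained_domains <- retained
  manifest$networks <- names(networks)
  manifest$status <- "OK"
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  write_manifest()
  invisible(structure(manifest, class = "psychnet_manifest"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.psychnet_manifest <- function(x, ...) {
  cat(sprintf("<study manifest> status=%s networks=%d retained=%s\n",
              x$status, length(x$networks),
              paste(x$retained_domains, collapse = ",")))
  invisible(x)
}
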