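#' Validate trees against a society table
#'
#' Report-only cross-checks of the matching between a tree sample and a
#' society table: taxa present in the trees but absent from the table, rows
#' of the table without a matching tip, societies mapped to more than one
#' taxon, and ordinal values outside 0..3.
#'
#' @param trees \code{multiPhylo}/\code{phylo}.
#' @param table Society data.frame (columns \code{society}, \code{taxon},
#'   trait columns).
#' @return List with elements \code{tips_not_in_table},
#'   \code{taxa_not_in_trees}, \code{duplicate_mappings},
#'   \code{bad_ordinal}, and a logical \code{ok}.
#' @export
validate_inputs <- function(trees, table) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  tips <- trees[[1]]$tip.label
  tips_extra <- setdiff(tips, table$taxon)
  taxa_extra <- setdiff(table$taxon, tips)
  dup <- character(0)
  if (!is.null(table$society)) {
    tab2 <- unique(table[, c("society", "taxon")])
    dup <- unique(tab2$society[duplicated(tab2$society)])
  }
  ord_cols <- intersect(c("political_authority", "religious_authority",
                          "authority_structure"), names(table))
  bad <- character(0)
  for (cc in ord_cols) {
    v <- table[[cc]]
    if (any(!is.na(v) & (v < 0 | v > 3 | v != floor(v)))) {
      bad <- c(bad, cc)
    }
  }
  out <- list(tips_not_in_table = tips_extra,
              taxa_not_in_trees = taxa_extra,
              duplicate_mappings = dup,
              bad_ordinal = bad)
  out$ok <- all(lengths(out[1:4]) == 0)
  out
}

pipeline_defaults <- function() {
  list(trees = NULL, data = NULL, out = "coevauth_out", seed = 1,
       scale = "desk",
       stages = c("signal", "coevolve", "multistate", "compare"),
       tree_draws = NULL, n_tips = 60, gp = NA,
       multistate_models = c("full", "weak_differentiation",
                             "strong_differentiation", "weak_unification",
                             "strong_unification"))
}

#' Read a pipeline configuration file
#'
#' Flat YAML key-value configuration; unknown keys are kept and echoed into
#' the run manifest.
#' @param path YAML file path.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(pipeline_defaults(), cfg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analyses in study order — input validation,
#' phylogenetic signal, the dynamic coevolutionary model, constrained
#' multistate models of the authority structure, and Bayes-factor model
#' comparison — writing per-stage CSV outputs and a JSON manifest (input
#' hashes, seeds, configuration, package version) into the output
#' directory. Stages are independent: a failed stage is recorded in the
#' manifest and later stages still run, except \code{compare}, which needs
#' the multistate stage. If no input data are given, a seeded synthetic
#' dataset is generated and analysed end-to-end.
#'
#' @param config Named list (see \code{\link{load_run_config}}): paths
#'   \code{trees}/\code{data} (or NULL for synthetic), \code{out},
#'   \code{seed}, \code{scale} ("desk"/"paper"), \code{stages},
#'   \code{tree_draws}.
#' @return Invisibly, a list with \code{exit} (0 success, 2 validation
#'   failure, 3 non-convergence in a fitted stage), \code{manifest} (path),
#'   and the per-stage results.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  logmsg <- function(...) {
    message(format(Sys.time(), "%H:%M:%S"), " [pipeline] ", ...)
  }
  manifest <- list(config = cfg[setdiff(names(cfg), c("trees", "data"))],
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("coevauth")),
                   stages = list(), outputs = character(0),
                   input_hashes = list())
  # inputs
  if (is.null(cfg$data) || is.null(cfg$trees)) {
    logmsg("no input data supplied: generating synthetic dataset (n_tips = ",
           cfg$n_tips, ", seed = ", cfg$seed, ")")
    ds <- synthetic_dataset(n_tips = cfg$n_tips, seed = cfg$seed)
    paths <- write_synthetic_dataset(ds, file.path(cfg$out, "synthetic"))
    manifest$outputs <- c(manifest$outputs, paths)
    trees <- c(ds$tree)
    table <- ds$society_table
  } else {
    trees <- if (inherits(cfg$trees, "phylo") ||
                 inherits(cfg$trees, "multiPhylo")) {
      if (inherits(cfg$trees, "phylo")) c(cfg$trees) else cfg$trees
    } else {
      fmt <- if (grepl("nex", tolower(cfg$trees))) "nexus" else "newick"
      manifest$input_hashes$trees <- unname(tools::md5sum(cfg$trees))
      parse_trees(cfg$trees, fmt)
    }
    table <- if (is.data.frame(cfg$data)) cfg$data else {
      manifest$input_hashes$data <- unname(tools::md5sum(cfg$data))
      utils::read.csv(cfg$data, stringsAsFactors = FALSE)
    }
  }
  rep <- validate_inputs(trees, table)
  if (length(rep$taxa_not_in_trees) || length(rep$bad_ordinal)) {
    logmsg("validation failed: ",
           paste(c(rep$taxa_not_in_trees, rep$bad_ordinal), collapse = ", "))
    manifest$stages$validate <- rep
    jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(list(exit = 2, manifest = file.path(cfg$out, "manifest.json"),
                          validation = rep)))
  }
  if (length(rep$tips_not_in_table)) {
    logmsg("pruning ", length(rep$tips_not_in_table),
           " tree tips absent from the table")
    trees <- structure(lapply(trees, prune_to_taxa, keep = table$taxon),
                       class = "multiPhylo")
  }
  manifest$stages$validate <- rep
  results <- list()
  exit <- 0L
  tdr <- cfg$tree_draws
  run_stage <- function(name, fun) {
    logmsg("stage ", name, " started")
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) {
      logmsg("stage ", name, " FAILED: ", conditionMessage(out))
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(out))
      NULL
    } else {
      logmsg("stage ", name, " done")
      out
    }
  }
  if ("signal" %in% cfg$stages) {
    results$signal <- run_stage("signal", function() {
      sc <- list()
      if (!is.null(tdr)) sc$n_trees <- tdr
      fit <- fit_signal_model(table, trees, config = sc, scale = cfg$scale,
                              seed = cfg$seed)
      f <- file.path(cfg$out, "signal_summary.csv")
      write_posterior_summary(fit, f)
      ftr <- file.path(cfg$out, "signal_draws.tsv")
      write_chain_traces(fit$draws, ftr,
                         meta = list(seed = cfg$seed, stage = "signal",
                                     tree_ids = fit$tree_ids))
      manifest$stages$signal <<- list(status = "ok", converged = fit$converged,
                                      files = c(f, ftr))
      manifest$outputs <<- c(manifest$outputs, f, ftr)
      if (!fit$converged) exit <<- 3L
      fit
    })
  }
  if ("coevolve" %in% cfg$stages) {
    results$coevolve <- run_stage("coevolve", function() {
      sc <- list(gp = cfg$gp)
      if (!is.null(tdr)) sc$n_trees <- tdr
      fit <- fit_coevolution(table, trees, config = sc, scale = cfg$scale,
                             seed = cfg$seed)
      f <- file.path(cfg$out, "coev_summary.csv")
      write_posterior_summary(fit, f)
      dt <- delta_theta(fit)
      fdt <- file.path(cfg$out, "coev_delta_theta.csv")
      utils::write.csv(cbind(direction = rownames(dt$summary), dt$summary),
                       fdt, row.names = FALSE)
      md <- coef(fit)
      A <- matrix(c(md["a11"], md["a21"], md["a12"], md["a22"]), 2, 2)
      pp <- phase_plane(ou_params(A, b = c(md["b_pol"], md["b_rel"]),
                                  cutpoints = list(c(md["cut_pol_1"], 0, md["cut_pol_3"]),
                                                   c(md["cut_rel_1"], 0, md["cut_rel_3"]))))
      fpp <- file.path(cfg$out, "coev_phase_plane.csv")
      utils::write.csv(pp$grid, fpp, row.names = FALSE)
      asr <- ancestral_states(fit, n_draws = 100, seed = cfg$seed)
      fasr <- file.path(cfg$out, "coev_ancestral_states.csv")
      utils::write.csv(asr, fasr, row.names = FALSE)
      manifest$stages$coevolve <<- list(status = "ok",
                                        converged = fit$converged,
                                        files = c(f, fdt, fpp, fasr))
      manifest$outputs <<- c(manifest$outputs, f, fdt, fpp, fasr)
      fit
    })
  }
  if ("multistate" %in% cfg$stages) {
    results$multistate <- run_stage("multistate", function() {
      states <- stats::setNames(table$authority_structure, table$taxon)
      logml <- vapply(cfg$multistate_models, function(m) {
        logmsg("  stepping-stone: ", m)
        stepping_stone_logml(trees, states, m, scale = cfg$scale,
                             seed = cfg$seed)$logml
      }, 1)
      f <- file.path(cfg$out, "multistate_logml.csv")
      utils::write.csv(data.frame(model = names(logml),
                                  logml = as.numeric(logml)),
                       f, row.names = FALSE)
      manifest$stages$multistate <<- list(status = "ok", files = f)
      manifest$outputs <<- c(manifest$outputs, f)
      logml
    })
  }
  if ("compare" %in% cfg$stages) {
    results$compare <- run_stage("compare", function() {
      if (is.null(results$multistate)) {
        stop("compare requires the multistate stage")
      }
      cmp <- compare_models(results$multistate)
      f1 <- file.path(cfg$out, "model_comparison_bf.csv")
      utils::write.csv(as.data.frame(cmp$bf2ln), f1, row.names = TRUE)
      f2 <- file.path(cfg$out, "model_comparison_labels.csv")
      utils::write.csv(as.data.frame(cmp$labels, stringsAsFactors = FALSE),
                       f2, row.names = TRUE)
      manifest$stages$compare <<- list(status = "ok", files = c(f1, f2))
      manifest$outputs <<- c(manifest$outputs, f1, f2)
      cmp
    })
  }
  manifest$output_hashes <- as.list(tools::md5sum(
    manifest$outputs[file.exists(manifest$outputs)]))
  mf <- file.path(cfg$out, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  logmsg("pipeline finished, exit = ", exit)
  invisible(list(exit = exit, manifest = mf, results = results))
}
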