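#' Pipeline configuration
#'
#' Collects the tunable parameters of the pipeline.  All defaults can be
#' overridden and the object round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param temperature Temperature in kelvin (default 310).
#' @param n_bootstrap Bootstrap replicates for uncertainties (default 100).
#' @param threshold Classification threshold tau, kJ/mol (default 4).
#' @param seed Base integer seed for stochastic steps (default 1).
#' @param estimator `"BAR"` or `"crooks_crossing"`.
#' @param psi_convention `"carbonyl"` or `"next_n"` (see [residue_psi()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(temperature = 310, n_bootstrap = 100L,
                       threshold = 4.0, seed = 1L,
                       estimator = c("BAR", "crooks_crossing"),
                       psi_convention = c("carbonyl", "next_n")) {
  beta_from_temperature(temperature)
  stopifnot(n_bootstrap >= 2L, threshold > 0)
  structure(list(temperature = as.numeric(temperature),
                 n_bootstrap = as.integer(n_bootstrap),
                 threshold = as.numeric(threshold),
                 seed = as.integer(seed),
                 estimator = match.arg(estimator),
                 psi_convention = match.arg(psi_convention)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path for the YAML serialization.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

# comment header stamped into every tabular output (no timestamps, so
# identical runs give byte-identical files)
output_header <- function(config) {
  c(sprintf("kitddg %s", as.character(utils::packageVersion("kitddg"))),
    sprintf("config_md5 %s", config_hash(config)))
}

#' Generate work tables for a set of transformations
#'
#' Runs [generate_cft_work_samples()] for each row of a specification table
#' and writes a single work TSV.
#'
#' @param specs Data frame with columns `transformation_id`, `dg_true`,
#'   `dissipation` and optionally `n_forward`, `n_reverse` (default 450).
#' @param path Output work TSV path.
#' @param config A [run_config()]; supplies temperature and the base seed
#'   (each transformation uses `seed + row - 1`).
#' @return Named list of the generated [work_set()]s, invisibly.
#' @export
simulate_work <- function(specs, path, config = run_config()) {
  stopifnot(is.data.frame(specs),
            all(c("transformation_id", "dg_true", "dissipation") %in%
                  names(specs)))
  if (is.null(specs$n_forward)) specs$n_forward <- 450L
  if (is.null(specs$n_reverse)) specs$n_reverse <- 450L
  ws <- lapply(seq_len(nrow(specs)), function(i) {
    generate_cft_work_samples(
      dg_true = specs$dg_true[i], dissipation = specs$dissipation[i],
      n_forward = specs$n_forward[i], n_reverse = specs$n_reverse[i],
      temperature = config$temperature, seed = config$seed + i - 1L,
      transformation_id = specs$transformation_id[i])
  })
  names(ws) <- specs$transformation_id
  write_work_tsv(ws, path, header_comment = output_header(config))
  invisible(ws)
}

#' Estimate dG for every transformation in a work table
#'
#' Reads a work TSV (see [read_work_tsv()]), estimates \eqn{\Delta G} with
#' the configured estimator, attaches bootstrap standard errors and the
#' forward/reverse overlap diagnostic, and optionally writes a
#' tab-separated estimates file.
#'
#' @param work_table Path to a work TSV, or a list of [work_set()]s.
#' @param config A [run_config()].
#' @param out Optional output TSV path.
#' @return Data frame with columns `transformation_id`, `method`,
#'   `dg_kJ_per_mol`, `se_kJ_per_mol`, `n_f`, `n_r`, `overlap`.
#' @export
run_estimate <- function(work_table, config = run_config(), out = NULL) {
  stopifnot(inherits(config, "run_config"))
  ws_list <- if (is.character(work_table))
    read_work_tsv(work_table, temperature = config$temperature)
  else work_table
  stopifnot(length(ws_list) >= 1L,
            all(vapply(ws_list, inherits, logical(1), "work_set")))
  rows <- lapply(seq_along(ws_list), function(i) {
    ws <- ws_list[[i]]
    est <- estimate_work_set(ws, estimator = config$estimator,
                             n_boot = config$n_bootstrap,
                             seed = config$seed + i - 1L)
    data.frame(transformation_id = ws$transformation_id,
               method = est$method,
               dg_kJ_per_mol = est$dg,
               se_kJ_per_mol = est$uncertainty,
               n_f = est$n_f, n_r = est$n_r,
               overlap = overlap_diagnostic(ws),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    con <- file(out, "w")
    on.exit(close(con))
    writeLines(paste0("# ", output_header(config)), con)
    utils::write.table(format(res, digits = 10, trim = TRUE), con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Assemble cycles and classify mutations from a per-state ddG table
#'
#' Accepts a direct \eqn{\Delta\Delta G} table (columns `mutation`, `state`,
#' `ddg_kJ_per_mol`, `se_kJ_per_mol`, as produced by [kit_printed_ddg()])
#' or a path to such a TSV.  Builds the per-mutation thermodynamic cycle,
#' classifies each mutation and returns plot-ready scatter data (the 2D
#' inactive-vs-active stability map).
#'
#' @param ddg_table Data frame or TSV path.
#' @param config A [run_config()] (threshold, output stamping).
#' @param out_dir Optional directory; writes `cycle_report.json` and
#'   `ddg_scatter.tsv` when given.
#' @return List with elements `cycles` (list of [mutation_cycle()]),
#'   `classifications` (list of `classification`) and `scatter`
#'   (data frame: mutation, ddg_inactive, se_inactive, ddg_active,
#'   se_active, ddg_activation, se_activation, active_assumed_zero, label).
#' @export
run_cycle <- function(ddg_table, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  tab <- if (is.character(ddg_table))
    utils::read.delim(ddg_table, stringsAsFactors = FALSE,
                      comment.char = "#")
  else as.data.frame(ddg_table)
  cycles <- cycles_from_ddg_table(tab)
  cls <- lapply(cycles, classify_mutation, threshold = config$threshold)
  scatter <- do.call(rbind, lapply(names(cycles), function(m) {
    cy <- cycles[[m]]
    assumed <- is.null(cy$ddg_active)
    act <- if (assumed) ddg(0, 0) else cy$ddg_active
    acti <- if (assumed) NULL else cy$ddg_activation
    data.frame(mutation = m,
               ddg_inactive = cy$ddg_inactive$value,
               se_inactive = cy$ddg_inactive$se,
               ddg_active = act$value, se_active = act$se,
               ddg_activation = if (is.null(acti)) NA_real_ else acti$value,
               se_activation = if (is.null(acti)) NA_real_ else acti$se,
               active_assumed_zero = assumed,
               label = cls[[m]]$label, stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- list(tool = "kitddg",
                   version = as.character(utils::packageVersion("kitddg")),
                   config_md5 = config_hash(config),
                   threshold_kJ_per_mol = config$threshold,
                   mutations = lapply(names(cycles), function(m) {
                     cy <- cycles[[m]]
                     list(mutation = m,
                          ddg_inactive = cy$ddg_inactive[c("value", "se")],
                          ddg_active = if (is.null(cy$ddg_active)) NULL else
                            cy$ddg_active[c("value", "se")],
                          ddg_activation =
                            if (is.null(cy$ddg_activation)) NULL else
                              cy$ddg_activation[c("value", "se")],
                          label = cls[[m]]$label,
                          rationale = cls[[m]]$rationale)
                   }))
    jsonlite::write_json(report, file.path(out_dir, "cycle_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    con <- file(file.path(out_dir, "ddg_scatter.tsv"), "w")
    writeLines(paste0("# ", output_header(config)), con)
    utils::write.table(scatter, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  list(cycles = cycles, classifications = cls, scatter = scatter)
}

#' Compute structural activation metrics on a coordinate ensemble
#'
#' Runs the requested kinase activation metrics on a multi-model PDB file
#' or an [ensemble()]: the DFG backbone dihedrals (`"dfg"`), the HDR Phi
#' (`"hdr"`) and the catalytic salt bridges (`"k623_e640"`,
#' `"k623_d810"`).  Residues that a requested metric needs but the
#' structure lacks are reported by name.
#'
#' @param input PDB path or [ensemble()].
#' @param metrics Character vector of metric names (see above).
#' @param config A [run_config()] (Psi convention, output stamping).
#' @param out_dir Optional directory; one TSV (`frame`, `value` columns)
#'   per metric series is written when given.
#' @return Named list of `metric_series`.
#' @export
run_metrics <- function(input,
                        metrics = c("dfg", "hdr", "k623_e640", "k623_d810"),
                        config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  ens <- if (is.character(input)) read_ensemble_pdb(input) else input
  stopifnot(inherits(ens, "ensemble"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- list()
  for (m in metrics) {
    res <- switch(
      m,
      dfg = {
        d <- dfg_descriptor(ens, convention = config$psi_convention)
        stats::setNames(d, c("dfg_phi_810", "dfg_psi_810",
                             "dfg_phi_811", "dfg_psi_811"))
      },
      hdr = list(hdr_phi_791 = hdr_descriptor(ens)),
      k623_e640 = list(k623_e640 = salt_bridge_distance(ens, 623L, 640L)),
      k623_d810 = list(k623_d810 = salt_bridge_distance(ens, 623L, 810L)))
    out <- c(out, res)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      s <- out[[nm]]
      con <- file(file.path(out_dir, paste0(nm, ".tsv")), "w")
      writeLines(paste0("# ", c(output_header(config),
                                paste("unit", s$unit))), con)
      utils::write.table(
        data.frame(frame = seq_along(s$values), value = s$values),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
    }
  }
  out
}

#' Run the bundled KIT worked example end-to-end
#'
#' Loads the printed per-state ddG values of the five KIT mutations
#' ([kit_printed_ddg()]), assembles the thermodynamic cycles and classifies
#' each mutation.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (see [run_cycle()]).
#' @return The [run_cycle()] result list.
#' @export
demo_kit <- function(config = run_config(), out_dir = NULL) {
  run_cycle(kit_printed_ddg(), config = config, out_dir = out_dir)
}
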