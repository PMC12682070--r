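#' Run the full ripening-methylome pipeline on a simulated study
#'
#' Wires every stage end to end: simulate (or reuse) a study, conversion QC,
#' genome-binned profiles and replicate correlation, per-tissue DMC and DMR
#' calling (ripe vs immature), tissue-specificity classification of the CHH
#' hyper-DMRs, promoter-bin responsive-gene calling, expression integration,
#' and recovery scoring against the simulator's truth manifest. All
#' intermediate tables are written under `out_dir` along with a JSON run
#' manifest echoing the configuration.
#'
#' @param sim_config A [simulation_config()] (its seed drives everything),
#'   or an existing `sim_study`.
#' @param out_dir Output directory; created if needed.
#' @param comparison A [comparison_config()].
#' @param write_inputs Also write the simulated raw inputs (FASTA, GFF3,
#'   cytosine reports) under `out_dir/inputs`.
#' @return Invisible list with all stage results (`study`, `qc`, `dmcs`,
#'   `dmrs`, `groups`, `responsive`, `integration`, `recovery`, `manifest`).
#' @export
run_all <- function(sim_config = simulation_config(), out_dir = tempfile(),
                    comparison = comparison_config(), write_inputs = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- if (inherits(sim_config, "sim_study")) sim_config else
    simulate_study(sim_config,
                   out_dir = if (write_inputs)
                     file.path(out_dir, "inputs") else NULL)
  ann <- study$annotations
  cp <- ann$chloroplast_name

  qc <- rbindlist(lapply(study$samples, function(s) {
    cr <- conversion_rate(s, cp)
    data.table(sample_id = s$sample_id, tissue = s$tissue, stage = s$stage,
               replicate = s$replicate, conversion_rate = cr$rate,
               pass = cr$pass)
  }))
  fwrite(qc, file.path(out_dir, "qc_conversion.tsv"), sep = "\t")

  glv <- rbindlist(lapply(study$samples, function(s) {
    g <- global_levels(s, exclude_chrom = cp)
    g[, sample_id := s$sample_id]
    g
  }))
  fwrite(glv, file.path(out_dir, "global_levels.tsv"), sep = "\t")

  by_ts <- split(study$samples,
                 vapply(study$samples,
                        function(s) paste(s$tissue, s$stage, sep = "_"),
                        character(1L)))
  dmcs <- list(); dmrs <- list()
  for (tis in c("pulp", "skin")) {
    dmc <- call_dmcs(by_ts[[paste0(tis, "_immature")]],
                     by_ts[[paste0(tis, "_ripe")]],
                     config = comparison, exclude_chrom = cp)
    dmr <- call_dmrs(dmc, config = comparison)
    dmcs[[tis]] <- dmc; dmrs[[tis]] <- dmr
    export_bed(dmr, file.path(out_dir, paste0("dmrs_", tis, ".bed")))
    fwrite(dmr, file.path(out_dir, paste0("dmrs_", tis, ".tsv")), sep = "\t")
    fwrite(dmc_composition(dmc),
           file.path(out_dir, paste0("dmc_composition_", tis, ".tsv")),
           sep = "\t")
  }

  chh_hyper <- lapply(dmrs, function(d)
    as.data.table(d)[context == "CHH" & direction == "hyper"])
  groups <- classify_dmr_groups(chh_hyper$pulp, chh_hyper$skin)
  fwrite(groups$assignments, file.path(out_dir, "dmr_groups.tsv"),
         sep = "\t")

  responsive <- list(); profiles_pb <- list()
  for (tis in c("pulp", "skin")) {
    pb <- promoter_bin_diffs(ann, by_ts[[paste0(tis, "_immature")]],
                             by_ts[[paste0(tis, "_ripe")]])
    profiles_pb[[tis]] <- pb
    responsive[[tis]] <- call_responsive_genes(pb)
    fwrite(responsive[[tis]],
           file.path(out_dir, paste0("responsive_genes_", tis, ".tsv")),
           sep = "\t")
  }
  categories <- classify_gene_tissue_specificity(responsive$pulp,
                                                 responsive$skin)
  integration <- integrate_expression(categories, study$expression)
  fwrite(integration$counts,
         file.path(out_dir, "expression_integration.tsv"), sep = "\t")

  recovery <- score_recovery(study$manifest,
                             pulp_dmrs = dmrs$pulp, skin_dmrs = dmrs$skin,
                             assignments = groups,
                             pulp_responsive = responsive$pulp,
                             skin_responsive = responsive$skin)

  manifest <- list(
    seed = study$manifest$seed,
    package_version = as.character(utils::packageVersion("methylripe")),
    comparison = unclass(comparison),
    n_samples = length(study$samples),
    artifacts = list.files(out_dir, recursive = TRUE),
    recovery = list(dmr = recovery$dmr,
                    group_accuracy = recovery$group_accuracy,
                    responsive = recovery$responsive))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(list(study = study, qc = qc, global_levels = glv, dmcs = dmcs,
                 dmrs = dmrs, groups = groups, responsive = responsive,
                 categories = categories, integration = integration,
                 recovery = recovery, manifest = manifest,
                 out_dir = out_dir))
}
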