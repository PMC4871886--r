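#' Run the full microcosm analysis pipeline
#'
#' Orchestrates simulate (optional) -> grazing -> biomass -> assays ->
#' community over one configuration, writing every stage output plus a run
#' manifest (config snapshot, input digests, seed, stage timings, output
#' inventory) to `out_dir`. The manifest is written even when a stage
#' fails, recording the failing stage.
#'
#' @param config configuration list from [load_config()]; `config$inputs`
#'   may name existing `counts`/`meta`/`taxa`/`otu_table` files, otherwise
#'   `config$preset = "table1_like"` simulates them
#' @param out_dir output directory (created if absent)
#' @return the run manifest, invisibly
#' @export
run_pipeline <- function(config = load_config(), out_dir) {
  if (missing(out_dir)) stopf("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, seed = config$seed,
                   inputs = list(), stages = list(), outputs = character(0))
  started <- Sys.time()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    manifest$stages[[name]] <<- list(seconds = NA)
    res <- fun()
    manifest$stages[[name]] <<- list(seconds = as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  out <- function(name) {
    p <- file.path(out_dir, name)
    manifest$outputs <<- c(manifest$outputs, p)
    p
  }
  write_manifest <- function(failed_stage = NULL) {
    manifest$failed_stage <- failed_stage
    manifest$elapsed_seconds <- as.numeric(Sys.time() - started, units = "secs")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  result <- tryCatch({
    design <- do.call(microcosm_design, config$design)
    inputs <- config$inputs %||% list()
    preset <- config$preset %||% if (length(inputs)) NULL else "table1_like"
    if (!length(inputs) && is.null(preset)) {
      stopf("config must name input files or a simulate preset")
    }

    if (!is.null(preset)) {
      sim <- stage("simulate", function() {
        if (!identical(preset, "table1_like")) stopf("unknown preset '%s'", preset)
        truth <- table1_like_truth(seed = config$seed)
        taxa <- ephyra_prey_taxa()
        counts <- simulate_grazing_experiment(truth)
        profiles <- list(
          T0 = c(Dinophyta = 62, Ciliophora = 8, Stramenopiles = 12,
                 Hacrobia = 7, Rhizaria = 4, Other_Alveolata = 7),
          T24_C = c(Dinophyta = 64, Ciliophora = 7, Stramenopiles = 11,
                    Hacrobia = 7, Rhizaria = 4, Other_Alveolata = 7),
          T24_E = c(Dinophyta = 57, Ciliophora = 3, Stramenopiles = 23,
                    Hacrobia = 7, Rhizaria = 4, Other_Alveolata = 6))
        truth$otu_group_profiles <- profiles
        otus <- simulate_otu_table(truth)
        assays <- simulate_assays(truth)
        write_count_matrix(counts, out("counts.tsv"), out("samples.tsv"))
        write_taxon_table(taxa, out("taxa.tsv"))
        write_otu_table(otus, out("otu_table.tsv"))
        utils::write.table(otus$meta, out("otu_samples.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        list(truth = truth, taxa = taxa, counts = counts, otus = otus,
             assays = assays)
      })
      taxa <- sim$taxa; counts <- sim$counts; otus <- sim$otus
      assay_data <- sim$assays
    } else {
      for (f in unlist(inputs)) {
        manifest$inputs[[f]] <- unname(tools::md5sum(f))
      }
      taxa <- read_taxon_table(inputs$taxa)
      counts <- read_count_matrix(inputs$counts, inputs$meta)
      otus <- if (!is.null(inputs$otu_table)) {
        read_otu_table(inputs$otu_table, inputs$otu_meta %||% inputs$meta)
      } else NULL
      assay_data <- NULL
    }

    est <- stage("grazing", function() {
      est <- estimate_ingestion(counts, taxa, design)
      write_grazing_estimates(est, out("grazing_estimates.tsv"))
      ri <- relative_ingestion(est)
      keep <- est$passed_filter
      idx <- match(names(ri), taxa$taxon_id)
      ra <- 100 * est$c0[keep] / sum(est$c0[keep])
      sel_ab <- selectivity(ri, ra, "relative_initial_abundance")
      per_capita <- est$ingestion_cells_mean[keep] / est$c0[keep]
      sel_bv <- selectivity(per_capita, taxa$biovolume_um3[idx], "biovolume")
      sel <- data.frame(
        covariate = c(sel_ab$covariate, sel_bv$covariate),
        pearson_r = format_num(c(sel_ab$pearson_r, sel_bv$pearson_r)),
        pearson_p = format_num(c(sel_ab$p_values["pearson"], sel_bv$p_values["pearson"])),
        spearman_rho = format_num(c(sel_ab$spearman_rho, sel_bv$spearman_rho)),
        spearman_p = format_num(c(sel_ab$p_values["spearman"], sel_bv$p_values["spearman"])),
        n = c(sel_ab$n, sel_bv$n))
      utils::write.table(sel, out("selectivity.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      est
    })

    stage("biomass", function() {
      bm <- community_biomass(counts, taxa)
      df <- data.frame(taxon_id = rownames(bm), apply(bm, 2, format_num),
                       check.names = FALSE, stringsAsFactors = FALSE)
      utils::write.table(df, out("biomass.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })

    if (!is.null(assay_data)) {
      stage("assays", function() {
        calib <- fit_calibration(assay_data$standards$concentration,
                                 assay_data$standards$fluorescence)
        fl <- assay_data$fluorescence
        amp <- vapply(seq_len(nrow(fl)), function(i) {
          aminopeptidase_rate(fl$f_start[i], fl$f_end[i], fl$blank_start[i],
                              fl$blank_end[i], fl$incubation[i], calib)
        }, numeric(1))
        lc <- assay_data$leucine
        hcp <- vapply(seq_len(nrow(lc)), function(i) {
          leu <- leucine_incorporation(c(lc$dpm_rep1[i], lc$dpm_rep2[i]),
                                       lc$dpm_killed[i], lc$sample_volume[i],
                                       lc$incubation[i], lc$specific_activity[i])
          heterotrophic_carbon_production(leu,
                                          config$assays$leu_to_carbon,
                                          config$assays$isotope_dilution)
        }, numeric(1))
        rates <- data.frame(
          sample_id = c(fl$sample_id, lc$sample_id),
          rate = format_num(c(amp, hcp)),
          units = c(rep("nM_h", length(amp)), rep("ugC_L_h", length(hcp))),
          method = c(rep("aminopeptidase", length(amp)), rep("hcp", length(hcp))))
        utils::write.table(rates, out("assay_rates.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      })
    }

    if (!is.null(otus)) {
      stage("community", function() {
        depth <- min(colSums(otus$counts))
        rar <- rarefy(otus, depth,
                      repeats = config$community$rarefaction_repeats,
                      seed = config$seed)
        prof <- relative_abundance_profile(rar, level = 1,
                                           threshold = config$community$others_threshold_pct)
        write_profile(prof, out("profiles.tsv"))
        ra_full <- sweep(rar$counts, 2, colSums(rar$counts), "/") * 100
        sim_mat <- bray_curtis(ra_full)
        write_similarity(sim_mat, out("similarity.tsv"))
        dend <- upgma(sim_mat)
        write_newick(dend, out("dendrogram.nwk"))
        grp <- paste(rar$meta$timepoint, rar$meta$condition, sep = "_")
        an <- anosim(sim_mat, grp,
                     n_permutations = config$community$anosim_permutations,
                     seed = config$seed)
        utils::write.table(
          data.frame(groups = paste(an$group_labels, collapse = "|"),
                     R = format_num(an$r_statistic), p = format_num(an$p_value),
                     permutations = an$n_permutations, method = an$method),
          out("anosim.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      })
    }

    write_manifest(NULL)
    manifest
  }, error = function(e) {
    failing <- names(manifest$stages)
    write_manifest(if (length(failing)) utils::tail(failing, 1) else "configuration")
    stop(e)
  })
  invisible(result)
}
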