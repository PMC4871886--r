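#' Microplankton groups recognised in taxon tables
#' @export
TAXON_GROUPS <- c(
  "Dinophyceae", "AloricateCiliate", "Tintinnid", "Metazoa",
  "Coccolithophyceae", "Bacillariophyceae", "Mediophyceae",
  "Fragilariophyceae", "Coscinodiscophyceae", "Dictyochophyceae", "Other"
)

#' Carbon-model labels for per-cell quota computation
#' @export
CARBON_MODELS <- c("diatom", "non_diatom", "fixed")

#' Microcosm experimental design
#'
#' Describes the bottle-incubation layout: bottle volume, predators per
#' treatment bottle, incubation duration and replicate counts. Defaults are
#' the study conditions of a 2.2-L bottle experiment with 5 ephyrae per
#' treatment bottle incubated for 1 day, 3 control and 3 treatment bottles.
#'
#' @param volume bottle volume in litres
#' @param n_predators predators per treatment bottle
#' @param duration incubation duration in days
#' @param n_control_reps number of control bottles
#' @param n_treatment_reps number of treatment bottles
#' @return an object of class `microcosm_design`
#' @export
microcosm_design <- function(volume = 2.2, n_predators = 5, duration = 1.0,
                             n_control_reps = 3, n_treatment_reps = 3) {
  if (!is.numeric(volume) || volume <= 0) stopf("volume must be > 0")
  if (n_predators < 1) stopf("n_predators must be >= 1")
  if (duration <= 0) stopf("duration must be > 0")
  structure(
    list(volume = volume, n_predators = n_predators, duration = duration,
         n_control_reps = n_control_reps, n_treatment_reps = n_treatment_reps),
    class = "microcosm_design"
  )
}

#' Validate a taxon record table
#'
#' A taxon table is a data.frame with columns `taxon_id`, `name`, `group`,
#' `biovolume_um3`, `carbon_model` and (for `carbon_model = "fixed"`)
#' `fixed_quota_pg` in pg C per cell.
#'
#' @param taxa data.frame of taxon records
#' @return the validated data.frame, invisibly classed `taxon_table`
#' @export
validate_taxa <- function(taxa) {
  req <- c("taxon_id", "group", "biovolume_um3", "carbon_model")
  miss <- setdiff(req, names(taxa))
  if (length(miss)) stopf("taxon table missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(taxa$taxon_id)) {
    stopf("duplicate taxon_id: %s",
          paste(unique(taxa$taxon_id[duplicated(taxa$taxon_id)]), collapse = ", "))
  }
  bad <- !(taxa$group %in% TAXON_GROUPS)
  if (any(bad)) stopf("unknown group(s): %s", paste(unique(taxa$group[bad]), collapse = ", "))
  if (any(!is.finite(taxa$biovolume_um3) | taxa$biovolume_um3 <= 0)) {
    stopf("biovolume must be > 0 for all taxa")
  }
  bad <- !(taxa$carbon_model %in% CARBON_MODELS)
  if (any(bad)) stopf("unknown carbon_model(s): %s",
                      paste(unique(taxa$carbon_model[bad]), collapse = ", "))
  fx <- taxa$carbon_model == "fixed"
  if (any(fx)) {
    if (!"fixed_quota_pg" %in% names(taxa) ||
        any(!is.finite(taxa$fixed_quota_pg[fx]) | taxa$fixed_quota_pg[fx] <= 0)) {
      stopf("fixed_quota_pg must be > 0 for every taxon with carbon_model = 'fixed'")
    }
  }
  if (!"name" %in% names(taxa)) taxa$name <- taxa$taxon_id
  class(taxa) <- unique(c("taxon_table", class(taxa)))
  invisible(taxa)
}

#' Read a taxon record table from TSV
#' @param path TSV with columns taxon_id, name, group, biovolume_um3,
#'   carbon_model, fixed_quota_pg
#' @return a validated `taxon_table` data.frame
#' @export
read_taxon_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_taxa(df)
}

#' Write a taxon record table to TSV
#' @param taxa taxon table
#' @param path output path
#' @export
write_taxon_table <- function(taxa, path) {
  utils::write.table(taxa, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sample metadata ----------------------------------------------------

#' Read sample metadata (sidecar TSV)
#'
#' Columns: `sample_id`, `timepoint` (T0/T24), `condition`
#' (control/treatment), `replicate` (integer >= 1).
#'
#' @param path TSV path
#' @return data.frame of sample metadata
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_meta(meta)
}

validate_sample_meta <- function(meta) {
  req <- c("sample_id", "timepoint", "condition", "replicate")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stopf("sample metadata missing columns: %s", paste(miss, collapse = ", "))
  if (!all(meta$timepoint %in% c("T0", "T24"))) stopf("timepoint must be T0 or T24")
  if (!all(meta$condition %in% c("control", "treatment"))) {
    stopf("condition must be control or treatment")
  }
  if (any(meta$replicate < 1)) stopf("replicate must be >= 1")
  key <- paste(meta$timepoint, meta$condition, meta$replicate)
  if (anyDuplicated(key)) {
    stopf("duplicate (timepoint, condition, replicate): %s", key[duplicated(key)][1])
  }
  if (anyDuplicated(meta$sample_id)) stopf("duplicate sample_id in metadata")
  meta
}

# ---- count matrix -------------------------------------------------------

#' Construct a validated count matrix
#'
#' @param values numeric matrix of abundances (cells per litre), taxa in rows
#'   (rownames = taxon_id), samples in columns (colnames = sample_id)
#' @param meta sample metadata data.frame (see [read_sample_meta()])
#' @return an object of class `count_matrix`
#' @export
count_matrix <- function(values, meta) {
  meta <- validate_sample_meta(meta)
  if ((nrow(values) > 0 && is.null(rownames(values))) || is.null(colnames(values))) {
    stopf("count matrix needs taxon_id rownames and sample_id colnames")
  }
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_meta)) {
    stopf("sample(s) without metadata row: %s", paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stopf("negative abundance at taxon '%s', sample '%s'",
          rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]])
  }
  structure(list(values = values, meta = meta), class = "count_matrix")
}

#' Read a count matrix (cells per litre) with its sample metadata
#'
#' @param path TSV: header row of sample ids, first column `taxon_id`
#' @param meta path to the sample-metadata TSV
#' @return a `count_matrix`
#' @export
read_count_matrix <- function(path, meta) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "taxon_id") stopf("first column of %s must be 'taxon_id'", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$taxon_id
  md <- if (is.character(meta)) read_sample_meta(meta) else validate_sample_meta(meta)
  cm <- count_matrix(m, md)
  mg_log("core_io", "read count matrix: %d taxa x %d samples from %s",
         nrow(m), ncol(m), path)
  cm
}

#' Write a count matrix to TSV (values) and its metadata sidecar
#' @param x a `count_matrix`
#' @param path output TSV for the values
#' @param meta_path optional output TSV for the sample metadata
#' @export
write_count_matrix <- function(x, path, meta_path = NULL) {
  df <- data.frame(taxon_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d taxa x %d samples (cells L^-1)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# convenience selectors used throughout the pipeline
samples_where <- function(x, timepoint = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(x$meta))
  if (!is.null(timepoint)) keep <- keep & x$meta$timepoint == timepoint
  if (!is.null(condition)) keep <- keep & x$meta$condition == condition
  x$meta$sample_id[keep]
}

# ---- OTU table ----------------------------------------------------------

#' Construct a validated OTU table
#'
#' @param counts integer matrix of reads, OTUs in rows (rownames = otu_id),
#'   samples in columns
#' @param lineages character vector of rank-delimited lineage strings
#'   (`domain;phylum;...;genus`), one per OTU; "Unclassified" allowed
#' @param meta sample metadata data.frame
#' @return an object of class `otu_table`
#' @export
otu_table <- function(counts, lineages, meta) {
  meta <- validate_sample_meta(meta)
  if (is.null(rownames(counts))) stopf("OTU table needs otu_id rownames")
  if (anyDuplicated(rownames(counts))) {
    stopf("duplicate OTU id: %s", rownames(counts)[duplicated(rownames(counts))][1])
  }
  if (length(lineages) != nrow(counts)) stopf("one lineage string required per OTU")
  if (any(is.na(lineages) | !nzchar(lineages))) stopf("empty lineage string; use 'Unclassified'")
  bad <- which(counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-integer or negative count at OTU '%s', sample '%s'",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  }
  missing_meta <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing_meta)) {
    stopf("sample(s) without metadata row: %s", paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, lineages = stats::setNames(lineages, rownames(counts)),
                 meta = meta),
            class = "otu_table")
}

#' Read a classic tab-separated OTU table
#'
#' First column OTU id, last column the taxonomy lineage, middle columns
#' per-sample integer read counts.
#'
#' @param path OTU table TSV
#' @param meta path to (or data.frame of) sample metadata
#' @return an `otu_table`
#' @export
read_otu_table <- function(path, meta) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3) stopf("OTU table %s must have id, >=1 sample and a lineage column", path)
  last <- names(df)[ncol(df)]
  if (tolower(last) != "taxonomy") {
    stopf("OTU table %s: last column must be the 'taxonomy' lineage column", path)
  }
  ids <- df[[1]]
  lineages <- df[[ncol(df)]]
  mid <- df[, -c(1, ncol(df)), drop = FALSE]
  m <- suppressWarnings(vapply(mid, as.numeric, numeric(nrow(mid))))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(mid), dimnames = list(NULL, names(mid)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("non-numeric count at OTU '%s', sample '%s'", ids[bad[1]], colnames(m)[bad[2]])
  }
  rownames(m) <- ids
  md <- if (is.character(meta)) read_sample_meta(meta) else validate_sample_meta(meta)
  ot <- otu_table(m, lineages, md)
  mg_log("core_io", "read OTU table: %d OTUs x %d samples from %s",
         nrow(m), ncol(m), path)
  ot
}

#' Write an OTU table in the classic tab-separated layout
#' @param x an `otu_table`
#' @param path output TSV
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(otu_id = rownames(x$counts), x$counts,
                   taxonomy = unname(x$lineages),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d samples, total reads %d\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

# ---- configuration ------------------------------------------------------

#' Default pipeline configuration
#'
#' Study constants: 2.2-L bottles, 5 predators, 1-day incubation; carbon
#' conversions (20/200 fg C per prokaryote cell, 183 fg C per cubic micron of
#' nanoplankton biovolume, allometric coefficients); leucine-to-carbon
#' 1.55 kg C per mol with twofold isotope dilution at specific activity
#' 52.9 Ci per mmol; community-statistics defaults (100 rarefaction repeats,
#' 999 ANOSIM permutations, 1% 'Others' threshold).
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    design = list(volume = 2.2, n_predators = 5, duration = 1.0,
                  n_control_reps = 3, n_treatment_reps = 3),
    carbon = list(diatom_a = 0.288, diatom_b = 0.811,
                  protist_a = 0.216, protist_b = 0.939,
                  het_prok_fg = 20, synechococcus_fg = 200,
                  nano_fg_per_um3 = 183,
                  nano_class_diameters = c(2.5, 4.0, 7.5)),
    assays = list(leu_to_carbon = 1.55, isotope_dilution = 2,
                  specific_activity = 52.9, dpm_per_ci = 2.22e12),
    community = list(rarefaction_repeats = 100, anosim_permutations = 999,
                     others_threshold_pct = 1.0),
    seed = 1
  )
}

#' Load a pipeline configuration file
#'
#' YAML-style key/value file; absent keys take the defaults of
#' [default_config()]; unknown keys are logged as warnings, not fatal.
#'
#' @param path config file path, or NULL for pure defaults
#' @return nested configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_section <- function(base, upd, prefix) {
    for (k in names(upd)) {
      if (!k %in% names(base)) {
        mg_warn("config", "unknown key '%s%s' ignored", prefix, k)
      } else if (is.list(base[[k]]) && is.list(upd[[k]])) {
        base[[k]] <- merge_section(base[[k]], upd[[k]], paste0(prefix, k, "."))
      } else {
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  merge_section(cfg, user, "")
}
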