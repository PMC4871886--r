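#' Per-cell carbon quota of a protist from its biovolume
#'
#' Allometric carbon-to-volume relationships for marine protists:
#' diatoms `pg C = 0.288 * V^0.811`, non-diatom protists
#' `pg C = 0.216 * V^0.939`, with V the cell biovolume in cubic microns.
#' Diatoms are less carbon-dense per unit volume because of the vacuole.
#'
#' @param biovolume cell biovolume in cubic microns (> 0); vectorised
#' @param model "diatom" or "non_diatom"
#' @return per-cell carbon quota in pg C
#' @export
protist_carbon_quota <- function(biovolume, model = c("non_diatom", "diatom")) {
  model <- match.arg(model)
  if (any(!is.finite(biovolume) | biovolume <= 0)) stopf("biovolume must be > 0")
  if (model == "diatom") 0.288 * biovolume^0.811 else 0.216 * biovolume^0.939
}

#' Biovolume of a sphere from its diameter
#' @param diameter sphere diameter in microns (> 0)
#' @return volume in cubic microns, `pi * d^3 / 6`
#' @export
sphere_biovolume <- function(diameter) {
  if (any(!is.finite(diameter) | diameter <= 0)) stopf("diameter must be > 0")
  pi * diameter^3 / 6
}

#' Nanoplankton carbon biomass from size-class abundances
#'
#' Cells are approximated as spheres at the mean diameter of each size class
#' (2-3, 3-5 and 5-10 micron classes; class means 2.5, 4.0, 7.5 microns) and
#' converted at 183 fg C per cubic micron.
#'
#' @param counts numeric vector of length 3: abundance (cells per litre) in
#'   the 2-3, 3-5 and 5-10 micron classes
#' @param class_diameters mean diameters of the classes, microns
#' @param fg_per_um3 carbon density, fg C per cubic micron
#' @return biomass in micrograms C per litre
#' @export
nanoplankton_biomass <- function(counts, class_diameters = c(2.5, 4.0, 7.5),
                                 fg_per_um3 = 183) {
  if (length(counts) != length(class_diameters)) {
    stopf("one abundance per size class required (%d classes)", length(class_diameters))
  }
  if (any(counts < 0)) stopf("abundances must be >= 0")
  fg_per_l <- sum(counts * sphere_biovolume(class_diameters) * fg_per_um3)
  fg_per_l * 1e-9  # fg -> ug
}

#' Prokaryote carbon biomass from cell abundance
#'
#' Fixed per-cell factors: 20 fg C per heterotrophic prokaryote cell and
#' 200 fg C per *Synechococcus* cell.
#'
#' @param abundance cells per litre (>= 0)
#' @param kind "heterotroph" or "synechococcus"
#' @return biomass in micrograms C per litre
#' @export
prokaryote_biomass <- function(abundance, kind = c("heterotroph", "synechococcus")) {
  kind <- match.arg(kind)
  if (any(abundance < 0)) stopf("abundance must be >= 0")
  fg <- if (kind == "heterotroph") 20 else 200
  abundance * fg * 1e-9
}

# per-cell quota (pg C) for every row of a taxon table, honouring the
# carbon_model column (fixed quotas override the allometric equations)
taxon_quotas <- function(taxa) {
  taxa <- validate_taxa(taxa)
  q <- numeric(nrow(taxa))
  for (i in seq_len(nrow(taxa))) {
    q[i] <- switch(taxa$carbon_model[i],
      diatom = protist_carbon_quota(taxa$biovolume_um3[i], "diatom"),
      non_diatom = protist_carbon_quota(taxa$biovolume_um3[i], "non_diatom"),
      fixed = taxa$fixed_quota_pg[i]
    )
  }
  stats::setNames(q, taxa$taxon_id)
}

#' Carbon biomass matrix of a counted community
#'
#' Multiplies each abundance (cells per litre) by the taxon's per-cell carbon
#' quota. All internal carbon arithmetic is in pg; the result is reported in
#' micrograms C per litre.
#'
#' @param counts a [count_matrix()]
#' @param taxa a taxon table resolving every counted taxon
#' @return matrix of biomass (ug C per litre), same layout as the counts
#' @export
community_biomass <- function(counts, taxa) {
  q <- taxon_quotas(taxa)
  unresolved <- setdiff(rownames(counts$values), names(q))
  if (length(unresolved)) {
    stopf("taxa without a carbon model: %s", paste(unresolved, collapse = ", "))
  }
  counts$values * q[rownames(counts$values)] * 1e-6  # pg -> ug
}
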