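options(micrograze.verbose = FALSE)

# ---- fixture builders ---------------------------------------------------

toy_meta <- function(t0 = 2, ctl = 2, trt = 2) {
  rbind(
    data.frame(sample_id = sprintf("T0_%d", seq_len(t0)), timepoint = "T0",
               condition = "control", replicate = seq_len(t0)),
    data.frame(sample_id = sprintf("C%d", seq_len(ctl)), timepoint = "T24",
               condition = "control", replicate = seq_len(ctl)),
    data.frame(sample_id = sprintf("E%d", seq_len(trt)), timepoint = "T24",
               condition = "treatment", replicate = seq_len(trt))
  )
}

toy_taxa <- function(ids, biovolume = 1000, model = "non_diatom") {
  validate_taxa(data.frame(
    taxon_id = ids, name = ids, group = "Other",
    biovolume_um3 = biovolume, carbon_model = model,
    fixed_quota_pg = NA_real_, stringsAsFactors = FALSE))
}

toy_otu <- function(counts, meta, lineages = NULL) {
  if (is.null(lineages)) lineages <- rep("Bacteria;ToyPhylum", nrow(counts))
  otu_table(counts, lineages, meta)
}

# ---- independent oracles ------------------------------------------------

# Mann-Whitney via pairwise comparisons (a different route to U than the
# rank-sum formula) and full enumeration of index assignments
oracle_mann_whitney <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(x, y)
  pooled <- c(x, y)
  m <- length(x)
  combs <- utils::combn(length(pooled), m)
  us <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p <- 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9))
  list(U = u_obs, p_value = min(1, p))
}

# ANOSIM R straight from the definition, explicit loops
oracle_anosim_r <- function(sim, labels) {
  n <- ncol(sim)
  d <- 100 - unclass(sim)
  dv <- c(); within <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dv <- c(dv, d[i, j]); within <- c(within, labels[i] == labels[j])
  }
  rk <- rank(dv)
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

# all 2+2 partitions of 4 samples, for brute-force ANOSIM comparison
partitions_2_2 <- function() list(c("a", "a", "b", "b"),
                                  c("a", "b", "a", "b"),
                                  c("a", "b", "b", "a"))
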