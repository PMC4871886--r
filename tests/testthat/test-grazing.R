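test_that("missing-taxon substitution only touches T24 treatment zeros", {
  meta <- toy_meta()
  m <- matrix(c(50, 50,  60, 60,  0, 5,   # present at T0, one treatment zero
                0, 0,    0, 0,    0, 0),  # absent everywhere: not resurrected
              nrow = 2, byrow = TRUE,
              dimnames = list(c("present", "absent"), meta$sample_id))
  cm <- count_matrix(m, meta)
  out <- apply_missing_taxon_rule(cm)
  expect_equal(out$values["present", "E1"], 1)
  expect_equal(out$values["present", "E2"], 5)
  expect_equal(out$values["absent", ], setNames(rep(0, 6), meta$sample_id))
  # controls untouched even when zero
  m2 <- m; m2["present", "C1"] <- 0
  out2 <- apply_missing_taxon_rule(count_matrix(m2, meta))
  expect_equal(out2$values["present", "C1"], 0)
  # no zeros -> identity
  m3 <- matrix(2, 2, 6, dimnames = dimnames(m))
  expect_equal(apply_missing_taxon_rule(count_matrix(m3, meta))$values, m3)
})

test_that("growth and grazing coefficients follow the exponential model", {
  expect_equal(growth_coefficient(100, 200, 1), log(2), tolerance = 1e-12)
  expect_equal(growth_coefficient(100, 100, 1), 0)
  expect_equal(growth_coefficient(100, 50, 2), -0.34657, tolerance = 1e-4)
  expect_error(growth_coefficient(0, 10, 1), "> 0")
  expect_equal(grazing_coefficient(100, 100, 1, log(2)), log(2))
  expect_equal(grazing_coefficient(100, 50, 1, 0), log(2))
  # treatment on the control trajectory -> no grazing
  expect_equal(grazing_coefficient(100, 200, 1, growth_coefficient(100, 200, 1)), 0)
})

test_that("time-averaged concentration matches the ODE integral", {
  expect_identical(mean_concentration(100, 0.5, 0.5, 1), 100)
  expect_equal(mean_concentration(100, log(2), 0, 1), 100 / log(2), tolerance = 1e-12)
  expect_equal(mean_concentration(100, 0, log(2), 1), 50 / log(2), tolerance = 1e-12)
  # numerical-integration oracle over a range of net rates
  for (r in c(-5, -1.3, -0.2, 0.2, 1.7, 5)) {
    num <- stats::integrate(function(s) 100 * exp(r * s), 0, 2)$value / 2
    expect_equal(mean_concentration(100, r, 0, 2), num, tolerance = 1e-8)
  }
})

test_that("clearance and ingestion arithmetic is g*V/n and F*<C>", {
  d <- microcosm_design(volume = 2.2, n_predators = 5)
  ir <- ingestion_rate(log(2), 100, d)
  expect_equal(ir$clearance, 0.30497, tolerance = 1e-4)
  expect_equal(ir$ingestion, 30.497, tolerance = 1e-3)
  expect_equal(ingestion_rate(0, 100, d)$ingestion, 0)
  d2 <- microcosm_design(volume = 2.2, n_predators = 10)
  expect_equal(ingestion_rate(log(2), 100, d2)$ingestion, ir$ingestion / 2)
})

test_that("treatment identical to control gives zero ingestion everywhere", {
  meta <- toy_meta(3, 3, 3)
  set.seed(1)
  t0 <- matrix(rpois(5 * 3, 100), 5)
  t24 <- matrix(rep(rpois(5, 110), 3), 5)  # identical control replicates
  m <- cbind(t0, t24, t24)                 # T24 treatment == T24 control
  dimnames(m) <- list(paste0("t", 1:5), meta$sample_id)
  cm <- count_matrix(m, meta)
  est <- estimate_ingestion(cm, toy_taxa(paste0("t", 1:5)))
  expect_equal(est$ingestion_cells_mean, rep(0, 5), tolerance = 1e-12)
  expect_false(any(est$passed_filter))
  expect_error(relative_ingestion(est), "no taxon passed")
})

test_that("carbon ingestion is exactly cells ingestion times the quota", {
  tr <- table1_like_truth(seed = 11)
  cm <- simulate_grazing_experiment(tr)
  taxa <- ephyra_prey_taxa()
  est <- estimate_ingestion(cm, taxa)
  q <- vapply(match(est$taxon_id, taxa$taxon_id), function(i) {
    protist_carbon_quota(taxa$biovolume_um3[i], taxa$carbon_model[i])
  }, numeric(1))
  expect_equal(est$ingestion_carbon_mean, est$ingestion_cells_mean * q * 1e-6)
  expect_equal(est$ingestion_carbon_sd, est$ingestion_cells_sd * q * 1e-6)
  expect_true(all(est$ingestion_cells_sd >= 0))
  expect_equal(est$passed_filter,
               est$ingestion_cells_mean > 2 * est$ingestion_cells_sd &
                 est$ingestion_cells_mean > 0)
})

test_that("taxa absent at T0 are excluded, not fabricated", {
  meta <- toy_meta()
  m <- matrix(c(100, 100, 120, 120, 60, 70,
                0, 0, 3, 2, 1, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("ok", "ghost"), meta$sample_id))
  est <- estimate_ingestion(count_matrix(m, meta), toy_taxa(c("ok", "ghost")))
  expect_identical(est$taxon_id, "ok")
})

test_that("relative ingestion is a percentage over filtered taxa", {
  est <- data.frame(taxon_id = c("a", "b", "c"),
                    ingestion_cells_mean = c(30, 10, 99),
                    passed_filter = c(TRUE, TRUE, FALSE))
  ri <- relative_ingestion(est)
  expect_equal(unname(ri), c(75, 25))
  expect_equal(sum(ri), 100, tolerance = 1e-9)
  est1 <- est[1, ]
  expect_equal(unname(relative_ingestion(est1)), 100)
})

test_that("selectivity reports Pearson and Spearman with rank ties averaged", {
  s <- selectivity(1:10, 1:10)
  expect_equal(s$pearson_r, 1)
  expect_equal(s$spearman_rho, 1)
  # hand-computed rank example: rho = 1 - 6*sum(d^2)/(n(n^2-1)) = 0.8
  s2 <- selectivity(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(s2$spearman_rho, 0.8)
  expect_warning(s3 <- selectivity(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(s3$pearson_r))
  expect_error(selectivity(1:2, 1:2), ">= 3")
})
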