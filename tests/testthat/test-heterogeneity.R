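test_that("collapsed ranges give exact midpoints", {
  sp <- heterogeneity_spec(P = 0)
  d <- sample_population(sp, 20, 20, seed = 1)
  expect_equal(unique(d$C50), 18)
  expect_equal(unique(d$n_exp), 1.4)
  expect_equal(unique(d$nu_max), 4)
  expect_gt(diff(range(d$g_Ks[d$pop == "E"])), 1) # intrinsic fully spread
  sp1 <- heterogeneity_spec(P = 1)
  d1 <- sample_population(sp1, 20, 20, seed = 1)
  expect_equal(unique(d1$g_Ks[d1$pop == "E"]), 3.5)
  expect_equal(unique(d1$g_Ks[d1$pop == "I"]), 0.6)
  expect_equal(unique(d1$E_L), -72.5)
  expect_gt(diff(range(d1$C50)), 5)
})

test_that("draws stay inside the P-scaled ranges", {
  sp <- heterogeneity_spec(P = 0.5)
  d <- sample_population(sp, 400, 400, seed = 2)
  expect_true(all(d$C50 >= 13 & d$C50 <= 23))        # [8,28] narrowed by 0.5
  expect_true(all(d$n_exp >= 1.2 & d$n_exp <= 1.6))
  expect_true(all(d$nu_max >= 3.75 & d$nu_max <= 4.25))
  gE <- d$g_Ks[d$pop == "E"]
  expect_true(all(gE >= 2 & gE <= 5))                # [0.5,6.5] narrowed by 0.5
  expect_true(all(d$E_L >= -75 & d$E_L <= -70))
  expect_error(heterogeneity_spec(P = 1.4), class = "ringcrf_parameter_error")
})

test_that("sampling is reproducible from the seed", {
  sp <- heterogeneity_spec(P = 0.7)
  expect_identical(sample_population(sp, 30, 30, seed = 5),
                   sample_population(sp, 30, 30, seed = 5))
})

test_that("heterogeneous parameters are wired into the network", {
  sp <- heterogeneity_spec(P = 0)
  het <- sample_population(sp, 24, 24, seed = 3)
  net <- build_network(24, 24, het = het)
  expect_equal(net$pars[1:24, 9], het$g_Ks[het$pop == "E"])
  expect_equal(net$pars[25:48, 2], het$E_L[het$pop == "I"])
  sp1 <- heterogeneity_spec(P = 1)
  het1 <- sample_population(sp1, 24, 24, seed = 3)
  net1 <- build_network(24, 24, het = het1)
  expect_equal(net1$lgn_het$C50[1:24], het1$C50[het1$pop == "E"])
})

test_that("a tiny heterogeneity experiment runs end to end with traceable seeds", {
  sp <- heterogeneity_spec(P = 1)
  res <- run_heterogeneity_experiment(
    sp, N_E = 48, N_I = 48, contrasts = crf_contrast_grid(7),
    trials = 1, n_orientations = 3, T = 700, transient = 300, seed = 4)
  expect_s3_class(res$fits, "tbl_df")
  expect_equal(nrow(res$fits), 96)
  expect_true(all(c("R_max", "C50", "n_exp", "good", "class") %in% names(res$fits)))
  expect_gte(res$good_fraction[["overall"]], 0)
  # rerun with the same seed reproduces the fits exactly
  res2 <- run_heterogeneity_experiment(
    sp, N_E = 48, N_I = 48, contrasts = crf_contrast_grid(7),
    trials = 1, n_orientations = 3, T = 700, transient = 300, seed = 4)
  expect_identical(res$fits$R_max, res2$fits$R_max)
})
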