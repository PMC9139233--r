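test_that("default profiles encode the documented phenotypes", {
  p <- default_profiles()
  expect_setequal(names(p), cll_classes())
  loc <- function(cls, ch, prof = p) prof[[cls]][[1]]$loc[[ch]]
  # CLL is CD5+ CD19+ CD200-bright with dim CD20; polytypic B is CD5-
  expect_gt(loc("CLL_cells", "CD5-BV480"), loc("B_cells", "CD5-BV480"))
  expect_lt(loc("CLL_cells", "CD20-APC-H7"), loc("B_cells", "CD20-APC-H7"))
  expect_gt(loc("CLL_cells", "CD200-BV421"), loc("B_cells", "CD200-BV421"))
  # atypical variant raises CLL CD20 above the default
  pa <- default_profiles(atypical_cd20_bright = TRUE)
  expect_gt(loc("CLL_cells", "CD20-APC-H7", pa),
            loc("CLL_cells", "CD20-APC-H7", p))
  # kappa restriction mirrors to lambda on request
  pl <- default_profiles(cll_lambda_restricted = TRUE)
  expect_gt(loc("CLL_cells", "Lambda-PE", pl), loc("CLL_cells", "Kappa-FITC", pl))
  expect_gt(loc("CLL_cells", "Kappa-FITC", p), loc("CLL_cells", "Lambda-PE", p))
  # every profile spreads are positive across all 13 channels
  for (cls in names(p)) {
    for (comp in p[[cls]]) {
      expect_length(comp$loc, 13L)
      expect_true(all(comp$sd > 0))
    }
  }
})

test_that("spillover matrix is diagonal-dominant and invertible", {
  s <- default_spillover()
  expect_equal(dim(s), c(10L, 10L))
  expect_true(all(diag(s) >= 0.7))
  expect_true(all(s >= 0))
  expect_gt(abs(det(s)), 1e-6)  # nonsingular: compensation possible
})

test_that("simulate_case is seed-deterministic and honors CLL fraction", {
  cfg <- case_config(n_events = 3000, seed = 7)
  a <- simulate_case(cfg)
  b <- simulate_case(cfg)
  expect_identical(unclass(a$events)[, ], unclass(b$events)[, ])
  expect_identical(a$truth, b$truth)
  z <- simulate_case(case_config(n_events = 3000,
                                 cll_fraction_of_wbc = 0, seed = 8))
  expect_equal(sum(z$truth == "CLL_cells"), 0L)
  expect_error(case_config(class_fractions = c(CLL_cells = 0.9,
                                               T_cells = 0.3)),
               "sum")
})

test_that("aggregates carry the doublet scatter signature", {
  cs <- simulate_case(case_config(n_events = 20000, seed = 3))
  ev <- unclass(cs$events)
  ratio_agg <- ev[cs$truth == "aggregates", 1] /
    ev[cs$truth == "aggregates", 2]
  ratio_single <- ev[cs$truth == "T_cells", 1] /
    ev[cs$truth == "T_cells", 2]
  # doublets: area well above height; singlets: area ~ height
  expect_gt(median(ratio_agg), 1.25 * median(ratio_single))
  expect_lt(median(ratio_single), 1.3)
})

test_that("realized CLL count stays inside the binomial sampling band", {
  # fraction applies to the WBC compartment (78% of events by default)
  cfg <- case_config(n_events = 1e6, cll_fraction_of_wbc = 2e-4, seed = 13)
  cs <- simulate_case(cfg)
  expected <- 2e-4 * 0.78 * 1e6
  band <- 4 * sqrt(expected)
  got <- sum(cs$truth == "CLL_cells")
  expect_gt(got, expected - band)
  expect_lt(got, expected + band)
})

test_that("realized class counts follow the configured multinomial", {
  fr <- case_config()$class_fractions  # effective (remainder applied)
  expect_equal(sum(fr), 1)
  pooled <- rep(0, 14)
  for (s in 1:20) {
    cs <- simulate_case(case_config(n_events = 4000, seed = 1000 + s))
    pooled <- pooled + c(table(factor(cs$truth, levels = cll_classes())))
  }
  gof <- suppressWarnings(
    stats::chisq.test(pooled, p = fr[cll_classes()])
  )
  expect_gt(gof$p.value, 0.001)
})

test_that("spike-in dilutions hit their targets within sampling error", {
  donor <- simulate_case(case_config(n_events = 20000,
                                     cll_fraction_of_wbc = 0.4,
                                     case_id = "donor", seed = 21))
  bg <- simulate_case(case_config(n_events = 5e5, cll_fraction_of_wbc = 0,
                                  case_id = "bg", seed = 22))
  plan <- dilution_plan(donor, bg, target_fractions = 1e-3,
                        replicates = 3, seed = 5)
  spiked <- spike_dilution(plan)
  expect_length(spiked, 3L)
  wbc_bg <- sum(!bg$truth %in% c("aggregates", "debris"))
  expected <- 1e-3 * wbc_bg
  for (cs in spiked) {
    k <- sum(cs$truth == "CLL_cells")
    expect_lt(abs(k - expected), 4 * sqrt(expected))
    expect_equal(nrow(cs$events), nrow(bg$events) + k)
  }
  # replicates are distinct draws
  expect_false(identical(spiked[[1]]$truth, spiked[[2]]$truth))
})

test_that("spiked-fraction estimator is unbiased across replicates", {
  donor <- simulate_case(case_config(n_events = 10000,
                                     cll_fraction_of_wbc = 0.4,
                                     case_id = "donor", seed = 31))
  bg <- simulate_case(case_config(n_events = 20000, cll_fraction_of_wbc = 0,
                                  case_id = "bg", seed = 32))
  target <- 0.02
  plan <- dilution_plan(donor, bg, target_fractions = target,
                        replicates = 60, seed = 6)
  realized <- vapply(spike_dilution(plan), `[[`, numeric(1),
                     "true_cll_fraction")
  se <- stats::sd(realized) / sqrt(length(realized))
  expect_lt(abs(mean(realized) - target), 2 * se + 1e-4)
})

test_that("dilution plans validate their preconditions", {
  donor <- tiny_case(n = 1000, cll_frac = 0.3, seed = 41, case_id = "d")
  bg <- tiny_case(n = 1000, cll_frac = 0, seed = 42, case_id = "b")
  expect_error(dilution_plan(bg, bg), "no CLL truth events")
  expect_error(dilution_plan(donor, donor), "CLL-free")
  expect_error(dilution_plan(donor, bg, target_fractions = 0), "\\(0, 1\\)")
})

test_that("cohorts mix MRD status and low-count roles as configured", {
  cohort <- make_cohort(202, mrd_positive_fraction = 143 / 202,
                        low_count_fraction = 0.55, n_events = 5000,
                        seed = 77)
  man <- cohort_manifest(cohort)
  expect_equal(nrow(man), 202L)
  expect_equal(sum(man$role != "negative"), 143L)
  expect_equal(sum(man$role == "negative"), 59L)
  # conservation: manifest counts match the cases
  expect_equal(sum(man$n_events),
               sum(vapply(cohort, function(cs) nrow(cs$events), numeric(1))))
  expect_identical(man$true_cll_count,
                   vapply(cohort, function(cs)
                     sum(cs$truth == "CLL_cells"), integer(1),
                     USE.NAMES = FALSE))
  # atypical phenotype only enters through high-burden cases
  expect_true(all(man$role[man$atypical] == "high"))
})

test_that("low_count_fraction = 1 keeps every positive case under 1000", {
  cohort <- make_cohort(8, mrd_positive_fraction = 0.75,
                        low_count_fraction = 1, n_events = 8000, seed = 55)
  man <- cohort_manifest(cohort)
  pos <- man[man$true_status == "MRD_positive", ]
  expect_gt(nrow(pos), 0)
  expect_true(all(pos$true_cll_count < 1000))
  expect_error(make_cohort(0), "n_cases")
})
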