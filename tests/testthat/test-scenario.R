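sv <- study_variables()

test_that("scenario grids enumerate the Cartesian product, outermost slowest", {
  s1 <- scenario_spec(grid = list(recognition = sv$recognition))
  expect_equal(nrow(scenario_grid(s1)), 3)
  s2 <- scenario_spec(grid = list(job_demand = sv$job_demand,
                                  control = sv$control,
                                  colleague_support = sv$colleague_support))
  g <- scenario_grid(s2)
  expect_equal(nrow(g), 18)
  # nested layout: job demand varies slowest, colleague support fastest
  expect_equal(as.character(g$job_demand[1:6]), rep(sv$job_demand[1], 6))
  expect_equal(as.character(g$colleague_support[1:3]), sv$colleague_support)
  # empty grid: single baseline row
  expect_equal(nrow(scenario_grid(scenario_spec())), 1)
  expect_error(scenario_spec(grid = list(control = "Yes", control = "No")),
               "duplicate")
  expect_error(scenario_spec(grid = list(stress = "Yes")), "target")
})

test_that("preset scenario tables reproduce the published row structures and labels", {
  expect_equal(nrow(scenario_grid(scenario_preset("table4"))), 4)
  g5 <- scenario_grid(scenario_preset("table5"))
  expect_equal(nrow(g5), 18)
  expect_setequal(unique(g5$colleague_support), sv$colleague_support)
  expect_equal(nrow(scenario_grid(scenario_preset("table6"))), 18)
  g7 <- scenario_grid(scenario_preset("table7"))
  expect_equal(nrow(g7), 6)
  expect_equal(scenario_preset("table7")$fixed,
               list(job_demand = "All & almost all of the time",
                    control = "No"))
  g8 <- scenario_grid(scenario_preset("table8"))
  expect_equal(nrow(g8), 12)
  expect_setequal(unique(g8$age_group), sv$age_group)
})

test_that("sensitivity percentages come from the exact posterior and honour d-separation", {
  gt <- build_ground_truth(generator_config())
  spec <- scenario_preset("table5")
  tab <- sensitivity_table(gt$bn, spec)
  expect_equal(nrow(tab), 18)
  expect_true(all(tab$stressed_pct >= 0 & tab$stressed_pct <= 100))
  expect_false(any(tab$zero_mass))
  # oracle equivalence on a few rows
  for (i in c(1, 9, 18)) {
    ev <- lapply(tab[i, names(spec$grid)], as.character)
    expect_equal(tab$stressed_pct[i],
                 100 * posterior_oracle(gt$bn, "stress", ev)[["Yes"]],
                 tolerance = 1e-9)
  }
  # monotone stress mechanism: higher demand never lowers the posterior
  # within the same control/support cell
  for (j in 1:6) {
    col <- tab$stressed_pct[c(j, j + 6, j + 12)]  # high/mid/low job demand
    expect_true(all(diff(col) <= 1e-9))
  }
  # a target d-separated from the grid: all rows equal the marginal
  flat <- new_bn(new_dag(c("stress", "control"),
                         NULL),
                 list(stress = sv$stress, control = sv$control),
                 list(stress = c(0.4, 0.6), control = c(0.5, 0.5)))
  ft <- sensitivity_table(flat, scenario_spec(grid = list(control = sv$control)))
  expect_equal(ft$stressed_pct, c(40, 40), tolerance = 1e-12)
})

test_that("weight sign flips reverse the corresponding posterior ordering", {
  up <- build_ground_truth(generator_config(n = 10))
  w <- default_stress_weights()
  w$job_demand <- -w$job_demand
  down <- build_ground_truth(generator_config(n = 10, weights = w))
  spec <- scenario_spec(grid = list(job_demand = sv$job_demand))
  t_up <- sensitivity_table(up$bn, spec)$stressed_pct
  t_down <- sensitivity_table(down$bn, spec)$stressed_pct
  expect_true(all(diff(t_up) < 0))   # adverse first category highest
  expect_true(all(diff(t_down) > 0))
})

test_that("deltas are computed on unrounded posteriors with the printed sign convention", {
  tab <- data.frame(stressed_pct = c(52.77, 94.05, 52.77, 30, 20),
                    zero_mass = FALSE)
  class(tab) <- c("stressbn_scenario_table", class(tab))
  expect_equal(delta_report(tab, 1, 2), 41.3)
  expect_equal(delta_report(tab, 1, 3), 0)
  expect_equal(delta_report(tab, 4, 5), -10)
  expect_error(delta_report(tab, 1, 9), "out of range")
  # rounding is presentation-only: unrounded delta within 0.15 of the
  # difference of the two-decimal rounded cells
  set.seed(33)
  for (i in 1:30) {
    p <- runif(2, 0, 100)
    d_unrounded <- p[2] - p[1]
    d_rounded <- round(p[2], 2) - round(p[1], 2)
    expect_lt(abs(d_unrounded - d_rounded), 0.15)
  }
})

test_that("zero-mass scenario rows are flagged, not dropped", {
  # control deterministically No; evidence control = Yes is impossible
  bn <- new_bn(new_dag(c("control", "stress"),
                       rbind(c("control", "stress"))),
               list(control = sv$control, stress = sv$stress),
               list(control = c(0, 1),
                    stress = matrix(c(0.3, 0.7, 0.6, 0.4), 2)))
  tab <- sensitivity_table(bn, scenario_spec(grid = list(control = sv$control)))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$zero_mass, c(TRUE, FALSE))
  expect_true(is.na(tab$stressed_pct[1]))
  txt <- format_scenario_table(tab)
  expect_match(txt[2], "zero-mass")
})

test_that("scenario specs round-trip through YAML", {
  spec <- scenario_preset("table7")
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(target = spec$target, target_state = spec$target_state,
                        grid = lapply(spec$grid, as.list),
                        fixed = spec$fixed), f)
  back <- read_scenario_spec(f)
  expect_equal(back$grid, spec$grid)
  expect_equal(back$fixed, spec$fixed)
})
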