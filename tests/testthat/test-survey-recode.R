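sv <- study_variables()

test_that("stress derivation uses the three-or-more symptom rule and is monotone", {
  expect_equal(derive_stress(c(1, 1, 1, 0, 0, 0, 0)), "Yes")
  expect_equal(derive_stress(c(0, 0, 0, 0, 0, 0, 0)), "No")
  expect_equal(derive_stress(c(1, 1, 0, 0, 0, 0, 0)), "No")
  expect_true(is.na(derive_stress(c(1, 1, NA, 0, 0, 0, 0))))
  expect_error(derive_stress(c(1, 1, 1)), "7 symptom flags")
  expect_error(derive_stress(c(1, 1, 1, 0, 0, 0, 2)), "0/1")
  # monotone: adding a positive flag never flips Yes -> No
  set.seed(1)
  for (i in 1:50) {
    f <- sample(0:1, 7, replace = TRUE)
    zeros <- which(f == 0)
    if (!length(zeros)) next
    base <- derive_stress(f)
    f2 <- f
    f2[zeros[sample.int(length(zeros), 1)]] <- 1
    expect_false(base == "Yes" && derive_stress(f2) == "No")
  }
})

test_that("scale collapses follow the published category groupings", {
  expect_equal(map_frequency7_to3(c(1, 2, 3, 4, 5, 6, 7)),
               c(1L, 1L, 2L, 2L, 2L, 3L, 3L))
  expect_error(map_frequency7_to3(8), "1..7")
  expect_equal(map_frequency5_to3(1:5), c(1L, 1L, 2L, 3L, 3L))
  expect_error(map_frequency5_to3(0), "1..5")
})

test_that("composite demand, control and support variables aggregate as declared", {
  # job demand: mean of the two codes, half away from zero, then 7->3
  expect_equal(derive_job_demand(1, 2), sv$job_demand[1])
  expect_equal(derive_job_demand(4, 4), sv$job_demand[2])
  expect_equal(derive_job_demand(2, 3), sv$job_demand[2])  # 2.5 -> 3 -> mid
  expect_equal(derive_job_demand(2, 3, rounding = "half_even"),
               sv$job_demand[1])                           # 2.5 -> 2 -> high
  # family demand / colleague support share the 5 -> 3 grouping
  expect_equal(derive_family_demand(c(1, 3, 5)), sv$family_demand)
  expect_equal(derive_colleague_support(c(2, 3, 4)), sv$colleague_support)
  # control: default rule needs both answers yes
  expect_equal(derive_control(1, 1), "Yes")
  expect_equal(derive_control(1, 2), "No")
  expect_equal(derive_control(2, 2), "No")
  expect_equal(derive_control(1, 2, rule = "any_yes"), "Yes")
  # boss support: rounded mean of the seven supervisor items
  expect_equal(derive_boss_support(rep(1, 7)), sv$boss_support[1])
  expect_equal(derive_boss_support(rep(5, 7)), sv$boss_support[3])
  expect_equal(derive_boss_support(c(2, 3, 3, 3, 3, 3, 3)),
               sv$boss_support[2])  # mean 20/7 = 2.857 -> 3
  expect_equal(derive_recognition(c(2, 3, 5)), sv$recognition)
})

test_that("age groups follow the <35 / 35-45 / 45-55 / >55 convention", {
  expect_equal(derive_age_group(c(15, 34)), rep("<35", 2))
  expect_equal(derive_age_group(c(35, 44)), rep("Between 35 and 45", 2))
  expect_equal(derive_age_group(c(45, 55)), rep("Between 45 and 55", 2))
  expect_equal(derive_age_group(c(56, 70)), rep(">55", 2))
  expect_error(derive_age_group(10), ">= 15")
})

test_that("recode helpers are idempotent on valid codes", {
  # re-deriving from the representative raw codes of each recoded state
  # returns that state
  for (i in 1:3) {
    expect_equal(derive_emotional_demand(c(2, 4, 7)[i]), sv$emotional_demand[i])
    expect_equal(derive_family_demand(c(1, 3, 5)[i]), sv$family_demand[i])
  }
})

test_that("Cronbach's alpha matches the brute-force formula and its edge cases", {
  # duplicated columns: exactly 1
  m <- cbind(c(1, 2, 3, 5), c(1, 2, 3, 5))
  expect_identical(cronbach_alpha(m), 1)
  # perfectly correlated but unequal-variance items: the formula gives 8/9
  # (alpha reaches 1 only for tau-equivalent items)
  expect_equal(cronbach_alpha(cbind(1:4, 2 * (1:4))), 8 / 9,
               tolerance = 1e-12)
  expect_equal(cronbach_alpha(cbind(1:4, 2 * (1:4))),
               alpha_oracle(cbind(1:4, 2 * (1:4))), tolerance = 1e-12)
  # formula-oracle identity on random toy matrices, including negative alpha
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(sample(1:5, 24, replace = TRUE), ncol = 4)
    if (var(rowSums(m)) == 0) next
    expect_equal(cronbach_alpha(m), alpha_oracle(m), tolerance = 1e-12)
  }
  anti <- cbind(c(1, 2, 1, 2, 1), c(2, 1, 2, 1, 2), c(1, 1, 2, 2, 1))
  expect_lt(cronbach_alpha(anti), 0)
  expect_equal(cronbach_alpha(anti), alpha_oracle(anti), tolerance = 1e-12)
  # constant total score: alpha undefined, explicit error
  expect_error(cronbach_alpha(cbind(c(1, 2, 1, 2), c(2, 1, 2, 1))),
               "undefined")
})

test_that("recode_dataset builds the ten variables, logs NR and honours the policy", {
  gt <- build_ground_truth(generator_config())
  rec0 <- ancestral_sample(gt, 40, seed = 3)
  raw <- raw_from_recoded(rec0)
  out <- recode_dataset(raw)
  expect_named(out$data, names(sv))
  expect_equal(nrow(out$data), 40)
  expect_equal(sum(out$log$n_nr), 0)
  # round trip: recoding the inverse-mapped raw codes reproduces the table
  for (v in names(sv)) {
    expect_equal(as.character(out$data[[v]]), as.character(rec0[[v]]),
                 label = v)
  }
  # complete-case policy drops records with a missing modeled answer
  raw3 <- raw[1:3, ]
  raw3$q54a[2] <- NA
  cc <- recode_dataset(raw3, default_codebook(policy = "complete_case"))
  expect_equal(nrow(cc$data), 2)
  expect_equal(attr(cc$log, "dropped"), 1L)
  expect_equal(cc$log$n_nr[cc$log$variable == "control"], 1L)
  # keep_NR keeps the record with an explicit NR state
  kn <- recode_dataset(raw3)
  expect_equal(nrow(kn$data), 3)
  expect_equal(as.character(kn$data$control[2]), "NR")
  # empty input, empty output
  empty <- recode_dataset(raw[0, ])
  expect_equal(nrow(empty$data), 0)
  expect_equal(sum(empty$log$n_nr), 0)
  # missing column named in the error
  expect_error(recode_dataset(raw[, setdiff(names(raw), "q30h")]), "q30h")
})

test_that("frequency tables include NR, use half-up rounding and sum to 100", {
  d <- data.frame(stress = factor(c(rep("Yes", 814), rep("No", 1397)),
                                  levels = sv$stress))
  ft <- frequency_table(d)
  expect_equal(ft$pct, c(36.8, 63.2))
  one <- frequency_table(data.frame(x = factor(rep("a", 5))))
  expect_equal(one$pct, 100.0)
  # percentages per variable sum to 100 +/- 0.2 after rounding, NR included
  gt <- build_ground_truth(generator_config())
  tab <- inject_missing(ancestral_sample(gt, 500, seed = 9), seed = 10)
  ft <- frequency_table(tab)
  sums <- tapply(ft$pct, ft$variable, sum)
  expect_true(all(abs(sums - 100) <= 0.2))
})
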