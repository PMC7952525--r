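test_that("built-in scheme has the published shape", {
  sch <- model5_scheme()
  expect_equal(sch$max_score, 11)
  expect_length(sch$components, 4)
  # minimum attainable total: all components at their mildest category
  closed <- echo_exam(transductal_diameter = 0, ductal_vmax_vmin_ratio = 0,
                      lpa_diastolic_velocity = 0, dao_flow_direction = "forward")
  expect_equal(compute_score(closed, sch)$total, 0)
})

test_that("boundary values fall in the closed middle ranges", {
  sch <- model5_scheme()
  td <- sch$components$transductal_diameter
  expect_equal(stage_component(1.5, td), 2)   # lower edge of "1.5-3"
  expect_equal(stage_component(3.0, td), 2)   # upper edge stays in "1.5-3"
  expect_equal(stage_component(3.2, td), 3)
  expect_equal(stage_component(1.49, td), 1)
  expect_equal(stage_component(0, td), 0)
  vm <- sch$components$ductal_vmax_vmin_ratio
  expect_equal(stage_component(2.0, vm), 2)
  expect_equal(stage_component(2.01, vm), 3)
  lpa <- sch$components$lpa_diastolic_velocity
  expect_equal(stage_component(30, lpa), 2)
  expect_equal(stage_component(50, lpa), 2)
  expect_equal(stage_component(50.1, lpa), 3)
  dao <- sch$components$dao_flow_direction
  expect_equal(stage_component("reverse", dao), 2)
  expect_equal(stage_component("forward", dao), 0)
  expect_error(stage_component("sideways", dao), "unknown category")
  expect_error(stage_component(-1, td), "non-negative")
})

test_that("total scores match direct exam examples", {
  sch <- model5_scheme()
  worst <- echo_exam(transductal_diameter = 3.5, ductal_vmax_vmin_ratio = 2.5,
                     lpa_diastolic_velocity = 60, dao_flow_direction = "reverse")
  expect_equal(compute_score(worst, sch)$total, 11)
  mixed <- echo_exam(transductal_diameter = 2.0, ductal_vmax_vmin_ratio = 1.6,
                     lpa_diastolic_velocity = 35, dao_flow_direction = "reverse")
  s <- compute_score(mixed, sch)
  expect_equal(unname(s$per_component), c(2, 2, 2, 2))
  expect_equal(s$total, 8)
  expect_error(compute_score(list(transductal_diameter = 2), sch),
               "missing measurement")
})

test_that("scores agree with a literal table re-reading on a boundary grid", {
  sch <- model5_scheme()
  tds <- c(0, 0.7, 1.49, 1.5, 2.2, 3, 3.01, 5)
  vms <- c(0.9, 1.5, 2, 2.4)
  lpas <- c(0, 29, 30, 50, 51)
  daos <- c("forward", "absent", "reverse")
  for (td in tds) for (vm in vms) for (lpa in lpas) for (dao in daos) {
    vm_use <- if (td == 0) 0 else vm
    exam <- list(transductal_diameter = td, ductal_vmax_vmin_ratio = vm_use,
                 lpa_diastolic_velocity = lpa, dao_flow_direction = dao)
    expect_equal(compute_score(exam, sch)$total,
                 table_score_oracle(td, vm_use, lpa, dao))
  }
})

test_that("increasing a staged measurement never decreases the total", {
  sch <- model5_scheme()
  set.seed(21)
  for (i in 1:50) {
    exam <- list(transductal_diameter = runif(1, 0.1, 4),
                 ductal_vmax_vmin_ratio = runif(1, 0.1, 3),
                 lpa_diastolic_velocity = runif(1, 0, 60),
                 dao_flow_direction = sample(c("forward", "absent", "reverse"), 1))
    base <- compute_score(exam, sch)$total
    for (v in c("transductal_diameter", "ductal_vmax_vmin_ratio",
                "lpa_diastolic_velocity")) {
      bumped <- exam
      bumped[[v]] <- bumped[[v]] + runif(1, 0, 2)
      expect_gte(compute_score(bumped, sch)$total, base)
    }
  }
})

test_that("random exams always score within 0 and 11", {
  set.seed(31)
  n <- 1e5
  cohort <- data.frame(
    transductal_diameter = rexp(n, 0.5),
    ductal_vmax_vmin_ratio = rexp(n, 0.5) + 0.01,
    lpa_diastolic_velocity = rexp(n, 1 / 25),
    dao_flow_direction = sample(c("forward", "absent", "reverse"), n, TRUE))
  scored <- score_cohort(cohort, model5_scheme())
  expect_true(all(scored$pda_score >= 0 & scored$pda_score <= 11))
  # vectorized and scalar paths agree on a subsample
  idx <- sample(n, 50)
  for (i in idx) {
    expect_equal(scored$pda_score[i],
                 compute_score(cohort[i, , drop = FALSE], model5_scheme())$total)
  }
})

test_that("scheme configs round-trip and invalid bins are rejected", {
  path <- system.file("extdata", "model5_scheme.json", package = "pdaclose")
  loaded <- load_scheme(path)
  builtin <- model5_scheme()
  expect_equal(loaded$max_score, builtin$max_score)
  expect_equal(names(loaded$components), names(builtin$components))
  for (nm in names(builtin$components)) {
    expect_equal(unclass(loaded$components[[nm]]),
                 unclass(builtin$components[[nm]]))
  }
  gap <- list(name = "gappy", components = list(list(
    variable = "x", kind = "numeric",
    bins = list(list(from = 0, to = 2, score = 1),
                list(from = 3, to = NULL, score = 2)))))
  expect_error(load_scheme(gap), "gap")
  overlap <- list(name = "overlappy", components = list(list(
    variable = "x", kind = "numeric",
    bins = list(list(from = 0, to = 2, score = 1),
                list(from = 1.5, to = NULL, score = 2)))))
  expect_error(load_scheme(overlap), "overlap")
  three <- list(name = "three", components = list(
    list(variable = "a", kind = "numeric",
         bins = list(list(from = 0, to = 1, score = 1),
                     list(from = 1, to = 2, score = 2),
                     list(from = 2, to = NULL, score = 3))),
    list(variable = "b", kind = "numeric",
         bins = list(list(from = 0, to = 5, score = 2),
                     list(from = 5, to = NULL, score = 3))),
    list(variable = "c", kind = "categorical",
         categories = list(low = 0, high = 2))))
  expect_equal(load_scheme(three)$max_score, 8)
})
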