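# Normality-gated test routing, DREADD inversion ANOVA, rabies filters.

# seeded fixtures whose Shapiro-Wilk outcomes are known (asserted below)
normal_group <- function(n = 12, mean = 0) {
  set.seed(13); rnorm(n, mean, 1)
}
skewed_group <- function(n = 12) {
  set.seed(5); exp(rnorm(n, 0, 1.2))   # strongly log-normal, fails SW
}

test_that("routing is a pure function of the per-group normality outcomes", {
  g1 <- normal_group(); g2 <- normal_group(mean = 0.5) + rnorm(12, 0, 1e-3)
  sk <- skewed_group()
  expect_gt(stats::shapiro.test(g1)$p.value, 0.05)
  expect_lt(stats::shapiro.test(sk)$p.value, 0.05)

  expect_equal(select_and_run_test(list(g1, g2))$test, "unpaired t-test")
  expect_equal(select_and_run_test(list(g1, g2), paired = TRUE)$test, "paired t-test")
  expect_equal(select_and_run_test(list(g1, sk))$test, "Mann-Whitney U")
  expect_equal(select_and_run_test(list(g1, sk), paired = TRUE)$test,
               "Wilcoxon signed-rank")
  expect_equal(select_and_run_test(list(g1, g2, g1 + 1))$test, "one-way ANOVA")
  expect_equal(select_and_run_test(list(g1, g2, g1 + 1), paired = TRUE)$test,
               "one-way RM ANOVA")
  expect_equal(select_and_run_test(list(g1, g2, sk))$test, "Kruskal-Wallis")
  expect_equal(select_and_run_test(list(g1, g2, sk), paired = TRUE)$test,
               "Kruskal-Wallis")

  res <- select_and_run_test(list(g1, sk))
  expect_false(res$parametric)
  expect_length(res$shapiro_p, 2L)
  expect_error(select_and_run_test(list(g1)), "two groups")
  expect_error(select_and_run_test(list(g1, rnorm(2))), "n >= 3")
})

test_that("identical groups give a null-centered statistic and p near 1", {
  g <- normal_group()
  res <- select_and_run_test(list(g, g))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  res_p <- select_and_run_test(list(g, g), paired = TRUE)
  expect_equal(res_p$p.value, 1)   # all-zero differences, Pratt
})

test_that("the unpaired parametric route is the pooled-variance Student t", {
  set.seed(93)
  a <- rnorm(7, 10, 2); b <- rnorm(7, 13, 2)
  res <- select_and_run_test(list(a, b))
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$df, 12)   # n1 + n2 - 2, the df the study reports
})

test_that("DREADD inversion ANOVA nulls symmetric effects and flags asymmetric ones", {
  mk <- function(vals_by_animal) {
    do.call(rbind, lapply(seq_along(vals_by_animal), function(a)
      data.frame(animal = paste0("m", a), order = seq_along(vals_by_animal[[a]]),
                 label = rep(c("Saline", "CNO"), length.out = length(vals_by_animal[[a]])),
                 value = vals_by_animal[[a]])))
  }
  # symmetric suppression with full washout: S->C delta -10, C->S delta +10;
  # after inversion both are +10 -> no transition-type effect
  set.seed(94)
  sym <- mk(lapply(1:6, function(a) {
    b <- 100 + a
    c(b, b - 10, b, b - 10, b, b - 10) + rnorm(6, 0, 0.5)
  }))
  res <- dreadd_inversion_rm_anova(sym)
  expect_gt(res$anova$p.value, 0.2)
  # the inversion was applied: Saline->CNO deltas were negative pre-inversion
  sc <- res$deltas$delta[res$deltas$transition == "Saline->CNO"]
  expect_true(all(sc > 0))

  # all-zero deltas: F pinned to 0
  flat <- mk(lapply(1:4, function(a) rep(50, 4)))
  expect_equal(dreadd_inversion_rm_anova(flat)$anova$F, 0)

  # non-alternating labels name the offending animal
  bad <- mk(list(c(1, 2, 3)))
  bad$label <- c("Saline", "Saline", "CNO")
  expect_error(dreadd_inversion_rm_anova(bad), "m1")
})

test_that("the DREADD generator scenario is detected at its stated effect and not under the null", {
  p_eff <- vapply(1:25, function(s)
    dreadd_inversion_rm_anova(
      gen_dreadd_scenario(generator_config(700 + s))$sessions)$anova$p.value,
    numeric(1))
  expect_gte(mean(p_eff < 0.05), 0.8)

  p_null <- vapply(1:40, function(s)
    dreadd_inversion_rm_anova(
      gen_dreadd_scenario(generator_config(800 + s,
                                           dreadd = list(cno_effect = 0)))$sessions)$anova$p.value,
    numeric(1))
  expect_lte(mean(p_null < 0.05), 0.15)
})

test_that("region inclusion applies the adjacent-pair sum rule with strict bounds", {
  mk_rows <- function(region, animal, sections, counts)
    count_table(rep(region, length(sections)), rep(animal, length(sections)),
                sections, counts)
  # > 5 cells summed over an adjacent pair in 4 of 7 animals: included
  t1 <- do.call(rbind, c(
    lapply(1:4, function(a) mk_rows("EPN", paste0("m", a), 1:2, c(3, 3))),
    lapply(5:7, function(a) mk_rows("EPN", paste0("m", a), 1:2, c(1, 1)))))
  expect_equal(rabies_region_filter(t1), "EPN")

  # same counts on non-adjacent sections only: excluded
  t2 <- do.call(rbind, lapply(1:7, function(a)
    mk_rows("LH", paste0("m", a), c(1, 3), c(6, 6))))
  expect_equal(rabies_region_filter(t2), character(0))

  # pair sum of exactly 5 everywhere: excluded (strict > 5)
  t3 <- do.call(rbind, lapply(1:7, function(a)
    mk_rows("VP", paste0("m", a), 1:2, c(2, 3))))
  expect_equal(rabies_region_filter(t3), character(0))

  # exactly 3 qualifying animals: excluded ("more than 3" is strict)
  t4 <- do.call(rbind, c(
    lapply(1:3, function(a) mk_rows("VTA", paste0("m", a), 1:2, c(4, 4))),
    lapply(4:7, function(a) mk_rows("VTA", paste0("m", a), 1:2, c(0, 0)))))
  expect_equal(rabies_region_filter(t4), character(0))

  # per-section variant requires each section of the pair above threshold
  t5 <- do.call(rbind, lapply(1:4, function(a)
    mk_rows("LPO", paste0("m", a), 1:2, c(6, 6))))
  expect_equal(rabies_region_filter(t5, per_section = TRUE), "LPO")
  t6 <- do.call(rbind, lapply(1:4, function(a)
    mk_rows("LPO", paste0("m", a), 1:2, c(12, 1))))
  expect_equal(rabies_region_filter(t6, per_section = TRUE), character(0))
  expect_equal(rabies_region_filter(t6), "LPO")   # sum rule: 13 > 5

  expect_equal(rabies_region_filter(t1[0, ]), character(0))
})

test_that("region inclusion is monotone under added cells", {
  set.seed(95)
  for (i in 1:20) {
    tab <- count_table(
      region = sample(c("A", "B"), 40, TRUE),
      animal = sample(paste0("m", 1:6), 40, TRUE),
      section = sample(1:4, 40, TRUE),
      rv_positive = rpois(40, 3))
    inc0 <- rabies_region_filter(tab)
    tab2 <- tab
    j <- sample.int(40, 1)
    tab2$rv_positive[j] <- tab2$rv_positive[j] + sample.int(10, 1)
    inc1 <- rabies_region_filter(tab2)
    expect_true(all(inc0 %in% inc1))
  }
})

test_that("animal exclusion fires the right rule at strict boundaries", {
  meta <- data.frame(
    animal = c("m1", "m2", "m3", "m4"),
    starter_spread_outside_frac = c(0.31, 0.30, 0.10, NA),
    starter_neuronal_frac = c(0.000, 0.005, 0.010, 0.001))
  res <- rabies_animal_exclusion(meta)
  expect_false(res$include[1]); expect_match(res$reason[1], "spread")
  expect_true(res$include[2])                       # both at boundary: included
  expect_false(res$include[3]); expect_match(res$reason[3], "neuronal")
  expect_true(is.na(res$include[4])); expect_match(res$reason[4], "missing")
})

test_that("neuronal fractions pool over included animals only", {
  tab <- count_table(
    region = rep("EPN", 4), animal = c("m1", "m1", "m2", "m3"),
    section = c(1, 2, 1, 1), rv_positive = c(20, 20, 40, 100),
    neun_positive_rv = c(15, 15, 30, 0))
  all_in <- neuronal_fraction_summary(tab)
  expect_equal(all_in$neuronal_frac, 60 / 180)
  sub <- neuronal_fraction_summary(tab, included_animals = c("m1", "m2"))
  expect_equal(sub$neuronal_frac, 0.75)
  one <- neuronal_fraction_summary(count_table("X", "m1", 1, 30, 30))
  expect_equal(one$neuronal_frac, 1)
  zero <- neuronal_fraction_summary(count_table("X", "m1", 1, 0, 0))
  expect_true(is.na(zero$neuronal_frac))
  expect_error(count_table("X", "m1", 1, 10, 12), "exceed")
})

test_that("the head-fixed group pipeline separates cohorts with different AC structure", {
  mk_cohort <- function(seeds, pc_median) {
    lapply(seeds, function(s)
      gen_motion_session(generator_config(s,
        motion = list(pc_median_s = pc_median)))$trace)
  }
  wt <- mk_cohort(101:107, 30)    # sparse AC
  ko <- mk_cohort(201:207, 12)    # denser AC (more bouts, more total AC)
  res <- headfixed_group_comparison(wt, ko)
  expect_equal(nrow(res$per_animal), 14L)
  expect_lt(res$total_ac_test$p.value, 0.05)
  expect_lt(res$n_bouts_test$p.value, 0.05)
})
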