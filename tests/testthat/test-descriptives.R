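test_that("group assignment partitions the cohort", {
  emr_calls <- tibble::tibble(scrambled_id = c("a", "b", "c", "d"),
                              frail = c(TRUE, TRUE, FALSE, FALSE))
  admin_calls <- tibble::tibble(scrambled_id = c("d", "c", "b", "a"),
                                frail = c(FALSE, TRUE, TRUE, FALSE))
  g <- assign_groups(emr_calls, admin_calls)
  expect_equal(as.character(g$group), c("emr_only", "both", "admin_only",
                                        "neither"))
  expect_equal(sum(table(g$group)), 4)
  expect_error(assign_groups(emr_calls[-1, ], admin_calls), "one call list")
})

test_that("rurality is the second character of the FSA", {
  expect_equal(as.character(rural_flag(c("R0G1J0", "V6T2B5", "A00000"))),
               c("rural", "urban", "rural"))
  expect_error(rural_flag("12345"), "postal")
})

test_that("blood pressure means use the three most recent readings", {
  obs <- dplyr::bind_rows(
    obs_row(obs_date = "2014-01-01", value = 120),
    obs_row(obs_date = "2014-02-01", value = 130),
    obs_row(obs_date = "2014-03-01", value = 140),
    obs_row(obs_date = "2014-04-01", value = 150))
  res <- mean_recent_bp(obs, "systolic_bp")
  expect_equal(res$mean, 140)
  expect_equal(res$n_used, 3)
  one <- mean_recent_bp(obs_row(value = 128), "systolic_bp")
  expect_equal(one$mean, 128)
  expect_equal(one$n_used, 1)
  none <- mean_recent_bp(obs[0, ], "systolic_bp")
  expect_true(is.na(none$mean))
  # window restriction drops old readings
  win <- c(as.Date("2014-02-15"), as.Date("2014-12-31"))
  expect_equal(mean_recent_bp(obs, "systolic_bp", win)$mean, 145)
})

test_that("polypharmacy is strictly more than five distinct medications", {
  six <- dplyr::bind_rows(lapply(
    c("A02BC01", "B01AA03", "C07AB02", "C10AA01", "N02BE01", "R03AC02"),
    function(a) rx_row(atc_code = a, dispense_date = "2015-03-01")))
  p6 <- polypharmacy_flag(six, 2015)
  expect_true(p6$polypharmacy)
  # five distinct codes dispensed repeatedly stay below the bar
  five_rep <- dplyr::bind_rows(six[rep(1:5, 4), ])
  p5 <- polypharmacy_flag(five_rep, 2015)
  expect_false(p5$polypharmacy)
  expect_equal(p5$n_distinct_atc, 5)
  expect_equal(nrow(polypharmacy_flag(six[0, ], 2015)), 0)
})

test_that("table percentages use half-away-from-zero rounding to one decimal", {
  expect_equal(table_pct(45, 70), 64.3)
  expect_equal(table_pct(15, 56), 26.8)
  expect_equal(table_pct(1, 8), 12.5)   # exact .5 rounds away from zero
  expect_equal(table_pct(5, 4978), 0.1)
  expect_true(is.na(table_pct(0, 0)))
})

test_that("chi-square (no continuity correction) matches the closed form", {
  # 2x2 table (10,20 / 20,10): X2 = n(ad-bc)^2 / (row and column products)
  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  cs <- chisq_nocorrect(tab)
  want <- 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30)
  expect_equal(cs$statistic, want) # = 6.6667
  expect_equal(cs$p, stats::pchisq(want, 1, lower.tail = FALSE))
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(cs$statistic, unname(ref$statistic))
  # identical groups: statistic 0, p 1
  same <- matrix(c(15, 15, 30, 30), 2)
  cs0 <- chisq_nocorrect(same)
  expect_equal(cs0$statistic, 0)
  expect_equal(cs0$p, 1)
  # random tables agree with stats::chisq.test
  set.seed(2)
  for (i in 1:20) {
    t2 <- matrix(sample(5:60, 6), 2, 3)
    ref2 <- suppressWarnings(stats::chisq.test(t2, correct = FALSE))
    got <- chisq_nocorrect(t2)
    expect_equal(got$statistic, unname(ref2$statistic))
    expect_equal(got$p, unname(ref2$p.value))
  }
})

test_that("degenerate equal-constant t-tests fall back to p = 1 with a warning", {
  expect_warning(res <- frailscan:::welch_p(rep(3, 5), rep(3, 7)), "degenerate")
  expect_equal(res$p, 1)
  ok <- frailscan:::welch_p(rnorm(20), rnorm(20, 2))
  expect_lt(ok$p, 0.05)
})

make_summary_world <- function(n = 400, seed = 17) {
  g <- generate_cohort(sim_config(n, seed = seed))
  cw <- link_deterministic(g$emr, g$admin)
  coh <- build_cohort(g$emr, g$admin, cw, 2014)
  ec <- apply_emr_definition(default_emr_definition(), g$emr, coh, 2014)
  ac <- apply_admin_definition(g$admin, coh, 2014)
  grp <- assign_groups(ec, ac)
  ce <- classify_conditions(g$emr, coh, 2014)
  ca <- classify_conditions(g$admin, coh, 2014)
  list(g = g, coh = coh, grp = grp,
       s = summarize_cohort(grp, coh, g$emr, g$admin, ce, ca, 2014))
}

test_that("summary blocks partition each group and exclude index-year deaths", {
  w <- make_summary_world()
  chars <- w$s$characteristics
  n_by_group <- setNames(chars$n[chars$block == "n"],
                         as.character(chars$group[chars$block == "n"]))
  expect_equal(sum(n_by_group), sum(w$coh$included))
  for (blk in c("age_band", "sex", "income_band", "residence",
                "comorb_band_emr", "comorb_band_admin")) {
    sums <- tapply(chars$n[chars$block == blk], chars$group[chars$block == blk],
                   sum)
    expect_equal(as.numeric(sums[names(n_by_group)]),
                 as.numeric(n_by_group), label = blk)
    pct_sums <- tapply(chars$pct[chars$block == blk],
                       chars$group[chars$block == blk], sum)
    nonzero <- n_by_group > 0
    expect_true(all(abs(pct_sums[names(n_by_group)][nonzero] - 100) <= 0.2),
                label = blk)
  }
  # death accounting: utilization denominators exclude index-year deaths
  util <- w$s$utilization
  util_n <- sum(util$n[util$block == "n"])
  ep <- w$g$emr$persons
  died_2014 <- !is.na(ep$death_date) &
    ep$death_date <= as.Date("2014-12-31") &
    ep$person_id %in% w$coh$emr_person_id[w$coh$included]
  expect_equal(util_n, sum(w$coh$included) - sum(died_2014))
})

test_that("group comparison flags significance at the reporting thresholds", {
  w <- make_summary_world()
  members <- w$coh[w$coh$included, c("scrambled_id", "age_on_jan1")]
  ep <- w$g$emr$persons
  members$sex <- ep$sex[match(w$coh$emr_person_id[w$coh$included],
                              ep$person_id)]
  res <- compare_groups(w$grp, members, categorical = "sex",
                        continuous = "age_on_jan1")
  expect_equal(nrow(res), 2)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$flag %in% c("", "p<0.05", "p<0.01", "p<0.0001")))
})
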