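marker_vec <- function(pro, anti) {
  stats::setNames(c(pro, anti), c(PRO_MARKERS, ANTI_MARKERS))
}

toy_summaries <- function() {
  data.frame(
    tumor_id = c("A", "B", "C", "D"),
    genotype = c("IDH_WT", "IDH_WT", "IDH_MUT", "IDH_MUT"),
    CD68 = c(30, 40, 60, 70), HLA_ABC = c(50, 55, 70, 80),
    TNF = c(10, 20, 40, 50),
    CD163 = c(60, 50, 30, 20), IL10 = c(40, 45, 25, 20),
    TGFB2 = c(35, 30, 20, 15),
    iba1_intensity = c(50, 60, 100, 120),
    mean_area_um2 = c(38, 42, 50, 55),
    survival_days = c(300, 400, 800, 900),
    lost_to_followup = c(FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

test_that("inflammatory profile is pro minus anti marker frequency", {
  expect_equal(inflammatory_profile(marker_vec(c(50, 50, 50), c(50, 50, 50))), 0)
  expect_equal(inflammatory_profile(marker_vec(c(100, 100, 100), c(0, 0, 0))), 100)
  expect_equal(inflammatory_profile(marker_vec(c(60, 70, 80), c(30, 20, 10))), 50)
  # sum aggregation differs from mean by exactly a factor of three
  expect_equal(inflammatory_profile(marker_vec(c(60, 70, 80), c(30, 20, 10)),
                                    aggregate = "sum"), 150)
  v <- marker_vec(c(60, 70, NA), c(30, 20, 10))
  expect_error(inflammatory_profile(v), "missing marker")
})

test_that("min-max scaling maps the cohort extremes to exactly 0 and 100", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 50, 100))
  set.seed(8)
  for (i in 1:10) {
    x <- stats::rnorm(7 + i)
    sc <- minmax_scale(x)
    expect_identical(sc[which.min(x)], 0)
    expect_identical(sc[which.max(x)], 100)
    expect_true(all(sc >= 0 & sc <= 100))
  }
  expect_error(minmax_scale(c(3, 3, 3)), "degenerate")
})

test_that("composite score sums three cohort-scaled components", {
  s <- toy_summaries()
  st <- composite_score(s)
  expect_equal(st$score, st$scaled_profile + st$scaled_intensity +
                 st$scaled_area)
  expect_true(all(st$score >= 0 & st$score <= 300))

  # one tumor dominating all three components attains 0 and 300
  two <- s[c(1, 4), ]
  st2 <- composite_score(two)
  expect_equal(sort(st2$score), c(0, 300))

  # permuting tumors leaves each tumor's score unchanged
  perm <- composite_score(s[c(3, 1, 4, 2), ])
  expect_equal(perm$score[match(st$tumor_id, perm$tumor_id)], st$score)

  # common affine rescaling of a raw component is absorbed by min-max
  s2 <- s; s2$iba1_intensity <- 3.7 * s2$iba1_intensity + 11
  expect_equal(composite_score(s2)$score, st$score)

  # incomplete tumors are excluded with a message
  s3 <- s; s3$TNF[2] <- NA
  expect_message(st3 <- composite_score(s3), "excluded")
  expect_equal(attr(st3, "excluded"), "B")
  expect_equal(nrow(st3), 3)
})

test_that("score is monotone in a non-extreme tumor's pro-marker frequency", {
  s <- toy_summaries()
  base <- composite_score(s)
  bumped <- s; bumped$CD68[2] <- bumped$CD68[2] + 15  # B is not the max
  st <- composite_score(bumped)
  expect_gte(st$score[st$tumor_id == "B"], base$score[base$tumor_id == "B"])
})

test_that("median split sends ties and the median itself to the low group", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(1, 2, 3)), c("low", "low", "high"))
  expect_warning(all_low <- median_split(c(5, 5, 5)), "all scores equal")
  expect_equal(all_low, rep("low", 3))
})

test_that("survival comparison excludes lost-to-follow-up and reports group stats", {
  st <- composite_score(toy_summaries())
  out <- compare_survival(st)
  expect_equal(out$mean_high, 850)
  expect_equal(out$mean_low, 350)
  expect_lt(out$p, 0.05)

  # lost-to-follow-up tumors drop out
  s <- toy_summaries(); s$lost_to_followup[1] <- TRUE
  st2 <- composite_score(s)
  expect_error(compare_survival(st2), ">= 2 tumors")
})

test_that("two-group t-test matches closed-form computation", {
  a <- c(1.2, 3.4, 2.2); b <- c(4.1, 5.0, 6.3)
  out <- compare_groups(a, b)
  sp2 <- (2 * stats::var(a) + 2 * stats::var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 4)
  expect_equal(out$p, p_hand, tolerance = 1e-10)
  expect_equal(out$mean_a, mean(a)); expect_equal(out$sd_b, stats::sd(b))

  # identical groups: no difference
  same <- compare_groups(c(2, 2), c(2, 2))
  expect_equal(same$p, 1)
  # constant groups with different means: maximal evidence
  expect_lt(compare_groups(c(0, 0), c(10, 10))$p, 0.05)
  # symmetry
  ab <- compare_groups(a, b); ba <- compare_groups(b, a)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$mean_a - ab$mean_b, -(ba$mean_a - ba$mean_b))
  expect_error(compare_groups(1, c(1, 2)), "insufficient")
})

test_that("WT vs MUT comparison table covers requested fields with optional Holm", {
  co <- generate_cohort(cohort_config(seed = 5))
  cmp <- wt_mut_comparison(co)
  expect_setequal(cmp$field, c("if_content_pct", ALL_MARKERS,
                               "iba1_intensity", "area_um2"))
  expect_equal(cmp$p, cmp$p_adjusted)  # no correction by default
  holm <- wt_mut_comparison(co, p_adjust = "holm")
  expect_true(all(holm$p_adjusted >= holm$p))
})

test_that("score pipeline separates genotypes under configured effects", {
  # with the default (cohort-emulating) effects the mutant mean score is
  # higher and usually significantly so
  ps <- vapply(1:30, function(s) {
    st <- composite_score(generate_cohort(cohort_config(seed = 500 + s)))
    mut <- st$genotype == "IDH_MUT"
    c(diff = mean(st$score[mut]) - mean(st$score[!mut]),
      p = compare_groups(st$score[mut], st$score[!mut])$p)
  }, numeric(2))
  expect_true(all(ps["diff", ] > 0))
  expect_gte(mean(ps["p", ] < 0.05), 0.8)
})
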