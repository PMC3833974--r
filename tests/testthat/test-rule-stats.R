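test_that("hypergeometric upper tail matches hand enumeration", {
  # N=20, K=10, n=6, k=6: 210 of the C(20,6)=38760 draws are all-class
  expect_equal(allergyrules:::hypergeom_upper(6, 10, 20, 6), 210 / 38760,
               tolerance = 1e-12)
  # N=4, K=2, n=2, k=2: 1 of the 6 draws
  expect_equal(allergyrules:::hypergeom_upper(2, 2, 4, 2), 1 / 6,
               tolerance = 1e-12)
  expect_identical(allergyrules:::hypergeom_upper(0, 5, 12, 4), 1.0)
  expect_error(allergyrules:::hypergeom_upper(5, 2, 10, 3),
               "inconsistent margins")
})

test_that("hypergeometric tail agrees with dhyper and is monotone in k", {
  for (N in c(8L, 15L)) {
    for (K in c(3L, N %/% 2)) {
      for (n in c(2L, N %/% 2, N)) {
        prev <- Inf
        for (k in 0:min(n, K)) {
          p <- allergyrules:::hypergeom_upper(k, K, N, n)
          oracle <- sum(dhyper(k:min(n, K), K, N - K, n))
          expect_equal(p, min(max(oracle, .Machine$double.xmin), 1),
                       tolerance = 1e-12)
          expect_lte(p, prev + 1e-15)
          prev <- p
        }
        # pmf sums to 1 over the support
        lo <- max(0, n - (N - K))
        expect_equal(sum(dhyper(lo:min(n, K), K, N - K, n)), 1,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("rule_pvalue extracts the margins from the table", {
  tab <- decision_table(data.frame(a = c("1", "1", "0", "0")),
                        c("affected", "affected", "unaffected",
                          "unaffected"))
  ht <- rule_pvalue(rule(c(a = "1"), "affected"), tab)
  expect_s3_class(ht, "hypergeom_test")
  expect_identical(c(ht$N, ht$K, ht$n, ht$k), c(4L, 2L, 2L, 2L))
  expect_equal(ht$p, 1 / 6, tolerance = 1e-12)
  expect_true(is.na(ht$p_adj))
  # k = 0: certainty
  ht0 <- rule_pvalue(rule(c(a = "0"), "affected"), tab)
  expect_identical(ht0$k, 0L)
  expect_identical(ht0$p, 1.0)
})

test_that("Bonferroni adjustment and threshold follow the definitions", {
  expect_equal(bonferroni(c(0.01, 0.5), m = 2), c(0.02, 1.0))
  expect_equal(bonferroni(0.07, m = 1), 0.07)
  expect_error(bonferroni(c(0, 0.5), m = 2), "must lie in \\(0, 1\\]")
  expect_error(bonferroni(c(1.5), m = 1), "must lie in \\(0, 1\\]")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
  expect_equal(bonferroni_threshold(0.05, 220), 0.05 / 220)
  expect_identical(signif(bonferroni_threshold(0.05, 220), 2), 2.3e-4)
  # monotone in m
  expect_lte(bonferroni(0.01, 5)[1], bonferroni(0.01, 10)[1])
})

test_that("2x2 odds ratios use Woolf intervals and Haldane correction", {
  res <- odds_ratio_2x2(10, 5, 5, 10)
  expect_equal(res$or, 4.0)
  expect_equal(res$ci_low, exp(log(4) - 1.96 * sqrt(0.6)), tolerance = 1e-12)
  expect_equal(round(res$ci_low, 3), 0.876)
  expect_equal(round(res$ci_high, 2), 18.26)
  expect_identical(res$method, "woolf")
  expect_false(res$correction_applied)
  expect_equal(odds_ratio_2x2(7, 7, 7, 7)$or, 1.0)
  corr <- odds_ratio_2x2(10, 0, 5, 10)
  expect_true(corr$correction_applied)
  expect_equal(corr$or, (10.5 * 10.5) / (0.5 * 5.5), tolerance = 1e-12)
  expect_equal(round(corr$or, 2), 40.09)
  expect_error(odds_ratio_2x2(0, 5, 0, 10), "margin is empty")
  # reciprocal identity (no zero cells)
  expect_equal(odds_ratio_2x2(8, 3, 5, 9)$or *
                 odds_ratio_2x2(3, 8, 9, 5)$or, 1.0, tolerance = 1e-12)
})

test_that("logistic OR equals the cross-product ratio for one predictor", {
  set.seed(60)
  outcome <- rep(c(TRUE, FALSE), c(120, 280))
  exposure <- c(rep(c(TRUE, FALSE), c(50, 70)),
                rep(c(TRUE, FALSE), c(60, 220)))
  res <- odds_ratio_logistic(outcome, exposure)
  expect_identical(res$method, "logistic_wald")
  cross <- (50 * 220) / (60 * 70)
  expect_equal(round(res$or, 4), round(cross, 4))
  # null fixture: exposure independent of outcome, CI straddles 1
  out0 <- rep(c(TRUE, FALSE), each = 200)
  exp0 <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 100)
  res0 <- odds_ratio_logistic(out0, exp0)
  expect_true(res0$ci_low <= 1 && res0$ci_high >= 1)
  # separation: an empty cell falls back to the corrected 2x2
  sep <- odds_ratio_logistic(rep(c(TRUE, FALSE), c(20, 20)),
                             rep(c(TRUE, FALSE), c(20, 20)))
  expect_true(sep$correction_applied)
  expect_match(sep$note, "separation")
  # Woolf and logistic agree within 1% when all cells >= 20
  w <- odds_ratio_2x2(50, 70, 60, 220)
  expect_lt(abs(res$or - w$or) / w$or, 0.01)
})

test_that("rule_or handles missing values and degenerate exposure", {
  tab <- decision_table(
    data.frame(a = c("1", "1", "0", "0", NA, "1"),
               b = c("1", "1", "1", "0", "1", "1")),
    c("affected", "affected", "unaffected", "unaffected", "affected",
      "unaffected"))
  res <- rule_or(rule(c(a = "1", b = "1"), "affected"), tab)
  expect_match(res$note, "1 children excluded for missing condition values")
  expect_s3_class(res, "or_result")
  # nobody fulfils the rule -> undefined, with a note
  res_none <- rule_or(rule(c(a = "1", b = "9"), "affected"), tab)
  expect_true(is.na(res_none$or))
  expect_match(res_none$note, "no child fulfils the rule")
  # everybody fulfils the rule -> no reference group
  all_tab <- decision_table(data.frame(a = rep("1", 6)),
                            rep(c("affected", "unaffected"), 3))
  expect_error(rule_or(rule(c(a = "1"), "affected"), all_tab),
               "no reference group")
  expect_error(rule_or(rule(c(zz = "1"), "affected"), tab), "not in table")
})

test_that("a planted OR-7 pair is recovered within its own CI", {
  spec <- cohort_spec("orr", 20000L,
                      data.frame(name = c("g1", "g2"),
                                 major_freq = c(0.7, 0.6)),
                      baseline = base5(eczema = 0.10),
                      effects = list(effect_spec("gene_gene",
                                                 c(g1 = "2", g2 = "1"),
                                                 7, "eczema_dx")),
                      missing_rate = 0, seed = 700L)
  tab <- phenotype_table(simulate_cohort(spec), "eczema")
  res <- rule_or(rule(c(g1 = "2", g2 = "1"), "affected"), tab)
  expect_true(res$ci_low <= 7 && res$ci_high >= 7)
})

test_that("a protective planted rule estimates below 1", {
  spec <- cohort_spec("prot", 20000L,
                      data.frame(name = c("g1", "g2"),
                                 major_freq = c(0.7, 0.6)),
                      baseline = base5(eczema = 0.15),
                      effects = list(effect_spec("gene_gene",
                                                 c(g1 = "2", g2 = "1"),
                                                 0.2, "eczema_dx")),
                      missing_rate = 0, seed = 20L)
  tab <- phenotype_table(simulate_cohort(spec), "eczema")
  res <- rule_or(rule(c(g1 = "2", g2 = "1"), "affected"), tab)
  expect_lt(res$or, 1)
})

test_that("external validation checks factor availability and direction", {
  other <- decision_table(
    data.frame(g1 = c("0", "1", "2", "1"), g2 = c("1", "0", "1", "2")),
    c("affected", "unaffected", "affected", "unaffected"))
  # attribute absent in the other cohort
  v <- validate_rule_external(rule(c(env9 = "yes"), "affected"), other)
  expect_false(v$validatable)
  expect_true(is.na(v$direction_match))
  expect_null(v$other_or)
  # category absent from the other cohort's domain
  v2 <- validate_rule_external(rule(c(g1 = "9"), "affected"), other)
  expect_false(v2$validatable)
  # hand-built contradiction: affected-rule with OR < 1 in the other cohort
  contra <- decision_table(
    data.frame(g1 = rep(c("2", "0"), c(10, 10))),
    rep(c("affected", "unaffected", "affected", "unaffected"),
        c(2, 8, 8, 2)))
  v3 <- validate_rule_external(rule(c(g1 = "2"), "affected"), contra)
  expect_true(v3$validatable)
  expect_false(v3$direction_match)
  expect_lt(v3$other_or$or, 1)
})

test_that("a shared planted effect replicates direction across cohorts", {
  ok <- 0L
  for (sd in 1:5) {
    snps <- data.frame(name = c("g1", "g2"), major_freq = c(0.7, 0.6))
    eff <- list(effect_spec("gene_gene", c(g1 = "2", g2 = "1"), 3,
                            "wheeze_12m"))
    sA <- cohort_spec("a", 2000L, snps, baseline = base5(wheeze = 0.12),
                      effects = eff, missing_rate = 0, seed = sd * 7L)
    sB <- cohort_spec("b", 2000L, snps, baseline = base5(wheeze = 0.12),
                      effects = eff, missing_rate = 0, seed = sd * 7L + 3L)
    pr <- simulate_cohort_pair(sA, sB, c("g1", "g2"))
    tb <- phenotype_table(pr$cohortB, "wheeze")
    v <- validate_rule_external(rule(c(g1 = "2", g2 = "1"), "affected"), tb)
    ok <- ok + isTRUE(v$direction_match)
  }
  expect_identical(ok, 5L)
})

test_that("dose-response references level 0 and rises under interaction", {
  spec <- cohort_spec("dr", 20000L,
                      data.frame(name = c("g1", "g2", "g3"),
                                 major_freq = c(0.7, 0.6, 0.8)),
                      baseline = base5(),
                      effects = list(effect_spec("gene_gene",
                                                 c(g1 = "2", g2 = "1"),
                                                 3.5, "asthma_dx_ever")),
                      missing_rate = 0, seed = 19L)
  tab <- phenotype_table(simulate_cohort(spec), "asthma")
  dr <- dose_response(rule(c(g1 = "2", g2 = "1"), "affected"), tab)
  expect_identical(dr$level, 0:2)
  expect_equal(dr$or[1], 1.0)
  expect_identical(sum(dr$n), n_objects(classified(tab)))
  expect_gt(dr$or[3], dr$or[2])
  expect_error(dose_response(rule(c(g1 = "2"), "affected"), tab),
               "at least 2 conditions")
})

test_that("rule_statistics assembles per-rule tests with a per-model family", {
  tab <- separable_table()
  model <- induce_rules(tab, filters = list(min_support = 1L,
                                            min_accuracy = 0))
  st <- rule_statistics(model, tab)
  expect_identical(nrow(st), length(model$rules))
  expect_true(all(c("id", "rule", "decision", "N", "K", "n", "k", "p",
                    "p_adj", "or", "ci_low", "ci_high") %in% names(st)))
  expect_equal(st$p_adj, pmin(1, nrow(st) * st$p))
  expect_true(all(st$p > 0 & st$p <= 1))
  expect_true(all(st$k <= st$n))
})
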