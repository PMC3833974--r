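test_that("genotype marginals follow binomial(2, p) at large n", {
  spec <- cohort_spec("hwe", 10000L,
                      data.frame(name = "g1", major_freq = 0.7),
                      baseline = base5(), missing_rate = 0, seed = 4L)
  g <- simulate_genotypes(spec)
  freq <- table(factor(g$g1, levels = c("2", "1", "0"))) / 10000
  # binomial(2, 0.7): P(2 copies)=0.49, P(1)=0.42, P(0)=0.09; 3 SE < 0.02
  expect_equal(unname(freq[["2"]]), 0.49, tolerance = 0.02 / 0.49)
  expect_equal(unname(freq[["1"]]), 0.42, tolerance = 0.02 / 0.42)
  expect_equal(unname(freq[["0"]]), 0.09, tolerance = 0.02 / 0.09)
})

test_that("a fixed major frequency of 1 yields only homozygous majors", {
  spec <- cohort_spec("fix", 200L, data.frame(name = "g1", major_freq = 1),
                      baseline = base5(), missing_rate = 0, seed = 1L)
  expect_true(all(simulate_genotypes(spec)$g1 == "2"))
})

test_that("genotype simulation is deterministic and per-SNP substreamed", {
  two <- data.frame(name = c("g1", "g2"), major_freq = c(0.7, 0.6))
  spec <- cohort_spec("det", 500L, two, baseline = base5(),
                      missing_rate = 0, seed = 8L)
  g1 <- simulate_genotypes(spec)
  g2 <- simulate_genotypes(spec)
  expect_identical(g1, g2)
  # listing the SNPs in the other order must not change either column
  spec_rev <- cohort_spec("det", 500L, two[2:1, ], baseline = base5(),
                          missing_rate = 0, seed = 8L)
  g3 <- simulate_genotypes(spec_rev)
  expect_identical(g3$g1, g1$g1)
  expect_identical(g3$g2, g1$g2)
})

test_that("environment categories match their declared probabilities", {
  yn <- function(p) c(yes = p, no = 1 - p)
  spec <- cohort_spec("env", 10000L,
                      data.frame(name = "g1", major_freq = 0.7),
                      env_factors = list(e1 = yn(0.35),
                                         e2 = c(lo = 0.2, mid = 0.5,
                                                hi = 0.3)),
                      baseline = base5(), missing_rate = 0, seed = 6L)
  env <- simulate_environment(spec)
  expect_equal(mean(env$e1 == "yes"), 0.35, tolerance = 0.02 / 0.35)
  expect_equal(mean(env$e2 == "mid"), 0.5, tolerance = 0.02 / 0.5)
  expect_equal(mean(env$e2 == "lo"), 0.2, tolerance = 0.02 / 0.2)
})

test_that("exposure clusters correlate factors; zero strength decouples them", {
  yn <- function(p) c(yes = p, no = 1 - p)
  mk <- function(strength) {
    cohort_spec("cl", 5000L, data.frame(name = "g1", major_freq = 0.7),
                env_factors = list(e1 = yn(0.5), e2 = yn(0.5)),
                clusters = list(list(factors = c("e1", "e2"),
                                     strength = strength)),
                baseline = base5(asthma = 0.1), missing_rate = 0, seed = 5L)
  }
  env <- simulate_environment(mk(0.6))
  tt <- table(env$e1, env$e2)
  phi <- (tt[1, 1] * tt[2, 2] - tt[1, 2] * tt[2, 1]) /
    sqrt(prod(rowSums(tt)) * prod(colSums(tt)))
  expect_gt(phi, 0.2)
  env0 <- simulate_environment(mk(0))
  expect_gt(chisq.test(table(env0$e1, env0$e2))$p.value, 0.01)
})

test_that("baseline prevalence is realized without planted effects", {
  spec <- cohort_spec("bl", 10000L,
                      data.frame(name = "g1", major_freq = 0.7),
                      baseline = base5(asthma = 0.15), missing_rate = 0,
                      seed = 9L)
  co <- simulate_cohort(spec)
  expect_equal(mean(co$records$asthma_dx_ever), 0.15, tolerance = 0.01 / 0.15)
})

test_that("planted odds ratios are recovered from the crude 2x2", {
  for (o in c(1.5, 3)) {
    spec <- cohort_spec("orr", 20000L,
                        data.frame(name = c("g1", "g2"),
                                   major_freq = c(0.7, 0.6)),
                        baseline = base5(eczema = 0.10),
                        effects = list(effect_spec("gene_gene",
                                                   c(g1 = "2", g2 = "1"),
                                                   o, "eczema_dx")),
                        missing_rate = 0, seed = round(o * 100))
    tab <- phenotype_table(simulate_cohort(spec), "eczema")
    res <- rule_or(rule(c(g1 = "2", g2 = "1"), "affected"), tab)
    expect_true(res$ci_low <= o && o <= res$ci_high)
  }
})

test_that("a planted OR-3.2 interaction lands near its generating value", {
  spec <- cohort_spec("or32", 20000L,
                      data.frame(name = c("g1", "g2"),
                                 major_freq = c(0.7, 0.6)),
                      baseline = base5(wheeze = 0.12),
                      effects = list(effect_spec("gene_gene",
                                                 c(g1 = "2", g2 = "1"),
                                                 3.2, "wheeze_12m")),
                      missing_rate = 0, seed = 21L)
  tab <- phenotype_table(simulate_cohort(spec), "wheeze")
  res <- rule_or(rule(c(g1 = "2", g2 = "1"), "affected"), tab)
  expect_gt(res$or, 2.6)
  expect_lt(res$or, 3.9)
  expect_true(res$ci_low <= 3.2 && res$ci_high >= 3.2)
})

test_that("IgE magnitudes are consistent with sensitization phenotypes", {
  spec <- cohort_spec("ige", 3000L,
                      data.frame(name = "g1", major_freq = 0.7),
                      baseline = base5(sens = 0.35), missing_rate = 0,
                      seed = 14L)
  co <- simulate_cohort(spec)
  top <- pmax(co$records$ige_inhalant, co$records$ige_food, na.rm = TRUE)
  aff <- co$phenotypes$sens_0.35 == "affected"
  expect_identical(aff, top >= 0.35)
  expect_true(all(top >= 0))
  # strict sensitization implies loose sensitization
  strict <- co$phenotypes$sens_3.5 == "affected"
  expect_true(all(aff[strict]))
})

test_that("the default two-cohort scenario matches the study dimensions", {
  dsp <- default_cohort_specs()
  pr <- simulate_cohort_pair(dsp$birth_cohort, dsp$cross_sectional, dsp$shared)
  A <- pr$cohortA; B <- pr$cohortB
  expect_identical(length(A$ids), 2033L)
  expect_identical(length(B$ids), 3113L)
  kindA <- vapply(A$attributes, `[[`, character(1), "kind")
  kindB <- vapply(B$attributes, `[[`, character(1), "kind")
  expect_identical(sum(kindA == "snp"), 110L)
  expect_identical(sum(kindB == "snp"), 188L)
  expect_identical(sum(kindB %in% c("environment", "lifestyle")), 33L)
  expect_identical(length(dsp$shared), 110L)
  # ingredients without planted effects stay within 2 percentage points of
  # their baselines; ingredients carrying a planted risk effect (wheeze in
  # both cohorts, asthma in B) can only sit above them
  base_A <- c(asthma_dx_ever = 0.150, wheeze_12m = 0.085,
              eczema_dx = 0.093, rhino_symptoms_12m = 0.154)
  base_B <- c(asthma_dx_ever = 0.045, wheeze_12m = 0.055,
              eczema_dx = 0.131, rhino_symptoms_12m = 0.070)
  for (ing in c("asthma_dx_ever", "eczema_dx", "rhino_symptoms_12m"))
    expect_lt(abs(mean(A$records[[ing]]) - base_A[[ing]]), 0.02)
  for (ing in c("eczema_dx", "rhino_symptoms_12m"))
    expect_lt(abs(mean(B$records[[ing]]) - base_B[[ing]]), 0.02)
  expect_gt(mean(A$records$wheeze_12m), base_A[["wheeze_12m"]])
  expect_gt(mean(B$records$wheeze_12m), base_B[["wheeze_12m"]])
  expect_gt(mean(B$records$asthma_dx_ever), base_B[["asthma_dx_ever"]])
  expect_lt(abs(mean(A$phenotypes$sens_0.35 == "affected") - 0.353), 0.02)
})

test_that("cohort specs round-trip through YAML", {
  spec <- cohort_spec("yy", 500L,
                      data.frame(name = c("g1", "g2"),
                                 major_freq = c(0.7, 0.6)),
                      env_factors = list(e1 = c(yes = 0.4, no = 0.6),
                                         e2 = c(yes = 0.5, no = 0.5)),
                      clusters = list(list(factors = c("e1", "e2"),
                                           strength = 0.3)),
                      baseline = base5(),
                      effects = list(effect_spec("gene_gene",
                                                 c(g1 = "2", g2 = "1"),
                                                 3, "wheeze_12m")),
                      missing_rate = 0.05, seed = 77L)
  path <- tempfile(fileext = ".yaml")
  write_cohort_spec(spec, path)
  back <- read_cohort_spec(path)
  expect_identical(back$name, spec$name)
  expect_identical(back$n, spec$n)
  expect_equal(back$snps, spec$snps)
  expect_equal(back$env_factors, spec$env_factors)
  expect_equal(back$baseline, spec$baseline)
  expect_equal(back$missing_rate, spec$missing_rate)
  expect_identical(back$seed, spec$seed)
  expect_equal(back$effects[[1]]$conditions, spec$effects[[1]]$conditions)
  expect_equal(back$effects[[1]]$odds_ratio, spec$effects[[1]]$odds_ratio)
  # and the round-tripped spec generates the identical cohort
  expect_identical(simulate_cohort(back)$cells, simulate_cohort(spec)$cells)
})

test_that("spec validation rejects malformed inputs", {
  snps <- data.frame(name = "g1", major_freq = 0.7)
  expect_error(cohort_spec("x", 100L,
                           data.frame(name = c("g1", "g1"),
                                      major_freq = c(0.7, 0.6)),
                           baseline = base5()),
               "duplicate SNP names")
  expect_error(cohort_spec("x", 100L, snps,
                           env_factors = list(e1 = c(0.4, 0.6)),
                           baseline = base5()),
               "must be named and sum to 1")
  expect_error(cohort_spec("x", 100L, snps,
                           baseline = c(base5(), list(extra = 0.5))),
               "unknown baseline ingredient")
  expect_error(cohort_spec("x", 100L, snps,
                           baseline = base5(asthma = 1.2)),
               "strictly in \\(0,1\\)")
  expect_error(cohort_spec("x", 100L, snps, baseline = base5(),
                           effects = list(effect_spec("main",
                                                      c(g9 = "2"), 2,
                                                      "wheeze_12m"))),
               "undeclared attribute")
  expect_error(effect_spec("main", c("2"), 2, "wheeze_12m"),
               "named vector")
  expect_error(effect_spec("main", c(g1 = "2"), 2, "banana"),
               "unknown effect target")
})

test_that("cohort pairing enforces shared-SNP compatibility", {
  snpsA <- data.frame(name = c("g1", "g2"), major_freq = c(0.7, 0.6))
  snpsB_badfreq <- data.frame(name = c("g1", "g2"),
                              major_freq = c(0.7, 0.65))
  sA <- cohort_spec("a", 200L, snpsA, baseline = base5(), seed = 1L)
  sB <- cohort_spec("b", 200L, snpsB_badfreq, baseline = base5(),
                    seed = 2L)
  expect_error(simulate_cohort_pair(sA, sB, c("g1", "g2")),
               "identical major-allele frequencies")
  sB2 <- cohort_spec("b", 200L, snpsA, baseline = base5(),
                     effects = list(effect_spec("gene_gene",
                                                c(g1 = "2", g2 = "1"),
                                                3, "wheeze_12m")),
                     seed = 2L)
  expect_error(simulate_cohort_pair(sA, sB2, c("g1", "g2")),
               "must be identical in both cohorts")
  expect_error(simulate_cohort_pair(sA, sB2, c("g1", "g9")),
               "declared in both cohort specs")
})

test_that("phenotype_table restricts attributes and validates the name", {
  spec <- cohort_spec("pt", 300L,
                      data.frame(name = c("g1", "g2"),
                                 major_freq = c(0.7, 0.6)),
                      env_factors = list(e1 = c(yes = 0.4, no = 0.6)),
                      baseline = base5(), missing_rate = 0, seed = 3L)
  co <- simulate_cohort(spec)
  tab <- phenotype_table(co, "wheeze")
  expect_s3_class(tab, "decision_table")
  expect_setequal(attribute_names(tab), c("g1", "g2", "e1"))
  tab_g <- phenotype_table(co, "wheeze", attrs = c("g1", "g2"))
  expect_identical(attribute_names(tab_g), c("g1", "g2"))
  expect_error(phenotype_table(co, "banana"), "unknown phenotype")
})
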