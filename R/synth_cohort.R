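#' Specify a planted effect on the odds scale
#'
#' A planted effect multiplies the odds of one raw health ingredient by
#' `odds_ratio` for every child satisfying *all* of its conditions (a child
#' missing a condition attribute never satisfies the effect). Effects combine
#' additively on the log-odds (liability) scale, matching how the analysis
#' reports associations as odds ratios.
#'
#' @param kind `"main"`, `"gene_gene"` or `"gene_environment"`.
#' @param conditions named character vector: attribute name -> required
#'   category code.
#' @param odds_ratio positive multiplicative effect on the odds.
#' @param target name of the raw health ingredient the effect acts on:
#'   one of `"asthma_dx_ever"`, `"wheeze_12m"`, `"eczema_dx"`,
#'   `"rhino_symptoms_12m"`, `"sensitized"`.
#' @return an object of class `"effect_spec"`.
#' @export
effect_spec <- function(kind = c("main", "gene_gene", "gene_environment"),
                        conditions, odds_ratio, target) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(odds_ratio), length(odds_ratio) == 1L, odds_ratio > 0)
  nms <- names(conditions) # before vapply: USE.NAMES would invent names
  conditions <- vapply(conditions, as.character, character(1),
                       USE.NAMES = FALSE)
  names(conditions) <- nms
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("conditions must be a named vector (attribute -> category)")
  if (!target %in% ingredient_names())
    stop("unknown effect target '", target, "'")
  structure(list(kind = kind, conditions = conditions,
                 odds_ratio = odds_ratio, target = target),
            class = "effect_spec")
}

ingredient_names <- function() {
  c("asthma_dx_ever", "wheeze_12m", "eczema_dx", "rhino_symptoms_12m",
    "sensitized")
}

#' Specify a synthetic cohort
#'
#' Defines everything the generator needs for one cohort: sample size, SNP
#' major-allele frequencies (genotypes are drawn under Hardy-Weinberg
#' equilibrium), categorical environment/lifestyle factors with optional
#' clustering through a shared latent lifestyle variable, a missingness
#' rate, baseline prevalences of the raw health ingredients, and the planted
#' effects.
#'
#' @param name cohort label.
#' @param n number of children.
#' @param snps data.frame with columns `name` and `major_freq` (major-allele
#'   frequency in (0,1]).
#' @param env_factors named list: factor name -> named numeric vector of
#'   category probabilities (must sum to 1).
#' @param clusters optional list of lists with elements `factors` (character
#'   vector of binary env factor names) and `strength` in \[0,1\]: clustered
#'   factors share a latent binary lifestyle variable that raises their
#'   pairwise concordance.
#' @param missing_rate fraction of genotype/environment cells set missing,
#'   in \[0, 0.2\].
#' @param baseline named list of ingredient prevalences in (0,1); names from
#'   `asthma_dx_ever`, `wheeze_12m`, `eczema_dx`, `rhino_symptoms_12m`,
#'   `sensitized`.
#' @param effects list of [effect_spec()] objects.
#' @param seed integer master seed for this cohort.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(name, n, snps, env_factors = list(), clusters = list(),
                        missing_rate = 0.02, baseline, effects = list(),
                        seed = 1L) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "major_freq") %in% names(snps)),
            all(snps$major_freq > 0 & snps$major_freq <= 1),
            missing_rate >= 0, missing_rate <= 0.2,
            n >= 1)
  if (anyDuplicated(snps$name)) stop("duplicate SNP names")
  for (nm in names(env_factors)) {
    p <- env_factors[[nm]]
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8)
      stop("env factor '", nm, "': category probabilities must be named and sum to 1")
  }
  stopifnot(is.list(baseline), length(baseline) > 0)
  if (!all(names(baseline) %in% ingredient_names()))
    stop("unknown baseline ingredient(s)")
  if (any(unlist(baseline) <= 0 | unlist(baseline) >= 1))
    stop("baseline prevalences must lie strictly in (0,1)")
  for (e in effects) {
    stopifnot(inherits(e, "effect_spec"))
    known <- c(snps$name, names(env_factors))
    bad <- setdiff(names(e$conditions), known)
    if (length(bad))
      stop("effect references undeclared attribute(s): ",
           paste(bad, collapse = ", "))
  }
  for (cl in clusters) {
    stopifnot(all(cl$factors %in% names(env_factors)),
              cl$strength >= 0, cl$strength <= 1)
  }
  structure(list(name = name, n = as.integer(n), snps = snps,
                 env_factors = env_factors, clusters = clusters,
                 missing_rate = missing_rate, baseline = baseline,
                 effects = effects, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @exportS3Method print cohort_spec
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s: n=%d, %d SNPs, %d environment factors, %d planted effect(s)\n",
              x$name, x$n, nrow(x$snps), length(x$env_factors),
              length(x$effects)))
  invisible(x)
}

#' Simulate SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Each child's major-allele copy count at a SNP is Binomial(2, major-allele
#' frequency); cells are set missing at the spec's `missing_rate`. Each SNP
#' draws from a substream keyed by its name, so results are invariant to SNP
#' order.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of character codes `"0"`/`"1"`/`"2"` (NA = missing),
#'   one column per SNP.
#' @export
simulate_genotypes <- function(spec) {
  n <- spec$n
  out <- vector("list", nrow(spec$snps))
  names(out) <- spec$snps$name
  for (i in seq_len(nrow(spec$snps))) {
    nm <- spec$snps$name[i]
    p <- spec$snps$major_freq[i]
    g <- with_seed(substream_seed(spec$seed, paste0("geno:", nm)),
                   rbinom(n, 2L, p))
    if (spec$missing_rate > 0) {
      miss <- with_seed(substream_seed(spec$seed, paste0("geno-miss:", nm)),
                        runif(n) < spec$missing_rate)
      g[miss] <- NA_integer_
    }
    out[[nm]] <- as.character(g)
  }
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Simulate categorical environment and lifestyle factors
#'
#' Factors are drawn independently per child from their category
#' probabilities, except factors declared in a cluster: those share a latent
#' binary lifestyle variable (per cluster, prevalence 0.5). With probability
#' `strength` a clustered factor copies the latent state (first category when
#' the latent variable is 1, last category otherwise), which raises the
#' pairwise concordance of the cluster's factors; with strength 0 factors are
#' independent.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of character category codes (NA = missing).
#' @export
simulate_environment <- function(spec) {
  n <- spec$n
  latent <- list()
  factor_cluster <- list()
  for (ci in seq_along(spec$clusters)) {
    cl <- spec$clusters[[ci]]
    z <- with_seed(substream_seed(spec$seed, paste0("cluster:", ci)),
                   rbinom(n, 1L, 0.5))
    for (f in cl$factors)
      factor_cluster[[f]] <- list(z = z, strength = cl$strength)
  }
  out <- vector("list", length(spec$env_factors))
  names(out) <- names(spec$env_factors)
  for (nm in names(spec$env_factors)) {
    probs <- spec$env_factors[[nm]]
    cats <- names(probs)
    v <- with_seed(substream_seed(spec$seed, paste0("env:", nm)), {
      base <- sample(cats, n, replace = TRUE, prob = probs)
      if (!is.null(factor_cluster[[nm]])) {
        fc <- factor_cluster[[nm]]
        copy <- runif(n) < fc$strength
        base[copy] <- ifelse(fc$z[copy] == 1L, cats[1L],
                             cats[length(cats)])
      }
      base
    })
    if (spec$missing_rate > 0) {
      miss <- with_seed(substream_seed(spec$seed, paste0("env-miss:", nm)),
                        runif(n) < spec$missing_rate)
      v[miss] <- NA_character_
    }
    out[[nm]] <- v
  }
  if (length(out) == 0L)
    return(data.frame(row.names = seq_len(n))[, 0, drop = FALSE])
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf, seed_key,
                         master) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  u <- with_seed(substream_seed(master, seed_key), runif(n, plo, phi))
  stats::qlnorm(u, meanlog, sdlog)
}

#' Simulate raw health records
#'
#' Each binary ingredient (asthma diagnosis ever, wheeze in the last 12
#' months, eczema diagnosis, rhinitis symptoms, atopic sensitization) is
#' drawn from a logistic model: log-odds = logit(baseline) + sum of
#' log odds ratios over the planted effects whose conditions the child
#' fulfils. Allergen-specific IgE values (inhalant and food, kU/L) are drawn
#' from a two-component log-normal mixture whose components straddle the
#' 0.35 and 3.5 kU/L thresholds; the mixing is governed by the realized
#' sensitization state, so that IgE >= 0.35 holds exactly for sensitized
#' children.
#'
#' @param spec a [cohort_spec()].
#' @param genotypes output of [simulate_genotypes()].
#' @param environment output of [simulate_environment()].
#' @return data.frame of raw health records with columns `asthma_dx_ever`,
#'   `wheeze_12m`, `eczema_dx`, `rhino_symptoms_12m`, `ige_inhalant`,
#'   `ige_food`.
#' @export
simulate_raw_health <- function(spec, genotypes, environment) {
  n <- spec$n
  if (nrow(genotypes) != n ||
      (ncol(environment) > 0 && nrow(environment) != n))
    stop("genotype/environment tables not aligned with spec")
  attrs <- if (ncol(environment) > 0) cbind(genotypes, environment)
           else genotypes

  effect_match <- function(e) {
    ok <- rep(TRUE, n)
    for (a in names(e$conditions)) {
      v <- attrs[[a]]
      ok <- ok & !is.na(v) & v == e$conditions[[a]]
    }
    ok
  }

  draw_ingredient <- function(ing) {
    base <- spec$baseline[[ing]]
    if (is.null(base)) stop("no baseline prevalence for ingredient '", ing, "'")
    lo <- rep(qlogis(base), n)
    for (e in spec$effects) {
      if (e$target != ing) next
      lo <- lo + log(e$odds_ratio) * effect_match(e)
    }
    with_seed(substream_seed(spec$seed, paste0("health:", ing)),
              runif(n) < plogis(lo))
  }

  rec <- data.frame(
    asthma_dx_ever = draw_ingredient("asthma_dx_ever"),
    wheeze_12m = draw_ingredient("wheeze_12m"),
    eczema_dx = draw_ingredient("eczema_dx"),
    rhino_symptoms_12m = draw_ingredient("rhino_symptoms_12m")
  )
  sens <- draw_ingredient("sensitized")

  # IgE mixture components: ln N(-2, 0.5^2) below the 0.35 kU/L threshold and
  # ln N(1.25, 1^2) above it; component choice (truncated at 0.35) is pinned
  # to the sensitization state. Which panel (inhalant/food/both) carries the
  # sensitizing value is drawn separately.
  carrier <- with_seed(substream_seed(spec$seed, "ige-carrier"),
                       sample(c("inhalant", "food", "both"), n, replace = TRUE,
                              prob = c(0.45, 0.35, 0.20)))
  low_i <- rlnorm_trunc(n, -2, 0.5, upper = 0.35 - 1e-9,
                        seed_key = "ige-low-inh", master = spec$seed)
  low_f <- rlnorm_trunc(n, -2, 0.5, upper = 0.35 - 1e-9,
                        seed_key = "ige-low-food", master = spec$seed)
  hi_i <- rlnorm_trunc(n, 1.25, 1, lower = 0.35,
                       seed_key = "ige-hi-inh", master = spec$seed)
  hi_f <- rlnorm_trunc(n, 1.25, 1, lower = 0.35,
                       seed_key = "ige-hi-food", master = spec$seed)
  inh_hi <- sens & carrier %in% c("inhalant", "both")
  food_hi <- sens & carrier %in% c("food", "both")
  rec$ige_inhalant <- ifelse(inh_hi, hi_i, low_i)
  rec$ige_food <- ifelse(food_hi, hi_f, low_f)
  rec
}

#' Simulate one full cohort
#'
#' Runs the genotype, environment and health generators and derives the
#' eleven phenotype decision columns.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `"synth_cohort"`: list with `name`, `spec`,
#'   `ids`, `cells` (all condition attributes as character codes),
#'   `attributes` (list of [attribute()]), `records` (raw health records)
#'   and `phenotypes` (data.frame of 11 phenotype status columns).
#' @export
simulate_cohort <- function(spec) {
  geno <- simulate_genotypes(spec)
  env <- simulate_environment(spec)
  cells <- if (ncol(env) > 0) cbind(geno, env) else geno
  ids <- sprintf("%s_%05d", spec$name, seq_len(spec$n))
  rownames(cells) <- NULL
  attrs <- c(
    lapply(spec$snps$name, function(nm) attribute(nm, "snp", c("0", "1", "2"))),
    lapply(names(spec$env_factors), function(nm)
      attribute(nm, "environment", names(spec$env_factors[[nm]])))
  )
  names(attrs) <- c(spec$snps$name, names(spec$env_factors))
  records <- simulate_raw_health(spec, geno, env)
  phen <- derive_phenotypes(records)
  structure(list(name = spec$name, spec = spec, ids = ids, cells = cells,
                 attributes = attrs, records = records, phenotypes = phen),
            class = "synth_cohort")
}

#' @exportS3Method print synth_cohort
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %s: %d children, %d attributes, %d phenotypes\n",
              x$name, length(x$ids), ncol(x$cells), ncol(x$phenotypes)))
  invisible(x)
}

#' Build a phenotype-specific decision table from a cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @param phenotype one of the 11 phenotype names (see [derive_phenotypes()]).
#' @param attrs optional attribute subset (default: all).
#' @return a [decision_table()] whose decision is the phenotype status.
#' @export
phenotype_table <- function(cohort, phenotype, attrs = NULL) {
  if (!phenotype %in% names(cohort$phenotypes))
    stop("unknown phenotype '", phenotype, "'")
  cells <- cohort$cells
  meta <- cohort$attributes
  if (!is.null(attrs)) {
    cells <- cells[, attrs, drop = FALSE]
    meta <- meta[attrs]
  }
  decision_table(cells, cohort$phenotypes[[phenotype]], ids = cohort$ids,
                 attributes = meta)
}

#' Simulate a paired two-cohort study
#'
#' Generates two cohorts that share a subset of SNPs (same names, major
#' allele frequencies and planted effects in both), emulating a design where
#' rules found in one material are validated in the other. The manifest
#' records the shared attributes and planted truth for recovery scoring.
#'
#' @param specA,specB [cohort_spec()] objects (seeds should differ unless
#'   identical draws are wanted).
#' @param shared character vector of SNP names present in both cohorts.
#' @return list with `cohortA`, `cohortB` and `manifest` (shared SNPs,
#'   shared environment factors, planted effects, cluster definitions --
#'   the cluster construct is a synthetic-device flag, not an estimate of
#'   any real exposure correlation).
#' @export
simulate_cohort_pair <- function(specA, specB, shared) {
  if (!all(shared %in% specA$snps$name) || !all(shared %in% specB$snps$name))
    stop("shared SNPs must be declared in both cohort specs")
  fa <- setNames(specA$snps$major_freq, specA$snps$name)[shared]
  fb <- setNames(specB$snps$major_freq, specB$snps$name)[shared]
  if (!isTRUE(all.equal(fa, fb)))
    stop("shared SNPs must have identical major-allele frequencies")
  eff_key <- function(e) paste(e$target, e$odds_ratio,
                               paste(names(e$conditions), e$conditions,
                                     sep = "=", collapse = "&"))
  shared_eff <- function(spec) {
    keep <- vapply(spec$effects,
                   function(e) all(names(e$conditions) %in% shared),
                   logical(1))
    sort(vapply(spec$effects[keep], eff_key, character(1)))
  }
  if (!identical(shared_eff(specA), shared_eff(specB)))
    stop("planted effects on shared SNPs must be identical in both cohorts")
  cohortA <- simulate_cohort(specA)
  cohortB <- simulate_cohort(specB)
  shared_env <- intersect(names(specA$env_factors), names(specB$env_factors))
  manifest <- list(
    shared_snps = shared,
    shared_env_factors = shared_env,
    n = c(specA$n, specB$n),
    effects = list(
      cohortA = lapply(specA$effects, unclass),
      cohortB = lapply(specB$effects, unclass)
    ),
    clusters = list(cohortA = specA$clusters, cohortB = specB$clusters),
    note = paste("exposure clustering is a synthetic construct;",
                 "no real joint exposure distribution is emulated")
  )
  list(cohortA = cohortA, cohortB = cohortB, manifest = manifest)
}

#' Default paired-cohort study specification
#'
#' The shipped scenario mirrors the shape of a Swedish birth cohort (2033
#' children, 110 SNPs plus a handful of replication-grade lifestyle factors)
#' paired with a larger European cross-sectional study (3113 children, 188
#' SNPs of which the same 110 are shared, plus 33 environment/lifestyle
#' factors). Two interactions are planted: a two-SNP genotype combination
#' (codes 2 and 1) with odds ratio 3.2 on the wheeze ingredient, and a
#' baby-formula-plus-early-antibiotics pair with odds ratio 7 on the asthma
#' ingredient (available only in the larger cohort, as the detailed exposures
#' are). Baseline prevalences are set so realized phenotype frequencies land
#' near the two studies' published ranges.
#'
#' @param seedA,seedB master seeds for the two cohorts.
#' @return list with elements `birth_cohort`, `cross_sectional` (both
#'   [cohort_spec()]) and `shared` (character vector of 110 shared SNP names).
#' @export
default_cohort_specs <- function(seedA = 101L, seedB = 202L) {
  n_shared <- 110L
  n_extra <- 78L # larger cohort genotypes 188 SNPs in total
  shared_names <- sprintf("snp%03d", seq_len(n_shared))
  extra_names <- sprintf("snp%03d", n_shared + seq_len(n_extra))
  # deterministic spread of major-allele frequencies over [0.5, 0.95]
  freq_for <- function(i) 0.5 + 0.45 * ((i * 61) %% 100) / 100
  shared_freq <- freq_for(seq_len(n_shared))
  shared_freq[1:2] <- c(0.70, 0.60) # planted pair: P(code 2)=.49, P(code 1)=.48
  snpsA <- data.frame(name = shared_names, major_freq = shared_freq)
  snpsB <- rbind(snpsA,
                 data.frame(name = extra_names,
                            major_freq = freq_for(n_shared + seq_len(n_extra))))

  yn <- function(p_yes) c(yes = p_yes, no = 1 - p_yes)
  env_full <- list(
    formula_fed = yn(0.50),
    antibiotics_1y = yn(0.40),
    farm_living = yn(0.20),
    farm_milk = yn(0.25),
    farm_animal_contact = yn(0.30),
    mother_farm_pregnancy = yn(0.15),
    pets_early = yn(0.35),
    mother_smoking = yn(0.15),
    older_siblings = c(none = 0.45, one = 0.35, two_plus = 0.20),
    day_care = yn(0.60),
    wool_clothing = yn(0.20),
    anthro_lifestyle = yn(0.15)
  )
  for (i in 13:33)
    env_full[[sprintf("lifestyle%02d", i)]] <-
      c(`0` = 0.6, `1` = 0.3, `2` = 0.1)
  # replication-grade factors also recorded in the birth cohort (no detailed
  # farm/antibiotics exposures there)
  env_small <- env_full[c("pets_early", "mother_smoking", "older_siblings",
                          "day_care", "farm_milk", "wool_clothing",
                          "mother_farm_pregnancy", "farm_animal_contact")]
  clusters <- list(list(factors = c("farm_living", "farm_milk",
                                    "farm_animal_contact",
                                    "mother_farm_pregnancy"),
                        strength = 0.4))
  clusters_small <- list(list(factors = c("farm_milk",
                                          "farm_animal_contact",
                                          "mother_farm_pregnancy"),
                              strength = 0.4))

  gene_pair <- effect_spec("gene_gene",
                           c(snp001 = "2", snp002 = "1"),
                           odds_ratio = 3.2, target = "wheeze_12m")
  env_pair <- effect_spec("gene_environment",
                          c(formula_fed = "yes", antibiotics_1y = "yes"),
                          odds_ratio = 7, target = "asthma_dx_ever")

  birth_cohort <- cohort_spec(
    name = "birth_cohort", n = 2033L, snps = snpsA, env_factors = env_small,
    clusters = clusters_small, missing_rate = 0.02,
    baseline = list(asthma_dx_ever = 0.150, wheeze_12m = 0.085,
                    eczema_dx = 0.093, rhino_symptoms_12m = 0.154,
                    sensitized = 0.353),
    effects = list(gene_pair), seed = seedA)
  cross_sectional <- cohort_spec(
    name = "cross_sectional", n = 3113L, snps = snpsB, env_factors = env_full,
    clusters = clusters, missing_rate = 0.02,
    baseline = list(asthma_dx_ever = 0.045, wheeze_12m = 0.055,
                    eczema_dx = 0.131, rhino_symptoms_12m = 0.070,
                    sensitized = 0.288),
    effects = list(gene_pair, env_pair), seed = seedB)
  list(birth_cohort = birth_cohort, cross_sectional = cross_sectional,
       shared = shared_names)
}

#' Read or write a cohort specification as YAML
#'
#' @param path file path.
#' @param spec a [cohort_spec()] (for writing).
#' @return for reading, a [cohort_spec()]; for writing, `path` invisibly.
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  effects <- lapply(x$effects, function(e)
    effect_spec(e$kind, unlist(e$conditions), e$odds_ratio, e$target))
  env <- lapply(x$env_factors, function(p) unlist(p))
  cohort_spec(x$name, x$n,
              data.frame(name = vapply(x$snps, `[[`, character(1), "name"),
                         major_freq = vapply(x$snps, `[[`, numeric(1),
                                             "major_freq")),
              env_factors = env,
              clusters = x$clusters %||% list(),
              missing_rate = x$missing_rate %||% 0.02,
              baseline = x$baseline, effects = effects,
              seed = x$seed %||% 1L)
}

#' @rdname read_cohort_spec
#' @export
write_cohort_spec <- function(spec, path) {
  x <- list(
    name = spec$name, n = spec$n,
    snps = lapply(seq_len(nrow(spec$snps)), function(i)
      list(name = spec$snps$name[i], major_freq = spec$snps$major_freq[i])),
    env_factors = lapply(spec$env_factors, as.list),
    clusters = spec$clusters,
    missing_rate = spec$missing_rate,
    baseline = spec$baseline,
    effects = lapply(spec$effects, function(e)
      list(kind = e$kind, conditions = as.list(e$conditions),
           odds_ratio = e$odds_ratio, target = e$target)),
    seed = spec$seed
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
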