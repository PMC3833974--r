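#' Configuration for the analysis pipelines
#'
#' One object carries the settings every stage needs: the MCFS parameter
#' template (its seed is re-derived per cohort and phenotype from the
#' pipeline seed, so stages are independently reproducible), the rule
#' filters, the fold count, and the Bonferroni level used to call rules
#' significant.
#'
#' @param mcfs an [mcfs_params()] template.
#' @param filters rule filters, see [induce_rules()].
#' @param cv_k cross-validation folds.
#' @param rule_alpha family-wise level for Bonferroni-significant rules.
#' @param min_class smallest class size a phenotype needs in a cohort to be
#'   analyzed (phenotypes below it are skipped with a warning).
#' @param seed pipeline master seed.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mcfs = mcfs_params(),
                            filters = list(min_support = 5L,
                                           min_accuracy = 0.6,
                                           johnson_fraction = 0.9),
                            cv_k = 10L, rule_alpha = 0.05,
                            min_class = NULL, seed = 1L) {
  min_class <- min_class %||% max(10L, cv_k)
  structure(list(mcfs = mcfs, filters = filters, cv_k = as.integer(cv_k),
                 rule_alpha = rule_alpha, min_class = as.integer(min_class),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

analyze_phenotype <- function(table, other_table, config, label,
                              validate_rules = c("significant", "all")) {
  validate_rules <- match.arg(validate_rules)
  counts <- table(factor(table$decision, levels = decision_levels))
  if (min(counts) < config$min_class) {
    warning(label, ": skipped, smallest class has ", min(counts),
            " objects")
    return(NULL)
  }
  params <- config$mcfs
  params$seed <- substream_seed(config$seed, paste0("mcfs:", label))
  sig <- mcfs_significance(table, params)
  factors <- sig$significant
  if (length(factors) == 0L) {
    report <- data.frame(
      n_factors_significant = 0L, cv_coverage = 0, cv_accuracy = NA_real_,
      n_rules = 0L, n_validatable_rules = 0L, n_validated_rules = 0L)
    return(list(report = report, mcfs = sig, model = NULL, stats = NULL,
                validation = NULL, cv = NULL))
  }
  model <- induce_rules(table, filters = config$filters, attrs = factors)
  cv <- cross_validate(table, k = config$cv_k, filters = config$filters,
                       seed = substream_seed(config$seed,
                                             paste0("cv:", label)),
                       attrs = factors)
  stats <- rule_statistics(model, table)
  to_validate <- if (validate_rules == "significant") {
    which(stats$p_adj < config$rule_alpha)
  } else {
    seq_along(model$rules)
  }
  val <- lapply(model$rules[to_validate], function(r) {
    if (is.null(other_table)) return(NULL)
    validate_rule_external(r, other_table)
  })
  val <- Filter(Negate(is.null), val)
  n_validatable <- sum(vapply(val, `[[`, logical(1), "validatable"))
  n_validated <- sum(vapply(val, function(v)
    isTRUE(v$direction_match), logical(1)))
  report <- data.frame(
    n_factors_significant = length(factors),
    cv_coverage = 100 * cv$coverage,
    cv_accuracy = 100 * cv$accuracy,
    n_rules = length(model$rules),
    n_validatable_rules = n_validatable,
    n_validated_rules = n_validated)
  list(report = report, mcfs = sig, model = model, stats = stats,
       validation = val, cv = cv)
}

#' Gene-gene analysis across two cohorts
#'
#' For each phenotype in each cohort: feature selection on the shared SNPs,
#' rule induction on the significant factors, cross-validated model coverage
#' and accuracy, hypergeometric rule significance, and cross-cohort
#' direction validation of the Bonferroni-significant rules in the other
#' material. With all eleven phenotypes available in both cohorts this
#' yields 22 model reports.
#'
#' @param cohortA,cohortB [simulate_cohort()] objects (or anything exposing
#'   `$cells`, `$attributes`, `$phenotypes`, `$ids`, `$name`).
#' @param config a [pipeline_config()].
#' @param shared_snps character vector of shared SNP names; default: SNP
#'   attributes present in both cohorts.
#' @param phenotypes phenotype subset (default all eleven).
#' @return list with `reports` (data.frame, one row per phenotype x cohort)
#'   and `details` (per-row list of mcfs/model/stats/validation objects).
#' @export
run_gene_gene <- function(cohortA, cohortB, config = pipeline_config(),
                          shared_snps = NULL, phenotypes = phenotype_names()) {
  is_snp <- function(co) names(Filter(function(a) a$kind == "snp",
                                      co$attributes))
  shared_snps <- shared_snps %||% intersect(is_snp(cohortA), is_snp(cohortB))
  if (length(shared_snps) == 0L) stop("no shared SNPs between the cohorts")
  reports <- list()
  details <- list()
  for (ph in phenotypes) {
    for (side in list(list(self = cohortA, other = cohortB),
                      list(self = cohortB, other = cohortA))) {
      if (!ph %in% names(side$self$phenotypes) ||
          !ph %in% names(side$other$phenotypes)) {
        warning("phenotype '", ph, "' absent; skipped")
        next
      }
      tab <- phenotype_table(side$self, ph, attrs = shared_snps)
      other <- phenotype_table(side$other, ph, attrs = shared_snps)
      label <- paste0("gg:", side$self$name, ":", ph)
      res <- analyze_phenotype(tab, other, config, label,
                               validate_rules = "significant")
      if (is.null(res)) next
      row <- cbind(data.frame(phenotype = ph, cohort = side$self$name,
                              stringsAsFactors = FALSE),
                   res$report)
      reports[[length(reports) + 1L]] <- row
      details[[label]] <- res
    }
  }
  list(reports = do.call(rbind, reports), details = details)
}

#' Gene-environment analysis in one cohort with external validation
#'
#' Runs the full attribute set (SNPs plus environment and lifestyle factors)
#' of one cohort through feature selection and rule induction for each
#' phenotype; every induced rule whose factors (attributes and categories)
#' exist in the validation cohort is checked there for an effect in the same
#' direction.
#'
#' @param cohort the cohort carrying the environment data.
#' @param validation_cohort the cohort used for direction validation where
#'   applicable (rules with factors absent there count in `n_rules` but not
#'   in `n_validatable_rules`).
#' @inheritParams run_gene_gene
#' @return as [run_gene_gene()], one report row per phenotype.
#' @export
run_gene_env <- function(cohort, validation_cohort,
                         config = pipeline_config(),
                         phenotypes = phenotype_names()) {
  if (length(cohort$attributes) == 0L) stop("cohort has no attributes")
  reports <- list()
  details <- list()
  for (ph in phenotypes) {
    if (!ph %in% names(cohort$phenotypes)) {
      warning("phenotype '", ph, "' absent; skipped")
      next
    }
    tab <- phenotype_table(cohort, ph)
    other <- if (!is.null(validation_cohort) &&
                 ph %in% names(validation_cohort$phenotypes))
      phenotype_table(validation_cohort, ph) else NULL
    label <- paste0("ge:", cohort$name, ":", ph)
    res <- analyze_phenotype(tab, other, config, label,
                             validate_rules = "all")
    if (is.null(res)) next
    row <- cbind(data.frame(phenotype = ph, cohort = cohort$name,
                            stringsAsFactors = FALSE),
                 res$report)
    reports[[length(reports) + 1L]] <- row
    details[[label]] <- res
  }
  list(reports = do.call(rbind, reports), details = details)
}

#' Randomization validation of the feature selection, per phenotype
#'
#' Runs [mcfs_null_validation()] (original / randomized-only / combined) for
#' each phenotype of a cohort.
#'
#' @inheritParams run_gene_env
#' @return data.frame: three rows per phenotype.
#' @export
run_mcfs_validation <- function(cohort, config = pipeline_config(),
                                phenotypes = phenotype_names()) {
  out <- list()
  for (ph in phenotypes) {
    tab <- phenotype_table(cohort, ph)
    counts <- table(factor(tab$decision, levels = decision_levels))
    if (min(counts) < config$min_class) {
      warning("phenotype '", ph, "' skipped: smallest class has ",
              min(counts), " objects")
      next
    }
    params <- config$mcfs
    params$seed <- substream_seed(config$seed, paste0("mcfsval:", ph))
    rep3 <- mcfs_null_validation(tab, params)
    rep3 <- cbind(data.frame(phenotype = ph, stringsAsFactors = FALSE), rep3)
    out[[ph]] <- rep3
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Column averages of a model-report table
#'
#' Arithmetic means of every numeric column, rounded to one decimal the way
#' summary tables print them; the unrounded means are attached as attribute
#' `"raw"`.
#'
#' @param reports data.frame of model reports (e.g. `$reports` from
#'   [run_gene_gene()], or a transcribed published summary table).
#' @return one-row data.frame of rounded means.
#' @export
summary_report <- function(reports) {
  stopifnot(nrow(reports) >= 1L)
  num <- vapply(reports, is.numeric, logical(1))
  means <- vapply(reports[num], mean, numeric(1), na.rm = TRUE)
  out <- as.data.frame(as.list(round(means, 1)))
  names(out) <- names(means)
  attr(out, "raw") <- means
  out
}

#' Percentage of validated among validatable rules
#'
#' @param n_validated,n_validatable counts.
#' @return percentage rounded to one decimal.
#' @export
#' @examples
#' validated_percentage(132, 143)
validated_percentage <- function(n_validated, n_validatable) {
  stopifnot(n_validatable > 0, n_validated <= n_validatable)
  round(100 * n_validated / n_validatable, 1)
}
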