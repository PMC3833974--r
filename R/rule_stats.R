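#' Exact hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` class members among `n` draws from a
#' population of `N` objects of which `K` are in the class, computed as an
#' exact sum of log-gamma binomial terms (numerically stable for cohort-sized
#' margins).
#'
#' @param k observed overlap (rule support).
#' @param K class size in the population.
#' @param N population size (classified objects).
#' @param n draw size (left-hand-side matches).
#' @return upper-tail probability in (0, 1].
#' @keywords internal
hypergeom_upper <- function(k, K, N, n) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N, k >= 0)
  if (k > min(n, K)) stop("inconsistent margins: k > min(n, K)")
  if (k == 0) return(1.0)
  i <- k:min(n, K)
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  # keep the result in (0, 1] as documented: extreme enrichment at
  # cohort-sized margins can underflow the exact sum to zero, and near-full
  # tails can exceed 1 by accumulated rounding
  min(max(sum(exp(logp)), .Machine$double.xmin), 1)
}

#' Hypergeometric significance of a rule
#'
#' Tests whether a rule's left-hand side is enriched for its decision class:
#' with `N` classified objects of which `K` are in the rule's class, `n`
#' objects matching the left-hand side and `k` of those in the class, the
#' p-value is the exact upper-tail hypergeometric probability P(X >= k).
#'
#' @param rule an [rule()] object.
#' @param table a [decision_table()].
#' @return an object of class `"hypergeom_test"`: list with `N`, `K`, `n`,
#'   `k`, `p` and `p_adj` (NA until [bonferroni()] is applied).
#' @export
rule_pvalue <- function(rule, table) {
  tab <- classified(table)
  N <- length(tab$ids)
  K <- sum(tab$decision == rule$decision)
  m <- rule_matches(rule$conditions, tab$cells)
  n <- sum(m)
  k <- sum(m & tab$decision == rule$decision)
  if (N < n || K < k) stop("inconsistent margins")
  structure(list(N = N, K = K, n = n, k = k,
                 p = hypergeom_upper(k, K, N, n), p_adj = NA_real_),
            class = "hypergeom_test")
}

#' Bonferroni adjustment with an explicit family size
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @param m family size (at least `length(p)`).
#' @return adjusted p-values `min(1, m p)`.
#' @export
#' @examples
#' bonferroni(c(0.01, 0.5), m = 2)
bonferroni <- function(p, m) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (m < length(p)) stop("family size m smaller than the number of tests")
  pmin(1, m * p)
}

#' @rdname bonferroni
#' @param alpha family-wise error rate.
#' @return `bonferroni_threshold`: the per-test threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

or_result <- function(a = NA, b = NA, c = NA, d = NA, or, ci_low, ci_high,
                      method, correction_applied = FALSE, note = NULL) {
  structure(list(a = a, b = b, c = c, d = d, or = or, ci_low = ci_low,
                 ci_high = ci_high, method = method,
                 correction_applied = correction_applied, note = note),
            class = "or_result")
}

#' @exportS3Method print or_result
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f) [%s%s]\n", x$or, x$ci_low,
              x$ci_high, x$method,
              if (x$correction_applied) ", 0.5 correction" else ""))
  invisible(x)
}

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' Counts follow the exposed-affected (`a`), exposed-unaffected (`b`),
#' unexposed-affected (`c`), unexposed-unaffected (`d`) layout. OR = ad/bc;
#' the 95% CI is `exp(ln OR +- 1.96 sqrt(1/a+1/b+1/c+1/d))`. Any zero cell
#' triggers the Haldane-Anscombe correction (0.5 added to every cell),
#' flagged in the result.
#'
#' @param a,b,c,d non-negative counts.
#' @return an `"or_result"` with `method = "woolf"`.
#' @export
#' @examples
#' odds_ratio_2x2(10, 5, 5, 10)
odds_ratio_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + c == 0 || b + d == 0)
    stop("odds ratio undefined: a margin is empty")
  corrected <- any(c(a, b, c, d) == 0)
  aa <- a; bb <- b; cc <- c; dd <- d
  if (corrected) {
    aa <- a + 0.5; bb <- b + 0.5; cc <- c + 0.5; dd <- d + 0.5
  }
  or <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  or_result(a, b, c, d, or = or,
            ci_low = exp(log(or) - 1.96 * se),
            ci_high = exp(log(or) + 1.96 * se),
            method = "woolf", correction_applied = corrected)
}

#' Odds ratio from a single-predictor logistic regression
#'
#' Maximum-likelihood logistic fit of the binary outcome on the binary
#' exposure; OR = exp(beta) with Wald 95% CI. When an exposure level is
#' absent from a class (separation) or the fit does not converge, the
#' corrected 2x2 estimate is returned instead and flagged.
#'
#' @param outcome logical vector (TRUE = affected).
#' @param exposure logical vector (TRUE = exposed).
#' @return an `"or_result"` with `method = "logistic_wald"` (or `"woolf"`
#'   with `correction_applied` on fallback).
#' @export
odds_ratio_logistic <- function(outcome, exposure) {
  keep <- !is.na(outcome) & !is.na(exposure)
  outcome <- outcome[keep]; exposure <- exposure[keep]
  a <- sum(exposure & outcome); b <- sum(exposure & !outcome)
  c_ <- sum(!exposure & outcome); d <- sum(!exposure & !outcome)
  fallback <- function(note) {
    res <- odds_ratio_2x2(a, b, c_, d)
    res$note <- note
    res
  }
  if (any(c(a, b, c_, d) == 0))
    return(fallback("separation: corrected 2x2 estimate"))
  fit <- tryCatch(
    glm(outcome ~ exposure, family = binomial()),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !fit$converged)
    return(fallback("logistic fit did not converge"))
  beta <- coef(fit)[["exposureTRUE"]]
  se <- sqrt(vcov(fit)["exposureTRUE", "exposureTRUE"])
  or_result(a, b, c_, d, or = exp(beta),
            ci_low = exp(beta - 1.96 * se),
            ci_high = exp(beta + 1.96 * se),
            method = "logistic_wald")
}

#' Odds ratio of fulfilling all conditions of a rule
#'
#' Exposure is fulfilment of every condition in the rule; the reference is
#' all other children. Children missing a value on any condition attribute
#' are excluded from the 2x2 (their count is reported in the result's
#' `note`), so the reference group is not diluted by unknowns.
#'
#' @param rule an [rule()] object.
#' @param table a [decision_table()].
#' @return an `"or_result"`; when no child fulfils the rule the estimate is
#'   undefined (`or = NA` with an explanatory note), and a rule matched by
#'   every child is an error (no reference group).
#' @export
rule_or <- function(rule, table) {
  tab <- classified(table)
  complete <- rep(TRUE, length(tab$ids))
  for (a in names(rule$conditions)) {
    v <- tab$cells[[a]]
    if (is.null(v)) stop("attribute '", a, "' not in table")
    complete <- complete & !is.na(v)
  }
  exposed <- rule_matches(rule$conditions, tab$cells)[complete]
  outcome <- tab$decision[complete] == "affected"
  n_excl <- sum(!complete)
  if (!any(exposed)) {
    return(or_result(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     method = "logistic_wald",
                     note = sprintf("no child fulfils the rule (%d missing-excluded)",
                                    n_excl)))
  }
  if (all(exposed)) stop("rule matches every child: no reference group")
  res <- odds_ratio_logistic(outcome, exposed)
  res$note <- paste(c(res$note,
                      sprintf("%d children excluded for missing condition values",
                              n_excl)), collapse = "; ")
  res
}

#' Cross-cohort direction validation of a rule
#'
#' A rule is validatable in another cohort when every condition's attribute
#' exists there with the condition's category in its domain; it passes
#' validation when its odds ratio in the other cohort points the way its
#' decision class implies (OR > 1 for affected-rules, OR < 1 for
#' unaffected-rules). No significance is required -- only an effect in the
#' same direction.
#'
#' @param rule an [rule()] object.
#' @param other_table the other cohort's [decision_table()] for the same
#'   phenotype.
#' @return list with `rule_id`, `validatable`, `direction_match` (NA when not
#'   validatable or the OR is undefined) and `other_or`.
#' @export
validate_rule_external <- function(rule, other_table) {
  ok <- TRUE
  for (a in names(rule$conditions)) {
    att <- other_table$attributes[[a]]
    if (is.null(att) || !(rule$conditions[[a]] %in% att$domain)) {
      ok <- FALSE
      break
    }
  }
  if (!ok)
    return(list(rule_id = rule$id, validatable = FALSE,
                direction_match = NA, other_or = NULL))
  oor <- rule_or(rule, other_table)
  dm <- if (is.na(oor$or)) NA
        else if (rule$decision == "affected") oor$or > 1 else oor$or < 1
  list(rule_id = rule$id, validatable = TRUE, direction_match = dm,
       other_or = oor)
}

#' Dose-response by number of fulfilled rule conditions
#'
#' Groups children by how many of the rule's conditions they fulfil (0 to L;
#' children missing a value on any condition attribute are excluded) and
#' estimates the odds ratio of each level against level 0.
#'
#' @param rule an [rule()] with at least two conditions.
#' @param table a [decision_table()].
#' @return data.frame with one row per level: `level`, `n`, `n_affected`,
#'   `or`, `ci_low`, `ci_high` (level 0 is the reference with OR 1; empty
#'   levels are NA).
#' @export
dose_response <- function(rule, table) {
  L <- length(rule$conditions)
  if (L < 2L) stop("dose-response needs a rule with at least 2 conditions")
  tab <- classified(table)
  complete <- rep(TRUE, length(tab$ids))
  level <- rep(0L, length(tab$ids))
  for (a in names(rule$conditions)) {
    v <- tab$cells[[a]]
    complete <- complete & !is.na(v)
    level <- level + (!is.na(v) & v == rule$conditions[[a]])
  }
  level <- level[complete]
  outcome <- tab$decision[complete] == "affected"
  out <- data.frame(level = 0:L, n = NA_integer_, n_affected = NA_integer_,
                    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  for (l in 0:L) {
    sel <- level == l
    out$n[l + 1L] <- sum(sel)
    out$n_affected[l + 1L] <- sum(outcome[sel])
    if (l == 0L) {
      out$or[1L] <- 1.0
      next
    }
    if (!any(sel) || !any(level == 0L)) next
    sub <- level %in% c(0L, l)
    res <- tryCatch(odds_ratio_logistic(outcome[sub], level[sub] == l),
                    error = function(e) NULL)
    if (!is.null(res)) {
      out$or[l + 1L] <- res$or
      out$ci_low[l + 1L] <- res$ci_low
      out$ci_high[l + 1L] <- res$ci_high
    }
  }
  out
}

#' Per-rule statistics table for a rule model
#'
#' Computes, for every rule in a model, the hypergeometric p-value, the
#' Bonferroni-adjusted p (family = number of rules in the model, the
#' per-analysis correction), and the crude odds ratio of rule fulfilment
#' with its 95% CI.
#'
#' @param model an [induce_rules()] result.
#' @param table the [decision_table()] the model was induced on.
#' @return data.frame with columns `id`, `rule`, `decision`, `N`, `K`, `n`,
#'   `k`, `p`, `p_adj`, `or`, `ci_low`, `ci_high`.
#' @export
rule_statistics <- function(model, table) {
  if (length(model$rules) == 0L)
    return(data.frame(id = integer(0), rule = character(0),
                      decision = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      p_adj = numeric(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0)))
  rows <- lapply(model$rules, function(r) {
    ht <- rule_pvalue(r, table)
    orr <- tryCatch(rule_or(r, table), error = function(e)
      or_result(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                method = "logistic_wald", note = conditionMessage(e)))
    data.frame(id = r$id, rule = rule_to_string(r), decision = r$decision,
               N = ht$N, K = ht$K, n = ht$n, k = ht$k, p = ht$p,
               p_adj = NA_real_, or = orr$or, ci_low = orr$ci_low,
               ci_high = orr$ci_high, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p, m = nrow(out))
  out
}
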