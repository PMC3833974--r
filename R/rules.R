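#' Construct an IF-THEN rule
#'
#' A rule is a conjunction of attribute = category conditions predicting a
#' decision class. Statistics (`support` = objects matching the left-hand
#' side with the rule's class, `lhs_matches`, `accuracy` =
#' support/lhs_matches, `class_coverage` = support/class size) are filled in
#' by [induce_rules()] or [rule_statistics()]; `generators` counts the
#' training objects whose reduct produced the rule.
#'
#' @param conditions named character vector: attribute name -> required
#'   category code; non-empty, attribute-unique.
#' @param decision `"affected"` or `"unaffected"`.
#' @param support,lhs_matches,accuracy,class_coverage,generators,id optional
#'   statistics.
#' @return an object of class `"allergy_rule"`.
#' @export
rule <- function(conditions, decision, support = NA_integer_,
                 lhs_matches = NA_integer_, accuracy = NA_real_,
                 class_coverage = NA_real_, generators = NA_integer_,
                 id = NA_integer_) {
  if (length(conditions) == 0L) stop("a rule needs at least one condition")
  conditions <- vapply(conditions, as.character, character(1))
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("conditions must be named by attribute")
  if (anyDuplicated(names(conditions)))
    stop("conditions must be attribute-unique")
  if (!decision %in% decision_levels)
    stop("decision must be 'affected' or 'unaffected'")
  structure(list(conditions = conditions, decision = decision,
                 support = support, lhs_matches = lhs_matches,
                 accuracy = accuracy, class_coverage = class_coverage,
                 generators = generators, id = id),
            class = "allergy_rule")
}

#' @exportS3Method print allergy_rule
print.allergy_rule <- function(x, ...) {
  cat(rule_to_string(x), "\n")
  if (!is.na(x$support))
    cat(sprintf("  support %d / lhs %d, accuracy %.3f\n",
                x$support, x$lhs_matches, x$accuracy))
  invisible(x)
}

# logical vector: which classified objects satisfy all rule conditions
# (a missing value never matches a condition)
rule_matches <- function(conditions, cells) {
  ok <- rep(TRUE, nrow(cells))
  for (a in names(conditions)) {
    v <- cells[[a]]
    if (is.null(v)) stop("attribute '", a, "' not in table")
    ok <- ok & !is.na(v) & v == conditions[[a]]
  }
  ok
}

#' Discernibility clauses of one object
#'
#' For each opposite-class object, the clause is the set of attributes on
#' which both objects have non-missing, differing values (a reduct must hit
#' every clause). An empty clause means the pair is indiscernible -- an
#' inconsistency; such clauses are kept in the output and flagged.
#'
#' @param table a [decision_table()].
#' @param object object id.
#' @return list of character vectors (one per opposite-class object) with
#'   attribute `"inconsistent"` set to `TRUE` when any clause is empty.
#' @export
discernibility_clauses <- function(table, object) {
  tab <- classified(table)
  i <- match(object, tab$ids)
  if (is.na(i)) stop("object '", object, "' not classified in table")
  opp <- which(tab$decision != tab$decision[i])
  anames <- attribute_names(tab)
  mine <- as.character(tab$cells[i, ])
  clauses <- lapply(opp, function(j) {
    other <- as.character(tab$cells[j, ])
    anames[!is.na(mine) & !is.na(other) & mine != other]
  })
  attr(clauses, "inconsistent") <- any(lengths(clauses) == 0L) &&
    length(clauses) > 0L
  clauses
}

#' Johnson-heuristic reduct (greedy set cover)
#'
#' Repeatedly picks the attribute occurring in the most uncovered clauses
#' (ties broken lexicographically by name) until every clause is covered.
#' The result always covers all clauses but is not guaranteed minimal.
#'
#' With `fraction < 1` the greedy loop stops as soon as at least that
#' fraction of the clauses is covered (the "approximate solutions" option of
#' the classical Johnson reducer). Approximate reducts are shorter, so the
#' resulting rules are more general: their left-hand sides match more
#' objects, at the price of accuracy below 1. On cohort-sized tables exact
#' object reducts need so many conditions that almost no rule reaches a
#' useful support, which is why rule induction at scale is normally run with
#' a fraction a little below 1.
#'
#' @param clauses list of character vectors of attribute names.
#' @param fraction minimum fraction of clauses the reduct must cover, in
#'   (0, 1]; 1 (the default) is the exact cover.
#' @return character vector of attributes; `character(0)` for an empty
#'   clause list (the object is discernible by nothing).
#' @export
johnson_reduct <- function(clauses, fraction = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  if (length(clauses) == 0L) return(character(0))
  if (any(lengths(clauses) == 0L))
    stop("empty discernibility clause: inconsistent object")
  attrs <- sort(unique(unlist(clauses)))
  mat <- vapply(attrs, function(a)
    vapply(clauses, function(cl) a %in% cl, logical(1)),
    logical(length(clauses)))
  mat <- matrix(mat, nrow = length(clauses), dimnames = list(NULL, attrs))
  uncovered <- rep(TRUE, nrow(mat))
  target <- nrow(mat) - floor((1 - fraction) * nrow(mat))
  reduct <- character(0)
  while (nrow(mat) - sum(uncovered) < target) {
    counts <- colSums(mat[uncovered, , drop = FALSE])
    best <- names(counts)[which.max(counts)] # which.max keeps first = lexic.
    reduct <- c(reduct, best)
    uncovered <- uncovered & !mat[, best]
  }
  sort(reduct)
}

#' All minimal reducts by exhaustive search (test oracle)
#'
#' Enumerates attribute subsets and returns every set that covers all of the
#' object's discernibility clauses and has no covering proper subset.
#' Exponential in the attribute count; refuses more than 12 attributes.
#'
#' @param table a [decision_table()].
#' @param object object id.
#' @return list of character vectors, each a minimal reduct.
#' @export
brute_force_reducts <- function(table, object) {
  if (ncol(table$cells) > 12L)
    stop("brute force limited to 12 attributes")
  clauses <- discernibility_clauses(table, object)
  if (any(lengths(clauses) == 0L))
    stop("empty discernibility clause: inconsistent object")
  attrs <- sort(unique(unlist(clauses)))
  if (length(attrs) == 0L) return(list(character(0)))
  covers <- function(set) all(vapply(clauses, function(cl)
    any(cl %in% set), logical(1)))
  found <- list()
  for (size in seq_along(attrs)) {
    combos <- utils::combn(attrs, size, simplify = FALSE)
    for (set in combos) {
      if (!covers(set)) next
      minimal <- !any(vapply(found, function(f) all(f %in% set), logical(1)))
      if (minimal) found[[length(found) + 1L]] <- set
    }
    if (length(found) > 0L && size >= max(lengths(found))) {
      # supersets of found reducts are never minimal; continue to collect
      # incomparable sets of this size, then sizes above can still contain
      # minimal sets not containing any found one
    }
  }
  found
}

profile_key <- function(cells) {
  vals <- lapply(cells, function(v) ifelse(is.na(v), "\x01NA", v))
  do.call(paste, c(vals, sep = "\x1f"))
}

#' Induce IF-THEN rules via object-related Johnson reducts
#'
#' For every consistent object (grouped by identical attribute profiles), the
#' Johnson reduct of its discernibility clauses yields a rule: one condition
#' per reduct attribute at the object's value, predicting the object's class.
#' Objects indiscernible from an opposite-class object are inconsistent and
#' skipped (their count is reported). Duplicate rules are merged, statistics
#' are computed on the full classified table, and the support/accuracy
#' filters are applied.
#'
#' @param table a [decision_table()].
#' @param filters list with `min_support` and `min_accuracy` (rules below
#'   either threshold are dropped) and optionally `johnson_fraction` (clause
#'   coverage the greedy reduct must reach, default 1 = exact; see
#'   [johnson_reduct()]). Defaults keep rule counts in a readable range on
#'   cohort-sized tables.
#' @param attrs optional attribute subset to induce over (e.g. the
#'   MCFS-significant factors).
#' @return an object of class `"rule_model"`: list with `rules` (list of
#'   [rule()]), `class_priors`, `filters`, `n_inconsistent`, `n_rules_raw`.
#' @export
induce_rules <- function(table,
                         filters = list(min_support = 5L, min_accuracy = 0.6),
                         attrs = NULL) {
  tab <- classified(table)
  if (!is.null(attrs)) tab <- select_attributes(tab, attrs)
  anames <- attribute_names(tab)
  n <- length(tab$ids)
  keys <- profile_key(tab$cells)
  prof <- unique(data.frame(key = keys, stringsAsFactors = FALSE))
  prof_rows <- match(prof$key, keys)
  kf <- factor(keys, levels = prof$key)
  n_aff <- as.integer(table(kf[tab$decision == "affected"]))
  n_unaff <- as.integer(table(kf[tab$decision == "unaffected"]))
  consistent <- xor(n_aff > 0L, n_unaff > 0L)
  n_inconsistent <- sum((n_aff + n_unaff)[!consistent])

  prof_cells <- tab$cells[prof_rows, , drop = FALSE]
  pm <- as.matrix(prof_cells)
  prof_class <- ifelse(n_aff > 0L, "affected", "unaffected")
  prof_count <- n_aff + n_unaff

  # clauses between profiles; empty clause vs an opposite profile (possible
  # through missing values) also marks the profile inconsistent
  rules <- list()
  merged <- new.env(parent = emptyenv())
  for (pi in which(consistent)) {
    mine <- pm[pi, ]
    opp <- which((if (prof_class[pi] == "affected") n_unaff else n_aff) > 0L)
    clauses <- lapply(opp, function(qj) {
      other <- pm[qj, ]
      anames[!is.na(mine) & !is.na(other) & mine != other]
    })
    if (any(lengths(clauses) == 0L) && length(clauses) > 0L) {
      n_inconsistent <- n_inconsistent + prof_count[pi]
      next
    }
    reduct <- johnson_reduct(unique(clauses),
                             fraction = filters$johnson_fraction %||% 1)
    if (length(reduct) == 0L) reduct <- anames[!is.na(mine)]
    reduct <- reduct[!is.na(mine[match(reduct, anames)])]
    if (length(reduct) == 0L) next
    conds <- setNames(mine[match(reduct, anames)], reduct)
    key <- paste(prof_class[pi],
                 paste(reduct, conds, sep = "=", collapse = "&"))
    prev <- merged[[key]]
    if (is.null(prev)) {
      merged[[key]] <- list(conditions = conds, decision = prof_class[pi],
                            generators = prof_count[pi])
    } else {
      prev$generators <- prev$generators + prof_count[pi]
      merged[[key]] <- prev
    }
  }

  class_sizes <- c(affected = sum(tab$decision == "affected"),
                   unaffected = sum(tab$decision == "unaffected"))
  raw <- mget(ls(merged), envir = merged)
  rules <- lapply(raw, function(r) {
    m <- rule_matches(r$conditions, tab$cells)
    supp <- sum(m & tab$decision == r$decision)
    lhs <- sum(m)
    rule(r$conditions, r$decision, support = supp, lhs_matches = lhs,
         accuracy = if (lhs > 0) supp / lhs else NA_real_,
         class_coverage = supp / class_sizes[[r$decision]],
         generators = r$generators)
  })
  n_raw <- length(rules)
  keep <- vapply(rules, function(r)
    !is.na(r$support) && r$support >= filters$min_support &&
      !is.na(r$accuracy) && r$accuracy >= filters$min_accuracy,
    logical(1))
  rules <- rules[keep]
  if (length(rules)) {
    ord <- order(-vapply(rules, `[[`, integer(1), "support"),
                 vapply(rules, rule_to_string, character(1)))
    rules <- rules[ord]
    for (i in seq_along(rules)) rules[[i]]$id <- i
  }
  structure(list(rules = unname(rules),
                 class_priors = class_sizes / sum(class_sizes),
                 filters = filters,
                 n_inconsistent = n_inconsistent,
                 n_rules_raw = n_raw),
            class = "rule_model")
}

#' @exportS3Method print rule_model
print.rule_model <- function(x, ...) {
  cat(sprintf("<rule_model> %d rules (of %d before filtering), %d inconsistent objects skipped\n",
              length(x$rules), x$n_rules_raw, x$n_inconsistent))
  invisible(x)
}

#' @exportS3Method as.data.frame rule_model
as.data.frame.rule_model <- function(x, ...) {
  if (length(x$rules) == 0L)
    return(data.frame(id = integer(0), rule = character(0),
                      decision = character(0), support = integer(0),
                      lhs_matches = integer(0), accuracy = numeric(0),
                      class_coverage = numeric(0), generators = integer(0)))
  data.frame(
    id = vapply(x$rules, `[[`, integer(1), "id"),
    rule = vapply(x$rules, rule_to_string, character(1)),
    decision = vapply(x$rules, `[[`, character(1), "decision"),
    support = vapply(x$rules, `[[`, integer(1), "support"),
    lhs_matches = vapply(x$rules, `[[`, integer(1), "lhs_matches"),
    accuracy = vapply(x$rules, `[[`, numeric(1), "accuracy"),
    class_coverage = vapply(x$rules, `[[`, numeric(1), "class_coverage"),
    generators = vapply(x$rules, `[[`, integer(1), "generators"),
    stringsAsFactors = FALSE
  )
}

#' Classify objects by support-weighted rule voting
#'
#' Every rule whose left-hand side an object satisfies votes its support for
#' its decision; the class with the larger vote wins. Objects matched by no
#' rule get `"ABSTAIN"`; vote ties go to the class with the larger training
#' prior.
#'
#' @param model a [induce_rules()] result.
#' @param table a [decision_table()] (or, for `classify_object`, a named
#'   character vector of attribute values).
#' @return character vector of `"affected"`, `"unaffected"` or `"ABSTAIN"`.
#' @export
classify_table <- function(model, table) {
  tab <- if (inherits(table, "decision_table")) table
         else decision_table(table, rep("EXCLUDED", nrow(table)))
  n <- nrow(tab$cells)
  votes <- matrix(0, n, 2, dimnames = list(NULL, decision_levels))
  for (r in model$rules) {
    m <- rule_matches(r$conditions, tab$cells)
    votes[m, r$decision] <- votes[m, r$decision] + r$support
  }
  out <- rep("ABSTAIN", n)
  any_vote <- rowSums(votes) > 0
  tie <- any_vote & votes[, 1] == votes[, 2]
  prior_class <- names(model$class_priors)[which.max(model$class_priors)]
  out[any_vote] <- ifelse(votes[any_vote, 1] > votes[any_vote, 2],
                          "affected", "unaffected")
  out[tie] <- prior_class
  out
}

#' @rdname classify_table
#' @param object named character vector of attribute values for one object.
#' @export
classify <- function(model, object) {
  cells <- as.data.frame(as.list(object), stringsAsFactors = FALSE,
                         check.names = FALSE, optional = TRUE)
  votes <- c(affected = 0, unaffected = 0)
  for (r in model$rules) {
    vals <- object[names(r$conditions)]
    if (all(!is.na(vals) & vals == r$conditions))
      votes[r$decision] <- votes[r$decision] + r$support
  }
  if (sum(votes) == 0) return("ABSTAIN")
  if (votes[1] == votes[2])
    return(names(model$class_priors)[which.max(model$class_priors)])
  names(votes)[which.max(votes)]
}

#' Cross-validated model coverage and accuracy
#'
#' Stratified k-fold cross-validation of the rule model: rules are induced on
#' k-1 folds and vote on the held-out fold. Coverage is the fraction of
#' held-out objects any rule fires on; accuracy is the fraction correct among
#' those (abstentions are excluded from the accuracy denominator). A fold
#' whose training part lacks a class is skipped with a message.
#'
#' @param table a [decision_table()].
#' @param k number of folds.
#' @param filters rule filters, see [induce_rules()].
#' @param seed integer seed for the fold split.
#' @param attrs optional attribute subset.
#' @return list with `coverage`, `accuracy`, `mean_rules` (means over folds)
#'   and `folds` (per-fold data.frame).
#' @export
cross_validate <- function(table, k = 10L,
                           filters = list(min_support = 5L,
                                          min_accuracy = 0.6),
                           seed = 1L, attrs = NULL) {
  tab <- classified(table)
  if (!is.null(attrs)) tab <- select_attributes(tab, attrs)
  folds <- stratified_folds(tab, k, seed)
  rows <- lapply(seq_len(k) - 1L, function(f)
    tab$ids %in% names(folds$membership)[folds$membership == f])
  res <- list()
  for (f in seq_len(k)) {
    test_rows <- rows[[f]]
    train <- subset_table(tab, !test_rows)
    if (length(unique(train$decision)) < 2L) {
      message("fold ", f - 1L, " skipped: training part has one class")
      next
    }
    model <- induce_rules(train, filters = filters)
    test <- subset_table(tab, test_rows)
    pred <- classify_table(model, test)
    fired <- pred != "ABSTAIN"
    res[[length(res) + 1L]] <- data.frame(
      fold = f - 1L,
      n_test = length(pred),
      n_rules = length(model$rules),
      coverage = mean(fired),
      accuracy = if (any(fired)) mean(pred[fired] == test$decision[fired])
                 else NA_real_
    )
  }
  folds_df <- do.call(rbind, res)
  list(coverage = mean(folds_df$coverage),
       accuracy = mean(folds_df$accuracy, na.rm = TRUE),
       mean_rules = mean(folds_df$n_rules),
       folds = folds_df)
}

#' Serialize and parse rules
#'
#' Grammar: `IF <attr>=<code>[<label>] AND ... THEN <phenotype>=<class>`;
#' the label bracket appears when the attribute metadata defines a display
#' label for the code (e.g. a genotype string), and a `THEN` part without
#' `=<class>` defaults to `affected`.
#'
#' @param rule an [rule()] object.
#' @param phenotype phenotype name for the THEN part.
#' @param attributes optional named list of [attribute()] metadata supplying
#'   display labels.
#' @return `rule_to_string`: a character scalar. `parse_rule`: a [rule()].
#' @export
rule_to_string <- function(rule, phenotype = NULL, attributes = NULL) {
  lhs <- vapply(seq_along(rule$conditions), function(i) {
    a <- names(rule$conditions)[i]
    v <- rule$conditions[[i]]
    lab <- attributes[[a]]$labels[[v]] %||% NULL
    if (!is.null(lab)) sprintf("%s=%s[%s]", a, v, lab)
    else sprintf("%s=%s", a, v)
  }, character(1))
  rhs <- if (is.null(phenotype)) rule$decision
         else sprintf("%s=%s", phenotype, rule$decision)
  paste0("IF ", paste(lhs, collapse = " AND "), " THEN ", rhs)
}

#' @rdname rule_to_string
#' @param text rule text to parse.
#' @param schema optional named list of [attribute()] objects to validate
#'   condition codes against.
#' @export
parse_rule <- function(text, schema = NULL) {
  m <- regexec("^IF\\s+(.+?)\\s+THEN\\s+(.+)$", text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) != 3L)
    stop("parse error at position 1: expected 'IF ... THEN ...'")
  conds_txt <- strsplit(parts[2], "\\s+AND\\s+")[[1]]
  if (length(conds_txt) == 0L || all(conds_txt == ""))
    stop("parse error: empty condition list")
  conds <- character(0)
  for (i in seq_along(conds_txt)) {
    # perl = TRUE: the default TRE engine treats the escaped brackets
    # inside the character classes as collating syntax, not literals
    cm <- regexec("^([^=\\[\\]]+)=([^\\[\\]]+)(\\[([^\\]]*)\\])?$",
                  conds_txt[i], perl = TRUE)
    cp <- regmatches(conds_txt[i], cm)[[1]]
    if (length(cp) < 3L)
      stop("parse error in condition ", i, ": '", conds_txt[i], "'")
    a <- trimws(cp[2]); v <- trimws(cp[3])
    if (!is.null(schema)) {
      if (!a %in% names(schema))
        stop("parse error in condition ", i, ": unknown attribute '", a, "'")
      if (!v %in% schema[[a]]$domain)
        stop("parse error in condition ", i, ": code '", v,
             "' not in domain of '", a, "'")
    }
    conds[a] <- v
  }
  rhs <- trimws(parts[3])
  eq <- regexec("^(.*?)=(affected|unaffected)$", rhs)
  ep <- regmatches(rhs, eq)[[1]]
  decision <- if (length(ep) == 3L) ep[3] else "affected"
  r <- rule(conds, decision)
  attr(r, "phenotype") <- if (length(ep) == 3L) trimws(ep[2]) else rhs
  r
}
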