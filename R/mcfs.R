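#' Parameters for Monte Carlo feature selection
#'
#' Monte Carlo feature selection (MCFS) ranks attributes by their relative
#' importance over a large ensemble of decision trees, each built on a random
#' projection of `m` attributes with `t` train/test splits per projection.
#' The relative importance of attribute g is
#' \deqn{RI_g = \sum_{trees} wAcc^u \sum_{nodes(g)} IG(node) \cdot
#'   (n_{node}/n_{tree})^v}
#' where wAcc is the tree's weighted accuracy (mean per-class recall) on its
#' test split, IG is the information gain (bits) of a node splitting on g,
#' and the node fraction term damps deep, small splits.
#'
#' @param s number of projections; `NULL` (default) chooses s so every
#'   attribute is expected in at least `min_appearances` projections,
#'   `ceiling(min_appearances * d / m)`.
#' @param t train/test splits per projection.
#' @param m attributes per projection; `NULL` means `ceiling(sqrt(d))`.
#' @param train_fraction fraction of classified objects in each training
#'   split (stratified by class).
#' @param u exponent on weighted accuracy.
#' @param v exponent on the node-fraction term.
#' @param max_depth tree depth cap. Depth trades significance calibration
#'   against power: shallow trees concentrate an attribute's importance in
#'   its near-root splits, whose chance association with the labels is fixed
#'   within a run and chi-square (right-skewed) under the null, so the
#'   Gaussian permutation null of [mcfs_significance()] becomes
#'   anti-conservative; deeper trees dilute that shared component with
#'   conditionally fresh deep-node noise, restoring calibration but also
#'   drowning planted signal on small attribute sets. The default of 5
#'   keeps the family-wise error rate of the significant set at its nominal
#'   level on wide pure-noise tables; for focused analyses of a few dozen
#'   candidate attributes where ranking power matters more than exact null
#'   calibration, `max_depth = 3` is markedly more sensitive.
#' @param B label-permutation replicates for the significance null.
#' @param alpha family-wise error rate for the Bonferroni-controlled
#'   significant set; the degenerate `alpha = 1` turns the threshold off
#'   (every attribute is reported significant).
#' @param min_appearances expected projections per attribute used to derive
#'   `s` when `s` is `NULL`.
#' @param seed integer master seed.
#' @return an object of class `"mcfs_params"`.
#' @export
mcfs_params <- function(s = NULL, t = 5L, m = NULL, train_fraction = 0.66,
                        u = 1, v = 1, max_depth = 5L, B = 50L, alpha = 0.05,
                        min_appearances = 30L, seed = 1L) {
  stopifnot(is.null(s) || s >= 1, t >= 1, is.null(m) || m >= 1,
            train_fraction > 0, train_fraction < 1, u >= 0, v >= 0,
            max_depth >= 1, B >= 1, alpha > 0, alpha <= 1)
  structure(list(s = s, t = as.integer(t), m = m,
                 train_fraction = train_fraction, u = u, v = v,
                 max_depth = as.integer(max_depth), B = as.integer(B),
                 alpha = alpha, min_appearances = as.integer(min_appearances),
                 seed = as.integer(seed)),
            class = "mcfs_params")
}

resolve_params <- function(params, d) {
  # exact-name access: `$` would partial-match a removed `s` to `seed`
  m <- params[["m"]] %||% ceiling(sqrt(d))
  if (m > d) stop("m = ", m, " exceeds the number of attributes d = ", d)
  s <- params[["s"]] %||% ceiling(params$min_appearances * d / m)
  params$m <- as.integer(m)
  params$s <- as.integer(s)
  params
}

#' Weighted accuracy of a 2x2 confusion matrix
#'
#' The mean of the per-class recalls; insensitive to class imbalance, so a
#' constant predictor on any class mix scores 0.5.
#'
#' @param confusion 2x2 matrix, rows = true class, columns = predicted class
#'   (same class order).
#' @return weighted accuracy in \[0,1\]; `NA` (with a message) when a true
#'   class has no objects, in which case the tree's contribution is skipped.
#' @export
#' @examples
#' weighted_accuracy(matrix(c(8, 4, 2, 6), 2)) # recalls 0.8 and 0.6 -> 0.7
weighted_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(all(dim(confusion) == c(2L, 2L)), all(confusion >= 0))
  totals <- rowSums(confusion)
  if (any(totals == 0)) {
    message("weighted_accuracy undefined: a true class is empty")
    return(NA_real_)
  }
  mean(diag(confusion) / totals)
}

#' Information gain of a categorical split (bits)
#'
#' Shannon entropy (base 2) of the parent class distribution minus the
#' size-weighted entropies of the children. Children must partition the
#' parent.
#'
#' @param parent numeric vector of parent class counts.
#' @param children list of numeric vectors of child class counts.
#' @return information gain in bits (non-negative up to rounding).
#' @export
#' @examples
#' information_gain(c(4, 4), list(c(4, 0), c(0, 4))) # 1 bit
information_gain <- function(parent, children) {
  entropy <- function(cnt) {
    n <- sum(cnt)
    if (n == 0) return(0)
    p <- cnt[cnt > 0] / n
    -sum(p * log2(p))
  }
  kid_sum <- Reduce(`+`, children)
  if (!isTRUE(all.equal(as.numeric(kid_sum), as.numeric(parent))))
    stop("children do not partition the parent")
  n <- sum(parent)
  entropy(parent) -
    sum(vapply(children, function(k) sum(k) / n * entropy(k), numeric(1)))
}

# Encode a decision table into the integer form the tree core uses:
# objects sorted by id, attributes sorted by name (so results are invariant
# to input order), categories 1..K per column, 0 = missing, classes 1/2.
encode_table <- function(table) {
  tab <- classified(table)
  ord <- order(tab$ids)
  anames <- sort(attribute_names(tab))
  cells <- tab$cells[ord, anames, drop = FALSE]
  X <- matrix(0L, nrow(cells), length(anames))
  ncat <- integer(length(anames))
  for (j in seq_along(anames)) {
    dom <- tab$attributes[[anames[j]]]$domain
    code <- match(cells[[j]], dom)
    code[is.na(code)] <- 0L
    X[, j] <- code
    ncat[j] <- length(dom)
  }
  y <- ifelse(tab$decision[ord] == "affected", 1L, 2L)
  list(X = X, y = y, ncat = ncat, anames = anames, ids = tab$ids[ord])
}

sample_projection <- function(d, m, t, y, train_fraction) {
  attrs <- sort(sample.int(d, m)) # columns are in name order already
  trains <- vector("list", t)
  tests <- vector("list", t)
  idx1 <- which(y == 1L)
  idx2 <- which(y == 2L)
  for (j in seq_len(t)) {
    take <- function(idx) {
      k <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
      sort(sample(idx, k))
    }
    tr <- c(take(idx1), take(idx2))
    trains[[j]] <- tr
    tests[[j]] <- setdiff(seq_along(y), tr)
  }
  list(attrs = attrs, trains = trains, tests = tests)
}

#' Build one information-gain decision tree
#'
#' Greedy multiway splits on the attribute with maximal information gain,
#' stopping at class purity, the depth cap, or when no split has positive
#' gain. Missing values follow the majority child. Ties in gain are broken
#' lexicographically by attribute name. Deterministic given the data.
#'
#' @param table a [decision_table()] (EXCLUDED objects are dropped).
#' @param attrs optional character vector of candidate attributes
#'   (default: all).
#' @param max_depth depth cap.
#' @return an object of class `"ig_tree"`: list with a `nodes` data.frame
#'   (`id`, `parent`, `split_attribute` -- `NA` for leaves --, `n`,
#'   `n_affected`, `n_unaffected`, `depth`, `ig`, `leaf_class`).
#' @export
build_tree <- function(table, attrs = NULL, max_depth = 8L) {
  enc <- encode_table(table)
  if (length(unique(enc$y)) < 2L)
    stop("training data needs both classes")
  cand <- if (is.null(attrs)) enc$anames else sort(attrs)
  ai <- match(cand, enc$anames)
  if (anyNA(ai)) stop("unknown attribute(s) in 'attrs'")
  res <- cpp_build_tree(enc$X, enc$y, enc$ncat, as.integer(ai),
                        seq_along(enc$y), integer(0),
                        as.integer(max_depth), 1)
  nodes <- res$nodes
  nodes$split_attribute <- rep(NA_character_, nrow(nodes))
  inner <- nodes$split_attr > 0L
  nodes$split_attribute[inner] <- enc$anames[nodes$split_attr[inner]]
  nodes$split_attr <- NULL
  nodes$leaf_class <- c("affected", "unaffected")[nodes$leaf_class]
  structure(list(nodes = nodes, attributes = cand), class = "ig_tree")
}

#' @exportS3Method print ig_tree
print.ig_tree <- function(x, ...) {
  cat(sprintf("<ig_tree> %d nodes, depth %d\n",
              nrow(x$nodes), max(x$nodes$depth)))
  invisible(x)
}

#' Monte Carlo feature selection: relative importance
#'
#' Runs `s` random projections of `m` attributes, each with `t` stratified
#' train/test splits, builds an information-gain tree per split and
#' accumulates each attribute's relative importance (see [mcfs_params()]).
#' Projection `i` draws from a substream keyed by `i`, so a run over
#' projections 1..s equals the sum of single-projection runs.
#'
#' @param table a [decision_table()]; both classes need at least 10
#'   classified objects.
#' @param params an [mcfs_params()].
#' @param proj_indices optional integer vector of projection indices to run
#'   (default `1:s`); used to decompose a run into its substreams.
#' @return an object of class `"mcfs_result"`: list with `ri` and
#'   `appearances` (named by attribute), `trees_used`, `trees_skipped`,
#'   `params`, plus `p_value`, `p_adjusted`, `significant` after
#'   [mcfs_significance()].
#' @export
mcfs_ri <- function(table, params = mcfs_params(), proj_indices = NULL) {
  enc <- encode_table(table)
  d <- length(enc$anames)
  if (min(table(enc$y)) < 10L)
    stop("both classes need at least 10 classified objects")
  params <- resolve_params(params, d)
  if (is.null(proj_indices)) proj_indices <- seq_len(params$s)
  projections <- lapply(proj_indices, function(i) {
    with_seed(substream_seed(params$seed, paste0("proj:", i)),
              sample_projection(d, params$m, params$t, enc$y,
                                params$train_fraction))
  })
  res <- cpp_mcfs_ri(enc$X, enc$y, enc$ncat, projections,
                     params$u, params$v, params$max_depth)
  structure(list(ri = setNames(res$ri, enc$anames),
                 appearances = setNames(res$appearances, enc$anames),
                 trees_used = res$trees_used,
                 trees_skipped = res$trees_skipped,
                 p_value = NULL, p_adjusted = NULL, significant = NULL,
                 params = params),
            class = "mcfs_result")
}

#' @exportS3Method print mcfs_result
print.mcfs_result <- function(x, ...) {
  cat(sprintf("<mcfs_result> %d attributes, %d trees", length(x$ri),
              x$trees_used))
  if (!is.null(x$significant))
    cat(sprintf(", %d significant (alpha = %g, Bonferroni)",
                length(x$significant), x$params$alpha))
  cat("\n")
  invisible(x)
}

#' Monte Carlo feature selection with permutation significance
#'
#' Repeats the full MCFS run on `B` label-permuted copies of the table, fits
#' a Gaussian to each attribute's null relative importances, and reports the
#' upper-tail p-value of the observed value, Bonferroni-adjusted over the
#' `d` attributes (`p_adj = min(1, d p)`). The Gaussian fit resolves
#' p-values far below `1/B`, matching the resolution a Bonferroni threshold
#' like 0.05/220 requires at feasible `B`.
#'
#' The upper tail of the fitted Gaussian is evaluated in its exact
#' predictive form: with mean and standard deviation estimated from `B`
#' draws, a new Gaussian draw standardized by the estimates follows a
#' t-distribution with `B - 1` degrees of freedom and scale
#' `sqrt(1 + 1/B)`, so `p = P(T > (ri - mean) / (sd sqrt(1 + 1/B)))`. The
#' naive plug-in normal tail is anti-conservative far out in the tail at
#' small `B` (at `B = 20` it inflates the family-wise error rate over a
#' 220-attribute family several-fold even when the null really is
#' Gaussian); the predictive form is exactly uniform under a Gaussian null
#' at any `B` and converges to the plug-in tail as `B` grows. An attribute
#' whose null has zero variance gets p = 1 when its observed value does not
#' exceed the null mean, otherwise a p from a half-range floor on the
#' standard deviation (noted via a message).
#'
#' @inheritParams mcfs_ri
#' @return an `"mcfs_result"` with `p_value`, `p_adjusted` and `significant`
#'   (attributes with `p_adjusted < alpha`) filled in, plus `null_ri`
#'   (B x d matrix of null importances).
#' @export
mcfs_significance <- function(table, params = mcfs_params()) {
  if (params$B < 10L) stop("B must be at least 10")
  obs <- mcfs_ri(table, params)
  d <- length(obs$ri)
  null_ri <- matrix(NA_real_, params$B, d,
                    dimnames = list(NULL, names(obs$ri)))
  for (b in seq_len(params$B)) {
    perm_tab <- permute_labels(table, substream_seed(params$seed,
                                                     paste0("permlab:", b)))
    pb <- params
    pb$seed <- substream_seed(params$seed, paste0("permrun:", b))
    null_ri[b, ] <- mcfs_ri(perm_tab, pb)$ri[names(obs$ri)]
  }
  mu <- colMeans(null_ri)
  sdev <- apply(null_ri, 2, sd)
  sd_floor <- max(1e-12, (max(null_ri) - min(null_ri)) / 2)
  p <- numeric(d)
  degenerate <- sdev < 1e-15
  if (any(degenerate))
    message(sum(degenerate), " attribute(s) with zero-variance null; ",
            "half-range sd floor applied")
  # exact predictive upper tail of the fitted Gaussian: t with B - 1 df,
  # scale inflated by sqrt(1 + 1/B) for the mean estimate
  pred_scale <- sqrt(1 + 1 / params$B)
  pred_p <- function(x, m, s)
    pt((x - m) / (s * pred_scale), df = params$B - 1, lower.tail = FALSE)
  for (j in seq_len(d)) {
    if (degenerate[j]) {
      p[j] <- if (obs$ri[j] <= mu[j]) 1 else
        pred_p(obs$ri[j], mu[j], sd_floor)
    } else {
      p[j] <- pred_p(obs$ri[j], mu[j], sdev[j])
    }
  }
  p <- pmax(p, .Machine$double.xmin) # p in (0, 1]
  names(p) <- names(obs$ri)
  obs$p_value <- p
  obs$p_adjusted <- pmin(d * p, 1) # named first arg keeps attribute names
  obs$significant <- if (params$alpha >= 1) names(p)
                     else names(p)[obs$p_adjusted < params$alpha]
  obs$null_ri <- null_ri
  obs
}

# permute the decision over classified objects, leaving attributes in place
permute_labels <- function(table, seed) {
  keep <- table$decision %in% decision_levels
  dec <- table$decision
  dec[keep] <- with_seed(seed, sample(dec[keep]))
  decision_table(table$cells, dec, ids = table$ids,
                 attributes = table$attributes)
}

#' Randomization validation of the feature selection
#'
#' Three runs: (1) the original table; (2) randomized-only, where every
#' attribute column is independently permuted so any significant hit is a
#' false positive; (3) combined, the original attributes plus their
#' randomized copies (suffix `_rnd`), testing whether adding non-informative
#' factors disturbs the selection.
#'
#' @inheritParams mcfs_ri
#' @return data.frame with one row per run: `run`, `n_attributes`,
#'   `n_significant_original`, `n_significant_randomized`.
#' @export
mcfs_null_validation <- function(table, params = mcfs_params()) {
  orig <- mcfs_significance(table, params)

  rnd_tab <- permute_columns(table, substream_seed(params$seed, "nullval"))
  p_rnd <- params
  p_rnd$seed <- substream_seed(params$seed, "nullval-run")
  rnd <- mcfs_significance(rnd_tab, p_rnd)

  rnd_cells <- rnd_tab$cells
  names(rnd_cells) <- paste0(names(rnd_cells), "_rnd")
  rnd_attrs <- lapply(rnd_tab$attributes, function(a) {
    a$name <- paste0(a$name, "_rnd")
    a
  })
  names(rnd_attrs) <- names(rnd_cells)
  comb_tab <- decision_table(cbind(table$cells, rnd_cells), table$decision,
                             ids = table$ids,
                             attributes = c(table$attributes, rnd_attrs))
  p_comb <- params
  p_comb$seed <- substream_seed(params$seed, "nullval-comb")
  if (!is.null(p_comb[["s"]])) p_comb["s"] <- list(NULL) # re-derive for 2d
  if (!is.null(p_comb[["m"]])) p_comb["m"] <- list(NULL)
  comb <- mcfs_significance(comb_tab, p_comb)

  is_rnd <- function(x) grepl("_rnd$", x)
  data.frame(
    run = c("original", "randomized_only", "combined"),
    n_attributes = c(length(orig$ri), length(rnd$ri), length(comb$ri)),
    n_significant_original = c(length(orig$significant),
                               0L,
                               sum(!is_rnd(comb$significant))),
    n_significant_randomized = c(0L,
                                 length(rnd$significant),
                                 sum(is_rnd(comb$significant))),
    stringsAsFactors = FALSE
  )
}
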