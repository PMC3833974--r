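#' Attribute metadata for a decision table
#'
#' An attribute is one categorical factor measured on every child: a SNP
#' genotype coded as the number of copies of the cohort's major allele
#' (domain `"0"`, `"1"`, `"2"`), an environmental exposure, a lifestyle
#' factor, or a covariate such as sex or country.
#'
#' @param name attribute identifier (column name in the table).
#' @param kind one of `"snp"`, `"environment"`, `"lifestyle"`, `"covariate"`.
#' @param domain character vector of allowed category codes (ordered, unique,
#'   non-empty). SNP domains must be a subset of `c("0","1","2")`.
#' @param labels optional named character vector mapping category code to a
#'   display label, e.g. `c("2" = "GG")`.
#' @param short_code optional short display code used in network figures,
#'   e.g. `"V"`.
#' @return an object of class `"allergy_attribute"`.
#' @export
#' @examples
#' attribute("ORMDL3_rs2305480", "snp", c("0", "1", "2"),
#'           labels = c("2" = "GG", "1" = "GA", "0" = "AA"))
attribute <- function(name,
                      kind = c("snp", "environment", "lifestyle", "covariate"),
                      domain,
                      labels = NULL,
                      short_code = NULL) {
  kind <- match.arg(kind)
  domain <- as.character(domain)
  if (length(domain) == 0L) stop("attribute '", name, "': empty domain")
  if (anyDuplicated(domain)) stop("attribute '", name, "': duplicate codes")
  if (kind == "snp" && !all(domain %in% c("0", "1", "2")))
    stop("attribute '", name, "': SNP domain must be within {0,1,2}")
  if (!is.null(labels)) {
    labels <- vapply(labels, as.character, character(1))
    if (is.null(names(labels)) || !all(names(labels) %in% domain))
      stop("attribute '", name, "': labels must be named by domain codes")
  }
  structure(
    list(name = as.character(name), kind = kind, domain = domain,
         labels = labels, short_code = short_code),
    class = "allergy_attribute"
  )
}

#' @exportS3Method print allergy_attribute
print.allergy_attribute <- function(x, ...) {
  cat(sprintf("<attribute> %s (%s): {%s}\n",
              x$name, x$kind, paste(x$domain, collapse = ",")))
  invisible(x)
}

decision_levels <- c("affected", "unaffected")

#' Construct a decision table
#'
#' The decision table is the substrate of every pipeline stage: objects
#' (children) by categorical condition attributes, plus a binary decision
#' (affected/unaffected). Children outside a phenotype's restricted reference
#' group carry the decision `"EXCLUDED"`; they are kept in files but dropped
#' from all computation.
#'
#' @param cells data.frame of character columns, one row per object, one
#'   column per attribute. `NA` encodes a missing value; a missing value
#'   never matches a rule condition and never discerns two objects.
#' @param decision character vector, one of `"affected"`, `"unaffected"`,
#'   `"EXCLUDED"` per object (`NA` is treated as `"EXCLUDED"`).
#' @param ids character vector of unique object identifiers.
#' @param attributes optional list of [attribute()] objects matching the
#'   columns of `cells`; inferred from the data when omitted (domain =
#'   observed codes; kind `"snp"` when the codes lie within \{0,1,2\}).
#' @return an object of class `"decision_table"`: a list with elements
#'   `ids`, `cells`, `decision`, `attributes`.
#' @export
decision_table <- function(cells, decision, ids = NULL, attributes = NULL) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  cells[] <- lapply(cells, as.character)
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(cells)) &&
               !identical(rownames(cells), as.character(seq_len(nrow(cells)))))
      rownames(cells) else sprintf("obj%d", seq_len(nrow(cells)))
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate object ids")
  if (length(ids) != nrow(cells)) stop("ids and cells disagree on object count")
  decision <- as.character(decision)
  decision[is.na(decision)] <- "EXCLUDED"
  bad <- setdiff(unique(decision), c(decision_levels, "EXCLUDED"))
  if (length(bad))
    stop("unknown decision value(s): ", paste(bad, collapse = ", "))
  if (length(decision) != nrow(cells)) stop("decision length mismatch")
  if (ncol(cells) < 1L) stop("a decision table needs at least one attribute")

  if (is.null(attributes)) {
    attributes <- lapply(names(cells), function(nm) {
      vals <- sort(unique(cells[[nm]][!is.na(cells[[nm]])]))
      if (length(vals) == 0L) vals <- "0"
      kind <- if (all(vals %in% c("0", "1", "2"))) "snp" else "environment"
      attribute(nm, kind, vals)
    })
  }
  names(attributes) <- vapply(attributes, `[[`, character(1), "name")
  if (!identical(sort(names(attributes)), sort(names(cells))))
    stop("attribute metadata does not match table columns")
  attributes <- attributes[names(cells)]
  for (nm in names(cells)) {
    v <- cells[[nm]]
    out <- !is.na(v) & !(v %in% attributes[[nm]]$domain)
    if (any(out))
      stop("attribute '", nm, "': ", sum(out), " cell(s) outside domain")
  }
  rownames(cells) <- NULL
  structure(list(ids = ids, cells = cells, decision = decision,
                 attributes = attributes),
            class = "decision_table")
}

#' @exportS3Method print decision_table
print.decision_table <- function(x, ...) {
  cat(sprintf(
    "<decision_table> %d objects x %d attributes (%d affected, %d unaffected, %d excluded)\n",
    length(x$ids), ncol(x$cells),
    sum(x$decision == "affected"), sum(x$decision == "unaffected"),
    sum(x$decision == "EXCLUDED")))
  invisible(x)
}

#' @exportS3Method dim decision_table
dim.decision_table <- function(x) c(length(x$ids), ncol(x$cells))

#' Number of objects, attribute names, and classified subset
#'
#' `n_objects()` counts all objects; `attribute_names()` lists condition
#' attributes; `classified()` returns the table restricted to objects whose
#' decision is affected or unaffected (the restricted reference-group
#' semantics: EXCLUDED rows never enter a computation).
#'
#' @param table a [decision_table()].
#' @return see description.
#' @export
classified <- function(table) {
  keep <- table$decision %in% decision_levels
  subset_table(table, keep)
}

#' @rdname classified
#' @export
n_objects <- function(table) length(table$ids)

#' @rdname classified
#' @export
attribute_names <- function(table) names(table$cells)

subset_table <- function(table, rows, cols = NULL) {
  cells <- table$cells[rows, , drop = FALSE]
  attrs <- table$attributes
  if (!is.null(cols)) {
    cells <- cells[, cols, drop = FALSE]
    attrs <- attrs[cols]
  }
  decision_table(cells, table$decision[rows], ids = table$ids[rows],
                 attributes = attrs)
}

#' Restrict a decision table to a subset of attributes
#'
#' @param table a [decision_table()].
#' @param attrs character vector of attribute names to keep.
#' @return a [decision_table()] with only those columns.
#' @export
select_attributes <- function(table, attrs) {
  missing_attrs <- setdiff(attrs, attribute_names(table))
  if (length(missing_attrs))
    stop("unknown attribute(s): ", paste(missing_attrs, collapse = ", "))
  subset_table(table, seq_along(table$ids), attrs)
}

#' Read a decision table from TSV
#'
#' The file format is tab-separated, UTF-8, with a header row; the first
#' column must be `id` (unique object identifiers) and one column (default
#' `decision`) holds the class. The missing-value token is `NA`. When a
#' schema is supplied, unparseable or out-of-domain cells are converted to
#' missing and counted; the count is attached as attribute `"n_warnings"`
#' and reported via one [warning()].
#'
#' @param path file path.
#' @param decision_col name of the decision column.
#' @param schema optional list of [attribute()] objects (or the result of
#'   [read_attribute_schema()]) to validate against.
#' @return a [decision_table()].
#' @export
read_table <- function(path, decision_col = "decision", schema = NULL) {
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   na.strings = "NA", check.names = FALSE,
                   fileEncoding = "UTF-8")
  if (!identical(names(df)[1], "id")) stop("first column must be 'id'")
  if (!decision_col %in% names(df))
    stop("decision column '", decision_col, "' not found")
  ids <- df$id
  if (anyDuplicated(ids)) stop("duplicate object ids in ", path)
  decision <- df[[decision_col]]
  cells <- df[, setdiff(names(df), c("id", decision_col)), drop = FALSE]
  n_warn <- 0L
  if (!is.null(schema)) {
    names(schema) <- vapply(schema, `[[`, character(1), "name")
    for (nm in names(cells)) {
      if (!nm %in% names(schema)) next
      v <- cells[[nm]]
      bad <- !is.na(v) & !(v %in% schema[[nm]]$domain)
      n_warn <- n_warn + sum(bad)
      v[bad] <- NA_character_
      cells[[nm]] <- v
    }
    if (n_warn > 0L)
      warning(n_warn, " out-of-domain cell(s) set to missing")
    schema <- schema[intersect(names(cells), names(schema))]
    if (length(schema) != ncol(cells)) schema <- NULL
  }
  tab <- decision_table(cells, decision, ids = ids, attributes = schema)
  attr(tab, "n_warnings") <- n_warn
  tab
}

#' Write a decision table to TSV
#'
#' Inverse of [read_table()]: missing cells become the token `NA`, the
#' decision column is written last under the given name.
#'
#' @param table a [decision_table()].
#' @param path output file path.
#' @param decision_col name for the decision column.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, decision_col = "decision") {
  df <- cbind(data.frame(id = table$ids, stringsAsFactors = FALSE),
              table$cells)
  df[[decision_col]] <- table$decision
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read attribute metadata from YAML
#'
#' The schema file is a YAML sequence of mappings with keys `name`, `kind`,
#' `domain`, and optional `labels` and `short_code`.
#'
#' @param path YAML file path.
#' @return a named list of [attribute()] objects.
#' @export
read_attribute_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  attrs <- lapply(raw, function(a) {
    labels <- if (!is.null(a$labels)) unlist(a$labels) else NULL
    attribute(a$name, a$kind, as.character(unlist(a$domain)),
              labels = labels, short_code = a$short_code)
  })
  names(attrs) <- vapply(attrs, `[[`, character(1), "name")
  attrs
}

#' Read genotypes from a VCF file as major-allele counts
#'
#' Each biallelic SNP record becomes one attribute; the major allele at a
#' site is the allele with the higher observed sample frequency (ties go to
#' REF), and each genotype is coded as the number of major-allele copies
#' (0, 1 or 2). Genotypes `./.` and malformed GT fields become missing;
#' multiallelic records are skipped with a warning.
#'
#' @param path VCF 4.x file path; only the GT subfield is consulted.
#' @return a [decision_table()] of SNP attributes with every decision set to
#'   `"EXCLUDED"` (phenotype columns are attached later).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(v@fix),
                                     dimnames = list(vcfR::getID(v), NULL))
  site_ids <- vcfR::getID(v)
  no_id <- is.na(site_ids) | site_ids == "."
  site_ids[no_id] <- paste0(vcfR::getCHROM(v)[no_id], "_",
                            vcfR::getPOS(v)[no_id])
  samples <- colnames(gt)
  n_alt <- function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2L || !all(alleles %in% c("0", "1")))
      return(NA_integer_)
    sum(alleles == "1")
  }
  cells <- as.data.frame(matrix(NA_character_, ncol(gt), nrow(gt)),
                         stringsAsFactors = FALSE)
  names(cells) <- site_ids
  for (i in seq_len(nrow(gt))) {
    alt_counts <- vapply(gt[i, ], n_alt, integer(1))
    ok <- !is.na(alt_counts)
    alt_freq <- if (any(ok)) sum(alt_counts[ok]) / (2 * sum(ok)) else 0
    major_is_ref <- alt_freq <= 0.5 # tie goes to REF
    code <- if (major_is_ref) 2L - alt_counts else alt_counts
    cells[[i]] <- ifelse(is.na(code), NA_character_, as.character(code))
  }
  attrs <- lapply(site_ids, function(nm) attribute(nm, "snp", c("0", "1", "2")))
  decision_table(cells, rep("EXCLUDED", length(samples)), ids = samples,
                 attributes = attrs)
}

#' Stratified cross-validation folds
#'
#' Partitions the classified objects of a table into `k` folds so that each
#' fold's class counts differ from exact proportionality by at most one
#' object, by shuffling within class and dealing round-robin. Fold indices
#' are 0-based. Reproducible under a fixed seed.
#'
#' @param table a [decision_table()].
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return an object of class `"fold_assignment"`: list with `k`,
#'   `membership` (named integer vector, object id -> fold index) and `seed`.
#' @export
stratified_folds <- function(table, k, seed) {
  stopifnot(k >= 2)
  tab <- classified(table)
  for (cl in decision_levels) {
    if (sum(tab$decision == cl) < k)
      stop("class '", cl, "' has fewer than k = ", k, " objects")
  }
  membership <- integer(0)
  for (cl in decision_levels) {
    ids <- tab$ids[tab$decision == cl]
    ids <- with_seed(substream_seed(seed, paste0("folds:", cl)),
                     sample(ids))
    f <- (seq_along(ids) - 1L) %% k
    membership <- c(membership, setNames(f, ids))
  }
  membership <- membership[tab$ids]
  structure(list(k = as.integer(k), membership = membership,
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Randomize attribute columns while keeping the decision fixed
#'
#' Each non-decision column is independently permuted over objects, which
#' preserves every per-column category histogram (including the missing
#' count) but destroys any association with the decision. This is the
#' randomization used to validate the feature selection: significant hits on
#' permuted columns are false positives by construction.
#'
#' @param table a [decision_table()].
#' @param seed integer seed; each column draws from a substream keyed by its
#'   name, so the result is invariant to column order.
#' @return a [decision_table()] of the same shape.
#' @export
permute_columns <- function(table, seed) {
  cells <- table$cells
  n <- nrow(cells)
  for (nm in names(cells)) {
    perm <- with_seed(substream_seed(seed, paste0("permcol:", nm)),
                      sample.int(n))
    cells[[nm]] <- cells[[nm]][perm]
  }
  decision_table(cells, table$decision, ids = table$ids,
                 attributes = table$attributes)
}
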