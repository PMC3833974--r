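#' Names of the eleven derived phenotypes
#'
#' @return character vector of phenotype names.
#' @export
phenotype_names <- function() {
  c("asthma", "allergic_asthma", "nonallergic_asthma", "current_asthma",
    "wheeze", "eczema", "allergic_eczema", "nonallergic_eczema",
    "rhinoconjunctivitis", "sens_0.35", "sens_3.5")
}

# Three-valued OR/AND where NA means "ingredient missing". R's native
# logical ops already give TRUE|NA = TRUE and FALSE&NA = FALSE, which is
# exactly the semantics needed: a child with one IgE panel >= threshold is
# sensitized even if the other panel is missing.
status_from <- function(affected, unaffected) {
  out <- rep("EXCLUDED", length(affected))
  out[!is.na(affected) & affected] <- "affected"
  out[!is.na(unaffected) & unaffected &
        !(!is.na(affected) & affected)] <- "unaffected"
  out
}

#' Derive phenotype decision columns from raw health records
#'
#' Implements the eleven allergy phenotypes with their restricted reference
#' groups:
#' \describe{
#'   \item{asthma / eczema / wheeze / rhinoconjunctivitis}{the raw ingredient
#'     itself (doctor's diagnosis ever, diagnosis, wheeze episode in last 12
#'     months, prolonged nasal symptoms in last 12 months).}
#'   \item{current_asthma}{asthma diagnosis plus at least one wheeze episode
#'     in the last 12 months; by default the reference group is all
#'     non-asthmatic children and asthmatics without recent wheeze are
#'     EXCLUDED (configurable via `current_asthma_reference`).}
#'   \item{allergic_asthma / nonallergic_asthma}{asthma with / without atopic
#'     sensitization; both share one reference group of children who neither
#'     have asthma nor are sensitized, everybody else is EXCLUDED. The
#'     eczema pair is analogous.}
#'   \item{sens_0.35 / sens_3.5}{atopic sensitization: allergen-specific
#'     serum IgE at or above 0.35 (strict: 3.5) kU/L against inhalant and/or
#'     food allergens.}
#' }
#' A child missing an ingredient a phenotype needs is EXCLUDED for that
#' phenotype.
#'
#' @param records data.frame with logical columns `asthma_dx_ever`,
#'   `wheeze_12m`, `eczema_dx`, `rhino_symptoms_12m` and non-negative numeric
#'   `ige_inhalant`, `ige_food` (kU/L); NA = missing.
#' @param ige_threshold,ige_threshold_strict sensitization cut-offs in kU/L.
#' @param current_asthma_reference `"non_asthma"` (default: reference is all
#'   non-asthmatics, asthmatics without recent wheeze EXCLUDED) or
#'   `"non_current"` (reference is everyone not fulfilling the definition).
#' @return data.frame with one status column (`"affected"`, `"unaffected"`,
#'   `"EXCLUDED"`) per phenotype, rows aligned with `records`.
#' @export
derive_phenotypes <- function(records,
                              ige_threshold = 0.35,
                              ige_threshold_strict = 3.5,
                              current_asthma_reference = c("non_asthma",
                                                           "non_current")) {
  current_asthma_reference <- match.arg(current_asthma_reference)
  need <- c("asthma_dx_ever", "wheeze_12m", "eczema_dx",
            "rhino_symptoms_12m", "ige_inhalant", "ige_food")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  if (any(records$ige_inhalant < 0, na.rm = TRUE) ||
      any(records$ige_food < 0, na.rm = TRUE))
    stop("IgE values must be non-negative")

  dx <- records$asthma_dx_ever
  wz <- records$wheeze_12m
  ec <- records$eczema_dx
  rh <- records$rhino_symptoms_12m
  sens <- (records$ige_inhalant >= ige_threshold) |
    (records$ige_food >= ige_threshold)
  sens_strict <- (records$ige_inhalant >= ige_threshold_strict) |
    (records$ige_food >= ige_threshold_strict)

  current <- if (current_asthma_reference == "non_asthma") {
    status_from(dx & wz, !dx)
  } else {
    status_from(dx & wz, !(dx & wz))
  }

  out <- data.frame(
    asthma = status_from(dx, !dx),
    allergic_asthma = status_from(dx & sens, !dx & !sens),
    nonallergic_asthma = status_from(dx & !sens, !dx & !sens),
    current_asthma = current,
    wheeze = status_from(wz, !wz),
    eczema = status_from(ec, !ec),
    allergic_eczema = status_from(ec & sens, !ec & !sens),
    nonallergic_eczema = status_from(ec & !sens, !ec & !sens),
    rhinoconjunctivitis = status_from(rh, !rh),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  out[["sens_0.35"]] <- status_from(sens, !sens)
  out[["sens_3.5"]] <- status_from(sens_strict, !sens_strict)
  out
}

#' Tabulate phenotype status counts
#'
#' @param assignments output of [derive_phenotypes()].
#' @return data.frame with one row per phenotype and columns `phenotype`,
#'   `affected`, `unaffected`, `excluded` (summing to the cohort size).
#' @export
phenotype_counts <- function(assignments) {
  rows <- lapply(names(assignments), function(ph) {
    v <- assignments[[ph]]
    data.frame(phenotype = ph,
               affected = sum(v == "affected"),
               unaffected = sum(v == "unaffected"),
               excluded = sum(v == "EXCLUDED"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
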