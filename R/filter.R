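#' Thresholds for the candidate-selection cascade
#'
#' The screen keeps ligands with molecular mass above 100 and below 900 Da,
#' water solubility above 1 uM, predicted blood-brain-barrier penetration
#' above 50 percent, plasma concentration above 0.5 nM (the total plasma
#' A-beta-40 concentration), at least 2 Alzheimer-literature references, and
#' excludes fatty acids. "Above"/"less than" are strict inequalities; the
#' reference requirement ("more than 1") is `>= 2`.
#'
#' @param mass_min,mass_max Mass window in Da, both bounds exclusive.
#' @param solubility_min Minimum water solubility, uM, exclusive.
#' @param bbb_min Minimum predicted BBB penetration, percent, exclusive.
#' @param plasma_min Minimum plasma concentration, nM, exclusive.
#' @param refs_min Minimum literature reference count, inclusive.
#' @param exclude_fatty_acids Drop records flagged as fatty acids?
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(mass_min = 100, mass_max = 900,
                              solubility_min = 1, bbb_min = 50,
                              plasma_min = 0.5, refs_min = 2L,
                              exclude_fatty_acids = TRUE) {
  check_number(mass_min, "mass_min", min = 0)
  check_number(mass_max, "mass_max", min = 0)
  if (mass_min >= mass_max) stopf("mass_min must be < mass_max")
  check_number(solubility_min, "solubility_min", min = 0)
  check_number(bbb_min, "bbb_min", min = 0)
  check_number(plasma_min, "plasma_min", min = 0)
  refs_min <- check_count(refs_min, "refs_min")
  structure(
    list(mass_min = mass_min, mass_max = mass_max,
         solubility_min = solubility_min, bbb_min = bbb_min,
         plasma_min = plasma_min, refs_min = refs_min,
         exclude_fatty_acids = isTRUE(exclude_fatty_acids)),
    class = "filter_thresholds"
  )
}

FILTER_STAGES <- c("mass", "solubility", "bbb", "plasma", "references",
                   "fatty_acid")

required_ligand_fields <- c("id", "mass", "solubility", "bbb_penetration",
                            "plasma_conc", "ad_refs", "is_fatty_acid")

validate_ligand_table <- function(records) {
  if (!is.data.frame(records)) stopf("'records' must be a data.frame")
  missing_cols <- setdiff(required_ligand_fields, names(records))
  if (length(missing_cols)) {
    stopf("ligand table is missing field(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  for (fld in setdiff(required_ligand_fields, "id")) {
    bad <- which(is.na(records[[fld]]))
    if (length(bad)) {
      stopf("record '%s' has a missing value in field '%s'",
            records$id[bad[1L]], fld)
    }
  }
  if (any(records$mass <= 0)) stopf("field 'mass' must be positive")
  if (any(records$bbb_penetration < 0 | records$bbb_penetration > 100)) {
    stopf("field 'bbb_penetration' must lie in [0, 100]")
  }
  if (any(records$solubility < 0)) stopf("field 'solubility' must be >= 0")
  if (any(records$plasma_conc < 0)) stopf("field 'plasma_conc' must be >= 0")
  invisible(records)
}

stage_predicate <- function(records, stage, thr) {
  switch(stage,
    mass = records$mass > thr$mass_min & records$mass < thr$mass_max,
    solubility = records$solubility > thr$solubility_min,
    bbb = records$bbb_penetration > thr$bbb_min,
    plasma = records$plasma_conc > thr$plasma_min,
    references = records$ad_refs >= thr$refs_min,
    fatty_acid = if (thr$exclude_fatty_acids) !records$is_fatty_acid
                 else rep(TRUE, nrow(records)),
    stopf("unknown filter stage '%s'", stage)
  )
}

#' Apply the candidate-selection filter cascade
#'
#' Runs the six filters in the fixed order mass, solubility, BBB
#' penetration, plasma concentration, literature references, fatty-acid
#' exclusion, and reports the number of survivors after each stage. The
#' final survivor set is the conjunction of the stage predicates, so it does
#' not depend on the stage order; the per-stage counts do.
#'
#' @param records Ligand table (`data.frame`) with the fields produced by
#'   [gen_ligand_table()]. Records with missing values raise an error
#'   naming the record and field.
#' @param thr A [filter_thresholds()] object.
#' @param stage_order Optional permutation of the stage names; the default
#'   is the canonical order above.
#' @return An object of class `filter_report`: list with `stage_names`,
#'   `survivors_after_stage`, `passing_ids`, `n_input` and the thresholds.
#' @export
#' @examples
#' tab <- gen_ligand_table(generator_config(seed = 1, n_ligands = 200))
#' rep <- apply_filters(tab)
#' rep$survivors_after_stage
apply_filters <- function(records, thr = filter_thresholds(),
                          stage_order = FILTER_STAGES) {
  stopifnot(inherits(thr, "filter_thresholds"))
  if (!setequal(stage_order, FILTER_STAGES)) {
    stopf("'stage_order' must be a permutation of the six stage names")
  }
  if (nrow(records) == 0L) {
    if (is.data.frame(records) &&
        !all(required_ligand_fields %in% names(records)) &&
        ncol(records) > 0L) {
      validate_ligand_table(records)
    }
    return(structure(
      list(stage_names = stage_order,
           survivors_after_stage = setNames(rep(0L, length(stage_order)),
                                            stage_order),
           passing_ids = character(0), n_input = 0L, thresholds = thr),
      class = "filter_report"
    ))
  }
  validate_ligand_table(records)
  alive <- rep(TRUE, nrow(records))
  survivors <- integer(length(stage_order))
  for (i in seq_along(stage_order)) {
    alive <- alive & stage_predicate(records, stage_order[i], thr)
    survivors[i] <- sum(alive)
  }
  structure(
    list(stage_names = stage_order,
         survivors_after_stage = setNames(survivors, stage_order),
         passing_ids = records$id[alive],
         n_input = nrow(records), thresholds = thr),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Ligand filter cascade:", x$n_input, "records in\n")
  for (i in seq_along(x$stage_names)) {
    cat(sprintf("  %-11s -> %d survivors\n", x$stage_names[i],
                x$survivors_after_stage[i]))
  }
  cat("Final panel:", length(x$passing_ids), "ligands\n")
  invisible(x)
}

#' Write a filter report as JSON
#'
#' @param report A `filter_report` from [apply_filters()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  jsonlite::write_json(
    list(n_input = report$n_input,
         stage_names = report$stage_names,
         survivors_after_stage = as.list(report$survivors_after_stage),
         passing_ids = report$passing_ids,
         thresholds = unclass(report$thresholds)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
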