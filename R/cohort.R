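#' Default condition/code/drug-class map
#'
#' The three chronic conditions studied, each with its qualifying ICD-9-CM and
#' ICD-10-CM code families and its oral pharmaceutical treatment classes.
#' Range notation (E08.x–E11.x, 401.x–405.x, I10.x–I15.x) is expanded to the
#' inclusive list of three-character families; dyslipidemia qualifies on the
#' specific four-digit families 272.0, 272.2 and 272.4 (ICD-9) and E78.0,
#' E78.2, E78.4, E78.5 (ICD-10).
#'
#' @return Named list, one entry per condition, each with character vectors
#'   `icd9`, `icd10` (code-family prefixes, dot-free normalised form) and
#'   `drug_classes`.
#' @export
condition_code_map <- function() {
  list(
    diabetes = list(
      icd9 = "250",
      icd10 = c("E08", "E09", "E10", "E11"),
      drug_classes = c("alpha_glucosidase_inhibitors", "dpp4_inhibitors",
                       "glp1_receptor_agonists", "meglitinides",
                       "metformin", "sglt2_inhibitors",
                       "sulfonylureas", "thiazolidinediones")
    ),
    dyslipidemia = list(
      icd9 = c("2720", "2722", "2724"),
      icd10 = c("E780", "E782", "E784", "E785"),
      drug_classes = c("bile_acid_sequestrants", "cholesterol_absorption_inhibitors",
                       "fibrates", "lipid_regulating_agents",
                       "nicotinic_acid_derivatives", "statins")
    ),
    hypertension = list(
      icd9 = c("401", "402", "403", "404", "405"),
      icd10 = c("I10", "I11", "I12", "I13", "I14", "I15"),
      drug_classes = c("ace_inhibitors", "arbs", "beta_blockers",
                       "calcium_channel_blockers", "clonidine",
                       "diuretics", "hydralazine", "renin_inhibitors")
    )
  )
}

# normalise an ICD code for family matching: uppercase, dots stripped
normalize_icd <- function(code) {
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

#' Does a diagnosis code qualify for a condition?
#'
#' Family (prefix) matching on the normalised code: case-insensitive,
#' dot-tolerant, wildcard over any suffix. E.g. `250.01` falls in family
#' `250.x` (diabetes, ICD-9) and `E10.9` in `E08.x–E11.x` (diabetes, ICD-10);
#' `272.1` is not one of the dyslipidemia families.
#'
#' @param code ICD code string(s).
#' @param version 9 or 10.
#' @param condition Condition id present in `code_map`.
#' @param code_map A [condition_code_map()].
#' @return Logical, vectorised over `code`.
#' @export
match_diagnosis <- function(code, version, condition,
                            code_map = condition_code_map()) {
  if (!condition %in% names(code_map)) {
    stop("unknown condition: ", condition)
  }
  if (any(!nzchar(trimws(code)))) stop("empty diagnosis code")
  if (!all(version %in% c(9, 10))) stop("icd version must be 9 or 10")
  patterns <- if (all(version == 9)) code_map[[condition]]$icd9
              else if (all(version == 10)) code_map[[condition]]$icd10
              else NULL
  norm <- normalize_icd(code)
  if (!is.null(patterns)) {
    Reduce(`|`, lapply(normalize_icd(patterns), function(p) startsWith(norm, p)))
  } else {
    # mixed versions: dispatch row-wise
    mapply(function(cd, v) match_diagnosis(cd, v, condition, code_map),
           code, version, USE.NAMES = FALSE)
  }
}

# schema guard: stop with the full list of missing columns
check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Build one condition's analysis cohort
#'
#' Applies the three inclusion rules to the linked input tables:
#' continuous insurance coverage over the whole study span (coverage starting
#' no later than the supply-period start and ending no earlier than the last
#' analysis day), at least one qualifying diagnosis inside the diagnosis
#' window, and at least one pharmacy fill of a condition-relevant drug class
#' during the supply or analysis period. Individuals with several conditions
#' are evaluated independently for each condition's cohort.
#'
#' @param demographics,diagnoses,claims data.frames with the documented CSV
#'   schemas (ISO dates; see [read_bundle()]).
#' @param condition Condition id.
#' @param calendar A [study_calendar()].
#' @param code_map A [condition_code_map()].
#' @return List with elements:
#'   * `members`: data.frame `individual_id`, `condition`, `age_years`, `sex`,
#'     `qualifying_diagnosis_date` (earliest in-window match, ISO);
#'   * `fills`: list parallel to `members` rows, each a data.frame
#'     `fill_day`, `days_supply`, `drug_class` restricted to the condition's
#'     classes and to fills inside supply ∪ analysis period;
#'   * `attrition`: per-individual filter accounting — data.frame
#'     `individual_id`, `condition`, `coverage_ok`, `diagnosis_ok`, `fill_ok`,
#'     `included`, one row per individual in `demographics`.
#' @export
build_cohort <- function(demographics, diagnoses, claims, condition,
                         calendar = study_calendar(),
                         code_map = condition_code_map()) {
  check_schema(demographics,
               c("individual_id", "age_years", "sex", "coverage_start", "coverage_end"),
               "demographics")
  check_schema(diagnoses, c("individual_id", "service_date", "icd_version", "code"),
               "diagnoses")
  check_schema(claims, c("individual_id", "fill_date", "days_supply", "drug_class"),
               "claims")
  if (!condition %in% names(code_map)) stop("unknown condition: ", condition)

  epoch <- calendar$epoch
  ids <- demographics$individual_id

  # (a) continuous coverage over [supply_start, analysis_end)
  cov_start <- day_offset(demographics$coverage_start, epoch)
  cov_end <- day_offset(demographics$coverage_end, epoch)      # last covered day, inclusive
  coverage_ok <- cov_start <= calendar$supply_start &
    (cov_end + 1L) >= calendar$analysis_end

  # (b) >=1 qualifying diagnosis in the diagnosis window
  dx_day <- day_offset(diagnoses$service_date, epoch)
  in_window <- dx_day >= calendar$diagnosis_start & dx_day < calendar$diagnosis_end
  dx <- diagnoses[in_window, , drop = FALSE]
  dx_day <- dx_day[in_window]
  hit <- logical(nrow(dx))
  for (v in c(9, 10)) {
    sel <- dx$icd_version == v
    if (any(sel)) hit[sel] <- match_diagnosis(dx$code[sel], v, condition, code_map)
  }
  first_dx <- tapply(dx_day[hit], dx$individual_id[hit], min)
  diagnosis_ok <- ids %in% names(first_dx)

  # (c) >=1 relevant fill during supply or analysis period
  classes <- code_map[[condition]]$drug_classes
  fill_day <- day_offset(claims$fill_date, epoch)
  relevant <- claims$drug_class %in% classes &
    fill_day >= calendar$supply_start & fill_day < calendar$analysis_end
  rel <- claims[relevant, , drop = FALSE]
  rel$fill_day <- fill_day[relevant]
  fill_ok <- ids %in% unique(rel$individual_id)

  included <- coverage_ok & diagnosis_ok & fill_ok
  attrition <- data.frame(individual_id = ids, condition = condition,
                          coverage_ok = coverage_ok, diagnosis_ok = diagnosis_ok,
                          fill_ok = fill_ok, included = included)

  keep <- demographics[included, , drop = FALSE]
  keep <- keep[order(keep$individual_id), , drop = FALSE]
  members <- data.frame(
    individual_id = keep$individual_id,
    condition = condition,
    age_years = keep$age_years,
    sex = keep$sex,
    qualifying_diagnosis_date = as.character(
      offset_date(unname(first_dx[as.character(keep$individual_id)]), epoch))
  )
  fills_split <- split(rel[, c("fill_day", "days_supply", "drug_class")],
                       rel$individual_id)
  fills <- lapply(as.character(members$individual_id), function(id) {
    f <- fills_split[[id]]
    f <- f[order(f$drug_class, f$fill_day), , drop = FALSE]
    rownames(f) <- NULL
    f
  })
  list(members = members, fills = fills, attrition = attrition)
}

#' Variable-PDC eligibility for one member and drug class
#'
#' A drug class enters the variable-denominator analysis only when the member
#' filled it at least twice *inside* the analysis period; otherwise the
#' variable window degenerates and the PDC would be trivially 1.0.
#'
#' @param fills data.frame with `fill_day`, `drug_class` for one member.
#' @param drug_class Class to test.
#' @param calendar A [study_calendar()].
#' @return Logical scalar.
#' @export
variable_eligible <- function(fills, drug_class, calendar = study_calendar()) {
  d <- fills$fill_day[fills$drug_class == drug_class]
  sum(d >= calendar$analysis_start & d < calendar$analysis_end) >= 2L
}

#' Read a bundle of analysis input tables from a directory
#'
#' Expects `demographics.csv`, `diagnoses.csv`, `claims.csv`, `activity.csv`
#' (and optionally `truth.json`) with the documented schemas.
#'
#' @param directory Path containing the CSV files.
#' @return List with `demographics`, `diagnoses`, `claims`, `activity` and,
#'   when present, `truth`.
#' @export
read_bundle <- function(directory) {
  need <- c("demographics.csv", "diagnoses.csv", "claims.csv", "activity.csv")
  paths <- file.path(directory, need)
  missing <- need[!file.exists(paths)]
  if (length(missing)) {
    stop("input directory ", directory, " is missing: ",
         paste(missing, collapse = ", "))
  }
  rd <- function(p, cls) utils::read.csv(p, stringsAsFactors = FALSE, colClasses = cls)
  bundle <- list(
    demographics = rd(paths[1], c(individual_id = "integer", age_years = "integer",
                                  sex = "character", coverage_start = "character",
                                  coverage_end = "character")),
    diagnoses = rd(paths[2], c(individual_id = "integer", service_date = "character",
                               icd_version = "integer", code = "character")),
    claims = rd(paths[3], c(individual_id = "integer", fill_date = "character",
                            days_supply = "integer", drug_class = "character",
                            condition = "character")),
    activity = rd(paths[4], c(individual_id = "integer", log_date = "character",
                              activity = "character", value = "numeric",
                              source = "character"))
  )
  tj <- file.path(directory, "truth.json")
  if (file.exists(tj)) bundle$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  class(bundle) <- "synthetic_bundle"
  bundle
}
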