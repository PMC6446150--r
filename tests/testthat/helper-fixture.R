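# Handcrafted 12-individual bundle exercising every inclusion rule, with the
# expected per-individual filter decisions computed by hand:
#   1  fully valid, hypertension + diabetes (multi-condition)
#   2  coverage ends 2016-01-01 -> continuous-coverage exclusion
#   3  diagnosis but zero claims -> fill exclusion
#   4  single analysis-period fill -> included, variable PDC absent
#   5  diagnosis dated after the diagnosis window -> diagnosis exclusion
#   6  code 272.1 only (matches no condition) -> diagnosis exclusion
#   7  only a dyslipidemia-class fill (statins) -> fill exclusion for hypertension
#   8  only fill predates the supply period -> fill exclusion
#   9  valid; tracker whose logs span 8 days -> metrics-ineligible
#   10 valid; phone-source step logs only -> not a tracker
#   11 valid; tracker logs 10 days apart -> metrics-eligible
#   12 coverage starts 2015-02-01 -> continuous-coverage exclusion

fixture_bundle <- function() {
  demographics <- data.frame(
    individual_id = 1:12,
    age_years = c(67L, 45L, 72L, 58L, 80L, 39L, 66L, 71L, 52L, 49L, 61L, 55L),
    sex = c("F", "M", "F", "M", "F", "F", "M", "F", "M", "F", "M", "F"),
    coverage_start = c("2014-01-01", "2014-01-01", "2014-01-01", "2014-01-01",
                       "2014-01-01", "2014-01-01", "2014-01-01", "2014-01-01",
                       "2014-01-01", "2014-01-01", "2014-01-01", "2015-02-01"),
    coverage_end = c("2016-12-31", "2016-01-01", "2016-12-31", "2016-12-31",
                     "2016-12-31", "2016-12-31", "2016-12-31", "2016-12-31",
                     "2016-12-31", "2016-12-31", "2016-12-31", "2016-12-31"))

  diagnoses <- data.frame(
    individual_id = c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L),
    service_date = c("2014-05-10", "2014-06-01", "2015-03-01", "2015-08-15",
                     "2010-01-01", "2015-10-01", "2014-01-01", "2014-07-01",
                     "2013-02-01", "2012-03-01", "2014-11-11", "2006-06-06",
                     "2014-01-01"),
    icd_version = c(9L, 9L, 9L, 10L, 9L, 9L, 9L, 10L, 9L, 10L, 9L, 9L, 10L),
    code = c("401.9", "250.00", "401.9", "I10", "401.1", "401.9", "272.1",
             "I11.9", "403.90", "I10", "405.99", "401.9", "I10"))

  claims <- data.frame(
    individual_id = c(1L, 1L, 1L, 1L, 1L, 2L, 4L, 5L, 5L, 6L, 7L, 7L, 8L,
                      9L, 9L, 10L, 10L, 11L, 11L, 11L, 12L, 12L),
    fill_date = c("2015-02-01", "2015-07-01", "2015-08-15",         # 1 diuretics
                  "2015-07-01", "2015-10-01",                        # 1 metformin
                  "2015-03-01",                                      # 2
                  "2015-09-01",                                      # 4 single
                  "2015-07-01", "2015-08-01",                        # 5
                  "2015-03-15",                                      # 6
                  "2015-07-15", "2015-09-15",                        # 7 statins
                  "2014-12-01",                                      # 8 pre-study
                  "2015-06-15", "2015-07-20",                        # 9
                  "2015-08-01", "2015-11-01",                        # 10
                  "2015-06-10", "2015-07-10", "2015-08-10",          # 11
                  "2015-06-15", "2015-07-15"),                       # 12
    days_supply = c(90L, 30L, 30L, 90L, 90L, 90L, 30L, 30L, 30L, 90L,
                    30L, 30L, 90L, 30L, 30L, 90L, 90L, 30L, 30L, 30L,
                    30L, 30L),
    drug_class = c("diuretics", "diuretics", "diuretics",
                   "metformin", "metformin",
                   "diuretics", "beta_blockers", "diuretics", "diuretics",
                   "ace_inhibitors", "statins", "statins", "diuretics",
                   "calcium_channel_blockers", "calcium_channel_blockers",
                   "arbs", "arbs", "diuretics", "diuretics", "diuretics",
                   "diuretics", "diuretics"),
    condition = c("hypertension", "hypertension", "hypertension",
                  "diabetes", "diabetes",
                  "hypertension", "hypertension", "hypertension", "hypertension",
                  "hypertension", "dyslipidemia", "dyslipidemia", "hypertension",
                  "hypertension", "hypertension", "hypertension", "hypertension",
                  "hypertension", "hypertension", "hypertension",
                  "hypertension", "hypertension"))

  activity <- data.frame(
    individual_id = c(9L, 9L, 10L, 10L, 10L, 10L, 10L, 11L, 11L),
    log_date = c("2015-07-01", "2015-07-09",
                 "2015-07-01", "2015-07-02", "2015-07-03", "2015-07-04", "2015-07-05",
                 "2015-07-01", "2015-07-11"),
    activity = "steps",
    value = c(4000, 6000, 1000, 1000, 1000, 1000, 1000, 3500, 3500),
    source = c("tracker", "tracker", "phone", "phone", "phone", "phone", "phone",
               "tracker", "tracker"))

  list(demographics = demographics, diagnoses = diagnoses,
       claims = claims, activity = activity)
}

# hand-computed expected filter decisions for the hypertension cohort
fixture_expected_attrition <- function() {
  data.frame(
    individual_id = 1:12,
    condition = "hypertension",
    coverage_ok = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                    TRUE, TRUE, TRUE, FALSE),
    diagnosis_ok = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                     TRUE, TRUE, TRUE, TRUE),
    fill_ok = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                TRUE, TRUE, TRUE, TRUE),
    included = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, TRUE, TRUE, FALSE))
}
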