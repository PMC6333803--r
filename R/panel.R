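#' Define a blood marker for the cohort generator
#'
#' A marker specification declares how one blood biochemistry or cell-count
#' marker responds to biological age, sex and smoking in the synthetic cohort:
#' a per-sex baseline mean, a Gaussian noise SD, a (possibly saturating)
#' biological-age slope, a direct additive smoking offset, and a
#' missing-completely-at-random rate.
#'
#' @param name Marker name; must be unique within a panel and a valid column
#'   name.
#' @param units Measurement units (free text, e.g. `"mmol/L"`).
#' @param mean_female,mean_male Baseline marker mean at the cohort age centre
#'   for each sex.
#' @param sd Gaussian noise SD around the marker mean; must be positive.
#' @param age_slope Change in marker units per year of biological age.
#' @param shape Either `"linear"` (slope applies uniformly) or `"saturating"`
#'   (the age response flattens via a tanh with a 20-year scale).
#' @param smoking_offset Additive shift in marker units applied to smokers
#'   (e.g. lower HDL, higher hemoglobin/RDW/MCV).
#' @param missing_rate Fraction of subjects missing the marker, in \[0, 0.6\].
#'
#' @return A one-row data frame with the marker specification.
#' @export
marker_spec <- function(name, units, mean_female, mean_male, sd,
                        age_slope = 0, shape = c("linear", "saturating"),
                        smoking_offset = 0, missing_rate = 0) {
  shape <- match.arg(shape)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("marker_spec: 'name' must be a non-empty string", call. = FALSE)
  if (!is.numeric(sd) || sd <= 0)
    stop(sprintf("marker_spec: 'sd' must be > 0 for marker '%s'", name),
         call. = FALSE)
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate > 0.6)
    stop(sprintf("marker_spec: 'missing_rate' must lie in [0, 0.6] for marker '%s'",
                 name), call. = FALSE)
  data.frame(name = name, units = units, mean_female = mean_female,
             mean_male = mean_male, sd = sd, age_slope = age_slope,
             shape = shape, smoking_offset = smoking_offset,
             missing_rate = missing_rate, stringsAsFactors = FALSE)
}

#' Default 66-marker blood biochemistry and cell-count panel
#'
#' The default panel emulates a routine clinical chemistry + hematology
#' profile: 22 core markers with no missingness (carrying most of the aging
#' signal), 24 markers with light-to-moderate missingness, and 20
#' "reconstructable" markers with 30-60% missingness. Age slopes are stated in
#' marker units per year of biological age and are conventions chosen so that
#' the full core panel determines biological age to roughly +/- 4 years —
#' strong enough for clean parameter-recovery checks. Smoking leaves a direct
#' signature on HDL (down) and hemoglobin, RDW and MCV (up).
#'
#' @param smoking_offset_sd Magnitude of the direct smoking offsets, in units
#'   of each affected marker's SD (default 0.5).
#'
#' @return A data frame of 66 marker specifications (see [marker_spec()]).
#' @export
default_marker_panel <- function(smoking_offset_sd = 0.5) {
  m <- marker_spec
  s <- smoking_offset_sd
  core <- rbind(
    m("glycated_hemoglobin", "%",        5.4,  5.4,  0.45, age_slope =  0.110 * 0.45),
    m("urea",                "mmol/L",   5.0,  5.4,  1.20, age_slope =  0.105 * 1.20),
    m("fasting_glucose",     "mmol/L",   5.0,  5.2,  0.70, age_slope =  0.100 * 0.70),
    m("ferritin",            "ug/L",    80.0, 130.0, 45.0, age_slope =  0.090 * 45.0),
    m("albumin",             "g/L",     44.0, 45.0,  2.50, age_slope = -0.085 * 2.50),
    m("creatinine",          "umol/L",  70.0, 85.0, 12.0,  age_slope =  0.085 * 12.0),
    m("alp",                 "U/L",     70.0, 72.0, 18.0,  age_slope =  0.070 * 18.0),
    m("total_cholesterol",   "mmol/L",   5.0,  5.1,  0.90, age_slope =  0.065 * 0.90),
    m("ldl",                 "mmol/L",   2.9,  3.0,  0.80, age_slope =  0.065 * 0.80),
    m("triglycerides",       "mmol/L",   1.2,  1.4,  0.60, age_slope =  0.065 * 0.60),
    m("mchc",                "g/L",    340.0, 340.0, 8.00,  age_slope = -0.065 * 8.00),
    m("rbc",                 "10^12/L",  4.5,  5.0,  0.35, age_slope = -0.065 * 0.35),
    m("platelets",           "10^9/L", 260.0, 240.0, 55.0, age_slope = -0.070 * 55.0),
    m("hematocrit",          "%",       40.0, 44.0,  2.80, age_slope = -0.060 * 2.80),
    m("potassium",           "mmol/L",   4.2,  4.2,  0.35, age_slope =  0.060 * 0.35),
    m("alt",                 "U/L",     22.0, 28.0,  9.00, age_slope = -0.060 * 9.00),
    m("wbc",                 "10^9/L",   6.8,  6.8,  1.60, age_slope =  0.050 * 1.60),
    m("rdw",                 "%",       13.2, 13.2,  0.90, age_slope =  0.045 * 0.90,
      smoking_offset =  s * 0.90),
    m("hdl",                 "mmol/L",   1.6,  1.3,  0.30, smoking_offset = -s * 0.30),
    m("hemoglobin",          "g/L",    135.0, 150.0, 9.00, smoking_offset =  s * 9.00),
    m("mcv",                 "fL",      90.0, 90.0,  4.00, smoking_offset =  s * 4.00),
    m("sodium",              "mmol/L", 140.0, 140.0, 2.00)
  )
  light <- rbind(
    m("bilirubin_total",   "umol/L", 10.0, 12.0, 4.0,  missing_rate = 0.05),
    m("ast",               "U/L",    22.0, 26.0, 7.0,  age_slope =  0.020 * 7.0,  missing_rate = 0.05),
    m("ggt",               "U/L",    20.0, 30.0, 12.0, age_slope =  0.025 * 12.0, missing_rate = 0.08),
    m("calcium",           "mmol/L",  2.35, 2.35, 0.09, missing_rate = 0.08),
    m("phosphate",         "mmol/L",  1.10, 1.05, 0.15, missing_rate = 0.10),
    m("magnesium",         "mmol/L",  0.85, 0.85, 0.07, missing_rate = 0.10),
    m("chloride",          "mmol/L", 103.0, 103.0, 2.5, missing_rate = 0.12),
    m("bicarbonate",       "mmol/L",  25.0, 25.0, 2.2,  missing_rate = 0.12),
    m("total_protein",     "g/L",    72.0, 72.0,  4.0,  age_slope = -0.020 * 4.0,  missing_rate = 0.14),
    m("globulin",          "g/L",    28.0, 27.0,  3.5,  missing_rate = 0.14),
    m("uric_acid",         "umol/L", 280.0, 340.0, 60.0, age_slope = 0.025 * 60.0, missing_rate = 0.15),
    m("iron",              "umol/L", 16.0, 18.0,  5.5,  missing_rate = 0.15),
    m("tibc",              "umol/L", 60.0, 58.0,  7.0,  missing_rate = 0.16),
    m("transferrin_sat",   "%",      28.0, 31.0,  9.0,  missing_rate = 0.16),
    m("vitamin_b12",       "pmol/L", 330.0, 320.0, 110.0, missing_rate = 0.18),
    m("folate",            "nmol/L", 20.0, 19.0,  7.0,  missing_rate = 0.18),
    m("tsh",               "mIU/L",   2.0,  1.9,  0.9,  age_slope =  0.020 * 0.9, missing_rate = 0.20),
    m("free_t4",           "pmol/L", 15.0, 15.0,  2.2,  missing_rate = 0.20),
    m("ldh",               "U/L",   180.0, 185.0, 30.0, age_slope =  0.020 * 30.0, missing_rate = 0.22),
    m("ck",                "U/L",    95.0, 140.0, 45.0, missing_rate = 0.22),
    m("amylase",           "U/L",    60.0, 60.0, 18.0,  missing_rate = 0.24),
    m("lipase",            "U/L",    35.0, 35.0, 13.0,  missing_rate = 0.24),
    m("crp",               "mg/L",    2.5,  2.3,  2.0,  age_slope = 0.030 * 2.0,
      shape = "saturating", missing_rate = 0.25),
    m("esr",               "mm/h",   10.0,  8.0,  6.0,  age_slope = 0.030 * 6.0,
      shape = "saturating", missing_rate = 0.25)
  )
  recon <- rbind(
    m("lymphocytes",       "10^9/L",  2.0,  2.0, 0.55, age_slope = -0.025 * 0.55, missing_rate = 0.30),
    m("neutrophils",       "10^9/L",  3.8,  3.9, 1.10, missing_rate = 0.32),
    m("monocytes",         "10^9/L",  0.50, 0.55, 0.15, missing_rate = 0.34),
    m("eosinophils",       "10^9/L",  0.18, 0.20, 0.10, missing_rate = 0.36),
    m("basophils",         "10^9/L",  0.04, 0.04, 0.02, missing_rate = 0.38),
    m("mch",               "pg",     30.0, 30.5, 1.6,  missing_rate = 0.40),
    m("mpv",               "fL",     10.3, 10.3, 0.8,  missing_rate = 0.42),
    m("insulin",           "pmol/L", 60.0, 65.0, 25.0, age_slope = 0.025 * 25.0, missing_rate = 0.44),
    m("c_peptide",         "nmol/L",  0.70, 0.75, 0.22, missing_rate = 0.46),
    m("vitamin_d",         "nmol/L", 70.0, 65.0, 22.0, missing_rate = 0.48),
    m("pth",               "pmol/L",  4.5,  4.3, 1.4,  age_slope = 0.025 * 1.4, missing_rate = 0.50),
    m("cortisol",          "nmol/L", 380.0, 390.0, 95.0, missing_rate = 0.52),
    m("testosterone",      "nmol/L",  1.2, 16.0,  3.5,  age_slope = -0.020 * 3.5, missing_rate = 0.54),
    m("shbg",              "nmol/L", 60.0, 40.0, 16.0,  age_slope = 0.030 * 16.0, missing_rate = 0.54),
    m("estradiol",         "pmol/L", 280.0, 90.0, 80.0, missing_rate = 0.56),
    m("prolactin",         "ug/L",   12.0,  9.0,  4.0,  missing_rate = 0.56),
    m("apolipoprotein_a1", "g/L",     1.55, 1.40, 0.24, missing_rate = 0.58),
    m("apolipoprotein_b",  "g/L",     0.95, 1.00, 0.22, age_slope = 0.030 * 0.22, missing_rate = 0.58),
    m("lipoprotein_a",     "nmol/L", 40.0, 40.0, 30.0,  missing_rate = 0.60),
    m("homocysteine",      "umol/L", 10.0, 11.5,  3.0,  age_slope = 0.035 * 3.0, missing_rate = 0.60)
  )
  panel <- rbind(core, light, recon)
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  needed <- c("name", "units", "mean_female", "mean_male", "sd", "age_slope",
              "shape", "smoking_offset", "missing_rate")
  if (!is.data.frame(panel) || !all(needed %in% names(panel)))
    stop("panel must be a data frame with columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (anyDuplicated(panel$name))
    stop("panel: duplicated marker names: ",
         paste(unique(panel$name[duplicated(panel$name)]), collapse = ", "),
         call. = FALSE)
  if (any(panel$sd <= 0))
    stop("panel: 'sd' must be > 0 for all markers", call. = FALSE)
  if (any(panel$missing_rate < 0 | panel$missing_rate > 0.6))
    stop("panel: 'missing_rate' must lie in [0, 0.6] for all markers",
         call. = FALSE)
  if (!all(panel$shape %in% c("linear", "saturating")))
    stop("panel: 'shape' must be 'linear' or 'saturating'", call. = FALSE)
  invisible(panel)
}
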