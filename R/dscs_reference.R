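#' Published summary tables of the Khuzestan Daily Smoking Consumption Survey
#'
#' The raw 2023 DSCS respondent data are not public; the package therefore
#' carries the survey's published summary statistics as plain reference
#' tables.  They serve three purposes: defaults for the synthetic-data
#' generator ([dscs_config()]), inputs for the arithmetic identity checks on
#' the fit indices and effect transforms, and fixtures for the descriptive
#' routines.
#'
#' @return Each accessor returns a data frame (or named list) evaluated
#'   fresh, so the objects are plain text in the package source.
#' @name dscs_reference
NULL

#' @describeIn dscs_reference Per-city respondent counts, smoker prevalence,
#'   severity shares (percent) and mean/SD of daily cigarettes for the 29
#'   cities (total n = 1,973).  Cities with no smokers have `NA` mean/SD.
#' @export
dscs_city_table <- function() {
  data.frame(
    city = c("Abadan", "Aghajari", "Omidiyeh", "Andika", "Andimeshk",
      "East Ahwaz", "West Ahwaz", "Izeh", "Baghmalek", "Bavi", "Behbahan",
      "Hamidiyeh", "Khorramshahr", "Dezful", "Dasht-e-Azadegan", "Dehdez",
      "Ramshir", "Ramhormoz", "Shadegan", "Shush", "Shushtar", "Karun",
      "Gotvand", "Lali", "Bandar-e Mahshahr", "Masjedsoleyman", "Haftgel",
      "Hendijan", "Hoveizeh"),
    n = c(148L, 5L, 30L, 11L, 65L, 178L, 176L, 72L, 55L, 77L, 51L, 29L,
      77L, 235L, 69L, 14L, 28L, 55L, 99L, 116L, 99L, 66L, 24L, 8L, 116L,
      31L, 17L, 7L, 15L),
    pct_smoker = c(9.46, 20.00, 6.67, 0.00, 9.23, 8.43, 13.06, 13.89,
      14.54, 11.69, 13.73, 17.24, 9.10, 11.49, 7.25, 21.43, 14.28, 5.45,
      10.10, 6.89, 6.06, 12.13, 4.17, 12.50, 6.03, 6.46, 5.88, 0.00, 13.34),
    pct_light = c(2.70, 20.0, 0.0, 0.0, 6.15, 5.06, 5.11, 5.56, 9.09,
      3.90, 13.73, 10.34, 3.90, 6.38, 4.35, 7.14, 10.71, 3.64, 1.01, 0.86,
      2.02, 6.06, 0.0, 0.0, 5.17, 3.23, 5.88, 0.0, 6.67),
    pct_moderate = c(3.38, 0.0, 0.0, 0.0, 1.54, 1.12, 2.27, 1.39, 3.63,
      2.60, 0.0, 6.90, 1.30, 2.13, 1.45, 0.0, 0.0, 0.0, 4.04, 0.86, 1.01,
      4.55, 0.0, 0.0, 0.0, 3.23, 0.0, 0.0, 6.67),
    pct_heavy = c(3.38, 0.0, 6.67, 0.0, 1.54, 2.25, 5.68, 6.94, 1.82,
      5.19, 0.0, 0.0, 3.90, 2.98, 1.45, 14.29, 3.57, 1.81, 5.05, 5.17,
      3.03, 1.52, 4.17, 12.50, 0.86, 0.0, 0.0, 0.0, 0.0),
    mean = c(0.934, 0.600, 1.667, NA, 0.615, 0.632, 1.523, 1.667, 1.091,
      1.636, 0.392, 0.897, 1.247, 1.264, 0.493, 3.786, 1.107, 0.346,
      1.400, 1.491, 0.727, 0.942, 1.042, 2.500, 0.526, 0.258, 0.294, NA,
      1.000),
    sd = c(3.508, 1.342, 6.477, NA, 2.805, 2.810, 4.952, 5.523, 3.395,
      6.048, 1.133, 2.320, 5.571, 5.693, 2.682, 9.234, 3.891, 1.734,
      5.045, 6.360, 3.531, 3.085, 5.103, 7.071, 3.796, 1.125, 1.213, NA,
      2.803))
}

#' @describeIn dscs_reference Pooled totals: sample size, smoker count,
#'   severity prevalences (percent of all respondents), mean and SD of the
#'   daily count.
#' @export
dscs_totals <- function() {
  list(n = 1973L, smokers = 195L, non_smokers = 1778L,
       pct_smoker = 9.88, pct_light = 4.71, pct_moderate = 1.88,
       pct_heavy = 3.29, mean = 1.050, sd = 4.468)
}

#' @describeIn dscs_reference Covariate level counts of the survey sample
#'   (the "Total" column of the published group table), as a named list of
#'   named integer vectors; the first level of each vector is the modeling
#'   reference level.
#' @export
dscs_covariate_counts <- function() {
  list(
    age_group = c("<=20" = 121L, "21-25" = 475L, "26-30" = 654L,
                  ">30" = 723L),
    sex = c(Female = 1252L, Male = 721L),
    bmi_class = c(Underweight = 110L, Normal = 787L, Overweight = 679L,
                  Obese = 286L, "Extremely obese" = 111L),
    marital = c(Married = 1419L, Single = 554L),
    education = c(Illiterate = 158L, "Elementary/Middle" = 848L,
                  Diploma = 545L, "AD/BSc" = 397L, "MSc/PhD" = 25L),
    occupation = c("Unemployed/student" = 249L, Organizational = 108L,
                   Freelance = 420L, "Agricultural/livestock" = 86L,
                   Housewife = 1110L),
    residence = c(Rural = 654L, Urban = 1319L),
    disease_hist = c(No = 1676L, Yes = 297L),
    fam_mental = c(No = 1371L, Yes = 602L),
    fam_chronic = c(No = 563L, Yes = 1410L),
    general_study = c(No = 1519L, Yes = 454L),
    hookah = c(No = 1838L, Yes = 135L))
}

#' @describeIn dscs_reference Published two-part effect estimates of the
#'   two-level zero-inflated Conway--Maxwell--Poisson fit: per non-reference
#'   covariate level, the zero-part and count-part estimates with standard
#'   errors and the printed odds-ratio / rate-ratio columns.
#' @export
dscs_zicmp_effects <- function() {
  data.frame(
    variable = rep(c("age_group", "sex", "bmi_class", "marital",
      "education", "occupation", "residence", "disease_hist", "fam_mental",
      "fam_chronic", "general_study", "hookah"),
      times = c(3L, 1L, 4L, 1L, 4L, 4L, 1L, 1L, 1L, 1L, 1L, 1L)),
    level = c("21-25", "26-30", ">30", "Male", "Normal", "Overweight",
      "Obese", "Extremely obese", "Single", "Elementary/Middle", "Diploma",
      "AD/BSc", "MSc/PhD", "Organizational", "Freelance",
      "Agricultural/livestock", "Housewife", "Urban", "Yes", "Yes", "Yes",
      "Yes", "Yes"),
    zero_est = c(-0.44109, -0.59867, -1.01933, -2.26432, -0.22026,
      0.09111, 0.20643, 0.08046, -0.36787, 0.35701, 1.08590, 0.59431,
      0.05623, -0.58931, -0.39806, 0.11483, 0.55142, -0.22949, 0.28857,
      -0.10962, -0.26693, 0.51302, 0.18491),
    zero_se = c(0.50504, 0.51041, 0.51929, 0.56626, 0.38289, 0.39402,
      0.44966, 0.54884, 0.22366, 0.34184, 0.38194, 0.40913, 1.20299,
      0.37386, 0.26251, 0.37260, 0.62593, 0.19590, 0.24677, 0.19167,
      0.18977, 0.27069, 0.27152),
    count_est = c(0.12075, 0.56700, 0.76794, 1.17575, -0.28213, -0.25832,
      -0.66341, -0.08630, 0.12694, -0.24852, -0.65698, -1.12731, -2.49417,
      -0.29927, -0.27259, -0.24061, 0.01011, -0.21474, 0.29239, 0.03155,
      -0.11941, -0.30323, -0.14772),
    count_se = c(0.43410, 0.44347, 0.44167, 0.49412, 0.26514, 0.27551,
      0.32452, 0.37434, 0.16951, 0.23027, 0.27284, 0.29517, 0.92141,
      0.28125, 0.19532, 0.26440, 0.50452, 0.14851, 0.19449, 0.14003,
      0.14287, 0.22387, 0.21535),
    or = c(0.6433, 0.5495, 0.3608, 0.1039, 0.8024, 1.0954, 1.2293,
      1.0838, 0.6922, 1.4291, 2.9621, 1.8118, 1.0578, 0.5547, 0.6716,
      1.1217, 1.7357, 0.7949, 1.3345, 0.8962, 0.7657, 1.6703, 1.2031),
    rr = c(1.1283, 1.7630, 2.1553, 3.2406, 0.7542, 0.7723, 0.5151,
      0.9173, 1.1353, 0.7800, 0.5184, 0.3239, 0.0826, 0.7414, 0.7614,
      0.7861, 1.0102, 0.8068, 1.3396, 1.0321, 0.8874, 0.7384, 0.8627))
}

#' @describeIn dscs_reference Published model-comparison indices for the six
#'   two-level fits (parameter count, log-likelihood, deviance, AIC, BIC,
#'   MSE, dispersion).
#' @export
dscs_model_table <- function() {
  data.frame(
    model = c("TL-P", "TL-NB", "TL-CMP", "TL-ZIP", "TL-ZINB", "TL-ZICMP"),
    P = c(25L, 26L, 26L, 50L, 51L, 51L),
    LL = c(-3486.847, -1167.437, -1665.115, -1298.044, -1083.787,
           -1081.795),
    D = c(6973.694, 2334.874, 3330.23, 2596.088, 2167.574, 2163.59),
    AIC = c(7023.694, 2386.874, 3382.230, 2696.088, 2269.574, 2265.590),
    BIC = c(7163.377, 2532.144, 3527.500, 2746.254, 2554.527, 2550.491),
    MSE = c(15.199, 21.859, 16.882, 16.643, 16.338, 16.331),
    dispersion = c(NA, 0.071, 0.04, NA, 1.75, 0.38))
}
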