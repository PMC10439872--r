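#' The 37-parameter pre-treatment feature schema
#'
#' Returns the ordered schema of the 37 clinical and anatomical parameters
#' used to model the hypotensive effect of angle-closure treatment: age,
#' gender, refraction and visual acuity, baseline IOP, presence of initial
#' cataract, macular choroidal thickness at 13 points, axial length,
#' anterior chamber depth, lens vault, iris curvature and thickness, angle
#' opening distance (AOD500/AOD750) and trabecular-iris space area
#' (TISA500/TISA750) in the 90 and 270 degree sectors, and Shaffer
#' gonioscopic grades for the same sectors.
#'
#' The `IOP` feature is the pre-treatment intraocular pressure; the
#' post-treatment pressure travels in the separate `IOP_post` cohort column
#' so that the treatment effect `delta_iop = IOP - IOP_post` is always
#' derivable. Gender is coded 0 = male, 1 = female; the 13 choroidal
#' thickness points are stored as `CT_1` ... `CT_13` without spatial
#' semantics.
#'
#' @return A tibble with one row per feature and columns `feature`, `unit`,
#'   `kind` (`"continuous"`, `"binary"` or `"ordinal"`), `lower` and
#'   `upper` (plausible range; for binary/ordinal features the enumerated
#'   bounds).
#' @export
#' @examples
#' pac_schema()
pac_schema <- function() {
  ct <- paste0("CT_", 1:13)
  tibble::tibble(
    feature = c(
      "age", "gender", "spherical_equivalent", "UCVA", "BCVA", "IOP",
      "cataract_present", ct, "AL", "ACD", "LV",
      "ICurv_nasal", "ICurv_temporal", "IT750_nasal", "IT750_temporal",
      "AOD500_90", "AOD750_90", "TISA500_90", "TISA750_90",
      "AOD500_270", "AOD750_270", "TISA500_270", "TISA750_270",
      "Shaffer_90", "Shaffer_270"
    ),
    unit = c(
      "years", "code", "D", "decimal", "decimal", "mm Hg",
      "code", rep("um", 13), "mm", "mm", "mm",
      "mm", "mm", "mm", "mm",
      "mm", "mm", "mm2", "mm2",
      "mm", "mm", "mm2", "mm2",
      "grade", "grade"
    ),
    kind = c(
      "continuous", "binary", "continuous", "continuous", "continuous",
      "continuous", "binary", rep("continuous", 13), "continuous",
      "continuous", "continuous", "continuous", "continuous", "continuous",
      "continuous", rep("continuous", 8), "ordinal", "ordinal"
    ),
    lower = c(
      30, 0, -6, 0.01, 0.05, 8,
      0, rep(80, 13), 19.5, 1.4, 0.15,
      0.02, 0.02, 0.2, 0.2,
      0.005, 0.01, 0.002, 0.005,
      0.005, 0.01, 0.002, 0.005,
      0, 0
    ),
    upper = c(
      95, 1, 8, 1.2, 1.2, 30,
      1, rep(480, 13), 26.5, 3.6, 1.5,
      0.8, 0.8, 0.7, 0.7,
      0.4, 0.6, 0.2, 0.3,
      0.45, 0.65, 0.22, 0.32,
      4, 4
    )
  )
}

#' Feature names of the schema
#'
#' @param schema A schema tibble, by default [pac_schema()].
#' @return Character vector of the 37 feature names, in schema order.
#' @export
pac_features <- function(schema = pac_schema()) schema$feature

# Non-feature columns a cohort may carry.
cohort_meta_cols <- function() c("id", "arm", "PAS", "IOP_post")

#' Read a patient cohort from CSV
#'
#' Expects a comma-delimited, "." decimal, UTF-8 file with one row per eye:
#' an `id` column, the 37 schema features, and optionally `arm`
#' (`"LE"`, `"LPI"` or `"none"`), `IOP_post` (mm Hg, empty when the eye is
#' untreated) and a logical `PAS` flag (peripheral anterior synechiae,
#' carried as metadata only, never as a predictor).
#'
#' @param path Path to the CSV file.
#' @param schema Feature schema, by default [pac_schema()].
#' @return A cohort tibble with typed columns, row order preserved.
#' @export
#' @examples
#' f <- system.file("extdata", "synthetic_cohort_example.csv",
#'                  package = "pacsel")
#' load_cohort(f)
load_cohort <- function(path, schema = pac_schema()) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  missing <- setdiff(c("id", schema$feature), header)
  if (length(missing) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  types <- do.call(readr::cols, c(
    stats::setNames(rep(list(readr::col_double()), nrow(schema)),
                    schema$feature),
    list(id = readr::col_character(), .default = readr::col_guess())
  ))
  x <- suppressWarnings(
    readr::read_csv(path, col_types = types, progress = FALSE))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    # readr problem rows count the header line; report the data row
    stop("could not parse cohort file: row ", probs$row[1] - 1, ", column '",
         names(x)[probs$col[1]], "': expected ", probs$expected[1],
         ", got '", probs$actual[1], "'", call. = FALSE)
  }
  if (!"arm" %in% names(x)) x$arm <- "none"
  if (!"IOP_post" %in% names(x)) x$IOP_post <- NA_real_
  x$IOP_post <- as.numeric(x$IOP_post)
  if ("PAS" %in% names(x)) x$PAS <- as.logical(x$PAS)
  dplyr::relocate(x, dplyr::any_of(cohort_meta_cols()))
}

#' Write a patient cohort to CSV
#'
#' Inverse of [load_cohort()]: numeric content round-trips exactly.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return The input cohort, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(cohort)
}

#' Validate a cohort against the feature schema
#'
#' Report-only check: flags missing feature values, values outside the
#' plausible range, and binary/ordinal codes outside their enumeration.
#' The cohort itself is never modified.
#'
#' @param cohort A cohort tibble.
#' @param schema Feature schema, by default [pac_schema()].
#' @return A tibble of violations with columns `row`, `feature`, `value`
#'   and `rule`; zero rows when the cohort is clean.
#' @export
validate_cohort <- function(cohort, schema = pac_schema()) {
  empty <- tibble::tibble(row = integer(), feature = character(),
                          value = numeric(), rule = character())
  if (nrow(cohort) == 0) return(empty)
  present <- intersect(schema$feature, names(cohort))
  out <- purrr::pmap(
    dplyr::filter(schema, .data$feature %in% present),
    function(feature, unit, kind, lower, upper) {
      v <- cohort[[feature]]
      bad_missing <- which(is.na(v))
      bad_range <- which(!is.na(v) & (v < lower | v > upper))
      bad_code <- if (kind %in% c("binary", "ordinal")) {
        which(!is.na(v) & v != round(v))
      } else integer()
      rule_range <- if (kind == "ordinal") {
        sprintf("grade outside %g-%g", lower, upper)
      } else if (kind == "binary") {
        "binary code outside {0, 1}"
      } else {
        sprintf("outside plausible range [%g, %g] %s", lower, upper, unit)
      }
      dplyr::bind_rows(
        tibble::tibble(row = bad_missing, feature = feature,
                       value = NA_real_, rule = "missing value"),
        tibble::tibble(row = bad_range, feature = feature,
                       value = v[bad_range], rule = rule_range),
        tibble::tibble(row = bad_code, feature = feature,
                       value = v[bad_code], rule = "non-integer code")
      )
    }
  )
  dplyr::arrange(dplyr::bind_rows(empty, out), .data$row)
}

#' Add the treatment effect column to a cohort
#'
#' Computes `delta_iop = IOP - IOP_post`, the IOP reduction achieved by the
#' treatment (mm Hg); `NA` for untreated rows.
#'
#' @param cohort A cohort tibble with `IOP` and `IOP_post` columns.
#' @return The cohort with a `delta_iop` column.
#' @export
with_delta_iop <- function(cohort) {
  dplyr::mutate(cohort, delta_iop = .data$IOP - .data$IOP_post)
}

# Extract the feature matrix (rows x 37) from a cohort, erroring on
# missing columns or missing values in modelling rows.
feature_matrix <- function(cohort, features = pac_features()) {
  missing <- setdiff(features, names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(cohort[, features, drop = FALSE])
  if (anyNA(X)) {
    bad <- which(apply(is.na(X), 1, any))
    stop("missing feature values in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}
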