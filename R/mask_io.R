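#' Read a binary lesion mask from a NIfTI file
#'
#' Reads a NIfTI-1 volume and binarizes it at `> 0` (masks often arrive as
#' probability-like floats). In-plane spacing and origin come from the
#' header; the through-plane slice profile comes from `thickness_mm` /
#' `gap_mm` when supplied, because clinical exports usually store only the
#' centre spacing with no gap semantics. When neither is given the header
#' z-spacing is trusted as the slice thickness with zero gap.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param thickness_mm,gap_mm Optional slice thickness and inter-slice gap in
#'   mm overriding the header z-spacing. Supply both or neither; their sum
#'   should equal the header's slice centre spacing for stacked clinical ROIs.
#' @return A [lesion_mask()]. An all-zero volume returns an empty mask with a
#'   warning (measurement functions will refuse it).
#' @export
read_mask <- function(path, thickness_mm = NULL, gap_mm = NULL) {
  if (!file.exists(path)) {
    lf_abort(sprintf("File not found: %s", path), "format")
  }
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) {
      lf_abort(sprintf("Not a readable NIfTI file: %s (%s)", path, conditionMessage(e)),
               "format")
    }
  )
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3L) {
    lf_abort("Mask volume must be 3-dimensional.", "format")
  }
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  if (is.null(pd) || length(pd) < 3L) pd <- c(1, 1, 1)
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  origin <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)

  if (xor(is.null(thickness_mm), is.null(gap_mm))) {
    lf_abort("Supply both `thickness_mm` and `gap_mm`, or neither.", "validation")
  }
  if (is.null(thickness_mm)) {
    thickness_mm <- pd[3]
    gap_mm <- 0
  }
  grid <- voxel_grid(
    dim(arr)[1], dim(arr)[2], dim(arr)[3],
    dx = pd[1], dy = pd[2],
    slice_thickness = thickness_mm, slice_gap = gap_mm,
    origin = origin
  )
  occ <- array(arr > 0, dim = dim(arr))
  if (!any(occ)) {
    lf_warn(sprintf("Mask %s contains no nonzero voxels.", path), "empty_mask")
  }
  lesion_mask(occ, grid)
}

#' Write a lesion mask to NIfTI
#'
#' Stores the occupancy as uint8 with the grid's spacings in the header; the
#' header z-spacing is the slice centre spacing (thickness + gap), so reading
#' back with the same `thickness_mm` / `gap_mm` reproduces the grid.
#'
#' @param mask A [lesion_mask()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  grid <- mask$grid
  arr <- array(as.integer(mask$occupancy), dim = dim(mask$occupancy))
  hdr <- RNifti::niftiHeader(list(
    dim = c(3, grid$nx, grid$ny, grid$nz, 1, 1, 1, 1),
    pixdim = c(1, grid$dx, grid$dy, slice_step(grid), 0, 0, 0, 0),
    qform_code = 0, sform_code = 2,
    srow_x = c(grid$dx, 0, 0, grid$origin[1]),
    srow_y = c(0, grid$dy, 0, grid$origin[2]),
    srow_z = c(0, 0, slice_step(grid), grid$origin[3])
  ))
  img <- RNifti::asNifti(arr, reference = hdr, datatype = "uint8")
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) lf_abort(conditionMessage(e), "io"))
  invisible(path)
}

cohort_required_cols <- c(
  "subject_id", "initial_score", "manual_tv_cc", "manual_tmd_cm",
  "auto_tv_cc", "auto_tmd_cm"
)

#' Validate a cohort measurement table
#'
#' Checks the schema every cohort-level function relies on: unique subject
#' ids, PI-RADS scores in 3-5, non-negative measurements. Extra columns are
#' allowed and preserved.
#'
#' @param table A data frame of per-subject paired measurements.
#' @return The validated table as a tibble.
#' @export
validate_cohort_table <- function(table) {
  if (!is.data.frame(table)) lf_abort("Cohort table must be a data frame.", "schema")
  missing_cols <- setdiff(cohort_required_cols, names(table))
  if (length(missing_cols) > 0) {
    lf_abort(sprintf("Cohort table is missing column(s): %s.",
                     paste(missing_cols, collapse = ", ")), "schema")
  }
  tb <- tibble::as_tibble(table)
  if (nrow(tb) == 0) return(tb)
  if (anyDuplicated(tb$subject_id)) {
    lf_abort("subject_id values must be unique.", "validation")
  }
  if (!all(tb$initial_score %in% 3:5)) {
    lf_abort("initial_score values must be 3, 4 or 5.", "validation")
  }
  if ("rescored_score" %in% names(tb)) {
    rs <- tb$rescored_score[!is.na(tb$rescored_score)]
    if (!all(rs %in% 3:5)) lf_abort("rescored_score values must be 3, 4 or 5.", "validation")
  }
  meas <- c("manual_tv_cc", "manual_tmd_cm", "auto_tv_cc", "auto_tmd_cm")
  for (cl in meas) {
    v <- tb[[cl]]
    if (!is.numeric(v) || any(!is.na(v) & v < 0)) {
      lf_abort(sprintf("Column %s must be numeric and non-negative.", cl), "validation")
    }
  }
  tb
}

#' Read a cohort measurement table from CSV
#'
#' Loads per-subject paired manual and automated measurements with initial
#' PI-RADS scores. The packaged fixture
#' `system.file("extdata", "table2.csv", package = "lesionfit3d")` holds the
#' published 15-subject rescoring cohort (4 initially score-3, 11 initially
#' score-4 subjects).
#'
#' @param path CSV path with header columns `subject_id`, `initial_score`,
#'   `manual_tv_cc`, `manual_tmd_cm`, `auto_tv_cc`, `auto_tmd_cm` and
#'   optionally `rescored_score`.
#' @return A validated cohort tibble.
#' @export
#' @examples
#' tb <- read_cohort_table(system.file("extdata", "table2.csv",
#'                                     package = "lesionfit3d"))
#' nrow(tb)
read_cohort_table <- function(path) {
  if (!file.exists(path)) lf_abort(sprintf("File not found: %s", path), "format")
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) lf_abort(sprintf("Cannot parse CSV: %s", conditionMessage(e)),
                                 "format")
  )
  validate_cohort_table(df)
}

#' Read a per-score summary table
#'
#' Loads a per-score mean/SD summary of manual and automated measurements
#' (the published cohort summary layout). The packaged fixture
#' `summary_by_score.csv` holds the published per-score means and SDs of
#' tumour volume (cc) and maximum diameter (cm) for scores 3-5, for both
#' measurement methods.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return A tibble with one row per score and mean/SD columns for each
#'   method and measure.
#' @export
#' @examples
#' read_score_summary()
read_score_summary <- function(path = system.file("extdata", "summary_by_score.csv",
                                                  package = "lesionfit3d")) {
  if (!file.exists(path)) lf_abort(sprintf("File not found: %s", path), "format")
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) lf_abort(sprintf("Cannot parse CSV: %s", conditionMessage(e)),
                                 "format")
  )
  need <- c("score", "manual_tv_mean_cc", "auto_tv_mean_cc",
            "manual_tmd_mean_cm", "auto_tmd_mean_cm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    lf_abort(sprintf("Summary table is missing column(s): %s.",
                     paste(missing_cols, collapse = ", ")), "schema")
  }
  tibble::as_tibble(df)
}

#' Write a measurement / rescoring / statistics report
#'
#' Deterministic writer: identical content yields byte-identical files. JSON
#' output sorts keys and prints numbers at 6 significant digits; CSV output
#' is written without row names and with 6-significant-digit numbers.
#'
#' @param report A named list (JSON) or data frame (CSV or JSON).
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  if (length(format) != 1L || !format %in% c("json", "csv")) {
    format <- tryCatch(match.arg(format),
                       error = function(e) lf_abort(
                         sprintf("Unknown report format '%s': use json or csv.",
                                 paste(format, collapse = "/")), "usage"))
  }
  if (is.null(report) || (is.list(report) && length(report) == 0)) {
    lf_abort("Report is empty.", "validation")
  }
  if (format == "csv") {
    if (!is.data.frame(report)) {
      lf_abort("CSV reports require a data frame.", "validation")
    }
    num <- vapply(report, is.numeric, logical(1))
    report[num] <- lapply(report[num], signif, digits = 6)
    out <- tryCatch({
      con <- file(path, open = "wb")
      on.exit(close(con))
      utils::write.csv(report, con, row.names = FALSE, eol = "\n")
      path
    }, error = function(e) lf_abort(conditionMessage(e), "io"))
    return(invisible(out))
  }
  sorted <- sort_report(report)
  json <- jsonlite::toJSON(sorted, auto_unbox = TRUE, digits = I(6), null = "null")
  tryCatch(writeLines(json, path, useBytes = TRUE),
           error = function(e) lf_abort(conditionMessage(e), "io"))
  invisible(path)
}

sort_report <- function(x) {
  if (is.data.frame(x)) return(x[, sort(names(x)), drop = FALSE])
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[sort(nm)]
    return(lapply(x, sort_report))
  }
  x
}
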