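# Numeric columns are serialized with %.17g so read -> write -> read is
# exact to double precision.
.fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

.read_csv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty input file: ", path, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
}

.check_numeric_col <- function(df, col, path, allow_na = FALSE) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & !(allow_na & (is.na(raw) | raw == "")))
  if (length(bad))
    stop(sprintf("%s: non-numeric value in column '%s' at data line %d",
                 path, col, bad[1]), call. = FALSE)
  val
}

#' Extract an HU histogram from masked pixel values
#'
#' Retains pixels with values in `[-200, 200]` HU (after applying the
#' optional mask) and bins them on the standard grid; the summed bin
#' values equal the retained pixel count.
#'
#' @param pixels Numeric HU values from a segmented cross-section.
#' @param mask Optional logical vector marking pixels to keep.
#' @param bin_width Bin width in HU (default 1).
#' @return A [hu_histogram] of counts.
#' @export
extract_histogram <- function(pixels, mask = NULL, bin_width = 1) {
  stopifnot(is.numeric(pixels))
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), length(mask) == length(pixels))
    pixels <- pixels[mask]
  }
  pixels <- pixels[is.finite(pixels) & pixels >= -200 & pixels <= 200]
  if (!length(pixels))
    stop("degenerate input: no pixels retained in [-200, 200] HU",
         call. = FALSE)
  centers <- seq(-200, 200, by = bin_width)
  hist_from_pixels(pixels, centers, bin_width)
}

#' Read / write an HU histogram as CSV
#'
#' Two-column file with header `hu,value`.
#' @param path File path.
#' @param hist A [hu_histogram].
#' @return `read_histogram` returns a [hu_histogram];
#'   `write_histogram` returns `path` invisibly.
#' @export
read_histogram <- function(path) {
  df <- .read_csv_checked(path)
  if (!identical(names(df), c("hu", "value")))
    stop(path, ": expected header 'hu,value', found '",
         paste(names(df), collapse = ","), "'", call. = FALSE)
  hu_histogram(.check_numeric_col(df, "hu", path),
               .check_numeric_col(df, "value", path))
}

#' @rdname read_histogram
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "hu_histogram"))
  df <- data.frame(hu = .fmt_num(hist$bin_centers),
                   value = .fmt_num(hist$values))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a trimodal profile as CSV
#'
#' Long format with header `tissue,parameter,value`, 11 rows in
#' canonical order.
#' @param path File path.
#' @param profile An [ntra_profile].
#' @return `read_profile` returns an [ntra_profile]; `write_profile`
#'   returns `path` invisibly.
#' @export
read_profile <- function(path) {
  df <- .read_csv_checked(path)
  if (!identical(names(df), c("tissue", "parameter", "value")))
    stop(path, ": expected header 'tissue,parameter,value'", call. = FALSE)
  key <- paste(df$tissue, df$parameter, sep = ".")
  expected <- c("fat.N", "fat.mu", "fat.sigma", "fat.alpha",
                "connective.N", "connective.mu", "connective.sigma",
                "muscle.N", "muscle.mu", "muscle.sigma", "muscle.alpha")
  if (!setequal(key, expected) || anyDuplicated(key))
    stop(path, ": profile rows must be exactly the 11 canonical ",
         "tissue/parameter pairs", call. = FALSE)
  val <- .check_numeric_col(df, "value", path)
  vector_to_profile(val[match(expected, key)])
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ntra_profile"))
  v <- profile_to_vector(profile)
  df <- data.frame(
    tissue = rep(c("fat", "connective", "muscle"), c(4L, 3L, 4L)),
    parameter = c("N", "mu", "sigma", "alpha", "N", "mu", "sigma",
                  "N", "mu", "sigma", "alpha"),
    value = .fmt_num(unname(v)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a cohort table as CSV
#'
#' Canonical schema `subject_id,timepoint,age,sex,chd,cvd,chf` followed
#' by the 11 parameter columns; missing condition flags are written as
#' empty fields.
#' @param path File path.
#' @param cohort A cohort table.
#' @return `read_cohort` returns a validated cohort data frame;
#'   `write_cohort` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- .read_csv_checked(path)
  expected <- .cohort_columns()
  if (!identical(names(df), expected)) {
    wrong <- c(setdiff(expected, names(df)), setdiff(names(df), expected))
    stop(path, ": cohort header mismatch on column(s): ",
         paste(unique(wrong), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(subject_id = df$subject_id,
                    timepoint = df$timepoint,
                    age = as.integer(.check_numeric_col(df, "age", path)),
                    sex = df$sex,
                    stringsAsFactors = FALSE)
  for (flag in c("chd", "cvd", "chf")) {
    raw <- df[[flag]]
    bad <- which(!(raw %in% c("TRUE", "FALSE", "", NA)))
    if (length(bad))
      stop(sprintf("%s: invalid logical in column '%s' at data line %d",
                   path, flag, bad[1]), call. = FALSE)
    out[[flag]] <- ifelse(raw %in% c("TRUE", "FALSE"), raw == "TRUE", NA)
  }
  for (col in ntra_parameter_names())
    out[[col]] <- .check_numeric_col(df, col, path)
  as_cohort_table(out)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_cohort_table(cohort)
  df <- cohort[, .cohort_columns()]
  for (flag in c("chd", "cvd", "chf"))
    df[[flag]] <- ifelse(is.na(df[[flag]]), "",
                         ifelse(df[[flag]], "TRUE", "FALSE"))
  for (col in ntra_parameter_names())
    df[[col]] <- .fmt_num(df[[col]])
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write / read a structured evaluation report as JSON
#' @param report A nested list (e.g. from [full_typology]).
#' @param path File path.
#' @return `read_report` returns the parsed list; `write_report`
#'   returns `path` invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
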