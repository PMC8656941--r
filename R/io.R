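#' Read and write cohort tables
#'
#' The cohort table travels as an RFC 4180 CSV in UTF-8 with a header row;
#' missing numeric entries are empty cells; floating-point values are
#' serialized at 17 significant digits so a write-read round trip is exact.
#' The column dictionary: `subject_id` (token), `group` (factor), `age`
#' (years), `gender` (`F`/`M`), `education` (years), cognitive scores
#' (`MMSE`, `fluency`, `TMTB`, `CERAD`, points/seconds/words), CAQ items
#' `caq_p06_a1` ... `caq_cur_a6` (integers 1--5), composites `cCAQ`,
#' `pCAQ`.
#'
#' @param path CSV file path.
#' @param required Columns that must be present (default `subject_id`,
#'   `group`).
#' @return `read_cohort()`: a `meg_cohort` tibble with the missingness mask
#'   attribute; `write_cohort()`: the path, invisibly.
#' @export
read_cohort <- function(path, required = c("subject_id", "group")) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = character())
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("cohort is missing mandatory columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(raw)
  char_cols <- c("subject_id", "group", "gender")
  for (v in setdiff(names(out), char_cols)) {
    val <- out[[v]]
    val[val == ""] <- NA
    num <- suppressWarnings(as.numeric(val))
    bad <- which(!is.na(val) & is.na(num))
    if (length(bad)) {
      abort(sprintf("malformed numeric cell in column '%s', row %d: '%s'",
                    v, bad[1L], val[bad[1L]]))
    }
    out[[v]] <- num
  }
  mask <- tibble::as_tibble(lapply(out, is.na))
  structure(out, missing_mask = mask, class = c("meg_cohort", class(tibble::tibble())))
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), "", formatC(v, digits = 17, format = "g"))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read and write source recordings as text containers
#'
#' A recording is stored as a pair of files: `<stem>.csv` holding the
#' regions x samples data matrix (one row per region, no header) and
#' `<stem>.json` holding `subject_id`, `fs` and `roi_names`.
#'
#' @param rec A `meg_recording`.
#' @param stem Path stem (without extension).
#' @return `write_recording()`: the stem, invisibly; `read_recording()`:
#'   the recording.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "meg_recording"))
  data.table::fwrite(data.table::as.data.table(rec$data),
                     paste0(stem, ".csv"), col.names = FALSE)
  jsonlite::write_json(
    list(subject_id = rec$subject_id, fs = rec$fs, roi_names = rec$roi_names),
    paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  data <- as.matrix(data.table::fread(paste0(stem, ".csv"), header = FALSE))
  dimnames(data) <- NULL
  structure(
    list(subject_id = meta$subject_id, fs = meta$fs,
         roi_names = meta$roi_names, data = data),
    class = "meg_recording"
  )
}

#' Write a connectivity matrix as CSV
#'
#' One CSV per subject and band with ROI names as header row and first
#' column.
#'
#' @param m A `meg_connectivity`.
#' @param path Output CSV path.
#' @export
write_connectivity <- function(m, path) {
  stopifnot(inherits(m, "meg_connectivity"))
  df <- as.data.frame(m$matrix)
  names(df) <- m$roi_names
  df <- cbind(roi = m$roi_names, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
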