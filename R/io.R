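#' Write tidy rating and choice tables
#'
#' Writers for the package's delimited-text interchange format: one row per
#' rating trial (subject, stimulus, category, repetition, three ratings) or
#' per choice trial (subject, contrast, stimuli, choice, confidence).
#'
#' @param subjects List of per-subject data from
#'   \code{\link{simulate_subject}} (or same-shaped tables).
#' @param path Output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_ratings_csv <- function(subjects, path) {
  out <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    d <- subjects[[i]]$ratings
    data.frame(subject = i,
               d[, c("trial", "stimulus", "category", "repetition",
                     "likability", "familiarity", "humanlikeness")],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' @rdname write_ratings_csv
#' @export
write_choices_csv <- function(subjects, path) {
  out <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    d <- subjects[[i]]$choices
    data.frame(subject = i,
               d[, c("trial", "contrast", "first", "second", "choice",
                     "confidence")],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read rating / choice tables written by the package
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_ratings_csv <- function(path) utils::read.csv(path,
                                                   stringsAsFactors = FALSE)

#' @rdname read_ratings_csv
#' @export
read_choices_csv <- function(path) utils::read.csv(path,
                                                   stringsAsFactors = FALSE)

#' Write an epoched ROI time course with its JSON sidecar
#'
#' The trials x time matrix goes to CSV; acquisition metadata (effective
#' sampling interval, epoch grid, onsets, region label) goes to a JSON
#' sidecar next to it.
#'
#' @param tc A \code{"roi_timecourse"}.
#' @param path CSV path; the sidecar replaces the extension with
#'   \code{.json}.
#' @param region Region label stored in the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_timecourse_csv <- function(tc, path, region = "ROI") {
  m <- as.data.frame(tc$epochs)
  names(m) <- sprintf("t_%g", tc$time)
  utils::write.csv(m, path, row.names = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(region = region, tr_effective = tc$tr_effective,
         time = tc$time, onsets = tc$onsets, oversample = tc$oversample),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an epoched ROI time course written by the package
#'
#' @param path CSV path with its \code{.json} sidecar alongside.
#' @return A \code{"roi_timecourse"}-shaped list.
#' @export
read_timecourse_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  sidecar <- sub("\\.[^.]+$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  structure(list(epochs = unname(m), time = meta$time,
                 tr_effective = meta$tr_effective, onsets = meta$onsets,
                 oversample = meta$oversample, degenerate = FALSE),
            class = "roi_timecourse")
}
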