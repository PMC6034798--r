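#' Write a record container to disk
#'
#' One directory per exam record: `meta.json` (sampling rate, duration,
#' quality, plus any caller metadata such as subject id, record index,
#' pulse spec and ground-truth medium for synthetic records) and
#' `samples.f32le`, the raw waveform as little-endian 32-bit floats.
#'
#' @param record an `acg_record`.
#' @param dir directory to create/write.
#' @param meta named list of extra metadata stored in `meta.json`.
#' @return `dir`, invisibly.
#' @export
write_record <- function(record, dir, meta = list()) {
  stopifnot(inherits(record, "acg_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- c(
    list(
      sampling_rate_hz = record$sampling_rate_hz,
      duration_s = record$duration_s,
      n_samples = length(record$samples),
      quality = if (is.na(record$quality)) NULL else record$quality
    ),
    meta
  )
  jsonlite::write_json(info, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(dir, "samples.f32le"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(record$samples), con, size = 4, endian = "little")
  invisible(dir)
}

#' Read a record container from disk
#'
#' @param dir a directory written by [write_record()].
#' @return an `acg_record` with the metadata list attached as attribute
#'   `meta`.
#' @export
read_record <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  path <- file.path(dir, "samples.f32le")
  con <- file(path, "rb")
  on.exit(close(con))
  samples <- readBin(con, numeric(), n = meta$n_samples, size = 4,
                     endian = "little")
  rec <- new_record(samples, meta$sampling_rate_hz, meta$duration_s,
                    quality = meta$quality %||% NA_real_)
  attr(rec, "meta") <- meta
  rec
}

#' Export a record waveform as CSV
#'
#' Two columns, `time_s` and `amplitude`, for interchange with other
#' tools.
#'
#' @param record an `acg_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
record_to_csv <- function(record, path) {
  n <- length(record$samples)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 1) / record$sampling_rate_hz,
               amplitude = record$samples),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Write a cohort manifest (and optionally its records) to disk
#'
#' Writes `cohort.json` holding the subject table (covariates, latent
#' feature targets and ground-truth medium parameters) and, when the
#' cohort carries simulated records, one [write_record()] container per
#' exam record under `<subject_id>/rec<k>/`. The covariate table is also
#' exported as `covariates.csv`.
#'
#' @param cohort an `acg_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(
      n_subjects = nrow(cohort$subjects),
      seed = cohort$config$seed,
      subjects = cohort$subjects
    ),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  utils::write.csv(
    cohort$subjects[c("subject_id", "group",
                      intersect(covariate_defaults()$covariate,
                                names(cohort$subjects)),
                      "age", "head_circumference_cm")],
    file.path(dir, "covariates.csv"), row.names = FALSE
  )
  if (!is.null(cohort$records)) {
    for (id in names(cohort$records)) {
      exam <- cohort$records[[id]]
      for (k in seq_along(exam$records)) {
        write_record(
          exam$records[[k]],
          file.path(dir, id, sprintf("rec%d", k)),
          meta = list(subject_id = id, record_index = k)
        )
      }
    }
  }
  invisible(dir)
}

#' Read a cohort manifest written by [write_cohort()]
#'
#' @param dir the cohort directory.
#' @return a list with `subjects` (tibble) and `seed`.
#' @export
read_cohort_manifest <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "cohort.json"),
                           simplifyVector = TRUE)
  list(subjects = tibble::as_tibble(m$subjects), seed = m$seed)
}
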