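#' Write a record as delimited text with a YAML sidecar
#'
#' Writes one CSV per record (rows = time samples, columns = channels) plus a
#' `.yaml` sidecar holding the sampling rate, label, repetition and subject,
#' so datasets round-trip through plain text.
#'
#' @param record An [emg_record()].
#' @param path Path of the CSV file to create; the sidecar replaces the
#'   extension with `.yaml`.
#' @return `path`, invisibly.
#' @export
write_emg_csv <- function(record, path) {
  stopifnot_record(record)
  m <- t(record$samples)
  colnames(m) <- sprintf("ch%02d", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE)
  meta <- list(fs = record$fs, label = record$label,
               repetition = record$repetition, subject = record$subject)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a record written by [write_emg_csv()]
#'
#' @param path Path of the CSV file; the YAML sidecar must sit next to it.
#' @return An [emg_record()].
#' @export
read_emg_csv <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  m <- as.matrix(utils::read.csv(path))
  emg_record(t(m), fs = meta$fs, label = meta$label,
             repetition = meta$repetition, subject = meta$subject)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".yaml", path)

#' Write a directory of records
#'
#' File names encode provenance: `<subject>_m<label>_r<repetition>.csv`.
#'
#' @param records List of [emg_record()]s.
#' @param dir Output directory (created if missing).
#' @return Character vector of file paths, invisibly.
#' @export
write_emg_dataset <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(records, function(rec) {
    p <- file.path(dir, sprintf("%s_m%02d_r%02d.csv",
                                rec$subject, rec$label, rec$repetition))
    write_emg_csv(rec, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a directory of records
#'
#' @param dir Directory containing CSV/YAML pairs from
#'   [write_emg_dataset()].
#' @return List of [emg_record()]s.
#' @export
read_emg_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  lapply(files, read_emg_csv)
}
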