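# File formats. Angle CSV: comma-separated, UTF-8, header
# "learner,session,trial,speed,t_s,elbow_deg,knee_deg", one trial contiguous.
# Labels TSV: tab-separated "learner,speed,cycle_index,session,trial,pattern"
# with cycle_index 0-based chronological within learner x speed. Models as
# versioned JSON with row-major matrices.

#' Read a joint-angle CSV file
#'
#' @param path File path.
#' @return A trace tibble (validated).
#' @export
read_angle_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            learner = readr::col_integer(),
                            session = readr::col_integer(),
                            trial = readr::col_integer(),
                            speed = readr::col_character(),
                            t_s = readr::col_double(),
                            elbow_deg = readr::col_double(),
                            knee_deg = readr::col_double()))
  validate_trace(data)
  data
}

#' Write a joint-angle CSV file
#'
#' @param data Trace tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_angle_csv <- function(data, path) {
  validate_trace(data)
  readr::write_csv(data[trace_cols], path)
  invisible(path)
}

#' Read / write chronological pattern-label TSV
#'
#' @param path File path.
#' @return Tibble with columns learner, speed, cycle_index (0-based
#'   chronological within learner x speed), session, trial, pattern.
#' @export
read_labels_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    learner = readr::col_integer(),
                    speed = readr::col_character(),
                    cycle_index = readr::col_integer(),
                    session = readr::col_integer(),
                    trial = readr::col_integer(),
                    pattern = readr::col_integer()))
}

#' @rdname read_labels_tsv
#' @param labels Labels tibble (columns as above).
#' @export
write_labels_tsv <- function(labels, path) {
  cols <- c("learner", "speed", "cycle_index", "session", "trial", "pattern")
  readr::write_tsv(labels[cols], path)
  invisible(path)
}

#' Serialize / deserialize a DMM as JSON
#'
#' Schema version 1: fields `schema`, `m`, `degree`, `n`, `supports`
#' (row-major), `alphabet`, and fit diagnostics when present.
#'
#' @param model A `"dmm"` object.
#' @param path File path.
#' @export
write_dmm_json <- function(model, path) {
  obj <- list(
    schema = "driftlearn-dmm/1",
    m = model$m, degree = model$degree, n = model$n,
    supports = purrr::map(model$supports, function(P) {
      as.vector(t(P))  # row-major
    }),
    alphabet = model$alphabet,
    loglik = model$loglik, npar = model$npar,
    aic = model$aic, bic = model$bic, method = model$method, x0 = model$x0
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dmm_json
#' @export
read_dmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "driftlearn-dmm/1")) {
    abort("unrecognized model schema")
  }
  raw <- obj$supports
  if (!is.list(raw)) {
    raw <- lapply(seq_len(nrow(raw)), function(i) raw[i, ])
  }
  supports <- purrr::map(
    raw, function(v) matrix(as.numeric(v), obj$m, obj$m, byrow = TRUE))
  model <- new_dmm(supports, n = obj$n, alphabet = obj$alphabet)
  for (fld in c("loglik", "npar", "aic", "bic", "method", "x0")) {
    model[[fld]] <- obj[[fld]]
  }
  model
}

#' Read the first sequence of a FASTA file as a label sequence
#'
#' Single-character alphabets (e.g. nucleotides) can be modelled directly
#' with [fit_dmm()], which is where this model family originated.
#'
#' @param path FASTA file path.
#' @return Upper-case character vector of single characters.
#' @export
read_fasta_sequence <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  headers <- grepl("^>", lines)
  if (!any(headers)) abort("not a FASTA file: no header line")
  first <- which(headers)[1]
  stop_at <- c(which(headers)[-1], length(lines) + 1)[1]
  seq <- paste(lines[(first + 1):(stop_at - 1)], collapse = "")
  toupper(strsplit(seq, "")[[1]])
}
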