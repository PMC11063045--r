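#' Write / read screening record tables
#'
#' Record tables travel as comma-separated UTF-8 text with the fixed header
#' `record_id,true_class,predicted_class,model_name`, one record per line.
#' The round trip is lossless.
#'
#' @param records record tibble (see [draw_true_classes()]).
#' @param path file path.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   returns a record tibble.
#' @export
write_records <- function(records, path) {
  check_records(records, require_predictions = FALSE)
  utils::write.csv(as.data.frame(records[RECORD_COLUMNS]), path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_records
#' @param classes optional character vector of admissible class names
#'   (diseases plus `"normal"`); when given, any other class token in the
#'   file is an error naming the token and its line.
#' @export
read_records <- function(path, classes = NULL) {
  if (!file.exists(path)) abort_sdca("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]  # provenance comment lines
  if (!length(lines)) abort_sdca("empty file (no header row): ", path)
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (!identical(header, RECORD_COLUMNS))
    abort_sdca("bad header; expected '", paste(RECORD_COLUMNS, collapse = ","), "'")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(tibble::tibble(record_id = character(), true_class = character(),
                          predicted_class = character(), model_name = character()))
  }
  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    i <- which(nf != 4L)[1L]
    abort_sdca("malformed row at line ", i + 1L, ": expected 4 columns, found ", nf[i])
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  out <- tibble::tibble(record_id = m[, 1L], true_class = m[, 2L],
                        predicted_class = m[, 3L], model_name = m[, 4L])
  out$predicted_class[out$predicted_class == "NA"] <- NA_character_
  out$model_name[out$model_name == "NA"] <- NA_character_
  if (!is.null(classes)) {
    for (col in c("true_class", "predicted_class")) {
      v <- out[[col]]
      bad <- which(!is.na(v) & !(v %in% classes))
      if (length(bad))
        abort_sdca("unknown class token '", v[bad[1L]], "' in column ", col,
                   " at line ", bad[1L] + 1L)
    }
  }
  check_records(out, require_predictions = FALSE)
  out
}
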