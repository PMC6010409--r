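#' Read and write repertoire samples
#'
#' The CSV dialect has columns `individual_id, population, x_m, y_m,
#' syllables`, the last holding semicolon-separated type labels; the JSON
#' mirror stores one object per individual with the syllables as an
#' array.
#'
#' @param sample A `repertoire_sample`.
#' @param path File path (`.csv` or `.json`, decided by extension).
#' @return `read_repertoires` returns the `repertoire_sample`.
#' @export
write_repertoires <- function(sample, path) {
  if (grepl("\\.json$", path)) {
    rows <- lapply(seq_len(nrow(sample)), function(i)
      list(individual_id = sample$individual_id[i],
           population = sample$population[i],
           x_m = sample$x_m[i], y_m = sample$y_m[i],
           syllables = sample$syllables[[i]]))
    jsonlite::write_json(rows, path, digits = NA, auto_unbox = TRUE)
  } else {
    flat <- data.frame(individual_id = sample$individual_id,
                       population = sample$population,
                       x_m = sample$x_m, y_m = sample$y_m,
                       syllables = vapply(sample$syllables, paste,
                                          "", collapse = ";"))
    write.csv(flat, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_repertoires
#' @export
read_repertoires <- function(path) {
  if (grepl("\\.json$", path)) {
    rows <- jsonlite::read_json(path, simplifyVector = FALSE)
    repertoire_sample(
      individual_id = vapply(rows, `[[`, "", "individual_id"),
      population = vapply(rows, `[[`, "", "population"),
      x_m = vapply(rows, function(r) as.numeric(r$x_m %||% NA), 0),
      y_m = vapply(rows, function(r) as.numeric(r$y_m %||% NA), 0),
      syllables = lapply(rows, function(r) unlist(r$syllables)))
  } else {
    flat <- read.csv(path, stringsAsFactors = FALSE,
                     colClasses = c(syllables = "character"))
    repertoire_sample(individual_id = flat$individual_id,
                      population = flat$population,
                      x_m = flat$x_m, y_m = flat$y_m,
                      syllables = strsplit(flat$syllables, ";",
                                           fixed = TRUE))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a particle set as CSV
#'
#' One row per particle: parameter columns plus `weight` and `distance`.
#'
#' @param ps A `particle_set`.
#' @param path File path.
#' @export
write_particles <- function(ps, path) {
  write.csv(as.data.frame(ps), path, row.names = FALSE)
  invisible(path)
}
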