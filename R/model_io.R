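# Model bundles are plain-text directories: config.json + manifest.json +
# weights.txt (per parameter: a "name nrow ncol" header line, then one line
# of %.17g values, row-major), so bundles survive text-only storage and
# load bit-exact.

write_weights <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(params)) {
    pr <- params[[nm]]
    writeLines(sprintf("%s %d %d", nm, nrow(pr$value), ncol(pr$value)), con)
    writeLines(paste(sprintf("%.17g", as.vector(t(pr$value))),
                     collapse = " "), con)
  }
  invisible(path)
}

read_weights <- function(params, path) {
  lines <- readLines(path)
  i <- 1L
  while (i < length(lines)) {
    hdr <- strsplit(lines[i], " ")[[1]]
    nm <- hdr[1]; nr <- as.integer(hdr[2]); nc <- as.integer(hdr[3])
    vals <- as.numeric(strsplit(lines[i + 1L], " ")[[1]])
    if (is.null(params[[nm]]))
      stop("weights file contains unknown parameter '", nm, "'")
    if (length(vals) != nr * nc)
      stop("parameter '", nm, "' has ", length(vals), " values; expected ",
           nr * nc)
    params[[nm]]$value <- matrix(vals, nr, nc, byrow = TRUE)
    i <- i + 2L
  }
  invisible(params)
}

#' Save a Place-Back model bundle
#'
#' Writes a directory with `config.json`, `manifest.json` (model id, MSRL,
#' seed, training steps) and `weights.txt`; [load_placeback()] restores the
#' model bit-exactly.
#'
#' @param model A `placeback_model`.
#' @param dir Bundle directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_placeback <- function(model, dir) {
  stopifnot(inherits(model, "placeback_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(kind = "placeback", model_id = model$model_id,
                            msrl = model$config$msrl,
                            seed = model$config$seed,
                            steps_trained = model$steps_trained),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  write_weights(model$params, file.path(dir, "weights.txt"))
  invisible(dir)
}

#' Load a Place-Back model bundle
#'
#' @param dir Directory written by [save_placeback()].
#' @return A `placeback_model`.
#' @export
load_placeback <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg$conv_channels <- as.integer(cfg$conv_channels)
  config <- structure(cfg, class = "placeback_config")
  model <- build_placeback(config)
  read_weights(model$params, file.path(dir, "weights.txt"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  model$steps_trained <- as.integer(man$steps_trained)
  model
}

#' Save a Determiner model bundle
#'
#' @param model A `determiner_model`.
#' @param dir Bundle directory.
#' @return Invisibly, `dir`.
#' @export
save_determiner <- function(model, dir) {
  stopifnot(inherits(model, "determiner_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(kind = "determiner", model_id = model$model_id,
                            seed = model$config$seed,
                            steps_trained = model$steps_trained),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  write_weights(model$params, file.path(dir, "weights.txt"))
  invisible(dir)
}

#' Load a Determiner model bundle
#'
#' @param dir Directory written by [save_determiner()].
#' @return A `determiner_model`.
#' @export
load_determiner <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- structure(cfg, class = "determiner_config")
  model <- build_determiner(config)
  read_weights(model$params, file.path(dir, "weights.txt"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  model$steps_trained <- as.integer(man$steps_trained)
  model
}

#' Save a Determiner ensemble bundle
#'
#' A directory of per-member bundles (`member_01` ...) plus a manifest.
#'
#' @param ensemble A `determiner_ensemble`.
#' @param dir Bundle directory.
#' @return Invisibly, `dir`.
#' @export
save_determiner_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "determiner_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ensemble$members))
    save_determiner(ensemble$members[[i]],
                    file.path(dir, sprintf("member_%02d", i)))
  jsonlite::write_json(list(kind = "determiner_ensemble",
                            n_members = length(ensemble$members)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a Determiner ensemble bundle
#'
#' @param dir Directory written by [save_determiner_ensemble()].
#' @return A `determiner_ensemble`.
#' @export
load_determiner_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  members <- lapply(seq_len(man$n_members), function(i)
    load_determiner(file.path(dir, sprintf("member_%02d", i))))
  structure(list(members = members), class = "determiner_ensemble")
}
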