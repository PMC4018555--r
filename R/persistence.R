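# Portable text persistence for trained models: dense matrices as
# tab-separated decimal text (17 significant digits, so doubles round-trip
# bitwise) plus a JSON metadata document.

write_matrix_txt <- function(m, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t")),
             con, useBytes = TRUE)
  invisible(path)
}

read_matrix_txt <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}

#' Save a trained model as a portable text archive
#'
#' Writes a directory containing the weight matrices as tab-separated decimal
#' text and a `metadata.json` with the configuration, lexicon and coding
#' geometry. The archive round-trips bitwise: [read_esn_model()] restores an
#' object whose numeric content is identical to the saved one.
#'
#' @param model A `comprehension_model` or `production_model`.
#' @param path Directory to create (must not already contain a model).
#' @export
write_esn_model <- function(model, path) {
  type <- if (inherits(model, "comprehension_model")) "comprehension"
          else if (inherits(model, "production_model")) "production"
          else stop("not a trained model")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    type = type,
    config = unclass(model$config),
    lexicon = list(words = model$lexicon$words, sw_symbol = model$lexicon$sw_symbol),
    n_pairs = model$n_pairs
  )
  if (type == "comprehension") {
    meta$max_len <- model$max_len
    meta$pause_len <- model$pause_len
  } else {
    meta$word_len <- model$word_len
    meta$gap_len <- model$gap_len
    meta$min_run <- model$min_run
    meta$T_max <- model$T_max
  }
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_matrix_txt(model$weights$w_in, file.path(path, "w_in.tsv"))
  write_matrix_txt(model$weights$w_res, file.path(path, "w_res.tsv"))
  write_matrix_txt(model$readout$w_out, file.path(path, "w_out.tsv"))
  invisible(path)
}

#' Load a model saved by [write_esn_model()]
#'
#' @param path Archive directory.
#' @return The restored `comprehension_model` or `production_model`.
#' @export
read_esn_model <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) stop(sprintf("no model archive at %s", path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cfg <- meta$config
  config <- reservoir_config(
    n_units = cfg$n_units, leak_rate = cfg$leak_rate,
    spectral_radius = cfg$spectral_radius, input_scaling = cfg$input_scaling,
    input_dim = cfg$input_dim, output_dim = cfg$output_dim, seed = cfg$seed,
    ridge = cfg$ridge, threshold = cfg$threshold, win_dist = cfg$win_dist
  )
  weights <- structure(
    list(w_in = read_matrix_txt(file.path(path, "w_in.tsv")),
         w_res = read_matrix_txt(file.path(path, "w_res.tsv"))),
    class = "reservoir_weights"
  )
  readout <- structure(
    list(w_out = read_matrix_txt(file.path(path, "w_out.tsv"))),
    class = "readout_weights"
  )
  lex <- lexicon(meta$lexicon$words, meta$lexicon$sw_symbol)
  if (meta$type == "comprehension") {
    structure(
      list(config = config, weights = weights, readout = readout, lexicon = lex,
           max_len = as.integer(meta$max_len),
           pause_len = as.integer(meta$pause_len),
           n_pairs = as.integer(meta$n_pairs), call = NULL),
      class = "comprehension_model"
    )
  } else {
    structure(
      list(config = config, weights = weights, readout = readout, lexicon = lex,
           word_len = as.integer(meta$word_len), gap_len = as.integer(meta$gap_len),
           min_run = as.integer(meta$min_run), T_max = as.integer(meta$T_max),
           n_pairs = as.integer(meta$n_pairs), call = NULL),
      class = "production_model"
    )
  }
}
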