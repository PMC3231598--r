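#' Full-precision CSV round trip for pipeline tables
#'
#' Numeric columns are serialised with 17 significant digits (`%.17g`), so
#' `read_et_csv(write_et_csv(x))` reproduces every double bit-for-bit;
#' decimal points are always `.` regardless of locale.
#'
#' @param x data frame.
#' @param path file path.
#' @return `write_et_csv` returns `path` invisibly; `read_et_csv` the data
#'   frame.
#' @export
write_et_csv <- function(x, path) {
  y <- x
  for (j in seq_along(y))
    if (is.numeric(y[[j]])) y[[j]] <- sprintf("%.17g", y[[j]])
  utils::write.csv(y, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_et_csv
#' @export
read_et_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  out
}

#' Serialise / restore a fitted inverse model (JSON)
#'
#' Stores layer sizes, transfer names, the weight vector and the
#' input/output scaling maps; `read_et_model()` rebuilds an `et_model` that
#' reproduces the original's predictions to full numerical precision
#' (training data and per-epoch history are not stored).
#'
#' @param model an `et_model`.
#' @param path file path.
#' @export
write_et_model <- function(model, path) {
  obj <- list(
    package = "etongue", format = 1L,
    layer_sizes = c(model$n_inputs, model$hidden, model$n_outputs),
    hidden_transfer = model$transfer, output_transfer = "purelin",
    theta = model$theta,
    input_names = model$input_names, ions = model$ions,
    input_scaling = model$input_scaling,
    output_scaling = model$output_scaling,
    log_outputs = model$log_outputs,
    alpha = model$alpha, beta = model$beta, gamma = model$gamma,
    seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_et_model
#' @export
read_et_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- obj$layer_sizes
  structure(list(theta = obj$theta, hidden = sizes[2],
                 transfer = obj$hidden_transfer,
                 n_inputs = sizes[1], n_outputs = sizes[3],
                 input_names = obj$input_names, ions = obj$ions,
                 input_scaling = lapply(obj$input_scaling, as.numeric),
                 output_scaling = lapply(obj$output_scaling, as.numeric),
                 log_outputs = isTRUE(obj$log_outputs),
                 alpha = obj$alpha, beta = obj$beta, gamma = obj$gamma,
                 seed = obj$seed, x = NULL, y = NULL,
                 restarts = NULL, history = NULL,
                 control = NULL, status = "restored", epochs = NA_integer_,
                 E_D = NA_real_, E_W = NA_real_, F = NA_real_),
            class = "et_model")
}
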