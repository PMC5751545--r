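# shared argument checks and error classes

stop_input <- function(msg) abort(msg, class = "ncproj_error_input")
stop_parse <- function(msg) abort(msg, class = "ncproj_error_parse")
stop_contract <- function(msg) abort(msg, class = "ncproj_error_contract")
stop_degenerate <- function(msg) abort(msg, class = "ncproj_error_degenerate")

check_scalar_number <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_contract(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop_contract(sprintf("`%s` must be strictly positive", name))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_contract(sprintf("`%s` must be a whole number", name))
  }
  invisible(x)
}

check_binary_matrix <- function(A, name = "A") {
  if (!is.matrix(A) || !is.numeric(A)) {
    stop_contract(sprintf("`%s` must be a numeric matrix", name))
  }
  if (nrow(A) < 1L || ncol(A) < 1L) {
    stop_contract(sprintf("`%s` must have at least one row and one column", name))
  }
  if (anyNA(A) || !all(A == 0 | A == 1)) {
    stop_contract(sprintf("every entry of `%s` must be exactly 0 or 1", name))
  }
  invisible(A)
}

# write a file atomically: stage in the same directory, then rename
write_atomic <- function(lines_or_fun, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  if (is.function(lines_or_fun)) {
    lines_or_fun(tmp)
  } else {
    writeLines(lines_or_fun, tmp)
  }
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
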