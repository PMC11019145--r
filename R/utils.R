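#' @keywords internal
"_PACKAGE"

# internal validation helpers ------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a single number in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop_field(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

# sample SD (n-1 convention) used throughout; NA-tolerant for phenotypes
col_center_scale <- function(x) {
  cn <- colMeans(x, na.rm = TRUE)
  xc <- sweep(x, 2L, cn, "-")
  nobs <- colSums(!is.na(x))
  sds <- sqrt(colSums(xc^2, na.rm = TRUE) / pmax(nobs - 1L, 1L))
  list(z = sweep(xc, 2L, sds, "/"), center = cn, scale = sds)
}
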