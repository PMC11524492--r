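# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# configuration-field validators: errors must name the offending field
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_number(x) || x < lower || x > upper)
    stop(sprintf("invalid configuration field '%s': must be a number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

check_prob <- function(x, name) check_number(x, name, 0, 1)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("invalid configuration field '%s': must be TRUE or FALSE", name),
         call. = FALSE)
  invisible(x)
}

check_sd_list <- function(x, name, keys) {
  if (!is.list(x) || !all(keys %in% names(x)))
    stop(sprintf("invalid configuration field '%s': must be a named list with entries %s",
                 name, paste(keys, collapse = ", ")), call. = FALSE)
  for (k in keys) check_number(x[[k]], paste0(name, "$", k), lower = 0)
  invisible(x)
}

as_one_row <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single record (one-row data frame)")
    as.list(x)
  } else if (is.list(x)) x
  else stop("expected a list or one-row data frame")
}

# deterministic provenance hash (polynomial hash of the serialized object,
# mod 2^31 - 1); not cryptographic, used only to stamp output artifacts
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
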