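#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop_if_not_scalar_num <- function(x, name, lo = -Inf, hi = Inf,
                                   integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (x < lo || x > hi)
    stop(sprintf("'%s' must be in [%s, %s]", name, format(lo), format(hi)),
         call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

## Derive a per-stage seed from a global seed without coupling stages.
## Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.numeric(seed)) * 1009 + offs) %% 2147483629)
}

## CSV writer used by the pipeline: header comment lines carry seed/config hash
## so outputs are self-describing; read back with read_header_csv().
write_header_csv <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_header_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

## Shoelace area of a closed polygon given vertex coordinates.
polygon_area <- function(x, y) {
  n <- length(x)
  i2 <- c(2:n, 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

polyline_length <- function(x, y, closed = TRUE) {
  if (closed) { x <- c(x, x[1L]); y <- c(y, y[1L]) }
  sum(sqrt(diff(x)^2 + diff(y)^2))
}
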