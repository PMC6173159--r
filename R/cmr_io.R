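## MARK-style ".inp" encounter-history files.
##
## Dialect: one record per line, `HISTORY freq [cov1 cov2 ...] ;` with
## optional `/* ... */` comments. A leading header comment written by
## write_inp() records the schedule and covariate column names so files
## round-trip exactly.

#' Write encounter histories to a MARK-style .inp file
#'
#' @param eh An `encounter_histories` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(eh, path) {
  stopifnot(inherits(eh, "encounter_histories"))
  covs <- eh$covariates
  if (!is.null(eh$group))
    covs <- cbind(data.frame(group = as.integer(eh$group)), covs)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("/* schedule %d x %d ; covariates: %s */",
                     eh$schedule$n_primary, eh$schedule$n_secondary,
                     if (is.null(covs) || !ncol(covs)) "-" else
                       paste(names(covs), collapse = ",")), con)
  hist_str <- apply(eh$histories, 1L, paste, collapse = "")
  cov_str <- if (is.null(covs) || !ncol(covs)) "" else
    apply(covs, 1L, function(r) paste0(" ", paste(format(r, trim = TRUE,
                                                         digits = 15),
                                                  collapse = " ")))
  writeLines(paste0(hist_str, " ", eh$freq, cov_str, ";"), con)
  invisible(path)
}

#' Read encounter histories from a MARK-style .inp file
#'
#' Parses history strings, frequencies and trailing numeric covariate
#' columns; `/* ... */` comments are ignored. A covariate column named
#' `group` (as written by [write_inp()]) is restored as the group factor.
#'
#' @param path Input path.
#' @param schedule A [survey_schedule()]; history lengths are validated
#'   against it. If NULL, a schedule header comment written by
#'   [write_inp()] is required.
#' @return An `encounter_histories` object.
#' @export
read_inp <- function(path, schedule = NULL) {
  raw <- readLines(path, warn = FALSE)
  txt <- paste(raw, collapse = "\n")
  ## recover schedule/covariate names from the header comment, if present
  hdr <- regmatches(txt, regexpr("/\\* schedule \\d+ x \\d+ ; covariates: [^*]* \\*/", txt))
  cov_names <- NULL
  if (length(hdr) == 1L) {
    nums <- as.integer(regmatches(hdr, gregexpr("\\d+", hdr))[[1L]][1:2])
    if (is.null(schedule)) schedule <- survey_schedule(nums[1L], nums[2L])
    cn <- sub(".*covariates: ", "", sub(" \\*/", "", hdr))
    if (cn != "-") cov_names <- strsplit(cn, ",")[[1L]]
  }
  if (is.null(schedule))
    stop("no schedule given and none recorded in the file header")
  txt <- gsub("/\\*([^*]|\\*[^/])*\\*/", " ", txt)  # strip comments
  lines <- strsplit(txt, "\n")[[1L]]
  recs <- list(); li <- 0L
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "") next
    if (!grepl(";\\s*$", s))
      stop(sprintf("line %d: record does not end with ';'", ln))
    s <- sub(";\\s*$", "", s)
    parts <- strsplit(trimws(s), "\\s+")[[1L]]
    hstr <- parts[1L]
    if (!grepl("^[01]+$", hstr))
      stop(sprintf("line %d: non-binary characters in history '%s'", ln, hstr))
    if (nchar(hstr) != schedule$n_events)
      stop(sprintf("line %d: history length %d does not match schedule (%d events)",
                   ln, nchar(hstr), schedule$n_events))
    if (length(parts) < 2L)
      stop(sprintf("line %d: missing frequency", ln))
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (any(is.na(vals)))
      stop(sprintf("line %d: non-numeric frequency or covariate", ln))
    if (vals[1L] == 0 || vals[1L] != round(vals[1L]))
      stop(sprintf("line %d: frequency must be a non-zero integer", ln))
    li <- li + 1L
    recs[[li]] <- list(h = as.integer(strsplit(hstr, "")[[1L]]),
                       freq = as.integer(vals[1L]), covs = vals[-1L])
  }
  if (li == 0L) stop("no records found")
  hist <- do.call(rbind, lapply(recs, `[[`, "h"))
  freq <- vapply(recs, `[[`, integer(1), "freq")
  ncov <- length(recs[[1L]]$covs)
  if (any(vapply(recs, function(r) length(r$covs), integer(1)) != ncov))
    stop("inconsistent number of covariate columns across records")
  covs <- NULL; group <- NULL
  if (ncov > 0L) {
    covs <- as.data.frame(do.call(rbind, lapply(recs, `[[`, "covs")))
    names(covs) <- if (!is.null(cov_names) && length(cov_names) == ncov)
      cov_names else sprintf("cov%d", seq_len(ncov))
    if ("group" %in% names(covs)) {
      group <- factor(as.integer(covs$group))
      covs$group <- NULL
    }
  }
  first_ev <- apply(hist, 1L, function(x) which.max(x == 1L))
  if (any(hist[cbind(seq_len(nrow(hist)), first_ev)] != 1L))
    stop("all-zero encounter history found")
  K <- schedule$n_secondary
  structure(list(histories = hist, schedule = schedule,
                 first_primary = (first_ev - 1L) %/% K + 1L,
                 first_event = first_ev,
                 group = group,
                 covariates = if (!is.null(covs) && ncol(covs)) covs else
                   data.frame(row.names = seq_len(nrow(hist))),
                 freq = freq, truth = NULL),
            class = "encounter_histories")
}
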