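#' Construct a run parameter set
#'
#' Bundles the tunables of an enrichment run. Defaults are the reference
#' configuration this method is normally run with:
#'
#' * `sample_times = 1000` — number of random-sampling iterations used to
#'   build each term's empirical null distribution.
#' * `cutoff = 4` — minimum co-occurrence frequency in Group A for a term to
#'   be tested and reported (equivalently "frequency > 3").
#' * `alpha = 0.05` — threshold on the Benjamini-Hochberg adjusted p-value;
#'   significance requires `p_adjusted < alpha` (strict).
#' * `z_threshold = 1.645` — the one-sided standard-normal critical value
#'   corresponding to `alpha`; carried for reporting, the decision itself
#'   uses the adjusted p-value.
#' * `seed = 0` — RNG seed; fixing it makes the sampling step, and hence the
#'   whole result table, reproducible.
#' * `sample_size` — records drawn per iteration; `NULL` means "use the
#'   Group A size", which matches the frequency being tested against the
#'   null on the same scale.
#'
#' @param sample_times positive integer, at least 2 (a standard deviation
#'   must be estimable).
#' @param cutoff positive integer.
#' @param alpha significance level in (0, 1).
#' @param z_threshold reference critical value (reporting only).
#' @param end_date search cutoff date, `Date` or `YYYY/MM/DD`, or `NULL`.
#' @param seed integer RNG seed.
#' @param sample_size optional positive integer override for the per-iteration
#'   sample size.
#' @return a `parameter_set` object.
#' @export
parameter_set <- function(sample_times = 1000, cutoff = 4, alpha = 0.05,
                          z_threshold = 1.645, end_date = NULL, seed = 0,
                          sample_size = NULL) {
  sample_times <- as.integer(sample_times)
  cutoff <- as.integer(cutoff)
  if (is.na(sample_times) || sample_times < 1) {
    abort("`sample_times` must be a positive integer")
  }
  if (is.na(cutoff) || cutoff < 1) {
    abort("`cutoff` must be a positive integer")
  }
  if (!is.numeric(alpha) || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1")
  }
  if (!is.null(end_date)) {
    end_date <- as_end_date(end_date)
  }
  if (!is.null(sample_size)) {
    sample_size <- as.integer(sample_size)
    if (is.na(sample_size) || sample_size < 1) {
      abort("`sample_size` must be a positive integer")
    }
  }
  structure(
    list(sample_times = sample_times, cutoff = cutoff, alpha = alpha,
         z_threshold = as.numeric(z_threshold), end_date = end_date,
         seed = as.integer(seed), sample_size = sample_size),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  sample_times: %d\n", x$sample_times))
  cat(sprintf("  cutoff:       %d\n", x$cutoff))
  cat(sprintf("  alpha:        %g\n", x$alpha))
  cat(sprintf("  z_threshold:  %g\n", x$z_threshold))
  cat(sprintf("  end_date:     %s\n",
              if (is.null(x$end_date)) "<none>" else format(x$end_date, "%Y/%m/%d")))
  cat(sprintf("  seed:         %d\n", x$seed))
  cat(sprintf("  sample_size:  %s\n",
              if (is.null(x$sample_size)) "|Group A|" else x$sample_size))
  invisible(x)
}

#' Load a parameter set from a key-value file
#'
#' Reads `key = value` lines (case-insensitive keys; `#` comments and blank
#' lines ignored). Recognised keys: `sample_times` (alias `sampletimes`),
#' `cutoff`, `p_value` (alias `pvalue`, mapped to `alpha`), `z_score` (alias
#' `zscore`, mapped to `z_threshold`), `end_date` (alias `enddate`), `seed`,
#' `sample_size` (alias `samplesize`). Missing keys take the defaults of
#' [parameter_set()]. `end_date` is required and must use the `YYYY/MM/DD`
#' format.
#'
#' @param path path to the parameter file.
#' @return a `parameter_set`.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("parameter file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  vals <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(sprintf("malformed parameter line %d: %s", i, trimws(lines[i])))
    }
    key <- tolower(gsub("[ _]", "", sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    parsed <- switch(key,
      sampletimes = parse_num_param(val, i),
      cutoff = parse_num_param(val, i),
      pvalue = parse_num_param(val, i),
      zscore = parse_num_param(val, i),
      seed = parse_num_param(val, i),
      samplesize = parse_num_param(val, i),
      enddate = val,
      abort(sprintf("unknown parameter '%s' on line %d", key, i))
    )
    name <- switch(key,
      sampletimes = "sample_times", pvalue = "alpha", zscore = "z_threshold",
      enddate = "end_date", samplesize = "sample_size", key
    )
    vals[[name]] <- parsed
  }
  if (is.null(vals$end_date)) {
    abort("parameter file must set end_date (format YYYY/MM/DD)")
  }
  if (!grepl("^\\d{4}/\\d{2}/\\d{2}$", vals$end_date)) {
    abort(sprintf(
      "end_date '%s' is invalid: the end date must be in the format of YYYY/MM/DD",
      vals$end_date
    ))
  }
  do.call(parameter_set, modifyList(
    list(sample_times = 1000, cutoff = 4, alpha = 0.05,
         z_threshold = 1.645, seed = 0),
    vals
  ))
}

parse_num_param <- function(val, line) {
  x <- suppressWarnings(as.numeric(val))
  if (is.na(x)) {
    abort(sprintf("malformed numeric value '%s' on parameter line %d", val, line))
  }
  x
}
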