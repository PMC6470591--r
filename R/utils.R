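#' @importFrom rlang %||% abort warn
#' @importFrom stats pnorm p.adjust sd
#' @importFrom utils head read.delim write.table
NULL

# Run code under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

MONTH_ABBR <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

#' Parse a publication date as recorded in a MEDLINE DP field
#'
#' Accepts `YYYY`, `YYYY Mon`, `YYYY Mon DD`, `YYYY/MM/DD` and `YYYY-MM-DD`.
#' Partial dates are completed to their earliest instant (missing month and
#' day become January 1), so a year-only record sorts before any fully dated
#' record of the same year.
#'
#' @param x character vector of raw date strings.
#' @return a `Date` vector; `NA` where the string could not be interpreted.
#' @keywords internal
parse_pub_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  x <- trimws(as.character(x))
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s) || !nzchar(s)) next
    if (grepl("^\\d{4}[/-]\\d{1,2}[/-]\\d{1,2}$", s)) {
      parts <- as.integer(strsplit(s, "[/-]")[[1]])
      out[i] <- make_date_safe(parts[1], parts[2], parts[3])
      next
    }
    toks <- strsplit(s, "\\s+")[[1]]
    if (!grepl("^\\d{4}$", toks[1])) next
    year <- as.integer(toks[1])
    month <- 1L
    day <- 1L
    if (length(toks) >= 2) {
      m <- match(substr(toks[2], 1, 3), MONTH_ABBR)
      if (is.na(m)) next
      month <- m
      if (length(toks) >= 3) {
        if (!grepl("^\\d{1,2}$", toks[3])) next
        day <- as.integer(toks[3])
      }
    }
    out[i] <- make_date_safe(year, month, day)
  }
  out
}

make_date_safe <- function(year, month, day) {
  d <- suppressWarnings(as.Date(sprintf("%04d-%02d-%02d", year, month, day)))
  d
}

# Coerce a user-supplied end date ("YYYY/MM/DD" or Date) to Date, or fail.
as_end_date <- function(end_date) {
  if (inherits(end_date, "Date")) {
    return(end_date)
  }
  if (is.character(end_date) && length(end_date) == 1 &&
      grepl("^\\d{4}/\\d{2}/\\d{2}$", end_date)) {
    d <- suppressWarnings(as.Date(end_date, format = "%Y/%m/%d"))
    if (!is.na(d)) return(d)
  }
  abort(paste0(
    "`end_date` must be a Date or a string in the format YYYY/MM/DD, got: ",
    deparse(substitute(end_date))
  ))
}
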