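#' Retrieve MEDLINE records for a drug from PubMed
#'
#' Optional live-retrieval interface. The actual HTTP exchange is delegated
#' to a `transport` function so that the operation can run against NCBI
#' E-utilities when a network is available, or against a canned body in
#' tests and offline batch runs. The default transport performs a real
#' esearch + efetch (`rettype=medline`) round trip; pass
#' `offline_transport()` (or run with `transport = NULL`) to make the
#' operation fail fast with a clear message instead.
#'
#' @param drug query drug name (non-empty).
#' @param end_date search cutoff, `Date` or `YYYY/MM/DD` string; forwarded to
#'   the transport as the `maxdate` of the date range.
#' @param transport function `(term, maxdate)` returning MEDLINE text, or
#'   `NULL` for offline mode.
#' @param api_key optional NCBI API key, forwarded to the default transport.
#' @return MEDLINE text (character vector of lines); empty with a warning
#'   when the query has no hits.
#' @export
fetch_pubmed <- function(drug, end_date, transport = NULL, api_key = NULL) {
  if (!is.character(drug) || length(drug) != 1 || !nzchar(drug)) {
    abort("`drug` must be a non-empty string")
  }
  end_date <- as_end_date(end_date)
  if (is.null(transport)) {
    abort(paste0(
      "PubMed retrieval is unavailable offline. Supply a `transport` ",
      "function (see `pubmed_http_transport()`) or use a local MEDLINE file."
    ))
  }
  txt <- transport(drug, format(end_date, "%Y/%m/%d"))
  if (length(txt) == 0 || all(!nzchar(trimws(txt)))) {
    warn(sprintf("PubMed query for '%s' returned no records", drug))
    return(character(0))
  }
  txt
}

#' HTTP transport for NCBI E-utilities
#'
#' Returns a transport function for [fetch_pubmed()] that runs
#' `esearch.fcgi` (history server) followed by `efetch.fcgi` with
#' `rettype=medline`, restricted to publication dates up to `maxdate`.
#' Requires network access; a failed exchange raises a retryable error.
#'
#' @param api_key optional NCBI API key appended to both requests.
#' @param base_url E-utilities endpoint base.
#' @return a function `(term, maxdate)` returning MEDLINE text lines.
#' @export
pubmed_http_transport <- function(api_key = NULL,
                                  base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils") {
  force(api_key)
  force(base_url)
  function(term, maxdate) {
    key <- if (is.null(api_key)) "" else paste0("&api_key=", api_key)
    search_url <- paste0(
      base_url, "/esearch.fcgi?db=pubmed&usehistory=y",
      "&term=", utils::URLencode(term, reserved = TRUE),
      "&datetype=pdat&mindate=1900/01/01&maxdate=",
      utils::URLencode(maxdate, reserved = TRUE), key
    )
    search_xml <- tryCatch(
      readLines(search_url, warn = FALSE),
      error = function(e) abort(paste0(
        "PubMed esearch failed (retry later): ", conditionMessage(e)
      ))
    )
    xml <- paste(search_xml, collapse = "")
    web <- sub(".*<WebEnv>([^<]*)</WebEnv>.*", "\\1", xml)
    qk <- sub(".*<QueryKey>([^<]*)</QueryKey>.*", "\\1", xml)
    count <- suppressWarnings(as.integer(sub(".*<Count>([0-9]+)</Count>.*", "\\1", xml)))
    if (is.na(count) || count == 0) {
      return(character(0))
    }
    fetch_url <- paste0(
      base_url, "/efetch.fcgi?db=pubmed&rettype=medline&retmode=text",
      "&WebEnv=", utils::URLencode(web, reserved = TRUE),
      "&query_key=", qk, key
    )
    tryCatch(
      readLines(fetch_url, warn = FALSE),
      error = function(e) abort(paste0(
        "PubMed efetch failed (retry later): ", conditionMessage(e)
      ))
    )
  }
}
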