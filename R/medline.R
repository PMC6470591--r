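#' Parse MEDLINE flat-format records into a tibble
#'
#' Reads the tag-value flat format used by PubMed's `rettype=medline` export:
#' each record is a block of `TAG - value` lines separated by a blank line,
#' with continuation lines indented. Only the fields this package analyses
#' are kept: `PMID`, `TI` (title), `JT` (journal), `DP` (publication date),
#' `MH` (MeSH headings) and the substance fields `RN` / `NM`. An `RN` value
#' has the form `registry-number (Substance Name)`; the registry number is
#' discarded and only the name retained. `NM` values are substance names as
#' written. Substance names are trimmed and de-duplicated within a record.
#'
#' Records lacking a `PMID` are rejected; their positions are reported in a
#' single warning and parsing continues.
#'
#' @param text MEDLINE content: a single string, a character vector of lines,
#'   or a connection.
#' @return a tibble with one row per record and columns `pmid`, `title`,
#'   `journal`, `pub_date` (`Date`; partial dates completed to their earliest
#'   instant, `NA` if unparseable), `pub_date_raw` (the `DP` string as seen),
#'   and list-columns `mesh_headings` and `substances`.
#' @examples
#' txt <- c(
#'   "PMID- 100", "TI  - A simvastatin interaction case",
#'   "DP  - 2014 Mar 10", "MH  - Drug Interactions",
#'   "RN  - 0 (Cyclosporine)", "NM  - Cytochrome P-450 CYP3A"
#' )
#' parse_medline(txt)
#' @seealso [write_medline()], [read_medline()]
#' @export
parse_medline <- function(text) {
  lines <- medline_lines(text)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    return(empty_records())
  }
  blank <- !nzchar(trimws(lines))
  block_id <- cumsum(c(TRUE, blank[-length(blank)])) # runs split at blanks
  blocks <- split(lines[!blank], block_id[!blank])
  blocks <- blocks[vapply(blocks, length, 1L) > 0]

  rows <- vector("list", length(blocks))
  rejected <- integer(0)
  for (k in seq_along(blocks)) {
    rec <- parse_medline_block(blocks[[k]])
    if (is.null(rec$pmid) || !nzchar(rec$pmid)) {
      rejected <- c(rejected, k)
    } else {
      rows[[k]] <- rec
    }
  }
  if (length(rejected) > 0) {
    warn(sprintf(
      "Rejected %d MEDLINE record(s) without a PMID (block %s)",
      length(rejected), paste(rejected, collapse = ", ")
    ))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(empty_records())
  }
  tibble::tibble(
    pmid = vapply(rows, function(r) r$pmid, ""),
    title = vapply(rows, function(r) r$title %||% NA_character_, ""),
    journal = vapply(rows, function(r) r$journal %||% NA_character_, ""),
    pub_date_raw = vapply(rows, function(r) r$dp %||% NA_character_, ""),
    pub_date = parse_pub_date(vapply(rows, function(r) r$dp %||% NA_character_, "")),
    mesh_headings = lapply(rows, function(r) r$mesh),
    substances = lapply(rows, function(r) r$substances)
  )
}

#' Read a MEDLINE file
#'
#' @param path path to a MEDLINE flat-format text file.
#' @return a records tibble; see [parse_medline()].
#' @export
read_medline <- function(path) {
  parse_medline(readLines(path, warn = FALSE))
}

medline_lines <- function(text) {
  if (inherits(text, "connection")) {
    return(readLines(text, warn = FALSE))
  }
  if (!is.character(text)) {
    abort("MEDLINE input must be a character vector or connection")
  }
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    return(strsplit(text, "\n", fixed = TRUE)[[1]])
  }
  text
}

# One block of non-blank lines -> named list of fields.
parse_medline_block <- function(lines) {
  # fold indented continuation lines into the previous tag line
  folded <- character(0)
  for (ln in lines) {
    if (grepl("^\\s", ln) && length(folded) > 0) {
      folded[length(folded)] <- paste(folded[length(folded)], trimws(ln))
    } else {
      folded <- c(folded, ln)
    }
  }
  tags <- toupper(trimws(substr(folded, 1, 4)))
  vals <- trimws(sub("^.{4}-\\s?", "", folded))
  keep <- grepl("^.{4}-", folded)
  tags <- tags[keep]
  vals <- vals[keep]

  substances <- character(0)
  for (i in which(tags == "RN")) {
    nm <- sub("^[^(]*\\(", "", vals[i])
    if (nm != vals[i] && grepl("\\)$", nm)) {
      substances <- c(substances, sub("\\)$", "", nm))
    }
    # bare registry numbers with no name carry no term and are dropped
  }
  substances <- c(substances, vals[tags == "NM"])
  substances <- unique(trimws(substances))
  substances <- substances[nzchar(substances)]

  list(
    pmid = if (any(tags == "PMID")) vals[which(tags == "PMID")[1]] else NULL,
    title = if (any(tags == "TI")) vals[which(tags == "TI")[1]] else NULL,
    journal = if (any(tags == "JT")) vals[which(tags == "JT")[1]] else NULL,
    dp = if (any(tags == "DP")) vals[which(tags == "DP")[1]] else NULL,
    mesh = vals[tags == "MH"],
    substances = substances
  )
}

empty_records <- function() {
  tibble::tibble(
    pmid = character(0), title = character(0), journal = character(0),
    pub_date_raw = character(0), pub_date = as.Date(character(0)),
    mesh_headings = list(), substances = list()
  )
}

#' Write records back to MEDLINE flat format
#'
#' Serialises a records tibble to the same tag-value dialect that
#' [parse_medline()] reads, so `parse_medline(write_medline(x))` reproduces
#' the content of `x` (the round-trip property the test suite asserts).
#' Substances are written as `RN  - 0 (Name)` lines; `0` is the conventional
#' placeholder registry number.
#'
#' @param records a records tibble (see [parse_medline()]).
#' @param path optional file path; if supplied the text is also written there.
#' @return invisibly, a character vector of MEDLINE lines.
#' @export
write_medline <- function(records, path = NULL) {
  validate_records(records)
  blocks <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    block <- sprintf("PMID- %s", records$pmid[i])
    if (!is.na(records$title[i])) {
      block <- c(block, sprintf("TI  - %s", records$title[i]))
    }
    if (!is.na(records$journal[i])) {
      block <- c(block, sprintf("JT  - %s", records$journal[i]))
    }
    dp <- records$pub_date_raw[i]
    if (is.na(dp) && !is.na(records$pub_date[i])) {
      dp <- format(records$pub_date[i], "%Y %b %d")
    }
    if (!is.na(dp)) {
      block <- c(block, sprintf("DP  - %s", dp))
    }
    blocks[[i]] <- c(
      block,
      sprintf("MH  - %s", records$mesh_headings[[i]]),
      sprintf("RN  - 0 (%s)", records$substances[[i]]),
      ""
    )
  }
  out <- unlist(blocks) %||% character(0)
  if (!is.null(path)) {
    writeLines(out, path)
  }
  invisible(out)
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("pmid", "mesh_headings", "substances")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("records tibble lacks column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- which(!nzchar(records$pmid) | is.na(records$pmid))
  if (length(bad) > 0) {
    abort(sprintf("record(s) at row %s have an empty PMID", paste(bad, collapse = ", ")))
  }
  for (i in seq_len(nrow(records))) {
    s <- trimws(records$substances[[i]])
    if (anyDuplicated(s) > 0) {
      abort(sprintf("record %s lists duplicate substances", records$pmid[i]))
    }
  }
  invisible(records)
}

#' Keep records published on or before a cutoff date
#'
#' Models the end-date bound of a literature search: records dated after
#' `end_date` are dropped, the bound itself is inclusive, and record order is
#' preserved. A record whose stored date could not be interpreted is retained
#' with a warning — the filter is a search cutoff, not a validity check.
#' Partial dates compare at their earliest completion (a bare year counts as
#' January 1 of that year).
#'
#' @param records a records tibble.
#' @param end_date a `Date` or a `YYYY/MM/DD` string.
#' @return the filtered records tibble.
#' @export
filter_by_end_date <- function(records, end_date) {
  end_date <- as_end_date(end_date)
  undated <- is.na(records$pub_date)
  if (any(undated)) {
    warn(sprintf(
      "%d record(s) have no interpretable publication date; retained",
      sum(undated)
    ))
  }
  records[undated | records$pub_date <= end_date, , drop = FALSE]
}

#' Default interaction-article classifier
#'
#' Classifies a record as interaction-related when its MeSH headings contain
#' the descriptor "Drug Interactions" (case-insensitive; subheading
#' qualifiers after `/` and the major-topic `*` marker are ignored). PubMed
#' indexers attach this descriptor to articles reporting drug-drug
#' interactions, making it the interaction signal available inside the
#' record itself.
#'
#' @return a function mapping a records tibble to a logical vector.
#' @export
mesh_ddi_predicate <- function() {
  function(records) {
    vapply(records$mesh_headings, function(mh) {
      if (length(mh) == 0) return(FALSE)
      desc <- tolower(trimws(sub("/.*$", "", sub("^\\*", "", mh))))
      any(desc == "drug interactions")
    }, TRUE)
  }
}

#' Split records into interaction (Group A) and background (Group B) sets
#'
#' Partitions the retrieved records for one query drug into the
#' interaction-indexed articles (Group A) whose substance co-occurrences are
#' tested, and the background articles (Group B) from which the empirical
#' null distribution is sampled. The classifier is injectable; the default is
#' [mesh_ddi_predicate()]. Both groups must be non-empty: without Group A
#' there is nothing to test, and without Group B no null distribution can be
#' built.
#'
#' @param records a records tibble (non-empty).
#' @param drug the query drug name.
#' @param ddi_predicate function from a records tibble to a logical vector.
#' @return a `grouped_corpus`: list with elements `drug`, `group_a`,
#'   `group_b`.
#' @export
split_groups <- function(records, drug, ddi_predicate = mesh_ddi_predicate()) {
  if (nrow(records) == 0) {
    abort("no records to split")
  }
  is_a <- ddi_predicate(records)
  if (anyNA(is_a) || !is.logical(is_a) || length(is_a) != nrow(records)) {
    abort("ddi_predicate must return one non-NA logical per record")
  }
  if (!any(is_a)) {
    abort(sprintf("no DDI-related articles for drug '%s' (Group A empty)", drug))
  }
  if (all(is_a)) {
    abort(sprintf(
      "all articles for drug '%s' are DDI-related (Group B empty; null distribution impossible)",
      drug
    ))
  }
  out <- structure(
    list(drug = drug, group_a = records[is_a, , drop = FALSE],
         group_b = records[!is_a, , drop = FALSE]),
    class = "grouped_corpus"
  )
  out
}

#' @export
print.grouped_corpus <- function(x, ...) {
  cat(sprintf(
    "<grouped_corpus> drug: %s | Group A (DDI): %d records | Group B: %d records\n",
    x$drug, nrow(x$group_a), nrow(x$group_b)
  ))
  invisible(x)
}
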