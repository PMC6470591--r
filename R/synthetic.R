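#' Specify a synthetic two-group literature corpus
#'
#' Describes a corpus of MEDLINE-style records for one query drug: `n_a`
#' interaction-indexed records (carrying the MeSH descriptor
#' "Drug Interactions") and `n_b` background records. Every record lists the
#' query drug as a substance; each catalogue term is additionally included
#' in each record independently, with probability `p_a` in Group A records
#' and `p_b` in Group B records. Setting `p_a > p_b` plants a true
#' enrichment; `p_a = p_b` gives a null term. This per-record independent
#' inclusion is exactly the data-generating structure under which a
#' binomial sampling null is well-founded, which is what makes the
#' generator usable as a calibration oracle for the whole pipeline.
#'
#' @param drug query drug name.
#' @param n_a,n_b record counts for Group A and Group B (non-negative).
#' @param term_catalog data frame with columns `term`, `p_a`, `p_b`
#'   (probabilities in \[0, 1\]).
#' @param date_range length-2 `Date` (or `YYYY/MM/DD` string) vector;
#'   publication dates are drawn uniformly from this range.
#' @param seed integer RNG seed; the generated corpus is a deterministic
#'   function of the spec.
#' @return a `corpus_spec` object.
#' @export
corpus_spec <- function(drug, n_a, n_b, term_catalog,
                        date_range = c("2005/01/01", "2015/12/31"), seed = 0) {
  stopifnot(is.data.frame(term_catalog),
            all(c("term", "p_a", "p_b") %in% names(term_catalog)))
  if (n_a < 0 || n_b < 0) abort("`n_a` and `n_b` must be non-negative")
  probs <- c(term_catalog$p_a, term_catalog$p_b)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    abort("all inclusion probabilities must lie in [0, 1]")
  }
  if (anyDuplicated(term_catalog$term) > 0) {
    abort("term_catalog terms must be unique")
  }
  date_range <- vapply(date_range, function(d) as.character(as_end_date(d)), "")
  structure(
    list(drug = drug, n_a = as.integer(n_a), n_b = as.integer(n_b),
         term_catalog = tibble::as_tibble(term_catalog),
         date_range = as.Date(date_range), seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' Generate a synthetic corpus with a known truth table
#'
#' Realises a [corpus_spec()]: emits the records (as a parsed tibble and as
#' MEDLINE flat-format text) together with a truth table recording, per
#' catalogue term, the nominal probabilities, the realised per-group
#' prevalences, and whether an enrichment was planted (`p_a > p_b`). The
#' truth table is what tests compare pipeline output against, so it is
#' produced here rather than re-derived downstream.
#'
#' @param spec a `corpus_spec`.
#' @return a list with elements `records` (tibble as from [parse_medline()]),
#'   `medline` (character lines), and `truth` (tibble with columns `term`,
#'   `p_a`, `p_b`, `prevalence_a`, `prevalence_b`, `count_a`, `count_b`,
#'   `enriched`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  n <- spec$n_a + spec$n_b
  terms <- spec$term_catalog$term
  k <- length(terms)

  if (n == 0) {
    truth <- tibble::tibble(
      term = terms, p_a = spec$term_catalog$p_a, p_b = spec$term_catalog$p_b,
      prevalence_a = rep(NA_real_, k), prevalence_b = rep(NA_real_, k),
      count_a = rep(0L, k), count_b = rep(0L, k),
      enriched = spec$term_catalog$p_a > spec$term_catalog$p_b
    )
    return(list(records = empty_records(), medline = character(0), truth = truth))
  }

  group <- rep(c("A", "B"), c(spec$n_a, spec$n_b))
  p <- matrix(rep(spec$term_catalog$p_b, each = n), nrow = n, ncol = k)
  if (spec$n_a > 0 && k > 0) {
    p[group == "A", ] <- matrix(rep(spec$term_catalog$p_a, each = spec$n_a),
                                nrow = spec$n_a, ncol = k)
  }
  with_seed(spec$seed, {
    present <- matrix(stats::runif(n * k) < p, nrow = n, ncol = k)
    span <- as.integer(spec$date_range[2] - spec$date_range[1])
    dates <- spec$date_range[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
  })

  substances <- lapply(seq_len(n), function(i) {
    c(spec$drug, terms[present[i, ]])
  })
  mesh <- lapply(group, function(g) {
    if (g == "A") c("Drug Interactions", "Humans") else "Humans"
  })
  records <- tibble::tibble(
    pmid = sprintf("SYN%06d", seq_len(n)),
    title = sprintf("Synthetic record %d for %s", seq_len(n), spec$drug),
    journal = "Synthetic Journal of Pharmacology",
    pub_date_raw = format(dates, "%Y %b %d"),
    pub_date = dates,
    mesh_headings = mesh,
    substances = substances
  )

  count_a <- if (spec$n_a > 0) colSums(present[group == "A", , drop = FALSE]) else rep(0L, k)
  count_b <- if (spec$n_b > 0) colSums(present[group == "B", , drop = FALSE]) else rep(0L, k)
  truth <- tibble::tibble(
    term = terms,
    p_a = spec$term_catalog$p_a,
    p_b = spec$term_catalog$p_b,
    prevalence_a = if (spec$n_a > 0) count_a / spec$n_a else NA_real_,
    prevalence_b = if (spec$n_b > 0) count_b / spec$n_b else NA_real_,
    count_a = as.integer(count_a),
    count_b = as.integer(count_b),
    enriched = spec$term_catalog$p_a > spec$term_catalog$p_b
  )
  list(records = records, medline = write_medline(records), truth = truth)
}

#' Write a truth table beside a corpus
#'
#' @param truth truth tibble from [generate_corpus()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Expected null moments for a generated term
#'
#' For draws of `n` records with replacement from Group B, a term present in
#' a realised fraction q of Group B has null counts distributed
#' Binomial(n, q), so the sampling null should concentrate on mean `n q` and
#' standard deviation `sqrt(n q (1 - q))`. Used as the analytic oracle in
#' sampling-calibration tests.
#'
#' @param corpus result of [generate_corpus()] (its `truth` table supplies
#'   the realised Group B prevalence).
#' @param term a catalogue term.
#' @param n per-iteration sample size.
#' @return a tibble with columns `mu`, `sigma`.
#' @export
expected_moments <- function(corpus, term, n) {
  truth <- corpus$truth
  i <- match(term, truth$term)
  if (is.na(i)) abort(sprintf("term '%s' is not in the corpus catalogue", term))
  q <- truth$prevalence_b[i]
  tibble::tibble(mu = n * q, sigma = sqrt(n * q * (1 - q)))
}
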