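#' Tabulate candidate substance terms from Group A
#'
#' A candidate term is any substance listed in at least one Group A
#' (interaction-indexed) record, other than the query drug itself. Its
#' frequency is the number of *distinct* Group A records listing it — a term
#' repeated within one record's substance field counts once. The query drug
#' is excluded by case-insensitive exact match: every retrieved record lists
#' it, so it carries no enrichment signal.
#'
#' @param group_a records tibble of the interaction group (non-empty).
#' @param drug query drug name to exclude.
#' @return a tibble with columns `term`, `frequency`, sorted by frequency
#'   descending then term.
#' @export
collect_candidates <- function(group_a, drug) {
  if (nrow(group_a) == 0) {
    abort("Group A is empty; no candidate terms to collect")
  }
  terms <- unlist(lapply(group_a$substances, function(s) unique(trimws(s))))
  terms <- terms[nzchar(terms)]
  terms <- terms[tolower(terms) != tolower(drug)]
  if (length(terms) == 0) {
    return(tibble::tibble(term = character(0), frequency = integer(0)))
  }
  tab <- table(terms)
  tibble::tibble(term = names(tab), frequency = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$term)
}

# records x terms presence matrix (0/1), with term column names.
term_membership <- function(records, terms) {
  m <- matrix(0L, nrow = nrow(records), ncol = length(terms),
              dimnames = list(NULL, terms))
  for (i in seq_len(nrow(records))) {
    hit <- match(unique(trimws(records$substances[[i]])), terms)
    hit <- hit[!is.na(hit)]
    if (length(hit) > 0) m[i, hit] <- 1L
  }
  m
}

#' Build the empirical null co-occurrence counts by random sampling
#'
#' For each of `sample_times` iterations, draws `n` records uniformly at
#' random *with replacement* from Group B (the background, non-interaction
#' articles) and counts, per candidate term, how many drawn records list it.
#' The resulting `sample_times x terms` matrix is the empirical null: under
#' no association, a term present in a fraction q of Group B yields counts
#' distributed Binomial(n, q).
#'
#' The draw sequence is a single seeded stream consuming exactly `n` values
#' per iteration, so a given `seed` always yields the identical matrix.
#'
#' @param candidates candidate table from [collect_candidates()] (only the
#'   `term` column is used).
#' @param group_b records tibble of the background group (non-empty).
#' @param n records drawn per iteration; conventionally the Group A size.
#' @param sample_times number of iterations.
#' @param seed integer RNG seed.
#' @return a `null_counts` object: list with `counts` (integer matrix,
#'   iterations x terms) and `n`.
#' @export
sample_null_counts <- function(candidates, group_b, n, sample_times, seed = 0) {
  if (nrow(group_b) == 0) abort("Group B is empty; cannot sample a null")
  n <- as.integer(n)
  sample_times <- as.integer(sample_times)
  if (n < 1) abort("`n` must be at least 1")
  if (sample_times < 1) abort("`sample_times` must be at least 1")
  terms <- candidates$term
  if (length(terms) == 0) {
    warn("empty candidate table; null counts matrix has no columns")
    return(structure(
      list(counts = matrix(0L, nrow = sample_times, ncol = 0), n = n),
      class = "null_counts"
    ))
  }
  m <- term_membership(group_b, terms)
  counts <- matrix(0L, nrow = sample_times, ncol = length(terms),
                   dimnames = list(NULL, terms))
  nb <- nrow(group_b)
  with_seed(seed, {
    for (i in seq_len(sample_times)) {
      idx <- sample.int(nb, n, replace = TRUE)
      counts[i, ] <- as.integer(colSums(m[idx, , drop = FALSE]))
    }
  })
  structure(list(counts = counts, n = n), class = "null_counts")
}

#' Summarise the empirical null per term
#'
#' Reduces the null-counts matrix to a per-term mean and sample standard
#' deviation (divisor `sample_times - 1`). At least two iterations are
#' required for the standard deviation to exist.
#'
#' @param null_counts a `null_counts` object (or a bare counts matrix).
#' @return a tibble with columns `term`, `null_mean`, `null_sd`.
#' @export
summarize_null <- function(null_counts) {
  counts <- if (inherits(null_counts, "null_counts")) null_counts$counts else null_counts
  if (nrow(counts) < 2) {
    abort("`sample_times` must be at least 2 to estimate a standard deviation")
  }
  tibble::tibble(
    term = colnames(counts) %||% character(0),
    null_mean = as.numeric(colMeans(counts)),
    null_sd = unname(apply(counts, 2, stats::sd))
  )
}

#' Z-score and one-sided p-value against the empirical null
#'
#' `z = (frequency - null_mean) / null_sd`, and the p-value is the
#' upper-tail standard-normal probability at `z` (one-sided: only
#' co-occurrence *above* the null is evidence of an interaction-related
#' term). When the null is degenerate (`null_sd = 0`) the normal
#' approximation collapses: the p-value is 0 if the observed frequency
#' exceeds the null mean (the term essentially never co-occurs by chance)
#' and 1 otherwise, with `z` reported as `Inf`, `-Inf` or 0 accordingly.
#'
#' @param frequency observed Group A frequency (vectorised).
#' @param null_mean,null_sd empirical null moments, recycled as usual.
#' @return a tibble with columns `z`, `p_raw`.
#' @export
compute_pvalues <- function(frequency, null_mean, null_sd) {
  if (any(null_sd < 0, na.rm = TRUE)) abort("`null_sd` must be non-negative")
  k <- max(length(frequency), length(null_mean), length(null_sd))
  frequency <- rep_len(frequency, k)
  null_mean <- rep_len(null_mean, k)
  null_sd <- rep_len(null_sd, k)
  z <- ifelse(null_sd > 0, (frequency - null_mean) / null_sd,
              ifelse(frequency > null_mean, Inf,
                     ifelse(frequency < null_mean, -Inf, 0)))
  p <- ifelse(null_sd > 0, stats::pnorm(z, lower.tail = FALSE),
              ifelse(frequency > null_mean, 0, 1))
  tibble::tibble(z = z, p_raw = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: adjusted p-values satisfy
#' `adj >= raw` elementwise and preserve the raw ranking. Returned in the
#' input order.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) abort("`p` must be non-empty")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("all p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Filter a term-statistics table to the significant terms
#'
#' Retains terms with `frequency >= cutoff` and `p_adjusted < alpha`
#' (strict), sorted by frequency descending, then raw p-value ascending,
#' then term, so the output order is deterministic.
#'
#' @param stats a tibble with at least `term`, `frequency`, `p_adjusted`
#'   (and optionally `p_raw`, used as a tie-break).
#' @param params a [parameter_set()] supplying `cutoff` and `alpha`.
#' @return the filtered, sorted tibble.
#' @export
filter_significant <- function(stats, params = parameter_set()) {
  stopifnot(inherits(params, "parameter_set"))
  keep <- stats$frequency >= params$cutoff & stats$p_adjusted < params$alpha
  out <- stats[keep, , drop = FALSE]
  p_tie <- if ("p_raw" %in% names(out)) out$p_raw else out$p_adjusted
  out[order(-out$frequency, p_tie, out$term), , drop = FALSE]
}

#' Run the full enrichment analysis on a grouped corpus
#'
#' The pipeline: collect candidate terms from Group A; drop terms below the
#' frequency cutoff (so the multiple-testing family contains only terms that
#' could be reported); build the empirical null by sampling
#' `params$sample_times` draws of `n` records from Group B (with
#' replacement, `n` defaulting to the Group A size); compute per-term
#' Z-scores and one-sided normal p-values; adjust across the tested terms by
#' Benjamini-Hochberg; flag significance at `p_adjusted < alpha`. The result
#' is deterministic for a fixed `params$seed`.
#'
#' @param corpus a `grouped_corpus` from [split_groups()].
#' @param params a [parameter_set()].
#' @return a `ddi_enrichment` object. Use [tidy()] for the per-term table
#'   (all tested terms, with a `significant` flag), [glance()] for a one-row
#'   run summary, and [filter_significant()] or `x$significant` for the
#'   reportable subset.
#' @examples
#' spec <- corpus_spec("simvastatin", n_a = 60, n_b = 200,
#'                     term_catalog = data.frame(term = c("Cyclosporine", "Filler"),
#'                                               p_a = c(0.5, 0.2), p_b = c(0.05, 0.2)),
#'                     seed = 1)
#' corpus <- generate_corpus(spec)
#' grouped <- split_groups(corpus$records, "simvastatin")
#' fit <- run_enrichment(grouped, parameter_set(sample_times = 200, seed = 1))
#' tidy(fit)
#' @export
run_enrichment <- function(corpus, params = parameter_set()) {
  stopifnot(inherits(corpus, "grouped_corpus"), inherits(params, "parameter_set"))
  candidates <- collect_candidates(corpus$group_a, corpus$drug)
  tested <- candidates[candidates$frequency >= params$cutoff, , drop = FALSE]
  n <- params$sample_size %||% nrow(corpus$group_a)

  if (nrow(tested) == 0) {
    stats <- tibble::tibble(
      term = character(0), frequency = integer(0), null_mean = numeric(0),
      null_sd = numeric(0), z = numeric(0), p_raw = numeric(0),
      p_adjusted = numeric(0), significant = logical(0)
    )
  } else {
    nulls <- sample_null_counts(tested, corpus$group_b, n = n,
                                sample_times = params$sample_times,
                                seed = params$seed)
    moments <- summarize_null(nulls)
    stats <- dplyr::left_join(tested, moments, by = "term")
    stats <- dplyr::bind_cols(
      stats, compute_pvalues(stats$frequency, stats$null_mean, stats$null_sd)
    )
    stats$p_adjusted <- adjust_bh(stats$p_raw)
    stats$significant <- stats$frequency >= params$cutoff &
      stats$p_adjusted < params$alpha
    stats <- stats[order(-stats$frequency, stats$p_raw, stats$term), , drop = FALSE]
  }

  structure(
    list(
      stats = stats,
      significant = filter_significant(stats, params),
      params = params,
      drug = corpus$drug,
      n_group_a = nrow(corpus$group_a),
      n_group_b = nrow(corpus$group_b),
      n_candidates = nrow(candidates),
      n_tested = nrow(tested),
      sample_size = n
    ),
    class = "ddi_enrichment"
  )
}

#' @export
print.ddi_enrichment <- function(x, ...) {
  cat(sprintf("<ddi_enrichment> drug: %s\n", x$drug))
  cat(sprintf("  Group A: %d records | Group B: %d records | sample size: %d\n",
              x$n_group_a, x$n_group_b, x$sample_size))
  cat(sprintf("  candidates: %d | tested (freq >= %d): %d | significant (adj p < %g): %d\n",
              x$n_candidates, x$params$cutoff, x$n_tested, x$params$alpha,
              nrow(x$significant)))
  if (nrow(x$significant) > 0) {
    print(utils::head(x$significant, 10))
  }
  invisible(x)
}
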