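#' Write an enrichment result table as TSV
#'
#' Columns: `term`, `frequency`, `null_mean`, `null_sd`, `z`, `p_raw`,
#' `p_adjusted`, `significant`; floating-point values are printed with six
#' significant digits. With a fixed seed the written file is byte-identical
#' across runs.
#'
#' @param stats per-term statistics tibble (as from `tidy()` on a
#'   `ddi_enrichment`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(stats, path) {
  out <- as.data.frame(stats)
  for (col in intersect(c("null_mean", "null_sd", "z", "p_raw", "p_adjusted"),
                        names(out))) {
    out[[col]] <- formatC(signif(out[[col]], 6), format = "g", digits = 6)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an enrichment result table written by [write_results_tsv()]
#'
#' @param path TSV path.
#' @return a tibble.
#' @export
read_results_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Run the end-to-end analysis for a list of drugs
#'
#' For each drug: select its records (those listing the drug as a
#' substance) from the input, apply the end-date cutoff, split into the
#' interaction and background groups, run the enrichment analysis, and
#' write a per-drug result TSV plus the co-occurrence network as GraphML
#' and edge-list files. A JSON manifest with the parameters and per-drug
#' group sizes is written last. One drug's failure is recorded and does not
#' abort the batch.
#'
#' @param drugs character vector of query drug names (non-empty), or a path
#'   to a text file with one drug per line.
#' @param records a records tibble, or a path to a MEDLINE file.
#' @param params a [parameter_set()]; its `end_date`, if set, is applied as
#'   the search cutoff.
#' @param output_dir directory for outputs (created if needed).
#' @param ddi_predicate group classifier, see [split_groups()].
#' @param quiet suppress progress messages.
#' @return a tibble with one row per drug: `drug`, `status` (`"ok"` or the
#'   error message), `n_group_a`, `n_group_b`, `n_significant`, and output
#'   paths. An attribute `exit_status` is 0 when every drug succeeded.
#' @export
run_pipeline <- function(drugs, records, params = parameter_set(),
                         output_dir = ".", ddi_predicate = mesh_ddi_predicate(),
                         quiet = FALSE) {
  if (is.character(drugs) && length(drugs) == 1 && file.exists(drugs)) {
    drugs <- readLines(drugs, warn = FALSE)
  }
  drugs <- trimws(drugs)
  drugs <- drugs[nzchar(drugs)]
  if (length(drugs) == 0) abort("drug list is empty")
  if (is.character(records)) {
    records <- read_medline(records)
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  say <- function(...) if (!quiet) message(sprintf(...))
  rows <- vector("list", length(drugs))
  for (j in seq_along(drugs)) {
    drug <- drugs[j]
    slug <- gsub("[^A-Za-z0-9._-]", "_", drug)
    res <- tryCatch({
      has_drug <- vapply(records$substances, function(s) {
        any(tolower(trimws(s)) == tolower(drug))
      }, TRUE)
      recs <- records[has_drug, , drop = FALSE]
      if (!is.null(params$end_date)) {
        recs <- filter_by_end_date(recs, params$end_date)
      }
      grouped <- split_groups(recs, drug, ddi_predicate)
      say("%s: Group A = %d, Group B = %d", drug,
          nrow(grouped$group_a), nrow(grouped$group_b))
      t0 <- proc.time()[["elapsed"]]
      fit <- run_enrichment(grouped, params)
      say("%s: %d candidates, %d tested, %d significant (%.1f s)", drug,
          fit$n_candidates, fit$n_tested, nrow(fit$significant),
          proc.time()[["elapsed"]] - t0)
      results_path <- file.path(output_dir, paste0(slug, "_results.tsv"))
      write_results_tsv(fit$stats, results_path)
      net <- build_network(fit$significant, grouped$group_a, drug = drug)
      graphml_path <- file.path(output_dir, paste0(slug, "_network.graphml"))
      edges_path <- file.path(output_dir, paste0(slug, "_edges.tsv"))
      export_network(net, graphml_path, "graphml")
      export_network(net, edges_path, "edge-list")
      tibble::tibble(
        drug = drug, status = "ok",
        n_group_a = fit$n_group_a, n_group_b = fit$n_group_b,
        n_significant = nrow(fit$significant),
        results = results_path, graphml = graphml_path, edges = edges_path
      )
    }, error = function(e) {
      say("%s: FAILED (%s)", drug, conditionMessage(e))
      tibble::tibble(
        drug = drug, status = conditionMessage(e),
        n_group_a = NA_integer_, n_group_b = NA_integer_,
        n_significant = NA_integer_,
        results = NA_character_, graphml = NA_character_, edges = NA_character_
      )
    })
    rows[[j]] <- res
  }
  summary <- dplyr::bind_rows(rows)

  manifest <- list(
    package = "ddimine",
    version = as.character(utils::packageVersion("ddimine")),
    parameters = list(
      sample_times = params$sample_times, cutoff = params$cutoff,
      alpha = params$alpha, z_threshold = params$z_threshold,
      end_date = if (is.null(params$end_date)) NULL else format(params$end_date, "%Y/%m/%d"),
      seed = params$seed
    ),
    drugs = lapply(seq_len(nrow(summary)), function(i) {
      list(drug = summary$drug[i], status = summary$status[i],
           n_group_a = summary$n_group_a[i], n_group_b = summary$n_group_b[i],
           n_significant = summary$n_significant[i])
    })
  )
  jsonlite::write_json(manifest, file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  attr(summary, "exit_status") <- if (all(summary$status == "ok")) 0L else 1L
  summary
}

#' Published simvastatin reference results
#'
#' The bundled TSV `simvastatin_reference.tsv` is the published list of
#' substance terms identified for a simvastatin query against a 2015 PubMed
#' snapshot (frequency > 3, adjusted p < 0.05), split into FDA-approved
#' drugs and proteins, with the adjusted p-values as printed and — for the
#' drug section — a gold-standard column (`Y`/`N`) recording whether an
#' interaction with simvastatin is confirmed by the drugs.com interaction
#' checker.
#'
#' @param section `"fda_drug"`, `"protein"`, or `"all"`.
#' @return a tibble with columns `section`, `term`, `frequency`,
#'   `p_adjusted`, `ddi_gold`.
#' @export
simvastatin_reference <- function(section = c("all", "fda_drug", "protein")) {
  section <- match.arg(section)
  path <- system.file("extdata", "simvastatin_reference.tsv",
                      package = "ddimine", mustWork = TRUE)
  df <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE,
                                     na.strings = ""))
  if (section != "all") {
    df <- df[df$section == section, , drop = FALSE]
  }
  df
}
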