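# Shared fixture builders and independent oracles.

make_record <- function(pmid, substances = character(0),
                        mesh = character(0), dp = "2014 Mar 10",
                        title = paste("Record", pmid)) {
  tibble::tibble(
    pmid = pmid, title = title, journal = "J Test",
    pub_date_raw = dp, pub_date = ddimine:::parse_pub_date(dp),
    mesh_headings = list(mesh), substances = list(substances)
  )
}

make_records <- function(...) dplyr::bind_rows(...)

# Randomised corpus of well-formed records for round-trip properties.
random_records <- function(n, seed = 1) {
  set.seed(seed)
  vocab <- c("Cyclosporine", "Warfarin", "Diltiazem", "Ketoconazole",
             "Cytochrome P-450 CYP3A", "Aspirin", "Verapamil", "Digoxin")
  mesh_vocab <- c("Drug Interactions", "Humans", "Aged", "Liver/metabolism")
  rows <- lapply(seq_len(n), function(i) {
    make_record(
      pmid = as.character(100000 + i),
      substances = sample(vocab, sample(0:5, 1)),
      mesh = sample(mesh_vocab, sample(0:3, 1)),
      dp = sprintf("%d %s %d", sample(2000:2015, 1),
                   sample(month.abb, 1), sample(1:28, 1))
    )
  })
  dplyr::bind_rows(rows)
}

# Independent step-up BH, straight from the definition.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ranked[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Naive per-record, per-term membership scan replaying the same draw stream
# that sample_null_counts consumes.
null_counts_bruteforce <- function(terms, group_b, n, sample_times, seed) {
  counts <- matrix(0L, nrow = sample_times, ncol = length(terms),
                   dimnames = list(NULL, terms))
  set.seed(seed)
  for (i in seq_len(sample_times)) {
    idx <- sample.int(nrow(group_b), n, replace = TRUE)
    for (j in idx) {
      subs <- unique(trimws(group_b$substances[[j]]))
      for (t in seq_along(terms)) {
        if (terms[t] %in% subs) counts[i, t] <- counts[i, t] + 1L
      }
    }
  }
  counts
}

default_catalog <- function(n_null = 10, p_null = 0.1,
                            planted = c(p_a = 0.3, p_b = 0.05)) {
  data.frame(
    term = c("PlantedTerm", sprintf("NullTerm%02d", seq_len(n_null))),
    p_a = c(planted[["p_a"]], rep(p_null, n_null)),
    p_b = c(planted[["p_b"]], rep(p_null, n_null))
  )
}
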