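# Small in-memory record builders shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical variant table from minimal arguments; counts is a named list
# population -> c(ac, an)
toy_records <- function(..., counts = list(pop = c(0L, 2000L))) {
  rows <- list(...)
  tab <- dplyr::bind_rows(lapply(rows, function(r) {
    base <- list(chrom = "16", pos = 1000L, ref = "C", alt = "T",
                 hgvs_c = NA_character_, hgvs_p = NA_character_,
                 consequence = "other", ptc_pos = NA_integer_, filters = "",
                 revel = NA_real_, spliceai = NA_real_)
    base[names(r)] <- r
    tibble::as_tibble(base)
  }))
  for (p in names(counts)) {
    if (!paste0("ac_", p) %in% names(tab))
      tab[[paste0("ac_", p)]] <- counts[[p]][1]
    tab[[paste0("an_", p)]] <- counts[[p]][2]
  }
  carrierprev:::finalize_variant_table(tab)
}

# two-exon toy transcript used by the NMD hand computations
two_exon_transcript <- function() {
  transcript_model(exon_lengths = c(200L, 100L), cds_start = 1L, cds_end = 300L)
}

extdata <- function(f) system.file("extdata", f, package = "carrierprev")

# full fixture pipeline -> report (computed once per test run)
fixture_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- palb2_fixture_bundle()
      q <- qualify_tables(b$tables, b$transcript, b$thresholds, b$clinvar, b$hgmd)
      cache <<- list(bundle = b, qualified = q,
                     report = prevalence_report(q, b$registry))
    }
    cache
  }
})

report_cell <- function(rep, cohort, source) {
  rep[rep$cohort == cohort & rep$source == source, ]
}

# the published qualifying-allele totals for every cohort x source cell
expected_cells <- function() {
  tibble::tribble(
    ~cohort, ~acmg, ~clinvar, ~hgmd,
    "global",     227L, 214L, 277L,
    "east_asian",   8L,   7L,  14L,
    "afr",         16L,  16L,  17L,
    "amr",         29L,  28L,  39L,
    "asj",          2L,   1L,   2L,
    "fin",         44L,  44L,  44L,
    "nfe",        105L,  98L, 137L,
    "sas",         15L,  12L,  14L,
    "oth",          8L,   8L,  10L,
    "kor",          2L,   1L,   0L,
    "jpn",          0L,   0L,   0L,
    "oea",          6L,   6L,  14L,
    "all_korean",  12L,  11L,   6L,
    "kova",        10L,  10L,   6L,
    "krgdb",        0L,   0L,   0L
  )
}
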