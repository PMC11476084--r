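# Synthetic PALB2 fixtures.
#
# These tables emulate the PALB2 allele-count landscape of gnomAD v2.1.1
# (125,748 exomes across eight continental populations, with the East Asian
# cohort split into Korean / Japanese / other East Asian), KOVA (5,305
# Koreans) and KRGDB (1,722 Koreans), together with ClinVar-style and
# HGMD-style assertion tables. Genomic coordinates and alleles are synthetic
# placeholders on a toy transcript; the HGVS labels, consequences and the
# per-population qualifying-allele sums mirror the published PALB2 landscape
# (e.g. the Finnish-enriched c.1592del founder frameshift at 46 alleles,
# absent in East Asians; c.2968G>T confined to non-Korean East Asians;
# c.1048C>T as the most frequent Korean allele). Where only marginal sums
# are published, the per-variant allocation is arbitrary but fixed.

GNOMAD_POPS <- c(afr = 8128L, amr = 17296L, asj = 5040L, kor = 1909L,
                 jpn = 76L, oea = 7212L, fin = 10824L, nfe = 56885L,
                 sas = 15308L, oth = 3070L)

#' Toy PALB2-like transcript model
#'
#' Thirteen exons, ~3.6 kb CDS; dimensions chosen so that every truncating
#' fixture variant lies upstream of the NMD boundary (50 nt before the last
#' exon-exon junction).
#'
#' @return A [transcript_model()].
#' @export
palb2_transcript <- function() {
  transcript_model(
    exon_lengths = c(100L, 1100L, 70L, 1500L, 170L, 90L, 90L, 160L,
                     115L, 150L, 220L, 100L, 240L),
    cds_start = 50L, cds_end = 3607L
  )
}

#' Threshold configuration used by the PALB2 fixtures
#'
#' Same calibrated REVEL/SpliceAI cutoffs as [threshold_config()], but PM2 at
#' moderate strength with a popmax cutoff of 2e-3: under the strict 2015
#' combining table a loss-of-function variant needs PVS1 plus a moderate
#' criterion to reach likely pathogenic, and the Finnish founder frameshift
#' reaches a popmax allele frequency of 1.4e-3 while remaining a bona fide
#' rare pathogenic allele.
#'
#' @return A [threshold_config()].
#' @export
palb2_fixture_thresholds <- function() {
  threshold_config(pm2_af_max = 2e-3, pm2_strength = "moderate")
}

# master spectrum: hgvs, consequence, scores, assertions and per-population
# allele counts ("pop=ac" pairs; pops absent from a table default to 0)
palb2_spectrum <- function() {
  sp <- tibble::tribble(
    ~hgvs_c, ~hgvs_p, ~consequence, ~ptc_pos, ~revel, ~spliceai, ~filters, ~clinvar, ~hgmd, ~counts,
    "c.1592del",      "p.(Leu531CysfsTer30)", "frameshift", 1700L, NA, NA, "", "Pathogenic", "DM", "afr=2,amr=3,fin=30,nfe=10,oth=1",
    "c.2167_2168del", "p.(Met723ValfsTer21)", "frameshift", 2290L, NA, NA, "", "Pathogenic", "DM", "amr=10,nfe=4,sas=2,kova=1",
    "c.3113G>A",      "p.(Trp1038Ter)",       "nonsense",   3162L, NA, NA, "", "Pathogenic", "DM", "afr=3,amr=2,fin=1,nfe=8",
    "c.172_175del",   "p.(Gln60ArgfsTer7)",   "frameshift",  280L, NA, NA, "", "Pathogenic", "DM", "amr=2,nfe=9,sas=2",
    "c.509_510del",   "p.(Arg170IlefsTer14)", "frameshift",  600L, NA, NA, "", "Pathogenic", "DM", "afr=2,amr=2,nfe=8",
    "c.2968G>T",      "p.(Glu990Ter)",        "nonsense",   3017L, NA, NA, "", "Likely_pathogenic", "DM", "oea=4",
    "c.1050_1053del", "p.(Thr351ArgfsTer4)",  "frameshift", 1160L, NA, NA, "", "Likely_pathogenic", "DM", "oea=1,sas=1",
    "c.3116del",      "p.(Asn1039IlefsTer2)", "frameshift", 3220L, NA, NA, "", "Pathogenic", "DM", "fin=8,nfe=20",
    "c.757C>T",       "p.(Gln253Ter)",        "nonsense",    806L, NA, NA, "", "Pathogenic", "DM", "afr=4,nfe=15",
    "c.3456dup",      "p.(Gln1153SerfsTer12)","frameshift", 3560L, NA, NA, "", "Pathogenic", "DM", "amr=5,nfe=12,oth=3",
    "c.196C>T",       "p.(Gln66Ter)",         "nonsense",    245L, NA, NA, "", "Pathogenic", "DM", "nfe=12,sas=4",
    "c.2390del",      "p.(Pro797GlnfsTer2)",  "frameshift", 2500L, NA, NA, "", "Pathogenic", "DM", "afr=5,asj=1,fin=5",
    "c.3549C>A",      "p.(Tyr1183Ter)",       "nonsense",   3598L, NA, NA, "", "Likely_pathogenic", "DM", "amr=4,sas=3,oth=4",
    "c.661A>T",       "p.(Lys221Ter)",        "nonsense",    710L, NA, NA, "", "Likely_pathogenic", "DM", "oea=1",
    "c.1048C>T",      "p.(Gln350Ter)",        "nonsense",   1097L, NA, NA, "", "Pathogenic", NA, "kor=1,kova=2",
    "c.2257C>T",      "p.(Arg753Ter)",        "nonsense",   2306L, NA, NA, "", NA, "DM", "nfe=7",
    "c.3201+1G>A",    NA,                     "canonical_splice", NA, NA, 0.84, "", NA, "DM", "amr=1,asj=1,sas=2",
    "c.93del",        "p.(Ile32SerfsTer8)",   "frameshift",  190L, NA, NA, "", NA, NA, "kor=1",
    "c.1684C>T",      "p.(Gln562Ter)",        "nonsense",   1733L, NA, NA, "", NA, NA, "sas=1",
    "c.2816T>G",      "p.(Leu939Trp)",        "missense",    NA, 0.52, NA, "", NA, "DM", "afr=1,amr=6,nfe=20",
    "c.1010T>C",      "p.(Leu337Ser)",        "missense",    NA, 0.47, NA, "", NA, "DM", "amr=4,nfe=12,oth=2",
    "c.3428T>A",      "p.(Leu1143His)",       "missense",    NA, 0.55, NA, "", NA, "DM", "oea=8",
    "c.2014G>C",      "p.(Glu672Gln)",        "missense",    NA, 0.12, NA, "", "Benign", NA, "afr=120,amr=260,asj=40,kor=15,jpn=1,oea=60,fin=110,nfe=2000,sas=150,oth=30,kova=180,krgdb=60",
    "c.212-5T>C",     NA,                     "splice_region", NA, NA, 0.05, "", "Uncertain_significance", "DP", "nfe=30",
    "c.2589C>T",      "p.(Ala863=)",          "synonymous",  NA, NA, NA, "", NA, "DM?", "amr=15",
    "c.448C>T",       "p.(Gln150Ter)",        "nonsense",    497L, NA, NA, "RF", "Pathogenic", "DM", "fin=2,nfe=5",
    "c.2T>C",         "p.(Met1?)",            "initiation_codon", NA, NA, NA, "AC0", "Likely_pathogenic", NA, "",
    "c.3300T>G",      "p.(Phe1100Cys)",       "missense",    NA, 0.97, NA, "", "Conflicting", NA, "nfe=600",
    "c.3267_3268del", "p.(Phe1090SerfsTer6)", "frameshift", 3380L, NA, NA, "", "Pathogenic", "DM", "kova=1",
    "c.2834+2T>C",    NA,                     "canonical_splice", NA, NA, 0.61, "", "Likely_pathogenic", NA, "kova=1",
    "c.530del",       "p.(Pro177LeufsTer8)",  "frameshift",  640L, NA, NA, "", "Likely_pathogenic", "DM", "kova=1",
    "c.757dup",       "p.(Gln253ProfsTer3)",  "frameshift",  860L, NA, NA, "", "Likely_pathogenic", "DM", "kova=1",
    "c.1240del",      "p.(Arg414GlufsTer5)",  "frameshift", 1350L, NA, NA, "", "Likely_pathogenic", "DM", "kova=1",
    "c.3350+1G>A",    NA,                     "canonical_splice", NA, NA, 0.92, "", "Likely_pathogenic", "DM", "kova=1",
    "c.208del",       "p.(Arg70GlyfsTer6)",   "frameshift",  310L, NA, NA, "", "Likely_pathogenic", NA, "kova=1",
    "c.1194G>A",      "p.(Val398=)",          "synonymous",  NA, NA, NA, "", NA, NA, "krgdb=12"
  )
  # synthetic placeholder coordinates: evenly spaced loci on chromosome 16,
  # alleles derived from the HGVS label (SNVs keep their substituted bases,
  # indels use anchored A-tract placeholders)
  sp$chrom <- "16"
  sp$pos <- 23600000L + 137L * seq_len(nrow(sp))
  alleles <- t(vapply(sp$hgvs_c, hgvs_placeholder_alleles, character(2)))
  sp$ref <- alleles[, 1]
  sp$alt <- alleles[, 2]
  sp
}

# ref/alt placeholders from an HGVS coding label
hgvs_placeholder_alleles <- function(hgvs) {
  if (grepl(">", hgvs, fixed = TRUE)) {
    m <- regmatches(hgvs, regexec("([ACGT])>([ACGT])$", hgvs))[[1]]
    return(c(m[2], m[3]))
  }
  if (grepl("dup$", hgvs)) return(c("G", "GG"))
  if (grepl("del$", hgvs)) {
    m <- regmatches(hgvs, regexec("c\\.([0-9]+)(?:[+-][0-9]+)?(?:_([0-9]+))?del", hgvs))[[1]]
    ndel <- if (is.na(m[3]) || m[3] == "") 1L else as.integer(m[3]) - as.integer(m[2]) + 1L
    return(c(paste0("C", strrep("A", ndel)), "C"))
  }
  stop(sprintf("cannot derive placeholder alleles for '%s'", hgvs), call. = FALSE)
}

parse_counts <- function(s) {
  if (!nzchar(s)) return(integer(0))
  kv <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) as.integer(x[2]), integer(1)),
                  vapply(kv, `[`, character(1), 1))
}

spectrum_to_table <- function(sp, pops, n_by_pop) {
  keep <- vapply(sp$counts, function(s) {
    cts <- parse_counts(s)
    any(names(cts) %in% pops)
  }, logical(1))
  # records absent from every population of this table are dropped, except
  # zero-count records explicitly tied to it (none currently) and the
  # AC0-flagged record which belongs to the gnomAD-style table
  if ("afr" %in% pops) keep <- keep | sp$filters == "AC0"
  tab <- sp[keep, c("chrom", "pos", "ref", "alt", "hgvs_c", "hgvs_p",
                    "consequence", "ptc_pos", "filters", "revel", "spliceai")]
  for (p in pops) {
    tab[[paste0("ac_", p)]] <- vapply(sp$counts[keep], function(s) {
      cts <- parse_counts(s)
      if (p %in% names(cts)) cts[[p]] else 0L
    }, integer(1))
    tab[[paste0("an_", p)]] <- 2L * n_by_pop[[p]]
  }
  finalize_variant_table(tab)
}

#' Synthetic PALB2 fixture bundle
#'
#' Builds the three variant tables (gnomAD-style, KOVA-style, KRGDB-style),
#' the ClinVar-style and HGMD-style assertion tables, the cohort registry,
#' the toy transcript and the fixture threshold configuration, entirely in
#' code. Running the classification and prevalence pipeline on this bundle
#' reproduces every published PALB2 qualifying-allele total (227 global ACMG
#' alleles, 8 East Asian, 44 Finnish, 2 + 10 + 0 Korean, ...).
#'
#' @return Named list: `tables` (list of variant tibbles), `clinvar`, `hgmd`
#'   (assertion tibbles), `registry`, `transcript`, `thresholds`.
#' @export
palb2_fixture_bundle <- function() {
  sp <- palb2_spectrum()
  tables <- list(
    gnomad = spectrum_to_table(sp, names(GNOMAD_POPS), as.list(GNOMAD_POPS)),
    kova   = spectrum_to_table(sp, "kova", list(kova = 5305L)),
    krgdb  = spectrum_to_table(sp, "krgdb", list(krgdb = 1722L))
  )
  keys <- dplyr::bind_rows(lapply(seq_len(nrow(sp)), function(i)
    normalize_variant(sp$chrom[i], sp$pos[i], sp$ref[i], sp$alt[i])))
  assertion_tab <- function(labels, source) {
    sel <- !is.na(labels)
    out <- tibble(key = keys$key[sel], chrom = keys$chrom[sel],
                  pos = keys$pos[sel], ref = keys$ref[sel],
                  alt = keys$alt[sel], assertion = labels[sel])
    attr(out, "source") <- source
    out
  }
  list(
    tables = tables,
    clinvar = assertion_tab(sp$clinvar, "clinvar"),
    hgmd = assertion_tab(sp$hgmd, "hgmd"),
    registry = palb2_registry(),
    transcript = palb2_transcript(),
    thresholds = palb2_fixture_thresholds()
  )
}

#' Cohort registry for the PALB2 fixtures
#'
#' gnomAD-style continental cohorts (East Asians split into Korean, Japanese
#' and other East Asian), the pooled East Asian and global cohorts, the two
#' Korean databases and the pooled all-Korean cohort
#' (1909 + 5305 + 1722 = 8936 individuals).
#'
#' @return A `cohort_registry`.
#' @export
palb2_registry <- function() {
  leaf <- function(name, n, table = "gnomad", src = "gnomad-exomes")
    cohort_spec(name, n, source = src, table = table, population = name)
  cohort_registry(list(
    cohort_spec("global", 125748L, source = "gnomad-exomes",
                members = c("afr", "amr", "asj", "east_asian", "fin",
                            "nfe", "sas", "oth")),
    cohort_spec("east_asian", 9197L, source = "gnomad-exomes",
                members = c("kor", "jpn", "oea")),
    leaf("afr", 8128L), leaf("amr", 17296L), leaf("asj", 5040L),
    leaf("fin", 10824L), leaf("nfe", 56885L), leaf("sas", 15308L),
    leaf("oth", 3070L),
    leaf("kor", 1909L), leaf("jpn", 76L), leaf("oea", 7212L),
    cohort_spec("all_korean", 8936L, source = "pooled",
                members = c("kor", "kova", "krgdb")),
    cohort_spec("kova", 5305L, source = "kova", table = "kova",
                population = "kova"),
    cohort_spec("krgdb", 1722L, source = "krgdb", table = "krgdb",
                population = "krgdb")
  ))
}

#' Write the PALB2 fixture bundle to disk
#'
#' Writes the canonical-dialect variant TSVs, the two assertion TSVs, the
#' cohort registry YAML and the threshold YAML into `dir`. These are the
#' files shipped under `inst/extdata/`.
#'
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_palb2_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- palb2_fixture_bundle()
  write_variant_table(b$tables$gnomad, file.path(dir, "palb2_gnomad_synthetic.tsv"))
  write_variant_table(b$tables$kova, file.path(dir, "palb2_kova_synthetic.tsv"))
  write_variant_table(b$tables$krgdb, file.path(dir, "palb2_krgdb_synthetic.tsv"))
  readr::write_tsv(b$clinvar[, c("chrom", "pos", "ref", "alt", "assertion")],
                   file.path(dir, "palb2_clinvar_synthetic.tsv"), progress = FALSE)
  readr::write_tsv(b$hgmd[, c("chrom", "pos", "ref", "alt", "assertion")],
                   file.path(dir, "palb2_hgmd_synthetic.tsv"), progress = FALSE)
  reg <- lapply(unname(unclass(b$registry)), function(s) {
    e <- list(name = s$name, n_individuals = s$n_individuals, source = s$source)
    if (!is.null(s$members)) e$members <- as.list(s$members)
    else { e$table <- s$table; e$population <- s$population }
    e
  })
  yaml::write_yaml(list(cohorts = reg), file.path(dir, "palb2_cohorts.yaml"))
  th <- b$thresholds
  yaml::write_yaml(list(
    spliceai_min = th$spliceai_min,
    revel_pathogenic = as.list(th$revel_pathogenic),
    revel_benign = as.list(th$revel_benign),
    pm2_af_max = th$pm2_af_max,
    pm2_strength = th$pm2_strength
  ), file.path(dir, "palb2_thresholds.yaml"))
  invisible(dir)
}
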