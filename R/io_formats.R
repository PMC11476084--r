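# Readers and writers for the canonical TSV dialect, gnomAD-style VCF,
# assertion tables and cohort registries.

MANDATORY_COLS <- c("chrom", "pos", "ref", "alt", "consequence", "filters")

CLINVAR_LABELS <- c("Pathogenic", "Likely_pathogenic", "Uncertain_significance",
                    "Likely_benign", "Benign", "Conflicting")
HGMD_LABELS <- c("DM", "DM?", "DP", "DFP", "FP", "R")

#' Population labels carried by a variant table
#'
#' @param records A variant table (tibble with paired `ac_<pop>`/`an_<pop>` columns).
#' @return Character vector of population labels.
#' @export
pop_labels <- function(records) {
  acs <- grep("^ac_", names(records), value = TRUE)
  sub("^ac_", "", acs)
}

finalize_variant_table <- function(records, path = "<in-memory>") {
  pops <- pop_labels(records)
  if (!length(pops))
    stop(sprintf("%s: no ac_<population>/an_<population> column pairs found", path),
         call. = FALSE)
  for (p in pops) {
    an_col <- paste0("an_", p)
    if (!an_col %in% names(records))
      stop(sprintf("%s: column ac_%s has no matching %s", path, p, an_col),
           call. = FALSE)
    bad <- which(records[[paste0("ac_", p)]] > records[[an_col]])
    if (length(bad))
      stop(sprintf("%s: AC > AN for population '%s' on row %d", path, p, bad[1]),
           call. = FALSE)
    records[[paste0("ac_", p)]] <- as.integer(records[[paste0("ac_", p)]])
    records[[an_col]] <- as.integer(records[[an_col]])
  }
  bad_cons <- setdiff(unique(records$consequence), CONSEQUENCES)
  if (length(bad_cons))
    stop(sprintf("%s: unknown consequence label(s): %s", path,
                 paste(bad_cons, collapse = ", ")), call. = FALSE)
  # normalize each variant and attach the join key
  if (nrow(records)) {
    norm <- dplyr::bind_rows(lapply(seq_len(nrow(records)), function(i) {
      normalize_variant(records$chrom[i], records$pos[i],
                        records$ref[i], records$alt[i])
    }))
    records$chrom <- norm$chrom
    records$pos <- norm$pos
    records$ref <- norm$ref
    records$alt <- norm$alt
    records$key <- norm$key
  } else {
    records$key <- character(0)
  }
  for (col in c("hgvs_c", "hgvs_p"))
    if (!col %in% names(records)) records[[col]] <- NA_character_
  for (col in c("revel", "spliceai"))
    if (!col %in% names(records)) records[[col]] <- NA_real_
  if (!"ptc_pos" %in% names(records)) records$ptc_pos <- NA_integer_
  records$ptc_pos <- as.integer(records$ptc_pos)
  records$filters[is.na(records$filters)] <- ""
  if (any(!is.na(records$revel) & records$consequence != "missense"))
    stop(sprintf("%s: REVEL scores are only meaningful on missense records", path),
         call. = FALSE)
  front <- c("key", "chrom", "pos", "ref", "alt", "hgvs_c", "hgvs_p",
             "consequence", "ptc_pos", "filters", "revel", "spliceai")
  records[, c(front, setdiff(names(records), front))]
}

#' Read a variant allele-count table
#'
#' Two dialects are supported. The canonical TSV dialect has columns
#' `chrom, pos, ref, alt, hgvs_c, hgvs_p, consequence, ptc_pos, filters,
#' revel, spliceai` plus one `ac_<pop>`/`an_<pop>` pair per population;
#' `filters` is a `;`-separated list of quality-filter flags (empty for
#' passing records). The VCF dialect reads per-population allele counts from
#' `AC_<pop>`/`AN_<pop>` INFO keys and decomposes multi-allelic rows into one
#' biallelic record per alternate allele.
#'
#' Column (or INFO-key) names are mapped to population labels through
#' `pop_map`, e.g. `c(AC_eas = "east_asian")`; unmapped `ac_*` columns keep
#' their own suffix as the label.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param pop_map Optional named character vector renaming population
#'   suffixes, `c(old = "new")`.
#' @return Tibble of variant records, one row per biallelic alternate allele,
#'   keyed by the normalized `key` column.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"), pop_map = NULL) {
  dialect <- match.arg(dialect)
  records <- switch(dialect,
    tsv = read_variant_tsv(path),
    vcf = read_variant_vcf(path)
  )
  if (!is.null(pop_map)) {
    for (old in names(pop_map)) {
      for (pre in c("ac_", "an_")) {
        from <- paste0(pre, old); to <- paste0(pre, pop_map[[old]])
        names(records)[names(records) == from] <- to
      }
    }
  }
  finalize_variant_table(records, path)
}

read_variant_tsv <- function(path) {
  records <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                             col_types = text_cols(path))
  missing <- setdiff(MANDATORY_COLS, names(records))
  if (length(missing))
    stop(sprintf("%s: missing mandatory column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  records$filters <- as.character(records$filters)
  records
}

read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- v@fix[, "INFO"]
  get_key <- function(inf, key) {
    m <- regmatches(inf, regexpr(paste0("(?:^|;)", key, "=[^;]*"), inf))
    if (!length(m)) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  ikeys <- unique(unlist(lapply(info, function(x)
    sub("=.*$", "", strsplit(x, ";", fixed = TRUE)[[1]]))))
  ac_keys <- grep("^AC_", ikeys, value = TRUE)
  out <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    filt <- fix$FILTER[i]
    filt <- if (is.na(filt) || filt %in% c("PASS", ".")) "" else filt
    for (j in seq_along(alts)) {
      row <- tibble(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j],
        hgvs_c = nth_or_na(get_key(info[i], "HGVSC"), j),
        hgvs_p = nth_or_na(get_key(info[i], "HGVSP"), j),
        consequence = nth_or_na(get_key(info[i], "CONSEQ"), j),
        ptc_pos = as.integer(nth_or_na(get_key(info[i], "PTC_POS"), j)),
        filters = filt,
        revel = as.numeric(nth_or_na(get_key(info[i], "REVEL"), j)),
        spliceai = as.numeric(nth_or_na(get_key(info[i], "SPLICEAI"), j))
      )
      for (k in ac_keys) {
        pop <- tolower(sub("^AC_", "", k))
        row[[paste0("ac_", pop)]] <- as.integer(nth_or_na(get_key(info[i], k), j))
        row[[paste0("an_", pop)]] <- as.integer(get_key(info[i], sub("^AC_", "AN_", k)))
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- dplyr::bind_rows(out)
  missing <- setdiff(MANDATORY_COLS, names(res))
  if (length(missing))
    stop(sprintf("%s: missing mandatory field(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  res
}

# j-th element of a comma-separated per-allele INFO value ("." and "" -> NA)
nth_or_na <- function(x, j) {
  if (is.na(x)) return(NA_character_)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  val <- if (j <= length(parts)) parts[j] else parts[1]
  if (val %in% c(".", "")) NA_character_ else val
}

# force text parsing for columns whose values can masquerade as logicals
# ("T" alleles) or numbers; everything else is guessed
text_cols <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  textual <- intersect(c("chrom", "ref", "alt", "filters", "hgvs_c", "hgvs_p",
                         "consequence", "assertion"), hdr)
  spec <- stats::setNames(as.list(rep("c", length(textual))), textual)
  do.call(readr::cols, c(spec, .default = "?"))
}

#' Write a variant table in the canonical TSV dialect
#'
#' Round-trips with [read_variant_table()]: re-reading the written file
#' reproduces the record list.
#'
#' @param records Variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path) {
  out <- records[, setdiff(names(records), "key")]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Drop records failing quality-control filters
#'
#' Keeps exactly the records whose filter-flag set is disjoint from
#' `excluded_flags`; order is preserved and the operation is idempotent.
#' The number of excluded records is attached as attribute `n_excluded`
#' so reproducibility reports can state the exclusion count.
#'
#' @param records Variant table.
#' @param excluded_flags Flags that disqualify a record. The default is the
#'   gnomAD-style trio `InbreedingCoeff`, `AC0`, `RF`.
#' @return Filtered variant table.
#' @export
apply_quality_filters <- function(records,
                                  excluded_flags = c("InbreedingCoeff", "AC0", "RF")) {
  if (!nrow(records)) {
    attr(records, "n_excluded") <- 0L
    return(records)
  }
  flags <- strsplit(records$filters, "[;,]")
  drop <- vapply(flags, function(f) any(trimws(f) %in% excluded_flags), logical(1))
  out <- records[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Read a ClinVar-style or HGMD-style assertion table
#'
#' Expects TSV columns `chrom, pos, ref, alt, assertion`. Keys are normalized
#' with [normalize_variant()]; duplicate rows carrying the same assertion are
#' collapsed, duplicate keys with conflicting assertions are an error (for
#' ClinVar-style sources, conflicts must be pre-resolved to `Conflicting`).
#'
#' @param path File path.
#' @param source `"clinvar"` or `"hgmd"`; fixes the allowed assertion labels.
#' @return Tibble `key, chrom, pos, ref, alt, assertion` with attribute `source`.
#' @export
read_assertion_table <- function(path, source = c("clinvar", "hgmd")) {
  source <- match.arg(source)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = text_cols(path))
  missing <- setdiff(c("chrom", "pos", "ref", "alt", "assertion"), names(tab))
  if (length(missing))
    stop(sprintf("%s: missing mandatory column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  allowed <- if (source == "clinvar") CLINVAR_LABELS else HGMD_LABELS
  bad <- setdiff(unique(tab$assertion), allowed)
  if (length(bad))
    stop(sprintf("%s: assertion label(s) not valid for %s-style source: %s",
                 path, source, paste(bad, collapse = ", ")), call. = FALSE)
  norm <- dplyr::bind_rows(lapply(seq_len(nrow(tab)), function(i)
    normalize_variant(tab$chrom[i], tab$pos[i], tab$ref[i], tab$alt[i])))
  tab$key <- norm$key
  tab$chrom <- norm$chrom; tab$pos <- norm$pos
  tab$ref <- norm$ref; tab$alt <- norm$alt
  tab <- unique(tab[, c("key", "chrom", "pos", "ref", "alt", "assertion")])
  dup <- tab$key[duplicated(tab$key)]
  if (length(dup))
    stop(sprintf("%s: conflicting assertions for key(s): %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  attr(tab, "source") <- source
  tab
}

#' Convert allele frequencies to allele counts
#'
#' For sources that publish frequencies rather than counts:
#' `ac = round(af * 2 * n_individuals)`.
#'
#' @param af Allele frequency vector.
#' @param n_individuals Number of diploid individuals.
#' @return Integer allele counts.
#' @export
af_to_counts <- function(af, n_individuals) {
  if (any(af < 0 | af > 1, na.rm = TRUE)) stop("af must lie in [0,1]", call. = FALSE)
  as.integer(round(af * 2 * n_individuals))
}

#' Read a cohort registry from YAML
#'
#' The file holds a top-level `cohorts:` list; each entry has `name`,
#' `n_individuals`, `source`, and either `table` + `population` (leaf) or
#' `members` (pooled). Pooled sizes are validated against the member sum.
#'
#' @param path YAML file path.
#' @return A `cohort_registry`.
#' @export
read_cohort_registry <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$cohorts)) stop(sprintf("%s: no 'cohorts' list", path), call. = FALSE)
  specs <- lapply(y$cohorts, function(e) {
    cohort_spec(name = e$name, n_individuals = e$n_individuals,
                source = e$source %||% "synthetic",
                table = e$table, population = e$population,
                members = if (!is.null(e$members)) unlist(e$members))
  })
  cohort_registry(specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
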