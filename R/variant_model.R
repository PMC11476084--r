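#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% bind_rows filter mutate arrange
NULL

#' Molecular consequence vocabulary
#'
#' The consequence labels understood by the classification engine. Exactly one
#' label is attached to each variant record.
#'
#' @format Character vector.
#' @export
CONSEQUENCES <- c(
  "nonsense", "frameshift", "canonical_splice", "splice_region",
  "missense", "synonymous", "initiation_codon", "other"
)

# consequences routed through the loss-of-function (PVS1) path
LOF_CONSEQUENCES <- c("nonsense", "frameshift", "canonical_splice", "initiation_codon")

chk_allele <- function(x, field) {
  if (length(x) != 1L || is.na(x) || !nzchar(x) || !grepl("^[ACGT]+$", x)) {
    stop(sprintf("malformed %s allele: %s (must be a non-empty uppercase A/C/G/T string)",
                 field, deparse(as.character(x))), call. = FALSE)
  }
  invisible(x)
}

#' Canonical string identity for a normalized variant
#'
#' Variant identity for all cross-database joins is the normalized
#' `chrom:pos:ref:alt` key; HGVS strings are carried as annotation only.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position.
#' @param ref,alt Allele strings.
#' @return A character key, one per input row.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Normalize a variant to its left-aligned, parsimonious representation
#'
#' Coordinates are 1-based and VCF-style: indels keep a single anchor base.
#' Shared trailing bases are trimmed first, then shared leading bases (moving
#' the position right), leaving the minimal representation. When the flanking
#' reference sequence is supplied, indels are additionally shifted left
#' through repeat tracts until no further equivalent representation exists
#' upstream, matching the usual VCF normalization algorithm.
#'
#' The operation is idempotent: normalizing an already-normal key returns it
#' unchanged.
#'
#' @param chrom Chromosome label.
#' @param pos 1-based position of the first ref base.
#' @param ref,alt Non-empty uppercase A/C/G/T allele strings, `ref != alt`.
#' @param context Optional reference sequence covering the variant locus,
#'   used for left-alignment through repeats.
#' @param context_start 1-based genomic position of `context[1]`.
#' @return One-row tibble with columns `chrom`, `pos`, `ref`, `alt`, `key`.
#' @examples
#' normalize_variant("16", 100, "AT", "AG")  # -> 101 T>G
#' @export
normalize_variant <- function(chrom, pos, ref, alt, context = NULL, context_start = 1L) {
  chk_allele(ref, "ref")
  chk_allele(alt, "alt")
  if (identical(ref, alt)) stop("ref and alt alleles are identical", call. = FALSE)
  if (!is.numeric(pos) || is.na(pos) || pos < 1) stop("pos must be >= 1", call. = FALSE)
  pos <- as.integer(pos)

  ctx_base <- function(p) {
    if (is.null(context)) return(NA_character_)
    i <- p - as.integer(context_start) + 1L
    if (i < 1L || i > nchar(context)) return(NA_character_)
    substr(context, i, i)
  }

  last1 <- function(s) substr(s, nchar(s), nchar(s))
  repeat {
    changed <- FALSE
    # trim shared trailing bases; extend left through context when one allele
    # would otherwise empty out (repeat-tract left shift)
    while (nzchar(ref) && nzchar(alt) && last1(ref) == last1(alt)) {
      if (nchar(ref) == 1L || nchar(alt) == 1L) {
        b <- ctx_base(pos - 1L)
        if (is.na(b)) break
        ref <- paste0(b, substr(ref, 1L, nchar(ref) - 1L))
        alt <- paste0(b, substr(alt, 1L, nchar(alt) - 1L))
        pos <- pos - 1L
      } else {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
      }
      changed <- TRUE
    }
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
      changed <- TRUE
    }
    if (!changed) break
  }

  tibble(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
         key = variant_key(chrom, pos, ref, alt))
}

#' Toy transcript model for the PVS1 decision tree
#'
#' Exon/CDS structure in transcript coordinates, sufficient for the
#' nonsense-mediated-decay (NMD) rule: a premature termination codon escapes
#' NMD when it falls in the last exon or within the last 50 nt upstream of
#' the final exon-exon junction.
#'
#' @param exon_lengths Ordered exon lengths in nucleotides (all >= 1).
#' @param cds_start,cds_end CDS boundaries in transcript coordinates,
#'   `cds_start < cds_end <= sum(exon_lengths)`.
#' @param strand `"+"` or `"-"` (annotation only; coordinates are transcript-relative).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(exon_lengths, cds_start, cds_end, strand = "+") {
  exon_lengths <- as.integer(exon_lengths)
  if (length(exon_lengths) < 1L || any(is.na(exon_lengths)) || any(exon_lengths < 1L))
    stop("all exon lengths must be >= 1", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  total <- sum(exon_lengths)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (is.na(cds_start) || is.na(cds_end) || cds_start < 1L || cds_end > total ||
      cds_start >= cds_end)
    stop("need 1 <= cds_start < cds_end <= transcript length", call. = FALSE)
  structure(
    list(exon_lengths = exon_lengths, cds_start = cds_start,
         cds_end = cds_end, strand = strand),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %d exons, %d nt, CDS %d-%d (%s)\n",
              length(x$exon_lengths), sum(x$exon_lengths),
              x$cds_start, x$cds_end, x$strand))
  invisible(x)
}

#' Define a cohort (a named population with its sequenced sample size)
#'
#' Leaf cohorts point at one population column of one variant table; pooled
#' cohorts list member cohort names and their size must equal the member sum
#' (checked when a registry is assembled).
#'
#' @param name Population label.
#' @param n_individuals Number of sequenced individuals (>= 1).
#' @param source Database label, e.g. `"gnomad-exomes"`, `"kova"`, `"synthetic"`.
#' @param table Name of the variant table the cohort's counts live in
#'   (leaf cohorts only).
#' @param population Population column label within that table (leaf only).
#' @param members Character vector of member cohort names (pooled only).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n_individuals, source = "synthetic",
                        table = NULL, population = NULL, members = NULL) {
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L)
    stop("n_individuals must be >= 1", call. = FALSE)
  if (is.null(members) && (is.null(table) || is.null(population)))
    stop(sprintf("leaf cohort '%s' needs a table and a population label", name),
         call. = FALSE)
  structure(
    list(name = name, n_individuals = n_individuals, source = source,
         table = table, population = population, members = members),
    class = "cohort_spec"
  )
}

#' Assemble cohort specs into a registry
#'
#' Validates that every pooled cohort's size equals the sum over its members
#' (resolved recursively) and that member names exist.
#'
#' @param ... `cohort_spec` objects, in the order reports should render them.
#' @return Named list of `cohort_spec` with class `cohort_registry`.
#' @export
cohort_registry <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1]]) && !inherits(specs[[1]], "cohort_spec"))
    specs <- specs[[1]]
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  reg <- structure(specs, class = "cohort_registry")
  for (s in specs) {
    if (!is.null(s$members)) {
      missing <- setdiff(s$members, names(specs))
      if (length(missing))
        stop(sprintf("cohort '%s' pools unknown members: %s",
                     s$name, paste(missing, collapse = ", ")), call. = FALSE)
      n_sum <- sum(vapply(s$members, function(m) specs[[m]]$n_individuals, integer(1)))
      if (n_sum != s$n_individuals)
        stop(sprintf("pooled cohort '%s' has n_individuals %d but members sum to %d",
                     s$name, s$n_individuals, n_sum), call. = FALSE)
    }
  }
  reg
}

#' Resolve a cohort to its leaf (table, population) pairs
#'
#' @param registry A `cohort_registry`.
#' @param name Cohort name.
#' @return Tibble with columns `table`, `population`, `n_individuals`.
#' @export
cohort_leaves <- function(registry, name) {
  if (!name %in% names(registry))
    stop(sprintf("unknown cohort '%s'", name), call. = FALSE)
  s <- registry[[name]]
  if (is.null(s$members)) {
    return(tibble(table = s$table, population = s$population,
                  n_individuals = s$n_individuals))
  }
  bind_rows(lapply(s$members, function(m) cohort_leaves(registry, m)))
}
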