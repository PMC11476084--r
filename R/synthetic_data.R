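# Synthetic gnomAD-like cohort tables with known ground truth.
#
# Allele counts are drawn per variant and cohort as Binomial(2n, af) in the
# rare-variant regime (af <= 0.01); in-silico scores are drawn from
# class-conditional distributions with margins wide enough that planted
# pathogenic/likely-pathogenic variants classify as such (NMD-positive
# nonsense or frameshift, extremely rare) and planted benign variants do not.

#' Simulation configuration
#'
#' @param seed Integer RNG seed; a fixed seed makes [simulate_cohort_table()]
#'   fully deterministic.
#' @param cohorts `cohort_registry` (leaf cohorts define the populations
#'   simulated; all leaves must point at the same table name).
#' @param spectrum Variant spectrum: tibble with the canonical record fields
#'   (`chrom, pos, ref, alt, hgvs_c, consequence, ptc_pos, revel, spliceai`),
#'   a `true_class` column, and one `af_<population>` column per leaf cohort
#'   (allele frequencies in [0, 0.01]). `NULL` uses [default_spectrum()].
#' @param flag_rate Fraction of records given an excluding quality flag.
#' @param excluded_flags Flags sampled for flagged records.
#' @return List with class `simulation_config`.
#' @export
simulation_config <- function(seed, cohorts, spectrum = NULL, flag_rate = 0,
                              excluded_flags = c("InbreedingCoeff", "AC0", "RF")) {
  stopifnot(inherits(cohorts, "cohort_registry"))
  leaves <- do.call(rbind, lapply(names(cohorts), function(nm) {
    s <- cohorts[[nm]]
    if (is.null(s$members)) data.frame(population = s$population,
                                       n_individuals = s$n_individuals)
  }))
  if (is.null(spectrum)) spectrum <- default_spectrum(leaves$population)
  af_cols <- paste0("af_", leaves$population)
  missing <- setdiff(af_cols, names(spectrum))
  if (length(missing))
    stop(sprintf("spectrum lacks frequency column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  afs <- as.matrix(spectrum[, af_cols])
  if (any(afs < 0 | afs > 0.01))
    stop("planted allele frequencies must lie in [0, 0.01] (rare-variant regime)",
         call. = FALSE)
  if (flag_rate < 0 || flag_rate > 1) stop("flag_rate must lie in [0,1]", call. = FALSE)
  structure(
    list(seed = as.integer(seed), cohorts = cohorts, leaves = leaves,
         spectrum = spectrum, flag_rate = flag_rate,
         excluded_flags = excluded_flags),
    class = "simulation_config"
  )
}

#' Default synthetic variant spectrum
#'
#' A small mixed spectrum: four NMD-positive truncating variants planted as
#' pathogenic/likely pathogenic (per-population allele frequencies 1e-4 to
#' 4e-4), one rare mid-REVEL missense VUS, one low-REVEL common missense and
#' one synonymous variant planted as benign.
#'
#' @param populations Population labels to generate `af_` columns for.
#' @return Spectrum tibble for [simulation_config()].
#' @export
default_spectrum <- function(populations) {
  base <- tibble(
    chrom = "16",
    pos = 1000L + 100L * (0:6),
    ref = c("C", "TA", "G", "CT", "A", "G", "C"),
    alt = c("T", "T", "A", "C", "G", "C", "G"),
    hgvs_c = sprintf("c.%dsim%d", 100 * (1:7), 1:7),
    hgvs_p = NA_character_,
    consequence = c("nonsense", "frameshift", "nonsense", "frameshift",
                    "missense", "missense", "synonymous"),
    ptc_pos = c(120L, 400L, 900L, 1500L, NA, NA, NA),
    revel = c(NA, NA, NA, NA, 0.45, 0.05, NA),
    spliceai = NA_real_,
    true_class = c("pathogenic", "pathogenic", "likely_pathogenic",
                   "likely_pathogenic", "uncertain_significance",
                   "benign", "benign"),
    af = c(2e-4, 1e-4, 4e-4, 3e-4, 2e-4, 8e-3, 6e-3)
  )
  for (p in populations) base[[paste0("af_", p)]] <- base$af
  base$af <- NULL
  base
}

#' Simulate a cohort allele-count table with its truth table
#'
#' For every spectrum variant and leaf cohort, the allele count is drawn as
#' Binomial(2 * n_individuals, af); AN is 2 * n_individuals. Deterministic
#' under the config's seed.
#'
#' @param config A [simulation_config()].
#' @return List with `variants` (canonical-dialect variant table) and `truth`
#'   (tibble of key, true_class and the planted frequencies).
#' @export
simulate_cohort_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  sp <- config$spectrum
  out <- sp[, c("chrom", "pos", "ref", "alt", "hgvs_c", "hgvs_p",
                "consequence", "ptc_pos", "revel", "spliceai")]
  out$filters <- ""
  if (config$flag_rate > 0) {
    flagged <- stats::runif(nrow(out)) < config$flag_rate
    out$filters[flagged] <- sample(config$excluded_flags, sum(flagged),
                                   replace = TRUE)
  }
  for (i in seq_len(nrow(config$leaves))) {
    pop <- config$leaves$population[i]
    n2 <- 2L * config$leaves$n_individuals[i]
    out[[paste0("ac_", pop)]] <- stats::rbinom(nrow(sp), n2,
                                               sp[[paste0("af_", pop)]])
    out[[paste0("an_", pop)]] <- n2
  }
  variants <- finalize_variant_table(out)
  truth <- tibble(key = variants$key, true_class = sp$true_class)
  for (col in grep("^af_", names(sp), value = TRUE)) truth[[col]] <- sp[[col]]
  list(variants = variants, truth = truth)
}
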