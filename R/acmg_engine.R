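# ACMG/AMP evidence assignment and five-tier combination.
#
# Evidence assignments are tibbles with columns (code, strength, rationale);
# strengths are one of very_strong, strong, moderate, supporting, stand_alone.
# Assignments with strength "none" are dropped before combination.

PATH_STRENGTHS <- c("very_strong", "strong", "moderate", "supporting")
ALL_STRENGTHS <- c(PATH_STRENGTHS, "stand_alone", "none")

FIVE_TIERS <- c("benign", "likely_benign", "uncertain_significance",
                "likely_pathogenic", "pathogenic")

#' Order the five classification tiers for reporting
#'
#' @param x Character vector of tier labels.
#' @return Ordered factor with levels benign < likely_benign <
#'   uncertain_significance < likely_pathogenic < pathogenic.
#' @export
tier_factor <- function(x) factor(x, levels = FIVE_TIERS, ordered = TRUE)

#' Build an evidence assignment
#'
#' @param code ACMG/AMP code (PVS1, PS1..PS4, PM1..PM6, PP1..PP5, BA1,
#'   BS1..BS4, BP1..BP7).
#' @param strength Assigned strength; codes count at their assigned strength,
#'   not their default. Pathogenic-side codes never carry `stand_alone`;
#'   `BA1` only ever carries `stand_alone`.
#' @param rationale Free-text audit string.
#' @return One-row tibble (code, strength, rationale).
#' @export
evidence <- function(code, strength, rationale = "") {
  valid <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
             "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
  if (!code %in% valid) stop(sprintf("unknown evidence code '%s'", code), call. = FALSE)
  if (!strength %in% ALL_STRENGTHS)
    stop(sprintf("unknown strength '%s'", strength), call. = FALSE)
  benign <- grepl("^B", code)
  if (!benign && strength == "stand_alone")
    stop("pathogenic-side codes never carry stand_alone strength", call. = FALSE)
  if (code == "BA1" && !strength %in% c("stand_alone", "none"))
    stop("BA1 only carries stand_alone strength", call. = FALSE)
  tibble(code = code, strength = strength, rationale = rationale)
}

no_evidence <- function() {
  tibble(code = character(), strength = character(), rationale = character())
}

#' Threshold configuration for computational and frequency evidence
#'
#' REVEL tier cutoffs follow the Pejaver et al. (2022) calibration; tier
#' boundaries are inclusive on both the pathogenic side (score >= cutoff
#' earns the tier) and the benign side (score <= cutoff). The SpliceAI
#' spliceogenicity threshold defaults to a maximum delta score of 0.2. PM2
#' uses the population-maximum allele frequency with a ClinGen-style default
#' of 1e-4 at supporting strength.
#'
#' @param spliceai_min SpliceAI delta-score cutoff in (0,1).
#' @param revel_pathogenic Named increasing cutoffs
#'   `c(supporting=, moderate=, strong=)` for PP3.
#' @param revel_benign Named decreasing cutoffs
#'   `c(supporting=, moderate=, strong=, very_strong=)` for BP4.
#' @param pm2_af_max Popmax allele-frequency cutoff (inclusive).
#' @param pm2_strength Strength at which PM2 is assigned.
#' @return List with class `threshold_config`.
#' @export
threshold_config <- function(
    spliceai_min = 0.2,
    revel_pathogenic = c(supporting = 0.644, moderate = 0.773, strong = 0.932),
    revel_benign = c(supporting = 0.290, moderate = 0.183,
                     strong = 0.016, very_strong = 0.003),
    pm2_af_max = 1e-4,
    pm2_strength = "supporting") {
  if (!(spliceai_min > 0 && spliceai_min < 1))
    stop("spliceai_min must lie in (0,1)", call. = FALSE)
  if (is.unsorted(revel_pathogenic, strictly = TRUE))
    stop("pathogenic-side REVEL cutoffs must strictly increase with strength",
         call. = FALSE)
  if (is.unsorted(rev(revel_benign), strictly = TRUE))
    stop("benign-side REVEL cutoffs must strictly decrease with strength",
         call. = FALSE)
  if (!pm2_strength %in% PATH_STRENGTHS)
    stop("pm2_strength must be a pathogenic-side strength", call. = FALSE)
  structure(
    list(spliceai_min = spliceai_min,
         revel_pathogenic = revel_pathogenic,
         revel_benign = revel_benign,
         pm2_af_max = pm2_af_max,
         pm2_strength = pm2_strength),
    class = "threshold_config"
  )
}

#' Read a threshold configuration from YAML
#'
#' @param path YAML file with any subset of the [threshold_config()] fields.
#' @return A `threshold_config`.
#' @export
read_threshold_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("spliceai_min", "pm2_af_max", "pm2_strength"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  for (f in c("revel_pathogenic", "revel_benign"))
    if (!is.null(y[[f]])) args[[f]] <- unlist(y[[f]])
  do.call(threshold_config, args)
}

#' Predict nonsense-mediated decay for a premature termination codon
#'
#' Implements the 50-nt rule: NMD is predicted when the PTC lies more than
#' 50 nt upstream of the last exon-exon junction. Single-exon transcripts
#' never trigger NMD.
#'
#' @param transcript A [transcript_model()].
#' @param ptc_transcript_pos PTC position in transcript coordinates; must
#'   fall within the CDS.
#' @return Logical scalar.
#' @export
predict_nmd <- function(transcript, ptc_transcript_pos) {
  stopifnot(inherits(transcript, "transcript_model"))
  pos <- as.integer(ptc_transcript_pos)
  if (is.na(pos) || pos < transcript$cds_start || pos > transcript$cds_end)
    stop(sprintf("PTC position %s falls outside the CDS (%d-%d)",
                 ptc_transcript_pos, transcript$cds_start, transcript$cds_end),
         call. = FALSE)
  n_exons <- length(transcript$exon_lengths)
  if (n_exons < 2L) return(FALSE)
  last_junction <- sum(transcript$exon_lengths) - transcript$exon_lengths[n_exons]
  (last_junction - pos) > 50L
}

#' Assign PVS1 (loss-of-function) evidence
#'
#' Reduced ClinGen-SVI decision tree: nonsense/frameshift variants predicted
#' to undergo NMD earn PVS1 at very strong, NMD-escaping ones at strong;
#' canonical +/-1,2 splice variants earn very strong when the SpliceAI delta
#' score supports spliceogenicity (or is unavailable) and strong otherwise;
#' initiation-codon variants earn moderate. All other consequences get
#' strength `none`.
#'
#' @param record One-row variant record (list or single-row tibble with
#'   `consequence`, `ptc_pos`, `spliceai`, `key`).
#' @param transcript [transcript_model()]; required for NMD evaluation.
#' @param thresholds [threshold_config()].
#' @return One-row evidence tibble (possibly strength `"none"`).
#' @export
assign_pvs1 <- function(record, transcript = NULL, thresholds = threshold_config()) {
  cons <- record$consequence
  if (cons %in% c("nonsense", "frameshift")) {
    if (is.null(transcript))
      stop(sprintf("variant %s: transcript model required for NMD evaluation",
                   record$key %||% "?"), call. = FALSE)
    if (is.na(record$ptc_pos))
      stop(sprintf("variant %s: PTC transcript position required for NMD evaluation",
                   record$key %||% "?"), call. = FALSE)
    nmd <- predict_nmd(transcript, record$ptc_pos)
    return(evidence("PVS1", if (nmd) "very_strong" else "strong",
                    sprintf("%s, NMD %s", cons, if (nmd) "predicted" else "escaped")))
  }
  if (cons == "canonical_splice") {
    d <- record$spliceai
    str <- if (is.na(d) || d >= thresholds$spliceai_min) "very_strong" else "strong"
    return(evidence("PVS1", str,
                    sprintf("canonical splice site, SpliceAI delta %s",
                            ifelse(is.na(d), "unavailable", format(d)))))
  }
  if (cons == "initiation_codon")
    return(evidence("PVS1", "moderate", "initiation codon"))
  evidence("PVS1", "none", "not a loss-of-function consequence")
}

#' Assign calibrated computational evidence (PP3 / BP4)
#'
#' Missense records are tiered by REVEL: the strongest pathogenic-side tier
#' whose cutoff the score meets (inclusive) gives PP3, the strongest
#' benign-side tier gives BP4, and scores in the uncalibrated middle zone
#' yield no evidence. Non-canonical splice-region records use the SpliceAI
#' delta score: at or above the spliceogenicity threshold, PP3 supporting;
#' below it, BP4 supporting.
#'
#' @inheritParams assign_pvs1
#' @return One-row evidence tibble (possibly strength `"none"`).
#' @export
assign_computational <- function(record, thresholds = threshold_config()) {
  cons <- record$consequence
  if (cons == "missense") {
    r <- record$revel
    if (is.na(r)) return(evidence("PP3", "none", "no REVEL score"))
    if (r < 0 || r > 1)
      stop(sprintf("variant %s: REVEL score %s outside [0,1]",
                   record$key %||% "?", r), call. = FALSE)
    pt <- thresholds$revel_pathogenic
    bt <- thresholds$revel_benign
    hit_p <- names(pt)[r >= pt]
    if (length(hit_p))
      return(evidence("PP3", hit_p[length(hit_p)], sprintf("REVEL %s", r)))
    hit_b <- names(bt)[r <= bt]
    if (length(hit_b))
      return(evidence("BP4", hit_b[length(hit_b)], sprintf("REVEL %s", r)))
    return(evidence("PP3", "none", sprintf("REVEL %s in uncalibrated zone", r)))
  }
  if (cons == "splice_region") {
    d <- record$spliceai
    if (is.na(d)) return(evidence("PP3", "none", "no SpliceAI score"))
    if (d < 0 || d > 1)
      stop(sprintf("variant %s: SpliceAI delta %s outside [0,1]",
                   record$key %||% "?", d), call. = FALSE)
    if (d >= thresholds$spliceai_min)
      return(evidence("PP3", "supporting", sprintf("SpliceAI delta %s", d)))
    return(evidence("BP4", "supporting", sprintf("SpliceAI delta %s", d)))
  }
  evidence("PP3", "none", "not a computational-evidence consequence")
}

#' Assign PM2 (absent or extremely rare in population databases)
#'
#' The population-maximum allele frequency is the maximum of ac/an over
#' populations with an > 0 (0 when the variant is absent everywhere). At or
#' below the configured cutoff (inclusive) PM2 is assigned at the configured
#' strength.
#'
#' @inheritParams assign_pvs1
#' @param populations Optional subset of population labels to consider;
#'   default all `ac_*` pairs on the record.
#' @return One-row evidence tibble (possibly strength `"none"`).
#' @export
assign_pm2 <- function(record, thresholds = threshold_config(), populations = NULL) {
  rec <- as.list(record)
  pops <- populations %||% sub("^ac_", "", grep("^ac_", names(rec), value = TRUE))
  afs <- vapply(pops, function(p) {
    ac <- rec[[paste0("ac_", p)]]; an <- rec[[paste0("an_", p)]]
    if (is.null(ac) || is.null(an) || is.na(an) || an == 0) return(NA_real_)
    ac / an
  }, numeric(1))
  popmax <- if (all(is.na(afs))) 0 else max(afs, na.rm = TRUE)
  if (popmax <= thresholds$pm2_af_max)
    return(evidence("PM2", thresholds$pm2_strength,
                    sprintf("popmax AF %.3g", popmax)))
  evidence("PM2", "none", sprintf("popmax AF %.3g above cutoff", popmax))
}

# strength counts used by the combining rules; additional very-strong
# assignments beyond the first count as strong (the 2015 table has no
# multi-very-strong row and downgrading them would break monotonicity)
strength_counts <- function(strengths) {
  vs <- sum(strengths == "very_strong")
  list(
    vs = as.integer(vs > 0),
    s  = sum(strengths == "strong") + max(vs - 1L, 0L),
    m  = sum(strengths == "moderate"),
    p  = sum(strengths == "supporting"),
    sa = sum(strengths == "stand_alone")
  )
}

#' Combine evidence assignments into a five-tier class
#'
#' Implements the 2015 ACMG/AMP combining-criteria table with
#' strength-modified counting: each code contributes at its assigned
#' strength. Pathogenic requires one very strong plus (one strong, two
#' moderate, one moderate and one supporting, or two supporting), or two
#' strong, or one strong plus (three moderate, two moderate and two
#' supporting, or one moderate and four supporting) - all "at least".
#' Likely pathogenic requires one very strong plus one moderate; one strong
#' plus one moderate or plus two supporting; three moderate; two moderate
#' plus two supporting; or one moderate plus four supporting. Benign requires
#' BA1 stand-alone or two benign strong; likely benign one benign strong plus
#' one benign supporting, or two benign supporting. When both a pathogenic
#' and a benign rule fire, or no rule fires, the class is uncertain
#' significance.
#'
#' @param assignments Evidence tibble (code, strength, ...); strength
#'   `"none"` rows are dropped, duplicate codes are an error.
#' @return A tier label (see [tier_factor()]).
#' @export
combine_evidence <- function(assignments) {
  ev <- assignments[assignments$strength != "none", , drop = FALSE]
  if (!nrow(ev)) return("uncertain_significance")
  if (anyDuplicated(ev$code))
    stop(sprintf("duplicate evidence code(s): %s",
                 paste(unique(ev$code[duplicated(ev$code)]), collapse = ", ")),
         call. = FALSE)
  benign <- grepl("^B", ev$code)
  pc <- strength_counts(ev$strength[!benign])
  bc <- strength_counts(ev$strength[benign])

  path_class <- if (
    (pc$vs >= 1 && (pc$s >= 1 || pc$m >= 2 || (pc$m >= 1 && pc$p >= 1) || pc$p >= 2)) ||
    pc$s >= 2 ||
    (pc$s >= 1 && (pc$m >= 3 || (pc$m >= 2 && pc$p >= 2) || (pc$m >= 1 && pc$p >= 4)))
  ) "pathogenic" else if (
    (pc$vs >= 1 && pc$m >= 1) ||
    (pc$s >= 1 && pc$m >= 1) ||
    (pc$s >= 1 && pc$p >= 2) ||
    pc$m >= 3 ||
    (pc$m >= 2 && pc$p >= 2) ||
    (pc$m >= 1 && pc$p >= 4)
  ) "likely_pathogenic" else NA_character_

  benign_class <- if (bc$sa >= 1 || bc$s >= 2) "benign"
    else if ((bc$s >= 1 && bc$p >= 1) || bc$p >= 2) "likely_benign"
    else NA_character_

  if (!is.na(path_class) && !is.na(benign_class)) return("uncertain_significance")
  if (!is.na(path_class)) return(path_class)
  if (!is.na(benign_class)) return(benign_class)
  "uncertain_significance"
}

#' Classify every record in a variant table
#'
#' Routes loss-of-function consequences through the PVS1 tree, missense and
#' splice-region records through the calibrated computational evidence, adds
#' PM2 from the record's own population counts, merges any pre-annotated
#' evidence (segregation, functional, ... - never auto-assigned), and
#' combines. Deterministic and invariant to record order.
#'
#' @param records Quality-filtered variant table.
#' @param transcript [transcript_model()] used by the NMD rule.
#' @param thresholds [threshold_config()].
#' @param extra_evidence Optional named list, key -> evidence tibble, of
#'   pre-annotated assignments to merge in.
#' @return Tibble `key, class, evidence` (one row per record; `evidence` is a
#'   `code:strength` audit string).
#' @export
classify_all <- function(records, transcript = NULL,
                         thresholds = threshold_config(),
                         extra_evidence = NULL) {
  if (!nrow(records)) {
    return(tibble(key = character(), class = character(), evidence = character()))
  }
  pops <- pop_labels(records)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    ev <- no_evidence()
    if (rec$consequence %in% LOF_CONSEQUENCES) {
      ev <- dplyr::bind_rows(ev, assign_pvs1(rec, transcript, thresholds))
    } else if (rec$consequence %in% c("missense", "splice_region")) {
      ev <- dplyr::bind_rows(ev, assign_computational(rec, thresholds))
    }
    ev <- dplyr::bind_rows(ev, assign_pm2(rec, thresholds, populations = pops))
    if (!is.null(extra_evidence) && !is.null(extra_evidence[[rec$key]]))
      ev <- dplyr::bind_rows(ev, extra_evidence[[rec$key]])
    ev <- ev[ev$strength != "none", , drop = FALSE]
    tibble(key = rec$key,
           class = combine_evidence(ev),
           evidence = paste(sprintf("%s:%s", ev$code, ev$strength), collapse = ";"))
  })
  dplyr::bind_rows(rows)
}

#' Qualifying variants for a prevalence source
#'
#' The prevalence analysis pools alleles over: variants the engine classifies
#' pathogenic or likely pathogenic (`acmg`); variants asserted Pathogenic or
#' Likely_pathogenic in a ClinVar-style table, excluding Conflicting and VUS
#' (`clinvar`); or variants asserted DM in an HGMD-style table, excluding DM?
#' (`hgmd`).
#'
#' @param records Quality-filtered variant table (defines the candidate keys).
#' @param classifications Output of [classify_all()] (used for `acmg`).
#' @param assertions Assertion table from [read_assertion_table()] (used for
#'   `clinvar` / `hgmd`).
#' @param source One of `"acmg"`, `"clinvar"`, `"hgmd"`.
#' @return Character vector of qualifying normalized keys.
#' @export
qualify_by_source <- function(records, classifications = NULL,
                              assertions = NULL, source) {
  if (!source %in% c("acmg", "clinvar", "hgmd"))
    stop(sprintf("unknown source '%s' (use acmg, clinvar or hgmd)", source),
         call. = FALSE)
  keys <- records$key
  if (source == "acmg") {
    if (is.null(classifications)) stop("acmg source needs classifications", call. = FALSE)
    hit <- classifications$key[
      classifications$class %in% c("pathogenic", "likely_pathogenic")]
  } else {
    if (is.null(assertions)) stop(sprintf("%s source needs an assertion table", source),
                                  call. = FALSE)
    wanted <- if (source == "clinvar") c("Pathogenic", "Likely_pathogenic") else "DM"
    hit <- assertions$key[assertions$assertion %in% wanted]
  }
  intersect(keys, hit)
}
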