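# Hardy-Weinberg carrier-prevalence estimation from pooled allele counts.
#
# With total_ac qualifying alleles among 2n chromosomes, the minor (disease)
# allele frequency is q = total_ac / 2n, and under Hardy-Weinberg equilibrium
# (1 = p^2 + 2pq + q^2) heterozygous carriers of an autosomal-dominant allele
# occur at frequency 2pq. Homozygotes (q^2) are excluded, and no small-q
# approximation is applied. The denominator is always 2 x cohort size, not
# per-variant AN, which is retained for QC only.

#' Sum qualifying allele counts in one population
#'
#' @param records Variant table.
#' @param qualifying_keys Normalized keys of qualifying variants.
#' @param population_label Population whose `ac_` column is summed; a
#'   population absent from the table contributes 0.
#' @return Integer total allele count.
#' @export
aggregate_qualifying_ac <- function(records, qualifying_keys, population_label) {
  col <- paste0("ac_", population_label)
  if (!col %in% names(records) || !length(qualifying_keys)) return(0L)
  sum(records[[col]][records$key %in% qualifying_keys], na.rm = TRUE)
}

#' "One carrier in every N" summary
#'
#' @param prevalence Carrier frequency (2pq scale).
#' @return `floor(1 / prevalence)`, or `NA` when the prevalence is zero.
#' @export
one_in_n <- function(prevalence) {
  ifelse(prevalence > 0, floor(1 / prevalence), NA_real_)
}

carrier_transform <- function(q) {
  q <- pmin(q, 0.5)  # 2q(1-q) is monotone on [0, 0.5]; carrier scale caps at 0.5
  2 * q * (1 - q)
}

#' Confidence interval for the carrier prevalence
#'
#' A CI for the allele frequency q is computed from `total_ac` successes in
#' `2 * n_individuals` trials and each bound is mapped through the monotone
#' carrier transform 2q(1-q). The default is the exact (Clopper-Pearson)
#' binomial interval; Wilson score and exact Poisson intervals are available
#' as alternatives. With zero observed alleles the lower bound is 0.
#'
#' @param total_ac Qualifying allele count.
#' @param n_individuals Cohort size (diploid individuals).
#' @param alpha CI level (default 0.05 for 95% intervals).
#' @param method `"exact_binomial"`, `"wilson"` or `"poisson_exact"`.
#' @return Named numeric `c(ci_low, ci_high)` on the carrier scale.
#' @export
prevalence_ci <- function(total_ac, n_individuals, alpha = 0.05,
                          method = c("exact_binomial", "wilson", "poisson_exact")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0,1)", call. = FALSE)
  x <- total_ac
  n <- 2 * n_individuals
  if (x < 0 || x > n) stop("need 0 <= total_ac <= 2 * n_individuals", call. = FALSE)
  bounds <- switch(method,
    exact_binomial = c(
      if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1),
      if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
    ),
    wilson = {
      z <- stats::qnorm(1 - alpha / 2)
      ph <- x / n
      centre <- (ph + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(max(0, centre - half), min(1, centre + half))
    },
    poisson_exact = c(
      if (x == 0) 0 else stats::qgamma(alpha / 2, x) / n,
      stats::qgamma(1 - alpha / 2, x + 1) / n
    )
  )
  out <- carrier_transform(bounds)
  names(out) <- c("ci_low", "ci_high")
  out
}

#' Carrier prevalence point estimate with confidence interval
#'
#' @inheritParams prevalence_ci
#' @param ci_method CI method passed to [prevalence_ci()].
#' @return One-row tibble: `total_ac`, `n_individuals`, `q`, `p`,
#'   `prevalence` (2pq), `ci_low`, `ci_high`, `one_in_n`, `alpha`, `ci_method`.
#' @examples
#' carrier_prevalence(227, 125748)  # global: 0.18%, one carrier in 554
#' @export
carrier_prevalence <- function(total_ac, n_individuals, alpha = 0.05,
                               ci_method = "exact_binomial") {
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L)
    stop("n_individuals must be >= 1", call. = FALSE)
  total_ac <- as.integer(total_ac)
  if (is.na(total_ac) || total_ac < 0L || total_ac > 2L * n_individuals)
    stop("need 0 <= total_ac <= 2 * n_individuals", call. = FALSE)
  q <- total_ac / (2 * n_individuals)
  prev <- 2 * q * (1 - q)
  ci <- prevalence_ci(total_ac, n_individuals, alpha, ci_method)
  tibble(
    total_ac = total_ac, n_individuals = n_individuals,
    q = q, p = 1 - q, prevalence = prev,
    ci_low = unname(ci[1]), ci_high = unname(ci[2]),
    one_in_n = one_in_n(prev),
    alpha = alpha, ci_method = ci_method
  )
}

#' Pool allele counts and cohort sizes over component cohorts
#'
#' @param components List of `c(total_ac, n_individuals)` pairs (or a two-
#'   column matrix / data frame).
#' @return Named numeric `c(total_ac, n_individuals)` of element-wise sums.
#' @examples
#' pool_cohorts(list(c(2, 1909), c(10, 5305), c(0, 1722)))  # 12 / 8936
#' @export
pool_cohorts <- function(components) {
  if (is.data.frame(components) || is.matrix(components))
    components <- lapply(seq_len(nrow(components)), function(i)
      as.numeric(components[i, 1:2]))
  if (!length(components)) stop("components must be non-empty", call. = FALSE)
  m <- do.call(rbind, lapply(components, function(x) as.numeric(x[1:2])))
  c(total_ac = sum(m[, 1]), n_individuals = sum(m[, 2]))
}

#' Project the number of carriers in a census population
#'
#' Applies a prevalence already rounded to 0.01 percentage points to a
#' population size and rounds to the nearest thousand, the convention used
#' when extrapolating database carrier frequencies to national populations.
#'
#' @param prevalence_rounded_pct Prevalence in percent, rounded to 2 dp.
#' @param population_size Census population size.
#' @return Projected carrier count (nearest thousand).
#' @examples
#' project_carriers(0.13, 51800000)  # ~67,000 carriers
#' @export
project_carriers <- function(prevalence_rounded_pct, population_size) {
  round(population_size * prevalence_rounded_pct / 100 / 1000) * 1000
}

#' Round half away from zero
#'
#' Rendering convention for prevalence percentages (R's `round()` rounds
#' half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Format a proportion as a percentage string
#'
#' Two decimal places, half rounded away from zero ("0.18" for 0.0018036).
#'
#' @param x Proportion (not percent).
#' @return Character vector.
#' @export
format_pct <- function(x) {
  sprintf("%.2f", round_half_up(100 * x, 2))
}
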