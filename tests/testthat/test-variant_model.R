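# Variant normalization and domain-type validation.

# reference helpers for the brute-force left-alignment oracle
apply_edit <- function(context, context_start, pos, ref, alt) {
  i <- pos - context_start + 1
  stopifnot(substr(context, i, i + nchar(ref) - 1) == ref)
  paste0(substr(context, 1, i - 1), alt,
         substr(context, i + nchar(ref), nchar(context)))
}

# enumerate every representation of an edit on `context` equivalent to the
# given one and return the leftmost parsimonious (shortest-allele) form
brute_force_normal <- function(context, context_start, pos, ref, alt) {
  target <- apply_edit(context, context_start, pos, ref, alt)
  best <- NULL
  L <- nchar(context)
  for (p in seq_len(L)) {
    for (rl in 1:4) {
      if (p + rl - 1 > L) next
      r <- substr(context, p, p + rl - 1)
      for (al in 1:4) {
        cand <- expand.grid(rep(list(c("A", "C", "G", "T")), al))
        alts <- apply(cand, 1, paste0, collapse = "")
        for (a in alts) {
          if (a == r) next
          if (apply_edit(context, context_start, context_start + p - 1, r, a) != target) next
          len <- nchar(r) + nchar(a)
          gp <- context_start + p - 1
          if (is.null(best) || len < best$len ||
              (len == best$len && gp < best$pos)) {
            best <- list(pos = gp, ref = r, alt = a, len = len)
          }
        }
      }
    }
  }
  best[c("pos", "ref", "alt")]
}

test_that("normalization trims shared bases and is the identity on normal SNVs", {
  v <- normalize_variant("16", 100, "AT", "AG")
  expect_equal(v$pos, 101L)
  expect_equal(v$ref, "T")
  expect_equal(v$alt, "G")

  v2 <- normalize_variant("16", 100, "A", "G")
  expect_equal(unlist(v2[c("pos", "ref", "alt")], use.names = FALSE),
               c("100", "A", "G"))

  v3 <- normalize_variant("16", 100, "CAA", "CA")
  expect_equal(v3$pos, 100L)
  expect_equal(v3$ref, "CA")
  expect_equal(v3$alt, "C")
})

test_that("context-aware normalization matches the brute-force enumeration oracle", {
  cases <- list(
    # 1-bp deletion inside an A-run: must shift to the run's left anchor
    list(ctx = "TGCAAAAG", start = 95L, pos = 100L, ref = "AA", alt = "A"),
    list(ctx = "TGCAAAAG", start = 95L, pos = 98L, ref = "AA", alt = "A"),
    # insertion into the same run
    list(ctx = "TGCAAAAG", start = 95L, pos = 100L, ref = "A", alt = "AA"),
    # CA-repeat deletion
    list(ctx = "TTCACACAG", start = 50L, pos = 53L, ref = "ACA", alt = "A"),
    # non-repeat indel stays put
    list(ctx = "TTGACCA", start = 10L, pos = 12L, ref = "GA", alt = "G")
  )
  for (cs in cases) {
    got <- normalize_variant("16", cs$pos, cs$ref, cs$alt,
                             context = cs$ctx, context_start = cs$start)
    want <- brute_force_normal(cs$ctx, cs$start, cs$pos, cs$ref, cs$alt)
    expect_equal(got$pos, want$pos, info = cs$ctx)
    expect_equal(got$ref, want$ref, info = cs$ctx)
    expect_equal(got$alt, want$alt, info = cs$ctx)
  }
})

test_that("normalization is idempotent on random indel representations", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:60) {
    ref <- paste0(sample(bases, sample(1:4, 1), replace = TRUE), collapse = "")
    alt <- paste0(sample(bases, sample(1:4, 1), replace = TRUE), collapse = "")
    if (ref == alt) next
    pos <- sample(100:200, 1)
    v1 <- normalize_variant("2", pos, ref, alt)
    v2 <- normalize_variant("2", v1$pos, v1$ref, v1$alt)
    expect_equal(v1$key, v2$key)
  }
})

test_that("padded representations of one edit normalize to the same key", {
  set.seed(23)
  bases <- c("A", "C", "G", "T")
  for (i in 1:40) {
    ctx <- paste0(sample(bases, 40, replace = TRUE), collapse = "")
    start <- 500L
    pos <- start + sample(10:25, 1)
    rl <- sample(1:3, 1)
    ref <- substr(ctx, pos - start + 1, pos - start + rl)
    alt <- paste0(sample(bases, sample(1:3, 1), replace = TRUE), collapse = "")
    if (alt == ref) next
    v1 <- normalize_variant("2", pos, ref, alt, context = ctx, context_start = start)
    # pad with k genuine flanking bases from the reference on each side
    for (k in 0:5) {
      left <- substr(ctx, pos - start + 1 - k, pos - start)
      right <- substr(ctx, pos - start + 1 + rl, pos - start + rl + k)
      vp <- normalize_variant("2", pos - k, paste0(left, ref, right),
                              paste0(left, alt, right),
                              context = ctx, context_start = start)
      expect_equal(vp$key, v1$key, info = sprintf("%s>%s k=%d", ref, alt, k))
    }
  }
})

test_that("malformed alleles are rejected with the offending field named", {
  expect_error(normalize_variant("16", 100, "AN", "A"), "ref")
  expect_error(normalize_variant("16", 100, "A", "a"), "alt")
  expect_error(normalize_variant("16", 100, "", "A"), "ref")
  expect_error(normalize_variant("16", 100, "A", "A"), "identical")
  expect_error(normalize_variant("16", 0, "A", "G"), "pos")
})

test_that("transcript and cohort constructors enforce their invariants", {
  expect_error(transcript_model(c(100, 0), 1, 50), "exon lengths")
  expect_error(transcript_model(c(100, 100), 150, 100), "cds_start")
  tr <- transcript_model(c(100, 100), 10, 190)
  expect_s3_class(tr, "transcript_model")

  expect_error(cohort_spec("x", 0, table = "t", population = "p"),
               "n_individuals")
  expect_error(cohort_spec("x", 5), "table and a population")
  # pooled cohort size must equal the member sum
  expect_error(cohort_registry(list(
    cohort_spec("a", 10, table = "t", population = "a"),
    cohort_spec("b", 20, table = "t", population = "b"),
    cohort_spec("ab", 31, members = c("a", "b"))
  )), "members sum")
  reg <- cohort_registry(list(
    cohort_spec("a", 10, table = "t", population = "a"),
    cohort_spec("b", 20, table = "t", population = "b"),
    cohort_spec("ab", 30, members = c("a", "b"))
  ))
  leaves <- cohort_leaves(reg, "ab")
  expect_equal(sum(leaves$n_individuals), 30)
})
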