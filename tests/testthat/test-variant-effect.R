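test_that("variant records validate and apply substitutions", {
  ref <- "ACGTACGTAC"
  v <- variant_record(ref, c(0L, 9L), c("A", "C"), c("G", "T"))
  alt <- apply_variants(v)
  expect_equal(alt, "GCGTACGTAT")
  expect_equal(nchar(alt), nchar(ref))
  # empty substitution list returns the reference
  expect_equal(apply_variants(variant_record(ref)), ref)
  # Hamming distance 1 for a single substitution
  one <- apply_variants(variant_record(ref, 3L, "T", "A"))
  expect_equal(sum(strsplit(one, "")[[1]] != strsplit(ref, "")[[1]]), 1L)
  expect_error(variant_record(ref, 0L, "C", "G"), "mismatch.*position 0")
  expect_error(variant_record(ref, 10L, "A", "G"), "outside")
  expect_error(variant_record(ref, c(1L, 1L), c("C", "C"), c("G", "T")),
               "duplicate")
})

test_that("variant effects are antisymmetric with zero self-effect", {
  m <- build_legnet(tiny_config(), seed = 3)
  ref <- random_insert(1)
  v0 <- variant_record(ref)
  expect_identical(variant_effect(m, v0, desk_flank()), 0)
  pos <- 10L
  base <- substr(ref, pos + 1, pos + 1)
  alt_base <- setdiff(c("A", "C", "G", "T"), base)[1]
  v <- variant_record(ref, pos, base, alt_base)
  alt <- apply_variants(v)
  back <- variant_record(alt, pos, alt_base, base)
  expect_equal(apply_variants(back), ref)
  eff <- variant_effect(m, v, desk_flank())
  eff_back <- variant_effect(m, back, desk_flank())
  expect_equal(eff, -eff_back, tolerance = 1e-6)
})

test_that("variant tables parse into grouped records", {
  refs <- stats::setNames(random_insert(2, 20), c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  b1 <- substr(refs[["s1"]], 3, 3)
  b2 <- substr(refs[["s2"]], 1, 1)
  b3 <- substr(refs[["s2"]], 8, 8)
  alt <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  writeLines(c(sprintf("s1\t2\t%s\t%s", b1, alt(b1)),
               sprintf("s2\t0\t%s\t%s", b2, alt(b2)),
               sprintf("s2\t7\t%s\t%s", b3, alt(b3))), path)
  vs <- read_variant_table(path, refs)
  expect_named(vs, c("s1", "s2"))
  expect_length(vs$s2$position, 2L)
  writeLines("missing\t0\tA\tC", path)
  expect_error(read_variant_table(path, refs), "without a reference")
})

test_that("drift evaluation groups by substitution count", {
  m <- build_legnet(tiny_config(), seed = 4)
  set.seed(9)
  refs <- random_insert(18)
  n_subs <- rep(1:3, each = 6)
  alts <- vapply(seq_along(refs), function(i)
    mutate_sequence(refs[i], n_subs[i]), "")
  pairs <- data.frame(ref = refs, alt = alts, observed = 0, n_subs = n_subs)
  first <- drift_evaluation(m, pairs, desk_flank())
  predicted <- attr(first, "predicted")
  # observations equal to predictions: perfect correlation per group
  pairs$observed <- predicted
  rep <- drift_evaluation(m, pairs, desk_flank())
  expect_equal(rep$pearson, rep(1, 3), tolerance = 1e-9)
  expect_equal(rep$spearman, rep(1, 3), tolerance = 1e-9)
  expect_equal(rep$n, rep(6L, 3))
  # negated observations flip the sign
  pairs$observed <- -predicted
  neg <- drift_evaluation(m, pairs, desk_flank())
  expect_equal(neg$pearson, rep(-1, 3), tolerance = 1e-9)
  # undersized groups are reported as missing with a reason
  small <- drift_evaluation(m, pairs[1:2, ], desk_flank())
  expect_true(is.na(small$pearson))
  expect_match(small$note, "fewer")
})

test_that("destroying an activating motif lowers predicted expression", {
  study <- desk_study()
  cfg <- study$cfg
  j <- which(cfg$motif_effects > 0)[1]
  pwm <- cfg$motifs[[j]]
  consensus <- c("A", "C", "G", "T")[apply(pwm, 2, which.max)]
  top <- which.max(apply(pwm, 2, max))  # highest-information position
  effects <- local({
    set.seed(77)
    replicate(100, {
      base <- random_insert(1)
      pos <- sample(80 - length(consensus), 1)
      planted <- paste0(substr(base, 1, pos),
                        paste(consensus, collapse = ""),
                        substr(base, pos + length(consensus) + 1, 80))
      hit <- pos + top
      ref_base <- substr(planted, hit, hit)
      worst <- c("A", "C", "G", "T")[which.min(pwm[, top])]
      if (worst == ref_base)
        worst <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
      v <- variant_record(planted, hit - 1L, ref_base, worst)
      variant_effect(study$model, v, desk_flank())
    })
  })
  expect_lt(median(effects), 0)
})

test_that("single-substitution effects are the hardest drift group", {
  study <- desk_study()
  cfg <- study$cfg
  wins <- 0L
  for (s in 1:3) {
    set.seed(200 + s)
    refs <- random_insert(120)
    n_subs <- rep(1:3, each = 40)
    alts <- vapply(seq_along(refs), function(i)
      mutate_sequence(refs[i], n_subs[i]), "")
    observed <- oracle_expression(alts, cfg) - oracle_expression(refs, cfg)
    rep <- drift_evaluation(study$model,
                            data.frame(ref = refs, alt = alts,
                                       observed = observed,
                                       n_subs = n_subs),
                            desk_flank())
    if (rep$pearson[rep$n_subs == 1] == min(rep$pearson)) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
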