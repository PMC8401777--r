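test_that("the worked abstract example decomposes exactly", {
  fx <- fig5_fixture()
  expect_equal(tanimoto_kernel(fx$support$core, fx$test$core), 2 / 3)
  expect_equal(tanimoto_kernel(fx$support$sub, fx$test$sub), 2 / 3)
  expect_equal(mmp_kernel(fx$support, fx$test), 4 / 9)
  # each shared (core, substituent) feature pair carries one ninth
  expect_equal(frag_fc_mmp(fx$support, 1, fx$test, 1, 3), 1 / 9)
  expect_equal(frag_fc_mmp(fx$support, 1, fx$test, 2, 3), 0)  # core 2 absent

  model <- manual_ac_svm(list(fx$support), dual_coef = 1, b = 0)
  ex <- explain(model, fx$test)
  per <- ex$per_feature
  get <- function(seg, id)
    per$contribution[per$segment == seg & per$identifier == id]
  expect_equal(get("core", 1), 1 / 9)
  expect_equal(get("core", 3), 1 / 9)
  expect_equal(get("sub_xor", 2), 1 / 9)
  expect_equal(get("sub_xor", 3), 1 / 9)
  expect_equal(get("sub_xor", 1), 0)  # present in test only: no overlap
  expect_equal(sum(per$contribution), 4 / 9)
  expect_equal(ex$kernel_sum, 4 / 9)
  expect_equal(ex$decision, 4 / 9)
})

test_that("Tanimoto fragment contributions follow the shared-feature rule", {
  expect_equal(frag_fc_tanimoto(c(1, 2, 3), 1, c(1, 3), 1), 1 / 3)
  expect_equal(frag_fc_tanimoto(c(1, 2, 3), 1, c(1, 3), 4), 0)
  expect_equal(frag_fc_tanimoto(c(2, 3), 1, c(1, 3), 1), 0)
  # summed over shared features the Tanimoto kernel is recovered
  s <- sum(vapply(c(1, 3), function(d)
    frag_fc_tanimoto(c(1, 2, 3), 1, c(1, 3), d), numeric(1)))
  expect_equal(s, tanimoto_kernel(c(1, 2, 3), c(1, 3)))
})

test_that("plain-Tanimoto explanations split K = 1 evenly", {
  x <- mmpcliff:::new_mmp_fp(core = c(1, 2), sub = c(5, 6))
  model <- manual_ac_svm(list(x), dual_coef = 1, b = 0, kernel = "tanimoto")
  ex <- explain(model, x)
  expect_equal(ex$kernel_sum, 1)
  expect_equal(ex$per_feature$contribution, rep(1 / 4, 4))
  # fully disjoint instance: decision falls back to the bias alone
  z <- mmpcliff:::new_mmp_fp(core = 9, sub = 99)
  model_b <- manual_ac_svm(list(x), dual_coef = 1, b = 0.25,
                           kernel = "tanimoto")
  ez <- explain(model_b, z)
  expect_equal(sum(ez$per_feature$contribution), 0)
  expect_equal(ez$decision, -0.25)
})

test_that("vectorised decomposition equals the exhaustive oracle", {
  set.seed(113)
  for (rep in 1:25) {
    n_sv <- sample(1:6, 1)
    svs <- replicate(n_sv, random_fp(), simplify = FALSE)
    coefs <- runif(n_sv, -2, 2)
    b <- runif(1, -1, 1)
    x <- random_fp()
    model <- manual_ac_svm(svs, coefs, b = b)
    ex <- explain(model, x)
    or <- oracle_decompose_mmp(svs, coefs, x)
    expect_equal(ex$kernel_sum, or$kernel_sum, tolerance = 1e-12)
    for (r in seq_len(nrow(ex$per_feature))) {
      key <- paste0(ifelse(ex$per_feature$segment[r] == "core", "c", "s"),
                    ex$per_feature$tagged[r])
      want <- or$contrib[[key]]
      expect_equal(ex$per_feature$contribution[r],
                   if (is.null(want)) 0 else want, tolerance = 1e-12)
    }
    # exactness: contributions minus bias reproduce the decision value
    K <- vapply(svs, function(s) mmp_kernel(s, x), numeric(1))
    expect_equal(sum(ex$per_feature$contribution) - b, sum(coefs * K) - b,
                 tolerance = 1e-9)
    expect_equal(ex$decision, sum(coefs * K) - b, tolerance = 1e-9)
  }
})

test_that("with identical cores the product kernel collapses", {
  # every fingerprint shares one fully overlapping core: the substituent
  # contributions equal half the plain-Tanimoto values (the other half of
  # every cross-term goes, by the split rule, to the core features)
  core <- c(1, 2, 3)
  set.seed(7)
  svs <- replicate(4, mmpcliff:::new_mmp_fp(core = core,
                                            sub = sample(1:10, 4)),
                   simplify = FALSE)
  coefs <- runif(4, -1, 1)
  x <- mmpcliff:::new_mmp_fp(core = core, sub = sample(1:10, 5))
  ex <- explain(manual_ac_svm(svs, coefs), x)
  sub_rows <- ex$per_feature[ex$per_feature$segment != "core", ]
  flat <- oracle_fc_tanimoto(lapply(svs, `[[`, "sub"), coefs, x$sub)
  expect_equal(sub_rows$contribution[match(x$sub, sub_rows$tagged)],
               unname(flat) / 2, tolerance = 1e-12)
  # and the kernel total matches the substituent-only Tanimoto model
  expect_equal(ex$kernel_sum, sum(flat), tolerance = 1e-12)
})

test_that("explanations follow the kernel the model was trained with", {
  fx <- fig5_fixture()
  m_tan <- manual_ac_svm(list(fx$support), 1, kernel = "tanimoto")
  ex <- explain(m_tan, fx$test)
  expect_equal(ex$kernel_sum,
               tanimoto_kernel(mmpcliff:::flatten_fp(fx$support),
                               mmpcliff:::flatten_fp(fx$test)))
})

test_that("atom mapping conserves every mapped contribution", {
  mm <- fixture_mmps()
  fit <- ac_svm(mm, C = 1)
  for (i in c(1, 3, nrow(mm))) {
    ex <- explain(fit, mm[i, ])
    aw <- map_to_structure(ex)
    expect_equal(sum(aw$weights$weight) + aw$remainder, ex$kernel_sum,
                 tolerance = 1e-9 * max(1, abs(ex$kernel_sum)))
    # chemistry fingerprints have complete back-maps: no remainder
    expect_equal(aw$remainder, 0)
  }
})

test_that("atom mapping divides evenly and accumulates overlaps", {
  # one feature spanning 2 atoms + 1 bond, contribution 0.6
  fp <- mmpcliff:::new_mmp_fp(
    core = 1, sub = numeric(0),
    backmap = list(`1` = list(core = list(list(atoms = c(1, 2), bonds = 1)))))
  ex <- structure(list(per_feature = data.frame(
    segment = "core", identifier = 1, tagged = 1, contribution = 0.6,
    bit = 1), kernel_sum = 0.6, bias = 0, decision = 0.6, pred = "AC",
    fp = fp), class = "ac_explanation")
  aw <- map_to_structure(ex)
  expect_equal(sort(aw$weights$weight), rep(0.2, 3))

  # two 1-atom features overlapping on the same atom: weights accumulate
  fp2 <- mmpcliff:::new_mmp_fp(
    core = c(1, 2), sub = numeric(0),
    backmap = list(
      `1` = list(core = list(list(atoms = 1, bonds = integer(0)))),
      `2` = list(core = list(list(atoms = 1, bonds = integer(0))))))
  ex2 <- structure(list(per_feature = data.frame(
    segment = "core", identifier = c(1, 2), tagged = c(1, 2),
    contribution = c(0.3, -0.1), bit = c(1, 2)),
    kernel_sum = 0.2, bias = 0, decision = 0.2, pred = "AC", fp = fp2),
    class = "ac_explanation")
  aw2 <- map_to_structure(ex2)
  expect_equal(aw2$weights$weight, 0.2)

  # features without a back-map go to the remainder, not silently dropped
  fx <- fig5_fixture()
  exa <- explain(manual_ac_svm(list(fx$support), 1), fx$test)
  awa <- map_to_structure(exa)
  expect_equal(nrow(awa$weights), 0)
  expect_equal(awa$remainder, exa$kernel_sum)
})

test_that("AND-channel contributions split across both substituents first", {
  fp <- fingerprint_mmp("*c1ccccc1", "*CC", "*CCO")
  off <- mmpcliff:::.AND_OFFSET
  and_id <- fp$sub[fp$sub >= off][1]
  ex <- structure(list(per_feature = data.frame(
    segment = "sub_and", identifier = and_id - off, tagged = and_id,
    contribution = 0.4, bit = NA), kernel_sum = 0.4, bias = 0,
    decision = 0.4, pred = "AC", fp = fp), class = "ac_explanation")
  aw <- map_to_structure(ex)
  for (role in c("sub_low", "sub_high")) {
    w <- aw$weights$weight[aw$weights$role == role]
    expect_equal(sum(w), 0.2, tolerance = 1e-12)
  }
})
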