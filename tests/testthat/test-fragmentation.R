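test_that("single cuts of ethylbenzene recover the two expected splits", {
  cuts <- enumerate_single_cuts("CCc1ccccc1")
  expect_equal(nrow(cuts), 2)
  expect_true(any(cuts$core == "*c1ccccc1" & cuts$sub == "*CC"))
  expect_true(any(cuts$core == "*Cc1ccccc1" & cuts$sub == "*C"))
})

test_that("molecules without acyclic single bonds yield no cuts", {
  expect_equal(nrow(enumerate_single_cuts("c1ccccc1")), 0)  # all ring bonds
  expect_equal(nrow(enumerate_single_cuts("C")), 0)          # single atom
  # double bonds are not cut
  expect_equal(nrow(enumerate_single_cuts("C=C")), 0)
})

test_that("the 13-heavy-atom substituent bound filters cuts", {
  # C30 chain: middle cuts leave a smaller side of 14 or 15 atoms and are
  # suppressed; symmetric cuts collapse to one row each
  smi <- strrep("C", 30)
  cuts <- enumerate_single_cuts(smi)
  expect_true(all(cuts$sub_atoms <= 13))
  expect_equal(nrow(cuts), 13)
  expect_equal(sort(cuts$sub_atoms), 1:13)
  # with a raised bound the middle cuts appear
  cuts20 <- enumerate_single_cuts(smi, max_sub_atoms = 20L)
  expect_equal(nrow(cuts20), 15)
})

test_that("every fragmentation reassembles to its parent", {
  smis <- c("CCc1ccccc1", "Oc1ccc(CC(C)C)cc1", "O=C(N)c1ccc(CCl)cc1",
            "Cc1nc2ccccc2n1CC", "NC(=O)c1csc(C3CCCC3)c1")
  for (smi in smis) {
    parent <- mmpcliff:::canonical_smiles(smi)
    cuts <- enumerate_single_cuts(smi)
    expect_gt(nrow(cuts), 0)
    for (k in seq_len(nrow(cuts))) {
      expect_equal(mmpcliff:::reattach_fragments(cuts$core[k], cuts$sub[k]),
                   parent, label = paste(smi, "cut", k))
    }
  }
})

test_that("phenol/anisole form one AC MMP through the phenyl core", {
  cpds <- data.frame(cid = c("phenol", "anisole"),
                     smiles = c("Oc1ccccc1", "COc1ccccc1"),
                     potency = c(5.0, 7.5))
  mm <- generate_mmps(cpds)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$core, "*c1ccccc1")
  expect_equal(sort(c(mm$sub_low, mm$sub_high)), c("*O", "*OC"))
  expect_equal(mm$delta_p, 2.5)
  expect_equal(mm$label, "AC")
  expect_equal(mm$cid_low, "phenol")
})

test_that("size constraints and self-pairs suppress MMPs", {
  # substituent difference of 9 heavy atoms: no MMP
  cpds <- data.frame(cid = c("m", "d"),
                     smiles = c("Oc1ccccc1C", paste0("Oc1ccccc1", strrep("C", 10))),
                     potency = c(5, 8))
  expect_equal(nrow(generate_mmps(cpds)), 0)
  # a compound cannot pair with a structural duplicate of itself
  cpds2 <- data.frame(cid = c("x", "y"),
                      smiles = c("CCc1ccccc1", "CCc1ccccc1"),
                      potency = c(5, 8))
  expect_equal(nrow(generate_mmps(cpds2)), 0)
})

test_that("ambiguous pairs are dropped and output is order-invariant", {
  cpds <- data.frame(cid = c("a", "b"),
                     smiles = c("Oc1ccccc1", "COc1ccccc1"),
                     potency = c(5.0, 6.5))  # delta 1.5: ambiguous
  expect_equal(nrow(generate_mmps(cpds)), 0)

  cp <- generate_cliff_dataset(cliff_spec(n_series = 2L, series_size = 4L,
                                          seed = 9L))
  mm1 <- generate_mmps(cp)
  mm2 <- generate_mmps(cp[rev(seq_len(nrow(cp))), ])
  expect_equal(as.data.frame(mm1), as.data.frame(mm2))
})

test_that("retained MMPs respect both printed size constraints", {
  mm <- fixture_mmps()
  expect_gt(nrow(mm), 0)
  for (k in seq_len(nrow(mm))) {
    ha_lo <- mmpcliff:::count_heavy_atoms_smiles(mm$sub_low[k])
    ha_hi <- mmpcliff:::count_heavy_atoms_smiles(mm$sub_high[k])
    expect_lte(ha_lo, 13)
    expect_lte(ha_hi, 13)
    expect_lte(abs(ha_lo - ha_hi), 8)
    expect_false(mm$sub_low[k] == mm$sub_high[k])
  }
})

test_that("series grouping removes single-class series", {
  mk <- function(core, label)
    data.frame(cid_low = paste0("l", seq_along(label)),
               cid_high = paste0("h", seq_along(label)), core = core,
               sub_low = "*C", sub_high = "*O", delta_p = 2.5, label = label)
  mm <- rbind(mk("A", c("AC", "NON_AC")), mk("B", "AC"))
  class(mm) <- c("mmp_table", "data.frame")
  ser <- group_into_mms(mm)
  expect_equal(names(ser), "A")
  expect_equal(nrow(ser$A), 2)
  # all-AC series removed; empty input gives empty output
  mm2 <- mk("C", c("AC", "AC")); class(mm2) <- c("mmp_table", "data.frame")
  expect_equal(length(group_into_mms(mm2)), 0)
  expect_equal(length(group_into_mms(mm[0, ])), 0)
})
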