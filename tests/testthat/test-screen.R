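cfg <- screen_config()

summ <- function(genes, tpm) {
  tibble::tibble(gene = genes, mean_tpm = tpm, n_samples = 4L,
                 expressed = tpm > cfg$expressed_cutoff,
                 high = tpm > cfg$high_cutoff,
                 very_high = tpm > cfg$very_high_cutoff)
}

test_that("quadrant assignment uses strict boundaries", {
  expect_equal(assign_quadrant(15, 12), "high_high")
  expect_equal(assign_quadrant(10, 12), "low_high")
  expect_equal(assign_quadrant(12, 10), "high_low")
  expect_equal(assign_quadrant(2.5, 0), "low_low")
  expect_equal(assign_quadrant(c(15, 1), c(1, 15)),
               c("high_low", "low_high"))
  expect_error(assign_quadrant(-1, 5), "non-negative")
})

test_that("identify_receptors filters on expression and curation", {
  db <- validate_pair_db(toy_db())
  rcv <- summ(c("ITGB1", "SDC4", "CD48", "CHRNB2", "GPR137", "BG1"),
              c(5, 2, 0.1, 30, 8, 500))
  rec <- identify_receptors(rcv, db, config = cfg)
  # SDC4 at exactly 2 TPM is not expressed; CD48 below; GPR137/BG1 not in db
  expect_equal(rec$gene, c("CHRNB2", "ITGB1")) # sorted by TPM desc
  expect_false(any(rec$orphan))

  rec2 <- identify_receptors(rcv, db, curation_list(exclude = "ITGB1"), cfg)
  expect_equal(rec2$gene, "CHRNB2")

  # force-include creates an expressed orphan; below-cutoff includes stay out
  rec3 <- identify_receptors(rcv, db,
                             curation_list(include = c("GPR137", "CD48")), cfg)
  expect_true("GPR137" %in% rec3$gene)
  expect_false("CD48" %in% rec3$gene)
  expect_true(rec3$orphan[rec3$gene == "GPR137"])
  expect_equal(find_orphans(rec3)$gene, "GPR137")
})

test_that("build_pair_table joins sender expression and flags missing ligands", {
  db <- validate_pair_db(toy_db())
  rcv <- summ(c("ITGB1", "SDC4"), c(20, 15))
  snd <- summ(c("MDK", "CXCL10"), c(15, 0.5)) # CCL5 absent
  pairs <- build_pair_table(identify_receptors(rcv, db, config = cfg),
                            snd, db, cfg)
  expect_equal(nrow(pairs), 4L)
  mdk_itgb1 <- pairs[pairs$receptor == "ITGB1" & pairs$ligand == "MDK", ]
  expect_equal(mdk_itgb1$quadrant, "high_high")
  expect_true(mdk_itgb1$plotted)
  cxcl10 <- pairs[pairs$ligand == "CXCL10", ]
  expect_equal(cxcl10$quadrant, "high_low")
  expect_false(cxcl10$plotted) # ligand 0.5 is not > 1
  ccl5 <- pairs[pairs$ligand == "CCL5", ]
  expect_true(ccl5$ligand_missing)
  expect_equal(ccl5$ligand_tpm, 0)
  expect_equal(ccl5$quadrant, "high_low")
})

test_that("rank_top is descending with alphabetical tie-break", {
  s <- summ(c("A", "B", "C"), c(5, 7, 7))
  expect_equal(rank_top(s, 2)$gene, c("B", "C"))
  expect_equal(rank_top(s, 10)$gene, c("B", "C", "A"))
  expect_identical(rank_top(s, 2), rank_top(s, 2)) # stable under repetition
})

test_that("identify_ligand_genes inventories expressed protein ligands only", {
  db <- validate_pair_db(toy_db())
  rcv <- summ(c("MDK", "IL18", "ACHE", "CCL5"), c(30, 1, 50, 2.5))
  inv <- identify_ligand_genes(rcv, db, cfg)
  # ACHE is a proxy (excluded); IL18 under cutoff; ranked descending
  expect_equal(inv$gene, c("MDK", "CCL5"))
})

test_that("screen operations match brute-force oracles on random instances", {
  set.seed(33)
  for (rep in 1:200) {
    inst <- random_instance()
    rec <- identify_receptors(inst$receiver, inst$db, config = inst$config)
    pairs <- build_pair_table(rec, inst$sender, inst$db, inst$config)
    oracle <- oracle_pair_table(inst$receiver, inst$sender, inst$db,
                                inst$config)
    if (is.null(oracle)) {
      expect_equal(nrow(pairs), 0L)
    } else {
      expect_equal(
        as.data.frame(pairs[c("category", "receptor", "receptor_tpm",
                              "ligand", "ligand_kind", "ligand_tpm",
                              "ligand_missing", "quadrant", "plotted")]),
        oracle, ignore_attr = TRUE)
      for (cat in unique(oracle$category)) {
        expect_equal(unname(count_quadrants(pairs, cat)),
                     unname(oracle_count_quadrants(oracle, cat)))
      }
    }
    expect_equal(rank_top(inst$receiver, 4)$gene,
                 oracle_rank_top(inst$receiver, 4))
    inc <- paste0("X", 1:2)
    rec_inc <- identify_receptors(
      dplyr::bind_rows(inst$receiver, summ(inc, c(50, 1))),
      inst$db, curation_list(include = inc), inst$config)
    expect_equal(sort(find_orphans(rec_inc)$gene),
                 oracle_orphans(dplyr::bind_rows(inst$receiver,
                                                 summ(inc, c(50, 1))),
                                inst$db, inc, inst$config))
  }
})

test_that("quadrant counts partition the category pair total", {
  set.seed(44)
  for (rep in 1:50) {
    inst <- random_instance()
    rec <- identify_receptors(inst$receiver, inst$db, config = inst$config)
    pairs <- build_pair_table(rec, inst$sender, inst$db, inst$config)
    for (cat in unique(pairs$category)) {
      expect_equal(sum(count_quadrants(pairs, cat)),
                   sum(pairs$category == cat))
    }
  }
  expect_equal(unname(count_quadrants(
    build_pair_table(summ(character(), numeric())[0, ],
                     summ("A", 1), validate_pair_db(toy_db()), cfg),
    "cytokine_chemokine")), rep(0L, 4))
  expect_error(count_quadrants(tibble::tibble(), "hormone"), "unknown category")
})

test_that("cutoff monotonicity: stricter cutoffs never enlarge the sets", {
  set.seed(55)
  for (rep in 1:30) {
    inst <- random_instance()
    lo <- inst$config
    hi <- screen_config(high_cutoff = 25)
    loose <- screen_config(expressed_cutoff = 1)
    rec_lo <- identify_receptors(inst$receiver, inst$db, config = lo)
    rec_loose <- identify_receptors(inst$receiver, inst$db, config = loose)
    expect_gte(nrow(rec_loose), nrow(rec_lo))
    p_lo <- build_pair_table(rec_lo, inst$sender, inst$db, lo)
    p_hi <- build_pair_table(rec_lo, inst$sender, inst$db, hi)
    expect_lte(sum(p_hi$quadrant == "high_high"),
               sum(p_lo$quadrant == "high_high"))
  }
})

test_that("the full screen is deterministic: identical inputs, identical atlas", {
  sim <- simulate_crosstalk(sim_config(n_genes = 500, seed = 9))
  a1 <- suppressMessages(lr_screen(sim$receiver, sim$sender, db = sim$pairs,
                                   curation = sim$curation))
  a2 <- suppressMessages(lr_screen(sim$receiver, sim$sender, db = sim$pairs,
                                   curation = sim$curation))
  expect_identical(serialize(a1, NULL), serialize(a2, NULL))
})

test_that("proxy pairs are kept out of the headline protein counts", {
  db <- validate_pair_db(toy_db())
  rcv <- toy_tpm(c("ITGB1", "CHRNB2"), s1 = c(20, 50), s2 = c(20, 50))
  snd <- toy_tpm(c("MDK", "ACHE"), s1 = c(15, 90), s2 = c(15, 90))
  atlas <- lr_screen(rcv, snd, db = db)
  qc <- atlas$quadrant_counts
  sm <- qc[qc$category == "small_molecule" & qc$quadrant == "high_high", ]
  expect_equal(sm$n_all, 1L)      # proxy quadrant still computed
  expect_equal(sm$n_protein, 0L)  # but excluded from the protein headline
  expect_equal(glance(atlas)$n_high_high_protein, 1L) # ITGB1-MDK only
})
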