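test_that("peptide masses match published and hand-derived values", {
  expect_equal(peptide_mass("WGF"), 408.18, tolerance = 0.005)
  expect_equal(peptide_mass("PL"), 228.15, tolerance = 0.005)
  expect_equal(peptide_mass("G"), 75.032, tolerance = 1e-3)
  expect_gt(peptide_mass("PL", "average"), peptide_mass("PL", "monoisotopic"))
  expect_error(peptide_mass("PXL"), "invalid residue")
})

test_that("mass is additive up to one water per chain", {
  withr::local_seed(13)
  for (i in 1:50) {
    a <- random_sequence(sample(1:15, 1))
    b <- random_sequence(sample(1:15, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - 18.01056,
                 tolerance = 1e-6)
  }
})

test_that("motif flags reflect sequence positions", {
  f <- motif_flags("QQPL")
  expect_true(f$pro_penultimate)
  expect_false(f$pro_c_terminal)
  f <- motif_flags("PAL")
  expect_true(f$pro_n_terminal)
  expect_true(f$n_term_hydrophobic)
  expect_equal(f$hydrophobic_fraction, 1)
  f <- motif_flags("GG")
  expect_false(any(unlist(f[-1])))
  expect_equal(f$hydrophobic_fraction, 0)
  # single-residue peptides: positional flags false, fraction defined
  f <- motif_flags("P")
  expect_false(f$pro_n_terminal)
  expect_false(f$pro_penultimate)
  expect_false(f$pro_c_terminal)
  expect_equal(f$hydrophobic_fraction, 1)
})

test_that("score ingestion parses the published table dialect", {
  s <- ingest_scores(table2_path())
  expect_equal(nrow(s), 47L)
  w <- s[s$sequence == "WGF", ]
  expect_equal(w$caco2_log, -6.147)
  expect_equal(w$mdck_cm_s, 8.9e-6)
  expect_equal(w$ppb_percent, 67.13)
  # both missing markers become explicit NA
  expect_true(is.na(s$dppiv_probability[s$sequence == "SF"]))
  expect_true(is.na(s$dppiv_probability[s$sequence == "SWQQPIVGGVGF"]))
  # ASCII scientific notation parses like the typeset form
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sequence,bioactivity,mdck_cm_s", "AA,0.9,8.90E-6"), csv)
  expect_equal(ingest_scores(csv)$mdck_cm_s, 8.9e-6)
  # empty table, duplicates, junk numerics
  writeLines("sequence,bioactivity,mdck_cm_s", csv)
  expect_equal(nrow(ingest_scores(csv)), 0L)
  writeLines(c("sequence,bioactivity", "AA,0.9", "AA,0.8"), csv)
  expect_error(ingest_scores(csv), "duplicate")
  writeLines(c("sequence,bioactivity", "AA,zero"), csv)
  expect_error(ingest_scores(csv), "unparseable")
})

test_that("MDCK banding assigns boundaries to the medium band", {
  expect_equal(classify_permeability(8.9e-6), "medium")
  expect_equal(classify_permeability(0), "low")
  expect_equal(classify_permeability(2.1e-5), "high")
  expect_equal(classify_permeability(2e-6), "medium")
  expect_equal(classify_permeability(20e-6), "medium")
  expect_error(classify_permeability(-1e-6), "non-negative")
})

test_that("screening filters on bioactivity and ranks by DPP-IV probability", {
  s <- ingest_scores(table2_path())
  out <- screen_peptides(s)
  expect_equal(nrow(out), 47L)
  expect_equal(head(out$sequence, 5), c("PAL", "QQPL", "PL", "PSL", "SSPL"))
  expect_equal(out$dppiv_probability[1], 0.724)
  # missing probabilities sort last
  expect_true(all(which(is.na(out$dppiv_probability)) >
                    max(which(!is.na(out$dppiv_probability) ))))
  # output is a subset of input
  expect_true(all(out$sequence %in% s$sequence))
  # ranking is a total order: no duplicated (prob, bioactivity, sequence)
  expect_false(any(duplicated(out$sequence)))
  # all-low bioactivity yields an empty table
  s2 <- s
  s2$bioactivity <- 0.4
  expect_equal(nrow(screen_peptides(s2)), 0L)
  # strictness of the cut: exactly at threshold is dropped
  s3 <- s
  s3$bioactivity[1] <- 0.5
  expect_equal(nrow(screen_peptides(s3)), 46L)
  # optional DPP-IV cut
  out2 <- screen_peptides(s, screen_config(dppiv_min = 0.4))
  expect_equal(out2$sequence, c("PAL", "QQPL", "PL"))
})
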