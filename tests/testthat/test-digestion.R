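test_that("cleavage sites follow the P1/P1' rule", {
  expect_equal(cleavage_sites("AAKAA", trypsin_rule()), 3L)
  expect_equal(cleavage_sites("KPR", trypsin_rule()), integer(0))
  expect_equal(cleavage_sites("GFPL", pepsin_rule()), integer(0))
  expect_equal(cleavage_sites("A", trypsin_rule()), integer(0))
  expect_error(cleavage_sites("", trypsin_rule()), "non-empty")
  # blockers only suppress, never create
  expect_equal(cleavage_sites("APAPA", trypsin_rule()), integer(0))
})

test_that("digest splits correctly and reports DH", {
  d <- digest(protein_record("p", "AAKAA"), trypsin_rule())
  expect_equal(d$peptides$sequence, c("AAK", "AA"))
  expect_equal(d$dh_percent, 25)
  expect_equal(d$cleaved_bonds, nrow(d$peptides) - 1L)

  d0 <- digest(protein_record("p", "AAAAA"), trypsin_rule())
  expect_equal(d0$peptides$sequence, "AAAAA")
  expect_equal(d0$dh_percent, 0)

  dall <- digest(protein_record("p", "FKLR"), list(pepsin_rule(), trypsin_rule()))
  expect_equal(dall$peptides$sequence, c("F", "K", "L", "R"))
  expect_equal(dall$dh_percent, 100)

  expect_error(digest(protein_record("p", "AAK"), list()), "at least one")
  expect_error(digest(protein_record("p", "AAK"), trypsin_rule(), mode = "x"))
})

test_that("concurrent and sequential modes agree for position-local rules", {
  withr::local_seed(42)
  for (i in 1:50) {
    seqc <- random_sequence(sample(10:120, 1))
    p <- protein_record("s", seqc)
    dc <- digest(p, list(pepsin_rule(), trypsin_rule()), mode = "concurrent")
    ds <- digest(p, list(pepsin_rule(), trypsin_rule()), mode = "sequential")
    expect_identical(dc$peptides, ds$peptides)
  }
})

test_that("digest agrees with the naive oracle and conserves sequence", {
  withr::local_seed(101)
  rules <- list(pepsin_rule(), trypsin_rule())
  for (i in 1:1000) {
    seqc <- random_sequence(sample(2:80, 1))
    d <- digest(protein_record("s", seqc), rules)
    o <- oracle_digest(seqc, rules)
    expect_identical(d$peptides$sequence, o$peptides)
    expect_identical(d$cleaved_bonds, o$cleaved)
    # conservation: concatenation reproduces the parent; coverage contiguous
    expect_identical(paste(d$peptides$sequence, collapse = ""), seqc)
    expect_identical(d$peptides$start[1], 0L)
    expect_identical(d$peptides$end[nrow(d$peptides)], nchar(seqc))
    if (nrow(d$peptides) > 1L)
      expect_identical(d$peptides$start[-1], d$peptides$end[-nrow(d$peptides)])
  }
})

test_that("adding an enzyme never decreases the degree of hydrolysis", {
  withr::local_seed(202)
  for (i in 1:200) {
    seqc <- random_sequence(sample(5:100, 1))
    p <- protein_record("s", seqc)
    dh1 <- digest(p, trypsin_rule())$dh_percent
    dh2 <- digest(p, list(trypsin_rule(), pepsin_rule()))$dh_percent
    expect_gte(dh2, dh1)
    expect_true(dh2 >= 0 && dh2 <= 100)
  }
})

test_that("census pools peptides and recounts like the oracle", {
  # direct example: lengths 3, 3, 7
  d <- digest(protein_record("p", "AAKAAKAAAAAAA"), trypsin_rule())
  expect_equal(nchar(d$peptides$sequence), c(3, 3, 7))
  cen <- census(d)
  expect_equal(cen$total_peptides, 3L)
  expect_equal(cen$fraction_below(5), 200 / 3, tolerance = 1e-9)
  expect_equal(sum(cen$length_histogram), cen$total_peptides)

  withr::local_seed(303)
  results <- lapply(1:10, function(i)
    digest(protein_record(paste0("p", i), random_sequence(sample(20:100, 1))),
           list(pepsin_rule(), trypsin_rule())))
  cen <- census(results)
  lens <- unlist(lapply(results, function(r) nchar(r$peptides$sequence)))
  expect_equal(cen$total_peptides, length(lens))
  for (k in c(2, 5, 10))
    expect_equal(cen$fraction_below(k), 100 * sum(lens < k) / length(lens))
  # bond-weighted DH across proteins
  expect_equal(cen$dh_percent,
               100 * sum(sapply(results, `[[`, "cleaved_bonds")) /
                 sum(sapply(results, `[[`, "total_bonds")))
})
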