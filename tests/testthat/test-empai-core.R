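test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(tryptic_digest("AKRP"), c("AK", "RP"))
  expect_equal(tryptic_digest("MGGG"), "MGGG")
  expect_equal(tryptic_digest("AKCK", digestion_rule(missed_cleavages = 1)),
               c("AK", "CK", "AKCK"))
  expect_error(tryptic_digest(""), "non-empty")
  expect_error(tryptic_digest("AKZ"), "Z")
})

test_that("digestion at 0 missed cleavages matches the position-scan oracle", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_aa_sequence(sample(5:60, 1))
    got <- tryptic_digest(s)
    expect_equal(got, digest_oracle(s), info = s)
    expect_equal(paste(got, collapse = ""), s, info = s)
  }
})

test_that("missed-cleavage digests emit every merged run of adjacent fragments", {
  s <- "AKCKDKEK"
  base <- tryptic_digest(s)
  m2 <- tryptic_digest(s, digestion_rule(missed_cleavages = 2))
  runs1 <- vapply(seq_len(length(base) - 1),
                  function(i) paste(base[i:(i + 1)], collapse = ""),
                  character(1))
  runs2 <- vapply(seq_len(length(base) - 2),
                  function(i) paste(base[i:(i + 2)], collapse = ""),
                  character(1))
  expect_setequal(m2, c(base, runs1, runs2))
})

test_that("observable counting applies the monoisotopic mass window", {
  # GG = 2 x 57.02146 + 18.01056 = 132.05 Da, below the default window
  expect_equal(peptide_mass("GG"), 132.05349, tolerance = 1e-5)
  expect_equal(count_observable("GG"), 0)
  # an all-pass window counts distinct peptides only
  wide <- digestion_rule(observable_window = c(0.1, 1e6))
  expect_equal(count_observable(c("AK", "AK", "CK"), wide), 2)
  # non-standard residues are dropped from the observable set with a warning
  expect_message(n <- count_observable(c("AXK"), wide), "non-standard")
  expect_equal(n, 0)
})

test_that("emPAI follows its closed form and bounds", {
  expect_equal(compute_empai(0, 7), 0)
  expect_equal(compute_empai(5, 5), 9)
  expect_equal(compute_empai(3, 10), 0.99526, tolerance = 1e-5)
  expect_error(compute_empai(3, 0), "observable")
  expect_error(compute_empai(11, 10), "exceeds")
  # strictly increasing in n_observed, bounded in [0, 9]
  vals <- compute_empai(0:12, 12)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 9))
})

test_that("cell normalization is linear and preserves zero", {
  expect_equal(normalize_to_cells(0.5, 5e4, 5e4), 0.5)
  expect_equal(normalize_to_cells(0.5, 2.5e4, 5e4), 1.0)
  expect_equal(normalize_to_cells(0, 123, 5e4), 0)
  expect_error(normalize_to_cells(0.5, 0, 5e4), "positive")
})

test_that("fraction tables assemble emPAI per protein and fraction", {
  # a deterministic protein built from 10 distinct observable tryptic blocks
  # (each 8-mer mass sits inside the default 800-4500 Da window)
  blocks <- c("DDDDDDDK", "EEEEEEEK", "FFFFFFFK", "HHHHHHHK", "IIIIIIIK",
              "LLLLLLLK", "MMMMMMMK", "NNNNNNNK", "QQQQQQQK", "TTTTTTTK")
  seqfull <- paste(blocks, collapse = "")
  prot <- data.frame(protein_id = "p1", description = "",
                     sequence = seqfull, stringsAsFactors = FALSE)
  expect_equal(count_observable(tryptic_digest(seqfull)), 10)

  rows <- data.frame(fraction_id = "COS", protein_id = "p1",
                     peptide_sequence = blocks[1:3], replicate_id = 1L,
                     stringsAsFactors = FALSE)
  tab <- build_fraction_table(rows, prot)
  expect_equal(tab$COS, 0.99526, tolerance = 1e-4)
  expect_equal(tab$CIS, 0)
  expect_equal(tab$ROS, 0)

  # two replicates contributing the same peptide count once
  rows2 <- rbind(rows, transform(rows[1, ], replicate_id = 2L))
  tab2 <- build_fraction_table(rows2, prot)
  expect_equal(tab2$COS, tab$COS)

  # peptides not in the digest are excluded with a warning
  rows3 <- rbind(rows, data.frame(fraction_id = "COS", protein_id = "p1",
                                  peptide_sequence = "WWWWWWWK",
                                  replicate_id = 1L))
  expect_message(tab3 <- build_fraction_table(rows3, prot), "not found")
  expect_equal(tab3$COS, tab$COS)

  # empty identification table gives all zeros over the proteome
  empty <- rows[0, ]
  tab0 <- build_fraction_table(empty, prot)
  expect_true(all(tab0[, c("ROS", "RIS", "COS", "CIS")] == 0))

  # unknown protein errors
  rows4 <- transform(rows, protein_id = "ghost")
  expect_error(build_fraction_table(rows4, prot), "ghost")
})

test_that("emPAI rank-tracks true abundance under the synthetic detection model", {
  rho <- vapply(1:3, function(s) {
    prot <- simulate_proteome(200, seed = s)
    ids <- simulate_fraction_tables(prot, seed = s + 100)
    tab <- suppressMessages(build_fraction_table(
      ids, prot[, c("protein_id", "description", "sequence")]))
    amounts <- attr(ids, "true_amounts")
    det <- tab$COS > 0
    cor(amounts[tab$protein_id[det], "COS"], tab$COS[det],
        method = "spearman")
  }, numeric(1))
  expect_gt(median(rho), 0.9)
})
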