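test_that("tryptic digestion enumerates fully tryptic peptides with missed cleavages", {
  # no cleavage site: the whole chain, zero missed
  d <- digest(protein_sequence("p", "AAGA"), max_missed = 3)
  expect_length(d, 1L)
  expect_equal(d[[1]]$sequence, "AAGA")
  expect_equal(d[[1]]$missed_cleavages, 0L)

  # forced enumeration for AKRGK at one missed cleavage
  d <- digest(protein_sequence("p", "AKRGK"), max_missed = 1)
  expect_setequal(vapply(d, `[[`, character(1), "sequence"),
                  c("AK", "R", "GK", "AKR", "RGK"))

  # the C-helix region: 0-missed AFETVAIDR and 1-missed full peptide
  d <- digest(protein_sequence("chx", "AFETVAIDRLDR", 582L), max_missed = 5)
  seqs <- vapply(d, `[[`, character(1), "sequence")
  expect_true("AFETVAIDR" %in% seqs)
  expect_true("AFETVAIDRLDR" %in% seqs)
  full <- d[[which(seqs == "AFETVAIDRLDR")]]
  expect_equal(c(full$start_residue, full$end_residue), c(582L, 593L))
  expect_equal(full$missed_cleavages, 1L)

  # proline suppression
  d <- digest(protein_sequence("p", "AKPGR"), max_missed = 0)
  expect_setequal(vapply(d, `[[`, character(1), "sequence"), c("AKPGR"))

  expect_error(protein_sequence("p", "ABZ"), "non-standard residue")
})

test_that("digestion matches brute-force enumeration and is monotone in missed cleavages", {
  set.seed(42)
  for (rep_i in 1:8) {
    seqstr <- rand_peptide_seq(sample(8:20, 1))
    prev <- -1L
    for (m in 0:3) {
      d <- digest(protein_sequence("p", seqstr), max_missed = m)
      got <- sort(unique(vapply(d, `[[`, character(1), "sequence")))
      expect_equal(got, oracle_digest(seqstr, m))
      expect_gte(length(d), prev)
      prev <- length(d)
      expect_false(any(duplicated(sapply(d, function(p)
        paste(p$start_residue, p$end_residue)))))
    }
    # concatenating the 0-missed products reconstructs the protein
    d0 <- digest(protein_sequence("p", seqstr), max_missed = 0)
    expect_equal(paste(vapply(d0, `[[`, character(1), "sequence"), collapse = ""),
                 seqstr)
  }
})

test_that("peptide spans carry correct protein numbering", {
  d <- digest(protein_sequence("s3", "SWFVVDFISSIPVDYIFLIVEKGMDSEVYK", 220L),
              max_missed = 5)
  key <- vapply(d, function(p) sprintf("%d-%d", p$start_residue, p$end_residue),
                character(1))
  expect_true("220-241" %in% key)
  expect_true("220-249" %in% key)
  p <- d[[which(key == "220-241")]]
  expect_equal(p$sequence, "SWFVVDFISSIPVDYIFLIVEK")
  expect_equal(residue_at(p, 234), "Y")
  expect_equal(residue_at(p, 227), "I")
})

test_that("monoisotopic peptide mass and m/z follow the standard constants", {
  pep <- peptide("LDR", 591L)
  expect_equal(peptide_mass(pep), 402.2227, tolerance = 1e-6)
  expect_equal(mz(peptide_mass(pep), 1), 403.2300, tolerance = 1e-6)
  expect_equal(mz(1000.0, 2), 501.007276, tolerance = 1e-9)
  expect_error(mz(500, 0), "charge")

  # round trip m/z -> neutral
  M <- peptide_mass(peptide("SWFVVDFISSIPVDYIFLIVEK", 220L))
  expect_equal(mz(M, 1) * 1 - 1 * proton_mass, M, tolerance = 1e-10)

  # adduct additivity is exact
  lab1 <- peptide("LDR", 591L, adduct_positions = 591L)
  lab2 <- peptide("LDR", 591L, adduct_positions = c(591L, 593L))
  expect_equal(peptide_mass(lab1) - peptide_mass(pep), 216.08)
  expect_equal(peptide_mass(lab2) - peptide_mass(pep), 2 * 216.08)

  # fixed modification handling and unknown-mod error
  nem <- peptide("ACK", 1L, fixed_mods = data.frame(position = 2L, name = "NEM"))
  expect_equal(peptide_mass(nem) - peptide_mass(peptide("ACK", 1L)),
               125.04768, tolerance = 1e-6)
  bad <- peptide("ACK", 1L, fixed_mods = data.frame(position = 2L, name = "nope"))
  expect_error(peptide_mass(bad), "unknown modification")
})

test_that("b/y fragment series satisfies complementarity and span-shift logic", {
  s3 <- peptide("SWFVVDFISSIPVDYIFLIVEK", 220L)
  fi <- fragment_ions(s3, adduct_positions = 234L)
  y <- fi[fi$series == "y", ]
  expect_equal(y$adduct_count[y$index == 7], 0L)
  expect_equal(y$adduct_count[y$index == 8], 1L)
  expect_equal(y$mz[y$index == 8] - y$mz[y$index == 7],
               aa_monoisotopic_masses[["Y"]] + 216.08, tolerance = 1e-6)

  # dipeptide with C-terminal adduct
  dp <- peptide("LK", 1L)
  fd <- fragment_ions(dp, adduct_positions = 2L)
  expect_equal(fd$adduct_count[fd$series == "y" & fd$index == 1], 1L)
  expect_equal(fd$adduct_count[fd$series == "b" & fd$index == 1], 0L)

  # complementarity identity on random unlabeled peptides
  set.seed(11)
  for (r in 1:10) {
    seqstr <- rand_peptide_seq(sample(3:15, 1))
    pp <- peptide(seqstr, 1L)
    fi <- fragment_ions(pp)
    M <- peptide_mass(pp)
    L <- nchar(seqstr)
    for (i in 1:(L - 1)) {
      bi <- fi$mz[fi$series == "b" & fi$index == i]
      yi <- fi$mz[fi$series == "y" & fi$index == L - i]
      expect_equal(bi + yi, M + 2 * proton_mass, tolerance = 1e-9)
    }
  }
})

test_that("smallest containing y index matches brute-force span search", {
  s3 <- peptide("SWFVVDFISSIPVDYIFLIVEK", 220L)
  expect_equal(min_containing_y_index(s3, 234), 8L)
  expect_equal(min_containing_y_index(s3, s3$end_residue), 1L)
  expect_error(min_containing_y_index(s3, 250), "outside")

  set.seed(5)
  for (r in 1:20) {
    L <- sample(3:25, 1)
    start <- sample(1:500, 1)
    pp <- peptide(rand_peptide_seq(L), start)
    res <- sample(start:(start + L - 2), 1)  # end residue gives index 1 trivially
    expect_equal(min_containing_y_index(pp, res),
                 oracle_min_y(start, start + L - 1, res))
  }
})

test_that("digest table reports masses and charge-state m/z", {
  d <- digest(protein_sequence("chx", "AFETVAIDRLDR", 582L), max_missed = 1)
  tab <- digest_table(d, charges = 1:3)
  ldr <- tab[tab$sequence == "LDR", ]
  expect_equal(ldr$neutral_mass, 402.2227, tolerance = 1e-6)
  expect_equal(ldr$mz_z1, 403.2300, tolerance = 1e-6)
  expect_equal(ldr$mz_z2, (402.2227 + 2 * proton_mass) / 2, tolerance = 1e-6)
})
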