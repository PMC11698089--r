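DELTA <- 216.08
S6_SEQ <- "AMSHMLCIGYGAQAPVSMSDLWITMLSMIVGATCYAMFVGHATALIQSLDSSR"

test_that("site-defining y-ion evidence pins the adduct to a unique residue", {
  # unshifted y1..y7 plus shifted y8..y10 identify residue 234
  sp <- oracle_spectrum("SWFVVDFISSIPVDYIFLIVEK", 220, 234, DELTA,
                        keep = function(series, index)
                          series == "y" && index <= 10)
  res <- localize(sp, peptide("SWFVVDFISSIPVDYIFLIVEK", 220L), 1)
  expect_equal(res$best_sites, list(234L))
  expect_equal(res$ambiguity_set, 234L)
  expect_true(any(res$evidence$site_determining))
})

test_that("a missing distinguishing ion yields the two-residue ambiguity call", {
  # y ions through y18 unshifted and y20+ shifted, y19 withheld:
  # C385 and Y386 cannot be separated
  sp <- oracle_spectrum(S6_SEQ, 352, 385, DELTA,
                        keep = function(series, index)
                          series == "y" && index != 19)
  res <- localize(sp, peptide(S6_SEQ, 352L), 1)
  expect_setequal(unlist(res$best_sites), c(385L, 386L))
  expect_equal(res$ambiguity_set, c(385L, 386L))

  # restoring y19 resolves the call
  sp_full <- oracle_spectrum(S6_SEQ, 352, 385, DELTA,
                             keep = function(series, index) series == "y")
  res <- localize(sp_full, peptide(S6_SEQ, 352L), 1)
  expect_equal(res$best_sites, list(385L))
})

test_that("unlabeled y3 and labeled y4 define the A-helix methionine site", {
  sp <- oracle_spectrum("LVATMPLFANADPNFVTAMLSK", 469, 487, DELTA,
                        keep = function(series, index) series == "y")
  res <- localize(sp, peptide("LVATMPLFANADPNFVTAMLSK", 469L), 1)
  expect_equal(res$best_sites, list(487L))
  ev <- res$evidence[res$evidence$series == "y", ]
  expect_equal(ev$adduct_count[ev$index == 3], 0L)
  expect_equal(ev$adduct_count[ev$index == 4], 1L)
})

test_that("dipeptide and degenerate spectra behave as declared", {
  dp <- peptide("LK", 100L)
  sp <- oracle_spectrum("LK", 100, 101, DELTA,
                        keep = function(series, index) series == "y")
  res <- localize(sp, dp, 1)
  expect_equal(res$best_sites, list(101L))

  empty <- localize(list(mz = numeric(0), intensity = numeric(0)), dp, 1)
  expect_equal(nrow(empty$evidence), 0L)
  expect_equal(empty$ambiguity_set, c(100L, 101L))
})

test_that("site-determining ions equal the brute-force span-intersection set", {
  s3 <- peptide("SWFVVDFISSIPVDYIFLIVEK", 220L)
  sdi <- site_determining_ions(s3, 234L, 227L)
  y <- sort(sdi$index[sdi$series == "y"])
  b <- sort(sdi$index[sdi$series == "b"])
  expect_equal(y, 8:14)
  expect_equal(b, 8:14)

  s6 <- peptide(S6_SEQ, 352L)
  sdi <- site_determining_ions(s6, 385L, 386L)
  expect_equal(sdi$index[sdi$series == "y"], 19L)
  expect_equal(sdi$index[sdi$series == "b"], 34L)

  dp <- peptide("LK", 1L)
  sdi <- site_determining_ions(dp, 1L, 2L)
  expect_setequal(paste0(sdi$series, sdi$index), c("b1", "y1"))

  expect_error(site_determining_ions(s3, 234L, 234L), "identical")

  # random peptides against a direct span-intersection oracle
  set.seed(77)
  for (r in 1:10) {
    L <- sample(4:12, 1)
    pp <- peptide(rand_peptide_seq(L), 50L)
    sites <- sample(50:(50 + L - 1), 2)
    sdi <- site_determining_ions(pp, sites[1], sites[2])
    ora <- oracle_by_ions(pp$sequence, 50, sites[1], DELTA)
    orb <- oracle_by_ions(pp$sequence, 50, sites[2], DELTA)
    differ <- ora$n_add != orb$n_add
    expect_equal(nrow(sdi), sum(differ))
    expect_setequal(paste0(sdi$series, sdi$index),
                    paste0(ora$series[differ], ora$index[differ]))
  }
})

test_that("deleting the ions separating adjacent residues widens the ambiguity set", {
  pep <- peptide("SWFVVDFISSIPVDYIFLIVEK", 220L)
  p <- 233L
  sep <- site_determining_ions(pep, p, p + 1L)
  drop_keys <- paste0(sep$series, sep$index)
  sp <- oracle_spectrum(pep$sequence, 220, p, DELTA,
                        keep = function(series, index)
                          !(paste0(series, index) %in% drop_keys))
  res <- localize(sp, pep, 1)
  expect_true(all(c(p, p + 1L) %in% res$ambiguity_set))
})

test_that("noiseless doubly-labeled spectra localize both sites", {
  pep <- peptide("SWFVVDFISSIPVDYIFLIVEK", 220L)
  sp <- oracle_spectrum(pep$sequence, 220, c(227, 234), DELTA)
  res <- localize(sp, pep, 2)
  expect_equal(res$best_sites, list(c(227L, 234L)))
})
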