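kras <- kras_fixture()

test_that("non-spliced enumeration counts follow the closed form", {
  s8 <- substrate("s8", "ACDEFGHI")
  expect_equal(nrow(enumerate_nonspliced(s8, c(8, 12))), 1L)
  s7 <- substrate("s7", "ACDEFGH")
  expect_equal(nrow(enumerate_nonspliced(s7, c(8, 12))), 0L)
  # L = 34, lengths 8..12: sum(34 - l + 1)
  n34 <- nrow(enumerate_nonspliced(kras$g12v, c(8, 12)))
  expect_equal(n34, sum(34 - 8:12 + 1))
  expect_equal(n34, 125L)
  expect_error(enumerate_nonspliced(s8, c(5, 3)), "length range")
})

test_that("cis enumeration matches the brute-force oracle and flag contract", {
  s9 <- substrate("s9", "ACDEFGHIK")
  got <- enumerate_cis(s9, c(8, 8), include_reverse = FALSE)
  want <- oracle_products("ACDEFGHIK", 8, 8, include_reverse = FALSE)
  want <- want[want$category == "cis-normal", ]
  expect_setequal(pkg_decomp_keys(got, 1L), decomp_keys(want))
  # reverse flag contract: no decomposition with sr2 before sr1
  expect_false(any(got$sr2_end < got$sr1_start, na.rm = TRUE))
  got_r <- enumerate_cis(s9, c(8, 8), include_reverse = TRUE)
  expect_true(any(got_r$category == "cis-reverse"))
  want_r <- oracle_products("ACDEFGHIK", 8, 8, include_reverse = TRUE)
  want_r <- want_r[want_r$category != "non-spliced", ]
  expect_setequal(pkg_decomp_keys(got_r, 1L), decomp_keys(want_r))
})

test_that("the KRAS G12V enumeration contains the spliced epitope candidate", {
  cis <- enumerate_cis(kras$g12v, c(8, 12), include_reverse = FALSE)
  hit <- cis[cis$sequence == "KLVVGAVGV", ]
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$category == "cis-normal"))
})

test_that("peptide mapping reproduces the three-decomposition worked example", {
  parent <- substrate("KRAS5-14_G12V", "KLVVVGAVGV", numbering_offset = 5L)
  dec <- map_peptide("KLVVGAVGV", parent)
  expect_equal(nrow(dec), 3L)
  expect_true(all(dec$category == "cis-normal"))
  expect_true(all(dec$intervening_length == 1L))
  expect_setequal(dec$psp_p1, c(6L, 7L, 8L))
  expect_true(all(dec$scs_p1 == 14L))
  expect_equal(classify_peptide(dec), "cis")
})

test_that("classification follows non-spliced > cis > trans precedence", {
  sub <- substrate("s", "ACDEFGHIKL")
  # substring: has cis decompositions too, but classifies non-spliced
  dec <- map_peptide("CDEFGH", sub)
  expect_true(any(dec$category == "non-spliced"))
  expect_equal(classify_peptide(dec), "non-spliced")
  # doubled substrate sequence needs two molecules
  sub5 <- substrate("s5", "ACDEF")
  dec_t <- map_peptide("ACDEFACDEF", sub5)
  expect_gt(nrow(dec_t), 0)
  expect_true(all(dec_t$category == "trans"))
  expect_equal(classify_peptide(dec_t), "trans")
  # unmappable peptide
  expect_equal(classify_peptide(map_peptide("WWWWYYYY", sub)), "unmapped")
})

test_that("mapping agrees with the brute-force oracle on random substrates", {
  set.seed(42)
  for (i in 1:25) {
    L <- sample(4:12, 1)
    seqstr <- random_substrate_seq(L)
    sub <- substrate(paste0("r", i), seqstr,
                     numbering_offset = sample(1:50, 1))
    lr <- c(2L, sample(3:8, 1))
    enum <- rbind(enumerate_nonspliced(sub, lr), enumerate_cis(sub, lr))
    want_enum <- oracle_products(seqstr, lr[1], lr[2])
    expect_setequal(pkg_decomp_keys(enum, sub$numbering_offset),
                    decomp_keys(want_enum))
    for (pep in unique(enum$sequence)[seq_len(min(12, length(unique(enum$sequence))))]) {
      got <- map_peptide(pep, sub)
      want <- oracle_map(pep, seqstr)
      expect_setequal(pkg_decomp_keys(got, sub$numbering_offset),
                      decomp_keys(want))
    }
  }
})

test_that("parental coordinate reporting honors the numbering offset", {
  set.seed(7)
  seqstr <- random_substrate_seq(10)
  for (off in c(1L, 2L, 37L)) {
    sub <- substrate("o", seqstr, numbering_offset = off)
    ns <- enumerate_nonspliced(sub, c(3, 5))
    expect_equal(min(ns$sr1_start), off)
    expect_equal(max(ns$sr1_end), off + 9L)
    expect_equal(ns$sequence[1],
                 substr(seqstr, ns$sr1_start[1] - off + 1L,
                        ns$sr1_end[1] - off + 1L))
  }
})

test_that("mutation filter keeps exactly decompositions covering the site", {
  cis <- enumerate_cis(kras$g12v, c(8, 12), include_reverse = FALSE)
  ns <- enumerate_nonspliced(kras$g12v, c(8, 12))
  all_prod <- rbind(ns, cis)
  kept <- filter_mutation(all_prod, kras$g12v, 12, "V")
  expect_true(all(kept$carries_mutation))
  expect_true("KLVVVGAVGV" %in% kept$sequence)
  expect_true("KLVVGAVGV" %in% kept$sequence)
  # a product drawn entirely from positions 20-30 is removed
  away <- all_prod[all_prod$sr1_start >= 20 & all_prod$sr1_end <= 30 &
                     (is.na(all_prod$sr2_start) |
                        (all_prod$sr2_start >= 20 & all_prod$sr2_end <= 30)), ]
  expect_false(any(away$sequence[1] %in%
                     filter_mutation(away, kras$g12v, 12, "V")$sequence))
  # inconsistent substrate errors
  expect_error(filter_mutation(all_prod, kras$g12v, 12, "G"), "not G")
  expect_error(filter_mutation(all_prod, kras$wild_type, 12, "V"), "not V")
})

test_that("binding filter is boundary-inclusive and pluggable", {
  cand <- data.frame(sequence = c("AAAA", "CCCC", "GGGG"),
                     stringsAsFactors = FALSE)
  preds <- data.frame(peptide = c("AAAA", "CCCC"), ic50_nM = c(99, 101))
  expect_warning(out <- filter_binding(cand, preds, 100), "dropped")
  expect_equal(out$sequence, "AAAA")
  expect_equal(out$predicted_ic50, 99)
  # callable predictor
  out2 <- filter_binding(cand, function(p) rep(50, length(p)), 100)
  expect_equal(nrow(out2), 3L)
  # empty input and bad cutoff
  expect_equal(nrow(filter_binding(cand[0, , drop = FALSE], preds, 100)), 0L)
  expect_error(filter_binding(cand, preds, -1), "positive")
})

test_that("uniqueness check agrees with a brute-force oracle", {
  prot <- c(p1 = "AAAACDEFAAAA", p2 = "CCCCC")
  r <- check_uniqueness("ACDEFA", prot)
  expect_true(r$report$nonspliced[r$report$id == "p1"])
  expect_false(r$unique)
  expect_true(check_uniqueness("AAAA", c(x = "CCCC"))$unique)
  # randomized peptides vs a small synthetic proteome
  set.seed(17)
  proteome <- stats::setNames(
    vapply(sample(20:60, 15, replace = TRUE), random_substrate_seq,
           character(1L)), sprintf("sp%02d", 1:15))
  for (i in 1:10) {
    pep <- random_substrate_seq(sample(4:9, 1))
    got <- check_uniqueness(pep, proteome)
    for (j in seq_along(proteome)) {
      om <- oracle_map(pep, proteome[[j]])
      expect_equal(got$report$nonspliced[j], any(om$category == "non-spliced"))
      expect_equal(got$report$cis[j],
                   any(om$category %in% c("cis-normal", "cis-reverse")))
    }
  }
})

test_that("search-database export collapses to unique sequences and round-trips", {
  ns <- enumerate_nonspliced(kras$g12v, c(8, 12))
  k_unique <- length(unique(ns$sequence))
  path <- tempfile(fileext = ".fasta")
  n_written <- export_search_database(ns, path, substrate_id = "KRAS2-35_G12V")
  expect_equal(n_written, k_unique)
  back <- read_fasta(path)
  expect_setequal(unname(back), unique(ns$sequence))
  # duplicate across categories: category chosen by precedence
  mixed <- rbind(ns[ns$sequence == "KLVVVGAVGV", ][1, ],
                 enumerate_cis(kras$g12v, c(10, 10))[1, ])
  mixed$sequence <- "KLVVVGAVGV"
  p2 <- tempfile(fileext = ".fasta")
  export_search_database(mixed, p2)
  expect_match(names(read_fasta(p2)), "non-spliced")
})

test_that("inclusion-list m/z values follow the monoisotopic mass formula", {
  # GG: 2 x 57.02146 + water
  expect_equal(peptide_mass("GG"), 2 * 57.021464 + 18.010565, tolerance = 1e-7)
  il <- build_inclusion_list(c("GG", "KLVVGAVGV"), charges = 1:3)
  gg2 <- il[il$sequence == "GG" & il$charge == 2L, ]
  expect_equal(gg2$mz, (peptide_mass("GG") + 2 * 1.007276) / 2,
               tolerance = 1e-9)
  expect_true(!is.unsorted(il$mz))
  # every mz recomputable within 1e-4 Th
  recomputed <- (vapply(il$sequence, peptide_mass, numeric(1)) +
                   il$charge * 1.007276) / il$charge
  expect_true(all(abs(il$mz - recomputed) < 1e-4))
  expect_error(build_inclusion_list("GG", charges = c(1, 9)), "1..7")
  expect_error(build_inclusion_list("GBG"), "non-canonical")
})
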