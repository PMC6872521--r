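make_psm <- function(spectrum_id, peptide, category, ion_score,
                     q_value = 0.01, rank = 1L) {
  data.frame(spectrum_id = spectrum_id, peptide = peptide,
             category = category, ion_score = ion_score, q_value = q_value,
             rank = rank, stringsAsFactors = FALSE)
}

test_that("PSM filter applies score, q-value and delta-score rules", {
  psms <- rbind(
    make_psm("s1", "AAAA", "non-spliced", 19),           # ion score below 20
    make_psm("s2", "CCCC", "non-spliced", 50, q_value = 0.06),  # q too high
    make_psm("s3", "GGGG", "non-spliced", 21, q_value = 0.04)   # passes
  )
  out <- filter_psms(psms)
  expect_equal(out$peptide, "GGGG")

  # top spliced score 50 vs best non-spliced 40: delta 20% < 30% -> rejected
  amb <- rbind(make_psm("t1", "LLLL", "cis", 50),
               make_psm("t1", "MMMM", "non-spliced", 40, rank = 2L))
  expect_equal(nrow(filter_psms(amb)), 0L)
  # best non-spliced 30: delta 40% -> accepted
  ok <- rbind(make_psm("t2", "LLLL", "cis", 50),
              make_psm("t2", "MMMM", "non-spliced", 30, rank = 2L))
  expect_equal(filter_psms(ok)$peptide, "LLLL")
  # delta also applies between two spliced hits
  amb2 <- rbind(make_psm("t3", "LLLL", "cis", 50),
                make_psm("t3", "IIII", "trans", 45, rank = 2L))
  expect_equal(nrow(filter_psms(amb2)), 0L)
  # non-spliced top hits face no delta rule
  ns <- rbind(make_psm("t4", "MMMM", "non-spliced", 50),
              make_psm("t4", "LLLL", "cis", 49, rank = 2L))
  expect_equal(filter_psms(ns)$peptide, "MMMM")
  expect_error(filter_psms(make_psm("t5", "AAAA", "cis", 50, rank = 2L)),
               "rank-1")
})

test_that("PSM filter is monotone in the ion-score cutoff", {
  set.seed(23)
  psms <- do.call(rbind, lapply(1:30, function(i) {
    make_psm(paste0("m", i), random_substrate_seq(9),
             sample(c("non-spliced", "cis"), 1), runif(1, 10, 60),
             q_value = runif(1, 0, 0.1))
  }))
  prev <- Inf
  for (cut in c(10, 20, 30, 40)) {
    n <- nrow(filter_psms(psms, ion_score_cutoff = cut))
    expect_lte(n, prev)
    prev <- n
  }
})

kin_row <- function(pep, areas, bio = "b1", tech = "t1",
                    times = seq(0, length.out = length(areas))) {
  data.frame(peptide = pep, bio_rep = bio, tech_rep = tech,
             time_h = times, area = areas, stringsAsFactors = FALSE)
}

# a clean series duplicated over 2 bio x 2 tech replicates
clean_kin <- function(pep, areas = c(0, 100, 200, 300, 400)) {
  do.call(rbind, lapply(c("b1", "b2"), function(b) {
    rbind(kin_row(pep, areas, b, "t1"), kin_row(pep, areas, b, "t2"))
  }))
}

test_that("kinetic filter rejects artifacts, alternation and irreproducibility", {
  # synthesis artifact: t0 = 200 with max 300 (> 5% of max)
  art <- clean_kin("ARTIFACT", c(200, 250, 300, 290, 280))
  r <- filter_kinetics(art)
  expect_false("ARTIFACT" %in% r$kept)
  expect_match(r$rejected$reason[r$rejected$peptide == "ARTIFACT"],
               "synthesis artifact")
  # alternating kinetics
  alt <- clean_kin("ALTERNATE", c(0, 100, 10, 120, 15))
  r2 <- filter_kinetics(alt)
  expect_match(r2$rejected$reason[r2$rejected$peptide == "ALTERNATE"],
               "alternating")
  # present in 1 of 3 biological replicates
  one_bio <- rbind(kin_row("LONELY", c(0, 10, 20), "b1", "t1"),
                   kin_row("LONELY", c(0, 11, 21), "b1", "t2"))
  r3 <- filter_kinetics(one_bio)
  expect_false("LONELY" %in% r3$kept)
  # single technical replicate within a biological replicate
  tech1 <- rbind(kin_row("THIN", c(0, 10, 20), "b1", "t1"),
                 kin_row("THIN", c(0, 10, 20), "b2", "t1"))
  r4 <- filter_kinetics(tech1)
  expect_match(r4$rejected$reason[r4$rejected$peptide == "THIN"],
               "technical")
  # a clean peptide survives with aggregated technical means
  good <- clean_kin("GOODPEP")
  r5 <- filter_kinetics(good)
  expect_equal(r5$kept, "GOODPEP")
  expect_equal(nrow(r5$aggregated), 10L)  # 2 bio x 5 time points
  expect_error(filter_kinetics(rbind(kin_row("SHORT", 5, times = 1, tech = "t1"),
                                     kin_row("SHORT", 5, times = 1, tech = "t2"))),
               "time points")
})

test_that("titration fit and inversion are exact on linear data", {
  curve <- fit_titration(c(0, 5, 10), c(0, 500, 1000))
  expect_equal(curve$slope, 100)
  expect_equal(curve$intercept, 0)
  expect_equal(quantify_by_titration(curve, 250), 2.5)
  expect_equal(quantify_by_titration(curve, 0), 0)
  expect_warning(out <- quantify_by_titration(curve, -10), "clipped")
  expect_equal(out, 0)
  # round trip: pmol -> predicted area -> pmol
  pm <- c(0.2, 1.7, 9.4)
  expect_equal(quantify_by_titration(curve, curve$slope * pm + curve$intercept),
               pm, tolerance = 1e-9)
  expect_error(fit_titration(c(0, 5), c(0, 1)), ">= 3")
  expect_error(fit_titration(c(1, 1, 1), c(1, 2, 3)), "zero range")
  expect_error(fit_titration(c(0, 5, 10), c(1000, 500, 0)), "slope")
})

test_that("noisy titration recovers the true slope within 10%", {
  set.seed(88)
  true_slope <- 730
  pm <- rep(c(0, 0.5, 1, 2, 5, 10), each = 2)
  area <- true_slope * pm * rlnorm(length(pm), 0, 0.05)
  curve <- fit_titration(pm, area)
  expect_lt(abs(curve$slope - true_slope) / true_slope, 0.10)
})

test_that("site profiles follow the definition, equal split and normalization", {
  kras <- kras_fixture()
  # single product: 100% at its C-terminal position
  a1 <- data.frame(peptide = "KLVVVGAVGV", time_h = c(0, 2), amount = c(0, 4))
  qp1 <- quantify_products(a1, kras$g12v)
  scs1 <- compute_site_profile(qp1, "SCS-P1")
  expect_equal(scs1$percent[scs1$position == 14], 100)
  expect_equal(sum(scs1$percent), 100, tolerance = 1e-9)

  # two equal products, C-termini at 10 and 14 -> 50/50
  a2 <- rbind(a1, data.frame(peptide = "TEYKLVVVG", time_h = c(0, 2),
                             amount = c(0, 4)))
  qp2 <- quantify_products(a2, kras$g12v)
  scs2 <- compute_site_profile(qp2, "SCS-P1")
  expect_equal(scs2$percent[scs2$position == 14], 50)
  expect_equal(scs2$percent[scs2$position == 10], 50)

  # KLVVGAVGV: PSP-P1 contributions A/3 at positions 6, 7, 8
  a3 <- data.frame(peptide = "KLVVGAVGV", time_h = c(0, 2), amount = c(0, 6))
  qp3 <- quantify_products(a3, kras$g12v)
  psp <- compute_site_profile(qp3, "PSP-P1")
  expect_equal(psp$percent[psp$position %in% c(6, 7, 8)], rep(100 / 3, 3))
  expect_equal(sum(psp$percent), 100, tolerance = 1e-9)

  # PSP-P1 gets no contribution from non-spliced products
  qp_mix <- quantify_products(rbind(a1, a3), kras$g12v)
  psp_mix <- compute_site_profile(qp_mix, "PSP-P1")
  expect_equal(sum(psp_mix$percent[psp_mix$position %in% 6:8]), 100)

  # all-zero amounts: flagged, not silently zeroed
  a0 <- data.frame(peptide = "KLVVVGAVGV", time_h = c(0, 2), amount = c(0, 0))
  expect_error(compute_site_profile(quantify_products(a0, kras$g12v)),
               "undefined")
})

test_that("category summary counts, percentages and shares are coherent", {
  kras <- kras_fixture()
  sub5 <- substrate("KRAS2-35_G12V", kras$g12v$sequence, 2)
  amounts <- rbind(
    data.frame(peptide = "KLVVVGAVGV", time_h = 1, amount = 6),  # non-spliced
    data.frame(peptide = "TEYKLVVVG", time_h = 1, amount = 2),   # non-spliced
    data.frame(peptide = "KLVVGAVGV", time_h = 1, amount = 1),   # cis
    data.frame(peptide = paste0(sub5$sequence, sub5$sequence), time_h = 1,
               amount = 1)                                        # trans
  )
  qp <- quantify_products(amounts, sub5)
  sm <- summarize_products(qp)
  expect_equal(sm$counts$n, c(2L, 1L, 1L))
  expect_equal(sm$counts$percent, c(50, 25, 25))
  expect_equal(sum(sm$counts$percent), 100, tolerance = 1e-9)
  expect_equal(sum(sm$counts$abundance_percent), 100, tolerance = 1e-9)
  expect_equal(sm$counts$abundance_percent, c(80, 10, 10))
  expect_true(all(c("product", "sr1", "sr2", "intervening") %in%
                    sm$lengths$quantity))
  expect_warning(summarize_products(quantify_products(
    amounts[0, ], sub5)), "empty")
})
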