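# Synthetic-data generators: all inputs needed to exercise every pipeline
# stage without external downloads, each emitted together with its ground
# truth so downstream tests are closed-loop.

# Average amino-acid frequencies of the human proteome (approximate),
# used as the base composition of simulated proteins.
BASE_AA_FREQ <- c(
  A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037,
  G = 0.066, H = 0.026, I = 0.043, K = 0.057, L = 0.100,
  M = 0.021, N = 0.036, P = 0.063, Q = 0.048, R = 0.056,
  S = 0.083, T = 0.053, V = 0.060, W = 0.012, Y = 0.027
)

#' The KRAS 2-35 substrate fixture
#'
#' Wild-type and G12V substrates spanning human KRAS residues 2-35
#' (UniProt P01116; numbering offset 2, G12V applied at parental
#' position 12), together with the two benchmark peptides: the cis
#' spliced epitope candidate KRAS 5-6/8-14 G12V `[KL][VVGAVGV]`
#' (KLVVGAVGV) and the non-spliced candidate KRAS 5-14 G12V
#' (KLVVVGAVGV).
#'
#' @return list with `wild_type` and `g12v` [substrate()] objects and a
#'   `peptides` data.frame (`name`, `sequence`).
#' @export
kras_fixture <- function() {
  wt_seq <- "TEYKLVVVGAGGVGKSALTIQLIQNHFVDEYDPT"  # P01116 residues 2-35
  mut_seq <- wt_seq
  substr(mut_seq, 11L, 11L) <- "V"  # parental position 12
  list(
    wild_type = substrate("KRAS2-35_WT", wt_seq, numbering_offset = 2L),
    g12v = substrate("KRAS2-35_G12V", mut_seq, numbering_offset = 2L),
    peptides = data.frame(
      name = c("KRAS5-6/8-14_G12V", "KRAS5-14_G12V"),
      sequence = c("KLVVGAVGV", "KLVVVGAVGV"),
      stringsAsFactors = FALSE
    )
  )
}

#' Simulate a proteome with planted representation structure
#'
#' Draws proteins with log-normal lengths and per-protein perturbed
#' amino-acid compositions (inducing natural spread and correlation in
#' the physicochemical features), then selects a represented-antigen
#' subset with probability proportional to
#' `plogis(-f(p_star) / temperature)` over standardized features, so
#' that negative ground-truth factors favor representation.
#'
#' @param n_proteins number of proteins (default 2000).
#' @param represented_fraction fraction selected as represented
#'   (default 0.2).
#' @param p_star ground-truth factor vector in \[-1, 1\]^4.
#' @param temperature selection temperature; large values decouple
#'   representation from the features.
#' @param length_meanlog,length_sdlog log-normal length parameters.
#' @param composition_sd log-normal perturbation sd of per-protein
#'   amino-acid weights.
#' @param seed integer seed; output is reproducible given it.
#' @param dir optional output directory: writes `proteome.fasta`,
#'   `represented.txt` and `truth.json`.
#' @return list with `proteins` (named character vector),
#'   `represented_ids`, `feature_table`, `p_star` and the standardized
#'   feature sums `f`.
#' @export
simulate_proteome <- function(n_proteins = 2000L,
                              represented_fraction = 0.2,
                              p_star = c(-1, 0.5, 0.1, 0.4),
                              temperature = 0.5,
                              length_meanlog = log(375), length_sdlog = 0.5,
                              composition_sd = 0.35,
                              seed = 1L, dir = NULL) {
  if (represented_fraction <= 0 || represented_fraction >= 1) {
    stop("represented_fraction must be in (0, 1)")
  }
  p_star <- validate_factors(p_star)
  n_rep <- round(n_proteins * represented_fraction)
  if (n_rep < 1L || n_rep >= n_proteins) stop("infeasible represented fraction")
  set.seed(seed)
  lens <- pmax(50L, round(stats::rlnorm(n_proteins, length_meanlog, length_sdlog)))
  seqs <- vapply(lens, function(L) {
    w <- BASE_AA_FREQ * exp(stats::rnorm(20L, 0, composition_sd))
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = w / sum(w)),
          collapse = "")
  }, character(1L))
  ids <- sprintf("SYNP%04d", seq_len(n_proteins))
  names(seqs) <- ids
  feats <- compute_feature_table(seqs)
  std <- standardize_features(feats)
  f <- feature_sum(p_star, std)
  prob <- stats::plogis(-f / temperature)
  represented <- sample(ids, n_rep, prob = prob)
  out <- list(proteins = seqs,
              represented_ids = sort(represented),
              feature_table = feats,
              p_star = p_star,
              f = f)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(seqs, file.path(dir, "proteome.fasta"))
    writeLines(out$represented_ids, file.path(dir, "represented.txt"))
    jsonlite::write_json(list(p_star = p_star, seed = seed),
                         file.path(dir, "truth.json"), digits = NA)
  }
  out
}

#' Simulate proteasome digestion kinetics with known site propensities
#'
#' Samples non-spliced products from per-position cleavage propensities
#' (C-terminal site) and cis-spliced products from splicing-site
#' propensities (C-terminus of the N-terminal splice-reactant), then
#' accumulates product amounts linearly over the digestion time course,
#' converts them to MS peak areas through a hidden per-peptide response
#' factor, and applies multiplicative log-normal noise per technical
#' replicate. Matched PSMs (scores passing default filters) and a
#' titration table per peptide are emitted, together with the true
#' SCS-P1 and PSP-P1 profiles implied by the generating coordinates.
#'
#' @param sub substrate to digest (default: KRAS 2-35 G12V fixture).
#' @param n_nonspliced,n_cis numbers of distinct products to generate.
#' @param length_range product length range.
#' @param time_points digestion time points in hours (must include 0).
#' @param turnover_rate total product amount (pmol) produced per hour
#'   across all products; the default places typical product amounts
#'   inside the 0-10 pmol titration range.
#' @param noise_sd log-normal sd of the multiplicative area noise per
#'   technical replicate.
#' @param titration_noise_sd log-normal sd of titration-point noise.
#' @param n_bio,n_tech biological and technical replicate counts.
#' @param artifact_peptide optional peptide sequence to plant a synthesis
#'   artifact for (non-zero area at t = 0).
#' @param seed integer seed.
#' @param dir optional output directory: writes `kinetics.csv`,
#'   `psms.tsv`, `titration.csv`, `truth_scs.csv`, `truth_psp.csv`.
#' @return list with `kinetics`, `psms`, `titration` (data.frames in the
#'   formats consumed by the digestion-analysis functions), `true_scs`,
#'   `true_psp` (position/percent data.frames), `true_amounts` and the
#'   substrate.
#' @export
simulate_digestion <- function(sub = kras_fixture()$g12v,
                               n_nonspliced = 15L, n_cis = 8L,
                               length_range = c(8L, 12L),
                               time_points = c(0, 1, 2, 3, 4),
                               turnover_rate = 20,
                               noise_sd = 0.05,
                               titration_noise_sd = 0.05,
                               n_bio = 2L, n_tech = 3L,
                               artifact_peptide = NULL,
                               seed = 1L, dir = NULL) {
  stopifnot(inherits(sub, "substrate"))
  if (!0 %in% time_points) stop("time_points must include 0")
  set.seed(seed)
  L <- nchar(sub$sequence)
  off <- sub$numbering_offset - 1L

  # hidden per-position propensities
  cleav_w <- stats::rgamma(L, shape = 1.2, rate = 1)
  psp_w <- stats::rgamma(L, shape = 0.8, rate = 1)
  if (sum(cleav_w) <= 0 || sum(psp_w) <= 0) stop("zero total propensity")

  nonspliced_pool <- enumerate_nonspliced(sub, length_range)
  cis_all <- enumerate_cis(sub, length_range, include_reverse = TRUE)
  # site attribution must be identifiable from the peptide sequence: keep
  # only sequences whose admissible sites (within their classification
  # category) are unique, so the generating coordinates are recoverable.
  # Ambiguous products (e.g. KLVVGAVGV) are exercised via map_peptide and
  # the equal-split rule directly, not planted in the simulation.
  ns_sites <- tapply(nonspliced_pool$scs_p1, nonspliced_pool$sequence,
                     function(x) length(unique(x)))
  ns_ok <- names(ns_sites)[ns_sites == 1L]
  ns_pool <- nonspliced_pool[nonspliced_pool$sequence %in% ns_ok &
                               !duplicated(nonspliced_pool$sequence), , drop = FALSE]
  if (n_nonspliced > nrow(ns_pool)) stop("n_nonspliced too large")
  ns <- ns_pool[sample(nrow(ns_pool), n_nonspliced), , drop = FALSE]
  ns$rate <- cleav_w[ns$scs_p1 - off] * stats::rlnorm(n_nonspliced, 0, 0.5)

  cis_cand <- cis_all[!cis_all$sequence %in% nonspliced_pool$sequence, , drop = FALSE]
  cis_psp <- tapply(cis_cand$psp_p1, cis_cand$sequence,
                    function(x) length(unique(x)))
  cis_scs <- tapply(cis_cand$scs_p1, cis_cand$sequence,
                    function(x) length(unique(x)))
  cis_ok <- names(cis_psp)[cis_psp == 1L & cis_scs[names(cis_psp)] == 1L]
  cis_pool <- cis_cand[cis_cand$sequence %in% cis_ok &
                         cis_cand$category == "cis-normal", , drop = FALSE]
  cis_pool <- cis_pool[!duplicated(cis_pool$sequence), , drop = FALSE]
  if (n_cis > nrow(cis_pool)) stop("n_cis too large")
  cis <- cis_pool[sample(nrow(cis_pool), n_cis), , drop = FALSE]
  cis$rate <- psp_w[cis$psp_p1 - off] * stats::rlnorm(n_cis, 0, 0.5)

  prods <- rbind(ns, cis)
  prods$rate <- turnover_rate * prods$rate / sum(prods$rate)

  # true amounts: linear accumulation amount = rate * t
  true_amounts <- do.call(rbind, lapply(seq_len(nrow(prods)), function(i) {
    data.frame(peptide = prods$sequence[i], time_h = time_points,
               amount = prods$rate[i] * time_points,
               stringsAsFactors = FALSE)
  }))

  # true site profiles from the generating coordinates (mean over time
  # points of each product; linear kinetics make this proportional to rate)
  profile_from <- function(sites, rates) {
    w <- tapply(rates, factor(sites, levels = seq_len(L) + off), sum,
                default = 0)
    data.frame(position = seq_len(L) + off,
               residue = strsplit(sub$sequence, "", fixed = TRUE)[[1L]],
               percent = 100 * as.numeric(w) / sum(rates),
               stringsAsFactors = FALSE)
  }
  true_scs <- profile_from(prods$scs_p1, prods$rate)
  true_psp <- profile_from(cis$psp_p1, cis$rate)  # spliced products only

  # peak areas with hidden response factors and replicate noise
  rf <- stats::setNames(stats::rlnorm(nrow(prods), log(1000), 0.4),
                        prods$sequence)
  kin <- list()
  for (b in seq_len(n_bio)) {
    for (tech in seq_len(n_tech)) {
      noise <- stats::rlnorm(nrow(prods) * length(time_points), 0, noise_sd)
      k <- 0L
      for (i in seq_len(nrow(prods))) {
        pep <- prods$sequence[i]
        areas <- vapply(time_points, function(t) {
          k <<- k + 1L
          amt <- prods$rate[i] * t
          if (!is.null(artifact_peptide) && pep == artifact_peptide && t == 0) {
            amt <- prods$rate[i] * max(time_points)  # planted artifact
          }
          amt * rf[[pep]] * noise[k]
        }, numeric(1L))
        kin[[length(kin) + 1L]] <- data.frame(
          peptide = pep, bio_rep = paste0("bio", b),
          tech_rep = paste0("tech", tech),
          time_h = time_points, area = areas, stringsAsFactors = FALSE)
      }
    }
  }
  kinetics <- do.call(rbind, kin)

  # PSMs: one confident spectrum per product per biological replicate
  psms <- do.call(rbind, lapply(seq_len(nrow(prods)), function(i) {
    dec <- map_peptide(prods$sequence[i], sub)
    data.frame(spectrum_id = sprintf("spec%03d", i),
               peptide = prods$sequence[i],
               category = classify_peptide(dec),
               ion_score = stats::runif(1L, 35, 90),
               q_value = stats::runif(1L, 0, 0.01),
               rank = 1L, stringsAsFactors = FALSE)
  }))

  # titration: 0-10 pmol injected, two measurements per point
  tit_pmol <- c(0, 0.5, 1, 2, 5, 10)
  titration <- do.call(rbind, lapply(prods$sequence, function(pep) {
    pm <- rep(tit_pmol, each = 2L)
    data.frame(peptide = pep, pmol = pm,
               area = pm * rf[[pep]] * stats::rlnorm(length(pm), 0,
                                                     titration_noise_sd),
               stringsAsFactors = FALSE)
  }))

  out <- list(kinetics = kinetics, psms = psms, titration = titration,
              true_scs = true_scs, true_psp = true_psp,
              true_amounts = true_amounts, substrate = sub,
              products = prods)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(kinetics, file.path(dir, "kinetics.csv"), row.names = FALSE)
    utils::write.table(psms, file.path(dir, "psms.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.csv(titration, file.path(dir, "titration.csv"), row.names = FALSE)
    utils::write.csv(true_scs, file.path(dir, "truth_scs.csv"), row.names = FALSE)
    utils::write.csv(true_psp, file.path(dir, "truth_psp.csv"), row.names = FALSE)
  }
  out
}

#' Estimate site profiles from a simulated (or real-format) digestion
#'
#' Convenience end-to-end path: kinetic filtering, per-peptide titration
#' fits, area-to-pmol conversion, product mapping and SCS-P1 / PSP-P1
#' profile computation.
#'
#' @param kinetics,titration data.frames in the formats produced by
#'   [simulate_digestion()].
#' @param sub the digested [substrate()].
#' @param config configuration list (see [default_config()]).
#' @return list with `scs`, `psp` (site profiles), `products` and the
#'   kinetic `filter` report.
#' @export
analyze_digestion <- function(kinetics, titration, sub,
                              config = default_config()) {
  filt <- filter_kinetics(kinetics,
                          artifact_fraction = config$artifact_fraction,
                          alternation_fraction = config$alternation_fraction,
                          min_bio = config$min_biological_replicates,
                          min_tech = config$min_technical_replicates)
  agg <- filt$aggregated
  if (!nrow(agg)) stop("no peptides survive the kinetic filters")
  rows <- list()
  for (pep in unique(agg$peptide)) {
    tt <- titration[titration$peptide == pep, , drop = FALSE]
    if (!nrow(tt)) next
    curve <- fit_titration(tt$pmol, tt$area)
    ap <- agg[agg$peptide == pep, , drop = FALSE]
    amt <- suppressWarnings(quantify_by_titration(curve, ap$area))
    # average bio replicates per time point
    for (t in unique(ap$time_h)) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, time_h = t, amount = mean(amt[ap$time_h == t]),
        stringsAsFactors = FALSE)
    }
  }
  amounts <- do.call(rbind, rows)
  products <- quantify_products(amounts, sub, min_sr = config$min_sr)
  list(scs = compute_site_profile(products, "SCS-P1"),
       psp = compute_site_profile(products, "PSP-P1"),
       products = products,
       filter = filt)
}
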