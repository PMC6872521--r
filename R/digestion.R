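# Quantitative analysis of in vitro proteasome digestion products:
# PSM and kinetic filtering, titration-based absolute quantification,
# SCS-P1 / PSP-P1 site profiles and category summaries.

#' Filter peptide-spectrum matches
#'
#' Applies the identification filters: ion score >= `ion_score_cutoff`,
#' q-value <= `q_value_cutoff`, and, for spectra whose top-ranked hit is
#' a spliced peptide, a relative delta score
#' `(score_top - score_alt) / score_top >= delta` against both the best
#' alternative spliced sequence and the best non-spliced hit; spectra
#' failing the delta rule are rejected as ambiguous.
#'
#' @param psms data.frame with columns `spectrum_id`, `peptide`,
#'   `category` (`"non-spliced"`, `"cis"`, `"trans"`), `ion_score`,
#'   `q_value`, `rank` (1 = top hit within the spectrum).
#' @param ion_score_cutoff minimum ion score (default 20).
#' @param q_value_cutoff maximum q-value (default 0.05).
#' @param delta minimum relative delta score (default 0.30).
#' @return The accepted top-hit PSMs (one row per surviving spectrum).
#' @export
filter_psms <- function(psms, ion_score_cutoff = 20, q_value_cutoff = 0.05,
                        delta = 0.30) {
  needed <- c("spectrum_id", "peptide", "category", "ion_score", "q_value", "rank")
  stopifnot(all(needed %in% names(psms)))
  keep_rows <- psms$ion_score >= ion_score_cutoff & psms$q_value <= q_value_cutoff
  out <- list()
  for (sid in unique(psms$spectrum_id)) {
    spec <- psms[psms$spectrum_id == sid, , drop = FALSE]
    if (!any(spec$rank == 1L)) stop("spectrum ", sid, " has no rank-1 hit")
    top <- spec[spec$rank == 1L, , drop = FALSE][1L, ]
    if (!(top$ion_score >= ion_score_cutoff && top$q_value <= q_value_cutoff)) next
    if (top$category != "non-spliced") {
      alt <- spec[spec$peptide != top$peptide, , drop = FALSE]
      alt_spliced <- alt$ion_score[alt$category != "non-spliced"]
      alt_nonspl <- alt$ion_score[alt$category == "non-spliced"]
      rel_delta <- function(s) (top$ion_score - s) / top$ion_score
      ok <- TRUE
      if (length(alt_spliced) && rel_delta(max(alt_spliced)) < delta) ok <- FALSE
      if (length(alt_nonspl) && rel_delta(max(alt_nonspl)) < delta) ok <- FALSE
      if (!ok) next
    }
    out[[length(out) + 1L]] <- top
  }
  if (!length(out)) return(psms[0L, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter digestion kinetics for artifacts and irreproducibility
#'
#' Per-peptide rejection rules, mirroring the kinetic quality filters of
#' substrate-digestion analysis:
#' \describe{
#'   \item{synthesis artifact}{mean area at t = 0 exceeds
#'     `artifact_fraction` (default 5%) of the series maximum;}
#'   \item{alternating kinetics}{a down-then-up or up-then-down excursion
#'     between consecutive time points with both relative changes above
#'     `alternation_fraction` (default 50%);}
#'   \item{technical irreproducibility}{quantified (non-zero area at some
#'     t > 0) in fewer than `min_tech` technical replicates of a
#'     biological replicate;}
#'   \item{biological reproducibility}{surviving in fewer than `min_bio`
#'     biological replicates.}
#' }
#'
#' @param kinetics long-format data.frame with columns `peptide`,
#'   `bio_rep`, `tech_rep`, `time_h`, `area`.
#' @param artifact_fraction,alternation_fraction,min_bio,min_tech
#'   thresholds (see above).
#' @return list with `kept` (character vector of peptide sequences),
#'   `rejected` (data.frame: peptide, reason) and `aggregated`
#'   (mean-over-technical-replicates areas, long format, kept peptides
#'   only).
#' @export
filter_kinetics <- function(kinetics, artifact_fraction = 0.05,
                            alternation_fraction = 0.50,
                            min_bio = 2L, min_tech = 2L) {
  needed <- c("peptide", "bio_rep", "tech_rep", "time_h", "area")
  stopifnot(all(needed %in% names(kinetics)))
  rejected <- list()
  kept <- character()
  agg_rows <- list()
  for (pep in unique(kinetics$peptide)) {
    kp <- kinetics[kinetics$peptide == pep, , drop = FALSE]
    good_bio <- 0L
    reasons <- character()
    pep_agg <- list()
    for (br in unique(kp$bio_rep)) {
      kb <- kp[kp$bio_rep == br, , drop = FALSE]
      # technical reproducibility: replicate counts with signal
      quant_tech <- vapply(split(kb, kb$tech_rep),
                           function(d) any(d$area[d$time_h > 0] > 0),
                           logical(1L))
      if (sum(quant_tech) < min_tech) {
        reasons <- c(reasons, "technical irreproducibility"); next
      }
      # mean over technical replicates per time point
      tm <- sort(unique(kb$time_h))
      if (length(tm) < 2L) stop("peptide ", pep, ": series with < 2 time points")
      areas <- vapply(tm, function(t) mean(kb$area[kb$time_h == t]), numeric(1L))
      if (max(areas) <= 0) { reasons <- c(reasons, "no signal"); next }
      if (0 %in% tm && areas[tm == 0] > artifact_fraction * max(areas)) {
        reasons <- c(reasons, "synthesis artifact"); next
      }
      # alternating kinetics: consecutive opposite swings both > threshold
      rel_change <- diff(areas) / pmax(utils::head(areas, -1L), .Machine$double.eps)
      alt <- FALSE
      if (length(rel_change) >= 2L) {
        for (i in seq_len(length(rel_change) - 1L)) {
          a <- rel_change[i]; b <- rel_change[i + 1L]
          if (sign(a) * sign(b) < 0 &&
              abs(a) > alternation_fraction && abs(b) > alternation_fraction) {
            alt <- TRUE; break
          }
        }
      }
      if (alt) { reasons <- c(reasons, "alternating kinetics"); next }
      good_bio <- good_bio + 1L
      pep_agg[[length(pep_agg) + 1L]] <-
        data.frame(peptide = pep, bio_rep = br, time_h = tm, area = areas,
                   stringsAsFactors = FALSE)
    }
    if (good_bio >= min_bio) {
      kept <- c(kept, pep)
      agg_rows <- c(agg_rows, pep_agg)
    } else {
      reason <- if (length(reasons)) paste(unique(reasons), collapse = "; ")
                else "insufficient biological replicates"
      if (good_bio > 0L) {
        reason <- paste(c(reason, sprintf("detected in %d biological replicate(s)",
                                          good_bio)), collapse = "; ")
      }
      rejected[[length(rejected) + 1L]] <-
        data.frame(peptide = pep, reason = reason, stringsAsFactors = FALSE)
    }
  }
  list(
    kept = kept,
    rejected = if (length(rejected)) do.call(rbind, rejected)
               else data.frame(peptide = character(), reason = character()),
    aggregated = if (length(agg_rows)) do.call(rbind, agg_rows)
                 else data.frame(peptide = character(), bio_rep = character(),
                                 time_h = numeric(), area = numeric())
  )
}

#' Fit a titration curve (injected amount vs peak area)
#'
#' Ordinary least-squares line `area = slope * pmol + intercept`.
#'
#' @param pmol injected amounts (>= 3 points spanning a non-zero range).
#' @param area measured peak areas.
#' @return Object of class `titration_curve` with `slope`, `intercept`,
#'   `sigma` (residual standard error) and the underlying [stats::lm()]
#'   fit.
#' @export
fit_titration <- function(pmol, area) {
  if (length(pmol) < 3L || length(area) != length(pmol)) {
    stop("need >= 3 matched titration points")
  }
  if (diff(range(pmol)) == 0) stop("titration points span zero range")
  fit <- stats::lm(area ~ pmol)
  slope <- unname(stats::coef(fit)[2L])
  if (slope <= 0) stop("unusable titration curve: non-positive slope")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 sigma = suppressWarnings(summary(fit)$sigma),
                 fit = fit),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("Titration curve: area = %.4g * pmol + %.4g (residual SE %.3g)\n",
              x$slope, x$intercept, x$sigma))
  invisible(x)
}

#' Convert a peak area to an absolute amount via a titration curve
#'
#' Inverts the fitted line; negative results are clipped to 0 with a
#' warning.
#'
#' @param curve a [fit_titration()] object.
#' @param area peak area(s).
#' @return Amount(s) in pmol.
#' @export
quantify_by_titration <- function(curve, area) {
  stopifnot(inherits(curve, "titration_curve"))
  pmol <- (area - curve$intercept) / curve$slope
  if (any(pmol < 0)) {
    warning("negative quantification(s) clipped to 0")
    pmol[pmol < 0] <- 0
  }
  pmol
}

#' Assemble quantified products
#'
#' Joins per-peptide amounts with their decompositions against the
#' substrate and the sequence-level category.
#'
#' @param amounts data.frame with columns `peptide`, `time_h`, `amount`
#'   (pmol), optionally `bio_rep`.
#' @param sub the [substrate()] the peptides derive from.
#' @param min_sr minimum splice-reactant length for mapping.
#' @return list of class `quantified_products`: per peptide the
#'   decomposition table, category and amount series.
#' @export
quantify_products <- function(amounts, sub, min_sr = 1L) {
  stopifnot(all(c("peptide", "time_h", "amount") %in% names(amounts)))
  if (any(amounts$amount < 0)) stop("amounts must be non-negative")
  peptides <- unique(amounts$peptide)
  prods <- lapply(peptides, function(pep) {
    dec <- map_peptide(pep, sub, min_sr = min_sr)
    list(sequence = pep,
         decompositions = dec,
         category = classify_peptide(dec),
         amounts = amounts[amounts$peptide == pep,
                           setdiff(names(amounts), "peptide"), drop = FALSE])
  })
  names(prods) <- peptides
  structure(prods, class = "quantified_products", substrate = sub)
}

#' @export
print.quantified_products <- function(x, ...) {
  cats <- vapply(x, `[[`, character(1L), "category")
  cat(sprintf("%d quantified products (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(cats)), table(cats)),
                    collapse = ", ")))
  invisible(x)
}

# mean amount of one product over the requested time selection
product_amount <- function(prod, time_selector) {
  a <- prod$amounts
  if (identical(time_selector, "mean")) {
    mean(vapply(split(a$amount, a$time_h), mean, numeric(1L)))
  } else {
    sel <- a$amount[a$time_h == time_selector]
    if (!length(sel)) 0 else mean(sel)
  }
}

#' Compute an SCS-P1 or PSP-P1 site profile
#'
#' For SCS-P1, every product contributes its amount at the parental
#' position(s) of its C-terminal residue; for PSP-P1 only spliced
#' products contribute, at the C-terminus of their N-terminal
#' splice-reactant. A product whose decompositions admit k distinct
#' positions contributes `amount / k` to each (equal split conserves the
#' total). The profile is normalized to sum to 100%.
#'
#' @param products a [quantify_products()] object.
#' @param kind `"SCS-P1"` or `"PSP-P1"`.
#' @param time_selector a time point (h) or `"mean"` (default): the
#'   average amount over all time points of each product.
#' @return data.frame of class `site_profile` with columns `position`
#'   (parental), `residue`, `percent`.
#' @export
compute_site_profile <- function(products, kind = c("SCS-P1", "PSP-P1"),
                                 time_selector = "mean") {
  kind <- match.arg(kind)
  stopifnot(inherits(products, "quantified_products"))
  sub <- attr(products, "substrate")
  L <- nchar(sub$sequence)
  positions <- seq_len(L) + sub$numbering_offset - 1L
  weight <- stats::setNames(numeric(L), positions)
  for (prod in products) {
    dec <- prod$decompositions
    if (!nrow(dec)) next
    # admissible decompositions are those of the product's classified
    # category (precedence non-spliced > cis > trans)
    dec <- switch(prod$category,
      "non-spliced" = dec[dec$category == "non-spliced", , drop = FALSE],
      "cis" = dec[dec$category %in% c("cis-normal", "cis-reverse"), , drop = FALSE],
      "trans" = dec[dec$category == "trans", , drop = FALSE],
      dec)
    if (kind == "PSP-P1") {
      if (prod$category == "non-spliced") next
      sites <- unique(dec$psp_p1)
    } else {
      sites <- unique(dec$scs_p1)
    }
    amt <- product_amount(prod, time_selector)
    if (amt <= 0) next
    share <- amt / length(sites)
    for (s in sites) weight[as.character(s)] <- weight[as.character(s)] + share
  }
  total <- sum(weight)
  if (total <= 0) {
    stop("undefined ", kind, " profile: no contributing product amount")
  }
  out <- data.frame(
    position = positions,
    residue = strsplit(sub$sequence, "", fixed = TRUE)[[1L]],
    percent = 100 * as.numeric(weight) / total,
    stringsAsFactors = FALSE
  )
  class(out) <- c("site_profile", class(out))
  attr(out, "kind") <- kind
  out
}

#' Summarize quantified products by splice category
#'
#' Counts and percentages of peptides per category, percentage of total
#' abundance per category, mean abundance per peptide per time point and
#' category, and medians of product, splice-reactant and intervening
#' lengths for cis products.
#'
#' @param products a [quantify_products()] object.
#' @param time_selector passed to the abundance computation (default
#'   `"mean"`).
#' @return list with `counts`, `abundance` and `lengths` data.frames.
#' @export
summarize_products <- function(products, time_selector = "mean") {
  stopifnot(inherits(products, "quantified_products"))
  if (!length(products)) {
    warning("empty product set")
    return(list(counts = data.frame(), abundance = data.frame(),
                lengths = data.frame()))
  }
  cats <- vapply(products, `[[`, character(1L), "category")
  amts <- vapply(products, product_amount, numeric(1L),
                 time_selector = time_selector)
  levels_ <- c("non-spliced", "cis", "trans")
  n_by <- vapply(levels_, function(cc) sum(cats == cc), numeric(1L))
  a_by <- vapply(levels_, function(cc) sum(amts[cats == cc]), numeric(1L))
  counts <- data.frame(
    category = levels_,
    n = as.integer(n_by),
    percent = 100 * n_by / sum(n_by),
    abundance_percent = if (sum(a_by) > 0) 100 * a_by / sum(a_by) else NA_real_,
    mean_abundance = ifelse(n_by > 0, a_by / n_by, NA_real_),
    stringsAsFactors = FALSE
  )
  # length distributions; splice-reactant and intervening lengths over
  # cis decompositions of cis-classified products
  prod_len <- nchar(vapply(products, `[[`, character(1L), "sequence"))
  sr1 <- sr2 <- interv <- numeric()
  for (prod in products) {
    if (prod$category != "cis") next
    dec <- prod$decompositions
    dec <- dec[dec$category %in% c("cis-normal", "cis-reverse"), , drop = FALSE]
    sr1 <- c(sr1, dec$sr1_end - dec$sr1_start + 1L)
    sr2 <- c(sr2, dec$sr2_end - dec$sr2_start + 1L)
    interv <- c(interv, dec$intervening_length)
  }
  med <- function(x) if (length(x)) stats::median(x) else NA_real_
  lengths <- data.frame(
    quantity = c("product", "sr1", "sr2", "intervening"),
    median = c(med(prod_len), med(sr1), med(sr2), med(interv)),
    stringsAsFactors = FALSE
  )
  list(counts = counts, abundance = data.frame(
    category = levels_, total_amount = a_by, stringsAsFactors = FALSE
  ), lengths = lengths)
}

#' KS test between two length (or any) distributions
#'
#' Thin wrapper over [stats::ks.test()] used for comparing product-length
#' distributions between splice categories.
#'
#' @param x,y numeric samples.
#' @return htest object.
#' @export
compare_distributions <- function(x, y) {
  stats::ks.test(x, y)
}
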