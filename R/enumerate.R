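# Exhaustive enumeration of non-spliced and cis-spliced peptide products
# and mapping of observed peptides onto splice-reactant decompositions.
#
# Coordinates are closed 1-based intervals in PARENTAL numbering: a
# substrate with numbering_offset o maps internal index i to parental
# position i + o - 1 (e.g. KRAS residues 2-35 have offset 2).

#' Construct a substrate polypeptide
#'
#' @param id substrate identifier.
#' @param sequence amino-acid sequence (canonical alphabet, length >= 2).
#' @param numbering_offset parental-protein position of the first residue
#'   (>= 1); reported coordinates are `internal index + offset - 1`.
#' @return An object of class `substrate`.
#' @examples
#' substrate("KRAS2-35_G12V", "TEYKLVVVGAVGVGKSALTIQLIQNHFVDEYDPT", 2)
#' @export
substrate <- function(id, sequence, numbering_offset = 1L) {
  sequence <- toupper(sequence)
  check_canonical(sequence)
  if (nchar(sequence) < 2L) stop("substrate sequence must have length >= 2")
  if (numbering_offset < 1L) stop("numbering_offset must be >= 1")
  structure(list(id = id, sequence = sequence,
                 numbering_offset = as.integer(numbering_offset)),
            class = "substrate")
}

#' @export
print.substrate <- function(x, ...) {
  cat(sprintf("Substrate %s: %d residues, parental positions %d-%d\n%s\n",
              x$id, nchar(x$sequence), x$numbering_offset,
              x$numbering_offset + nchar(x$sequence) - 1L, x$sequence))
  invisible(x)
}

# internal: one decomposition row in parental coordinates
decomp_row <- function(sub, category, i1, j1, i2 = NA_integer_, j2 = NA_integer_) {
  o <- sub$numbering_offset - 1L
  interv <- if (category == "cis-normal") i2 - j1 - 1L
            else if (category == "cis-reverse") i1 - j2 - 1L
            else NA_integer_
  scs <- if (category == "non-spliced") j1 + o else j2 + o
  data.frame(category = category,
             sr1_start = i1 + o, sr1_end = j1 + o,
             sr2_start = i2 + o, sr2_end = j2 + o,
             intervening_length = interv,
             psp_p1 = if (category == "non-spliced") NA_integer_ else j1 + o,
             scs_p1 = scs,
             stringsAsFactors = FALSE)
}

#' Enumerate all theoretical non-spliced peptides of a substrate
#'
#' Every contiguous subsequence with length in `length_range`, one entry
#' per coordinate interval (identical sequences from different intervals
#' are distinct entries).
#'
#' @param sub a [substrate()].
#' @param length_range integer vector `c(min, max)` of product lengths.
#' @return data.frame with columns `sequence`, `category`, interval and
#'   site columns (parental numbering).
#' @export
enumerate_nonspliced <- function(sub, length_range = c(8L, 12L)) {
  stopifnot(inherits(sub, "substrate"))
  lmin <- length_range[1L]; lmax <- length_range[2L]
  if (lmin > lmax || lmin < 1L) stop("invalid length range")
  L <- nchar(sub$sequence)
  if (lmin > L) return(empty_decomp_table())
  i <- integer(); j <- integer()
  for (len in seq(lmin, min(lmax, L))) {
    st <- seq_len(L - len + 1L)
    i <- c(i, st); j <- c(j, st + len - 1L)
  }
  build_decomp_table(sub, "non-spliced", i, j)
}

# vectorized constructor for a block of same-category decompositions
# (internal coordinates in; parental numbering out)
build_decomp_table <- function(sub, category, i1, j1,
                               i2 = rep(NA_integer_, length(i1)),
                               j2 = rep(NA_integer_, length(i1))) {
  if (!length(i1)) return(empty_decomp_table())
  o <- sub$numbering_offset - 1L
  seq1 <- substring(sub$sequence, i1, j1)
  seq2 <- ifelse(is.na(i2), "", substring(sub$sequence, i2, j2))
  interv <- switch(category,
                   "cis-normal" = i2 - j1 - 1L,
                   "cis-reverse" = i1 - j2 - 1L,
                   rep(NA_integer_, length(i1)))
  data.frame(
    sequence = paste0(seq1, seq2),
    category = category,
    sr1_start = i1 + o, sr1_end = j1 + o,
    sr2_start = i2 + o, sr2_end = j2 + o,
    intervening_length = interv,
    psp_p1 = if (category == "non-spliced") rep(NA_integer_, length(i1))
             else j1 + o,
    scs_p1 = if (category == "non-spliced") j1 + o else j2 + o,
    stringsAsFactors = FALSE
  )
}

#' Enumerate all theoretical cis-spliced peptides of a substrate
#'
#' All ordered pairs of disjoint substrate intervals whose concatenated
#' length lies in `length_range`: normal order (`sr1` strictly before
#' `sr2`) always, reverse order (`sr2` strictly before `sr1`) when
#' `include_reverse = TRUE`.
#'
#' @inheritParams enumerate_nonspliced
#' @param include_reverse also enumerate reverse-order cis products.
#' @param min_sr minimum splice-reactant length (default 1).
#' @return data.frame as in [enumerate_nonspliced()].
#' @export
enumerate_cis <- function(sub, length_range = c(8L, 12L),
                          include_reverse = TRUE, min_sr = 1L) {
  stopifnot(inherits(sub, "substrate"))
  lmin <- length_range[1L]; lmax <- length_range[2L]
  if (lmin > lmax || lmin < 1L) stop("invalid length range")
  if (min_sr < 1L) stop("min_sr must be >= 1")
  L <- nchar(sub$sequence)
  A1 <- integer(); B1 <- integer(); A2 <- integer(); B2 <- integer()
  # upstream segment [a1,b1], downstream segment [a2,b2], a2 > b1
  for (a1 in seq_len(L)) {
    b1_hi <- min(L - 1L, a1 + lmax - min_sr - 1L)
    b1_lo <- a1 + min_sr - 1L
    if (b1_lo > b1_hi) next
    for (b1 in seq(b1_lo, b1_hi)) {
      len1 <- b1 - a1 + 1L
      for (a2 in seq(b1 + 1L, L)) {
        lo2 <- max(min_sr, lmin - len1)
        hi2 <- min(lmax - len1, L - a2 + 1L)
        if (lo2 > hi2) next
        len2 <- seq(lo2, hi2)
        A1 <- c(A1, rep(a1, length(len2)))
        B1 <- c(B1, rep(b1, length(len2)))
        A2 <- c(A2, rep(a2, length(len2)))
        B2 <- c(B2, a2 + len2 - 1L)
      }
    }
  }
  out <- build_decomp_table(sub, "cis-normal", A1, B1, A2, B2)
  if (include_reverse) {
    out <- rbind(out, build_decomp_table(sub, "cis-reverse", A2, B2, A1, B1))
  }
  out
}

empty_decomp_table <- function() {
  data.frame(sequence = character(), category = character(),
             sr1_start = integer(), sr1_end = integer(),
             sr2_start = integer(), sr2_end = integer(),
             intervening_length = integer(), psp_p1 = integer(),
             scs_p1 = integer(), stringsAsFactors = FALSE)
}

# all start positions of `needle` in `haystack` (exact, overlapping)
find_occurrences <- function(needle, haystack) {
  hits <- integer()
  start <- 1L
  repeat {
    p <- regexpr(needle, substr(haystack, start, nchar(haystack)), fixed = TRUE)
    if (p == -1L) break
    hits <- c(hits, start + as.integer(p) - 1L)
    start <- start + as.integer(p)
  }
  hits
}

#' Map an observed peptide onto a substrate
#'
#' Finds every explanation of the peptide as one substrate segment
#' (non-spliced) or an ordered pair of segments: disjoint in normal order
#' (cis-normal), disjoint in reverse order (cis-reverse), or overlapping
#' (trans; requires two substrate molecules). Peptides needing three or
#' more fragments get an empty table ("unmapped").
#'
#' @param peptide amino-acid sequence (length >= 2).
#' @param sub a [substrate()].
#' @param min_sr minimum splice-reactant length.
#' @return data.frame of decompositions (possibly empty), as in
#'   [enumerate_nonspliced()].
#' @examples
#' parent <- substrate("KRAS5-14_G12V", "KLVVVGAVGV", 5)
#' map_peptide("KLVVGAVGV", parent)  # 3 cis-normal decompositions
#' @export
map_peptide <- function(peptide, sub, min_sr = 1L) {
  stopifnot(inherits(sub, "substrate"))
  peptide <- toupper(peptide)
  if (nchar(peptide) < 2L) stop("peptide length must be >= 2")
  rows <- list()
  # non-spliced
  for (i in find_occurrences(peptide, sub$sequence)) {
    r <- decomp_row(sub, "non-spliced", i, i + nchar(peptide) - 1L)
    r$sequence <- peptide
    rows[[length(rows) + 1L]] <- r
  }
  # two-segment splits
  n <- nchar(peptide)
  for (k in seq(min_sr, n - min_sr)) {
    left <- substr(peptide, 1L, k)
    right <- substr(peptide, k + 1L, n)
    occ1 <- find_occurrences(left, sub$sequence)
    if (!length(occ1)) next
    occ2 <- find_occurrences(right, sub$sequence)
    for (i1 in occ1) {
      j1 <- i1 + k - 1L
      for (i2 in occ2) {
        j2 <- i2 + (n - k) - 1L
        cat_ <- if (j1 < i2) "cis-normal"
                else if (j2 < i1) "cis-reverse"
                else "trans"
        r <- decomp_row(sub, cat_, i1, j1, i2, j2)
        r$sequence <- peptide
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  if (!length(rows)) return(empty_decomp_table())
  out <- do.call(rbind, rows)
  out <- out[c("sequence", setdiff(names(out), "sequence"))]
  rownames(out) <- NULL
  out
}

#' Classify a peptide from its decomposition table
#'
#' Precedence: non-spliced > cis > trans. A peptide is cis only if it has
#' no non-spliced decomposition, and trans only if it has neither; an
#' empty table yields `"unmapped"`.
#'
#' @param decompositions data.frame from [map_peptide()].
#' @return One of `"non-spliced"`, `"cis"`, `"trans"`, `"unmapped"`.
#' @export
classify_peptide <- function(decompositions) {
  if (!nrow(decompositions)) return("unmapped")
  cats <- decompositions$category
  if (any(cats == "non-spliced")) "non-spliced"
  else if (any(cats %in% c("cis-normal", "cis-reverse"))) "cis"
  else "trans"
}

#' Keep candidates whose decompositions cover a mutation position
#'
#' @param candidates data.frame with a `sequence` column (coordinate-level
#'   decomposition columns as produced by the enumeration functions).
#' @param sub the mutated [substrate()].
#' @param position parental position of the mutation (e.g. 12 for G12V).
#' @param mutant single-letter mutant residue; the substrate must already
#'   carry it at `position` (otherwise an error is raised).
#' @return The subset of `candidates` with at least one decomposition row
#'   covering `position`, with a logical `carries_mutation` column added.
#' @export
filter_mutation <- function(candidates, sub, position, mutant) {
  stopifnot(inherits(sub, "substrate"))
  idx <- position - sub$numbering_offset + 1L
  if (idx < 1L || idx > nchar(sub$sequence)) stop("mutation position outside substrate")
  if (substr(sub$sequence, idx, idx) != mutant) {
    stop(sprintf("substrate residue at position %d is %s, not %s",
                 position, substr(sub$sequence, idx, idx), mutant))
  }
  covers <- function(r) {
    (!is.na(r[["sr1_start"]]) && position >= r[["sr1_start"]] && position <= r[["sr1_end"]]) ||
      (!is.na(r[["sr2_start"]]) && position >= r[["sr2_start"]] && position <= r[["sr2_end"]])
  }
  keep <- vapply(seq_len(nrow(candidates)), function(i) covers(candidates[i, ]),
                 logical(1L))
  out <- candidates[keep, , drop = FALSE]
  out$carries_mutation <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Filter candidates by predicted HLA-I binding affinity
#'
#' Keeps candidates whose predicted IC50 is at or below the cutoff
#' (default 100 nM, boundary inclusive). The prediction source is
#' pluggable: a data.frame (columns `peptide`, `ic50_nM`) or a function
#' `f(peptides) -> ic50 vector`.
#'
#' @param candidates data.frame with a `sequence` column.
#' @param predictions prediction table or callable.
#' @param cutoff_nM IC50 cutoff in nM (> 0).
#' @return Subset of `candidates` with a `predicted_ic50` column;
#'   candidates without a prediction are dropped with a warning.
#' @export
filter_binding <- function(candidates, predictions, cutoff_nM = 100) {
  if (cutoff_nM <= 0) stop("cutoff must be positive")
  if (!nrow(candidates)) {
    candidates$predicted_ic50 <- numeric(0)
    return(candidates)
  }
  if (is.function(predictions)) {
    ic50 <- predictions(candidates$sequence)
  } else {
    stopifnot(all(c("peptide", "ic50_nM") %in% names(predictions)))
    ic50 <- predictions$ic50_nM[match(candidates$sequence, predictions$peptide)]
  }
  if (anyNA(ic50)) {
    warning(sprintf("%d candidate(s) without a binding prediction were dropped",
                    sum(is.na(ic50))))
  }
  keep <- !is.na(ic50) & ic50 <= cutoff_nM
  out <- candidates[keep, , drop = FALSE]
  out$predicted_ic50 <- ic50[keep]
  rownames(out) <- NULL
  out
}

#' Check whether a peptide is unique to its source protein
#'
#' For every proteome entry, reports whether the peptide can be produced
#' by hydrolysis (substring) or by cis peptide splicing (>= 1 two-segment
#' disjoint decomposition). The peptide is "unique" when no protein other
#' than `source_id` can produce it either way.
#'
#' @param peptide amino-acid sequence.
#' @param proteome named character vector of protein sequences (names are
#'   IDs) or data.frame with `id`, `sequence`.
#' @param source_id optional ID of the designated source protein.
#' @param include_reverse consider reverse-order cis splicing too.
#' @return list with `report` (data.frame: id, nonspliced, cis) and
#'   `unique` flag.
#' @export
check_uniqueness <- function(peptide, proteome, source_id = NULL,
                             include_reverse = TRUE) {
  if (is.data.frame(proteome)) {
    proteome <- stats::setNames(proteome$sequence, proteome$id)
  }
  if (!length(proteome)) stop("proteome is empty")
  peptide <- toupper(peptide)
  n <- nchar(peptide)
  res <- lapply(names(proteome), function(id) {
    seqp <- toupper(proteome[[id]])
    nonspliced <- length(find_occurrences(peptide, seqp)) > 0L
    cis <- FALSE
    if (n >= 2L) {
      for (k in seq_len(n - 1L)) {
        occ1 <- find_occurrences(substr(peptide, 1L, k), seqp)
        if (!length(occ1)) next
        occ2 <- find_occurrences(substr(peptide, k + 1L, n), seqp)
        if (!length(occ2)) next
        for (i1 in occ1) {
          j1 <- i1 + k - 1L
          for (i2 in occ2) {
            j2 <- i2 + (n - k) - 1L
            if (j1 < i2 || (include_reverse && j2 < i1)) { cis <- TRUE; break }
          }
          if (cis) break
        }
        if (cis) break
      }
    }
    data.frame(id = id, nonspliced = nonspliced, cis = cis,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, res)
  producers <- report$id[report$nonspliced | report$cis]
  unique_flag <- !length(setdiff(producers, source_id))
  list(report = report, unique = unique_flag)
}
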