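#' Validate an amino-acid sequence against the canonical alphabet
#'
#' @param sequence character scalar, amino-acid sequence.
#' @return Invisibly `TRUE`; errors with the offending positions otherwise.
#' @keywords internal
check_canonical <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("sequence is empty")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad)) {
    stop(sprintf("non-canonical residue(s) %s at position(s) %s",
                 paste(unique(chars[bad]), collapse = ","),
                 paste(utils::head(bad, 10L), collapse = ",")))
  }
  invisible(TRUE)
}

#' Net charge of a peptide/protein at a given pH
#'
#' Henderson-Hasselbalch net charge under the EMBOSS pKa set: positive
#' contributions from the N-terminus, K, R and H; negative from the
#' C-terminus, D, E, C and Y.
#'
#' @param sequence amino-acid sequence (canonical alphabet).
#' @param pH pH value(s).
#' @return Net charge, same length as `pH`.
#' @export
net_charge <- function(sequence, pH) {
  check_canonical(sequence)
  counts <- table(factor(strsplit(sequence, "", fixed = TRUE)[[1L]],
                         levels = AA_ALPHABET))
  pos <- function(pka) 1 / (1 + 10^(pH - pka))    # fraction protonated
  neg <- function(pka) 1 / (1 + 10^(pka - pH))    # fraction deprotonated
  charge <- pos(EMBOSS_PKA$Nterm) - neg(EMBOSS_PKA$Cterm)
  charge <- charge +
    counts[["K"]] * pos(EMBOSS_PKA$K) +
    counts[["R"]] * pos(EMBOSS_PKA$R) +
    counts[["H"]] * pos(EMBOSS_PKA$H) -
    counts[["D"]] * neg(EMBOSS_PKA$D) -
    counts[["E"]] * neg(EMBOSS_PKA$E) -
    counts[["C"]] * neg(EMBOSS_PKA$C) -
    counts[["Y"]] * neg(EMBOSS_PKA$Y)
  charge
}

#' Isoelectric point by bisection on the net-charge function
#'
#' @inheritParams net_charge
#' @param tol bisection tolerance in pH units.
#' @return pI in pH units, in (0, 14).
#' @export
isoelectric_point <- function(sequence, tol = 1e-6) {
  lo <- 0; hi <- 14
  # net_charge is monotone decreasing in pH
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical feature vector of a protein
#'
#' Computes the four features used by the antigen-representation model:
#' sequence length, mean Kyte-Doolittle hydropathy (GRAVY), isoelectric
#' point (EMBOSS pKa set, bisection) and the Guruprasad instability index
#' `II = (10/L) * sum_i DIWV(x_i, x_{i+1})`.
#'
#' @param sequence amino-acid sequence over the canonical 20-letter
#'   alphabet; non-canonical residues raise an error naming the position.
#' @return Named numeric vector with elements `length`, `hydrophobicity`,
#'   `isoelectric_point`, `instability`.
#' @examples
#' compute_protein_features("KLVVVGAVGV")
#' @export
compute_protein_features <- function(sequence) {
  check_canonical(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  gravy <- mean(KD_HYDROPATHY[chars])
  instab <- if (L >= 2L) {
    (10 / L) * sum(DIWV[cbind(chars[-L], chars[-1L])])
  } else 0
  c(length = L,
    hydrophobicity = gravy,
    isoelectric_point = isoelectric_point(sequence),
    instability = instab)
}

#' Feature table for a set of proteins
#'
#' @param proteins named character vector (names are protein IDs) or a
#'   data.frame with columns `id` and `sequence`.
#' @param on_noncanonical `"skip"` (default; skipped records are counted
#'   in a message) or `"error"`.
#' @return data.frame with columns `id`, `length`, `hydrophobicity`,
#'   `isoelectric_point`, `instability`.
#' @export
compute_feature_table <- function(proteins, on_noncanonical = c("skip", "error")) {
  on_noncanonical <- match.arg(on_noncanonical)
  if (is.data.frame(proteins)) {
    seqs <- stats::setNames(proteins$sequence, proteins$id)
  } else {
    seqs <- proteins
    if (is.null(names(seqs))) names(seqs) <- paste0("protein", seq_along(seqs))
  }
  ok <- vapply(seqs, function(s) {
    nzchar(s) && !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), s)
  }, logical(1L))
  if (any(!ok)) {
    if (on_noncanonical == "error") {
      stop(sprintf("%d sequence(s) contain non-canonical residues: %s",
                   sum(!ok), paste(utils::head(names(seqs)[!ok], 5L), collapse = ", ")))
    }
    message(sprintf("skipping %d sequence(s) with non-canonical residues", sum(!ok)))
    seqs <- seqs[ok]
  }
  if (!length(seqs)) stop("no usable sequences")
  feats <- t(vapply(seqs, compute_protein_features, numeric(4L)))
  data.frame(id = names(seqs), feats, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Standardize a feature table against a reference (control) set
#'
#' Each feature column is transformed to zero mean and unit standard
#' deviation with respect to the reference table; the same scaling is then
#' applied to any other table (e.g. candidate antigens) so that feature
#' sums are comparable.
#'
#' @param feature_table data.frame from [compute_feature_table()].
#' @param reference reference feature table supplying mean/sd; defaults to
#'   `feature_table` itself.
#' @param scaling optional pre-computed scaling (as returned in the
#'   `"scaling"` attribute) overriding `reference`.
#' @return The standardized table, with a `"scaling"` attribute holding a
#'   data.frame of per-feature `mean` and `sd`.
#' @export
standardize_features <- function(feature_table, reference = feature_table,
                                 scaling = NULL) {
  cols <- c("length", "hydrophobicity", "isoelectric_point", "instability")
  stopifnot(all(cols %in% names(feature_table)))
  if (is.null(scaling)) {
    if (!nrow(reference)) stop("reference set is empty")
    mu <- vapply(reference[cols], mean, numeric(1L))
    sd <- vapply(reference[cols], stats::sd, numeric(1L))
    zero <- cols[is.na(sd) | sd == 0]
    if (length(zero)) {
      stop("zero-variance feature(s) in reference: ",
           paste(zero, collapse = ", "))
    }
    scaling <- data.frame(feature = cols, mean = mu, sd = sd,
                          row.names = NULL)
  }
  out <- feature_table
  for (i in seq_along(cols)) {
    out[[cols[i]]] <- (feature_table[[cols[i]]] - scaling$mean[i]) / scaling$sd[i]
  }
  attr(out, "scaling") <- scaling
  out
}

#' Feature sum f = sum(p_i * c_i)
#'
#' Dot product of the factor vector with (standardized) feature values.
#' Negative factors favor representation in HLA-I immunopeptidomes,
#' positive factors disfavor it.
#'
#' @param factors numeric vector of 4 weights in \[-1, 1\].
#' @param features numeric vector of 4 standardized features, or a
#'   standardized feature table (data.frame), in which case one feature
#'   sum per row is returned.
#' @return Numeric feature sum(s).
#' @export
feature_sum <- function(factors, features) {
  factors <- validate_factors(factors)
  cols <- c("length", "hydrophobicity", "isoelectric_point", "instability")
  if (is.data.frame(features)) {
    as.numeric(as.matrix(features[cols]) %*% factors)
  } else {
    if (length(features) != 4L) stop("feature vector must have 4 components")
    sum(factors * features)
  }
}

#' @keywords internal
validate_factors <- function(factors) {
  if (length(factors) != 4L || !is.numeric(factors)) {
    stop("factor vector must be numeric of length 4")
  }
  if (any(!is.finite(factors)) || any(abs(factors) > 1)) {
    stop("factors must lie within [-1, 1]")
  }
  as.numeric(factors)
}
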