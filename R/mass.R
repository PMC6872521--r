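#' Monoisotopic neutral mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water.
#'
#' @param peptide amino-acid sequence (canonical alphabet).
#' @return Mass in Da.
#' @export
peptide_mass <- function(peptide) {
  check_canonical(peptide)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  sum(AA_MONO_MASS[chars]) + MASS_WATER
}

#' Build a targeted-MS m/z inclusion list
#'
#' One entry per peptide and charge state, `mz = (M + z * m_proton) / z`
#' with the monoisotopic neutral mass M; sorted by m/z.
#'
#' @param peptides character vector of peptide sequences (a data.frame
#'   with `sequence` and optionally `category` columns is also accepted).
#' @param charges integer charge states, subset of 1..7.
#' @return data.frame with columns `sequence`, `charge`, `mz` (and
#'   `category` if supplied), sorted non-decreasing in `mz`.
#' @export
build_inclusion_list <- function(peptides, charges = 1:3) {
  if (!all(charges %in% 1:7)) stop("charges must be within 1..7")
  category <- NULL
  if (is.data.frame(peptides)) {
    category <- peptides$category
    peptides <- peptides$sequence
  }
  u <- !duplicated(peptides)
  peptides <- peptides[u]
  if (!is.null(category)) category <- category[u]
  masses <- vapply(peptides, peptide_mass, numeric(1L))
  out <- do.call(rbind, lapply(seq_along(charges), function(k) {
    z <- charges[k]
    data.frame(sequence = peptides,
               charge = z,
               mz = (masses + z * MASS_PROTON) / z,
               category = if (is.null(category)) NA_character_ else category,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$mz, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export enumerated peptides as a customized FASTA search database
#'
#' One record per unique peptide sequence. The header encodes the
#' substrate ID, the sequence-level category (classification precedence
#' non-spliced > cis > trans over all of the sequence's decompositions),
#' the coordinates of one representative decomposition and the number of
#' alternative decompositions.
#'
#' @param entries data.frame of coordinate-level entries as produced by
#'   [enumerate_nonspliced()] / [enumerate_cis()] / [map_peptide()].
#' @param path output FASTA path.
#' @param substrate_id substrate identifier embedded in headers.
#' @return Invisibly, the number of records written.
#' @export
export_search_database <- function(entries, path, substrate_id = "substrate") {
  if (!nrow(entries)) stop("no entries to export")
  split_idx <- split(seq_len(nrow(entries)), entries$sequence)
  precedence <- c("non-spliced" = 1L, "cis-normal" = 2L, "cis-reverse" = 2L,
                  trans = 3L)
  headers <- character(length(split_idx))
  seqs <- character(length(split_idx))
  for (k in seq_along(split_idx)) {
    rows <- entries[split_idx[[k]], , drop = FALSE]
    cat_seq <- classify_peptide(rows)
    best <- rows[order(precedence[rows$category]), , drop = FALSE][1L, ]
    coord <- if (is.na(best$sr2_start)) {
      sprintf("%d-%d", best$sr1_start, best$sr1_end)
    } else {
      sprintf("%d-%d/%d-%d", best$sr1_start, best$sr1_end,
              best$sr2_start, best$sr2_end)
    }
    headers[k] <- sprintf("%s|%s|%s|alt=%d", substrate_id, cat_seq, coord,
                          nrow(rows) - 1L)
    seqs[k] <- best$sequence
  }
  write_fasta(stats::setNames(seqs, headers), path)
  invisible(length(seqs))
}
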