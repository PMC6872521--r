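# Independent brute-force oracles used to validate enumeration, mapping
# and uniqueness checks. Deliberately naive: nested loops over all
# intervals, no shared code with the package internals.

# every (sequence, category, coordinates) product of a substrate string,
# internal 1-based coordinates
oracle_products <- function(seqstr, lmin, lmax, include_reverse = TRUE,
                            min_sr = 1L) {
  L <- nchar(seqstr)
  rows <- list()
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (j < i) next
    len <- j - i + 1L
    if (len >= lmin && len <= lmax) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(seqstr, i, j), category = "non-spliced",
        i1 = i, j1 = j, i2 = NA_integer_, j2 = NA_integer_)
    }
  }
  for (i1 in seq_len(L)) for (j1 in seq_len(L)) {
    if (j1 < i1 || j1 - i1 + 1L < min_sr) next
    for (i2 in seq_len(L)) for (j2 in seq_len(L)) {
      if (j2 < i2 || j2 - i2 + 1L < min_sr) next
      total <- (j1 - i1 + 1L) + (j2 - i2 + 1L)
      if (total < lmin || total > lmax) next
      if (j1 < i2) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = paste0(substr(seqstr, i1, j1), substr(seqstr, i2, j2)),
          category = "cis-normal", i1 = i1, j1 = j1, i2 = i2, j2 = j2)
      } else if (include_reverse && j2 < i1) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = paste0(substr(seqstr, i1, j1), substr(seqstr, i2, j2)),
          category = "cis-reverse", i1 = i1, j1 = j1, i2 = i2, j2 = j2)
      }
    }
  }
  do.call(rbind, rows)
}

# every decomposition (non-spliced, cis both orders, trans) of a peptide
# against a substrate string, internal coordinates
oracle_map <- function(peptide, seqstr, min_sr = 1L) {
  n <- nchar(peptide)
  L <- nchar(seqstr)
  rows <- list()
  for (i in seq_len(L)) {
    j <- i + n - 1L
    if (j <= L && substr(seqstr, i, j) == peptide) {
      rows[[length(rows) + 1L]] <- data.frame(
        category = "non-spliced", i1 = i, j1 = j,
        i2 = NA_integer_, j2 = NA_integer_)
    }
  }
  if (n >= 2L) {
    for (k in seq(min_sr, n - min_sr)) {
      for (i1 in seq_len(L)) {
        j1 <- i1 + k - 1L
        if (j1 > L || substr(seqstr, i1, j1) != substr(peptide, 1L, k)) next
        for (i2 in seq_len(L)) {
          j2 <- i2 + (n - k) - 1L
          if (j2 > L || substr(seqstr, i2, j2) != substr(peptide, k + 1L, n)) next
          cat_ <- if (j1 < i2) "cis-normal"
                  else if (j2 < i1) "cis-reverse"
                  else "trans"
          rows[[length(rows) + 1L]] <- data.frame(
            category = cat_, i1 = i1, j1 = j1, i2 = i2, j2 = j2)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(category = character(), i1 = integer(), j1 = integer(),
                      i2 = integer(), j2 = integer()))
  }
  do.call(rbind, rows)
}

# canonical string keys for set comparison of decomposition tables
decomp_keys <- function(df, cols = c("category", "i1", "j1", "i2", "j2")) {
  sort(do.call(paste, c(df[cols], sep = "|")))
}

# package table (parental coords) -> internal-coordinate key strings
pkg_decomp_keys <- function(df, offset) {
  o <- offset - 1L
  sort(paste(df$category, df$sr1_start - o, df$sr1_end - o,
             ifelse(is.na(df$sr2_start), NA, df$sr2_start - o),
             ifelse(is.na(df$sr2_end), NA, df$sr2_end - o), sep = "|"))
}

random_substrate_seq <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

cosine_similarity <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
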