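#' Read protein records from a FASTA file
#'
#' Parsing is delegated to Biostrings; IDs are taken from headers up to
#' the first whitespace and sequences are uppercased.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (!length(set)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write protein records to a FASTA file
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  if (!length(records)) stop("no records to write")
  set <- Biostrings::AAStringSet(records)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All thresholds of the candidate-identification pipeline with their
#' default values: length range 8-12, IC50 cutoff 100 nM, ion score 20,
#' q-value 0.05, relative delta score 30%, synthesis-artifact threshold
#' 5% of the series maximum, alternation threshold 50%, plus the MCMC
#' and KDE blocks.
#'
#' @param ... named overrides of any default (nested lists are merged
#'   shallowly per block).
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_len = 8L, max_len = 12L,
    ic50_cutoff = 100,
    include_reverse = TRUE,
    min_sr = 1L,
    ion_score_cutoff = 20,
    q_value_cutoff = 0.05,
    delta_score = 0.30,
    artifact_fraction = 0.05,
    alternation_fraction = 0.50,
    min_biological_replicates = 2L,
    min_technical_replicates = 2L,
    mcmc = list(n_samples = 1000L, burn_in = 1000L, thin = 1L,
                proposal_sd = 0.1, beta = 50),
    kde = list(n_grid = 512L, pad = 3),
    seed = 1L
  )
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys override [default_config()] values.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(default_config, user)
}

#' Run the in silico candidate-identification pipeline
#'
#' Chains enumeration of all theoretical spliced and non-spliced
#' products, the mutation-coverage filter, the length filter (implicit in
#' enumeration) and the HLA-I binding filter, and reports the surviving
#' candidate sequences together with a per-stage funnel count table.
#' Optionally cross-checks candidates against a table of quantified
#' digestion products.
#'
#' @param sub the mutated [substrate()].
#' @param mutation list with `position` (parental) and `residue`
#'   (mutant letter).
#' @param predictions binding-prediction table or callable
#'   (see [filter_binding()]).
#' @param config configuration list from [default_config()].
#' @param quantified optional data.frame of quantified products with a
#'   `sequence` column; surviving candidates get a `detected` flag.
#' @return list with `candidates` (data.frame, sequence level) and
#'   `funnel` (data.frame of per-stage counts, monotone non-increasing).
#' @export
run_pipeline <- function(sub, mutation, predictions,
                         config = default_config(), quantified = NULL) {
  lr <- c(config$min_len, config$max_len)
  theoretical <- rbind(
    enumerate_nonspliced(sub, lr),
    enumerate_cis(sub, lr, include_reverse = config$include_reverse,
                  min_sr = config$min_sr)
  )
  n_coord <- nrow(theoretical)
  uniq <- theoretical[!duplicated(theoretical$sequence), , drop = FALSE]
  n_seq <- nrow(uniq)

  mut <- filter_mutation(theoretical, sub, mutation$position, mutation$residue)
  mut_seq <- mut[!duplicated(mut$sequence), , drop = FALSE]
  n_mut <- nrow(mut_seq)

  bound <- filter_binding(mut_seq, predictions, config$ic50_cutoff)
  n_bind <- nrow(bound)

  if (!n_bind) warning("no candidates survive the binding filter")
  if (!is.null(quantified)) {
    bound$detected <- bound$sequence %in% quantified$sequence
  }
  funnel <- data.frame(
    stage = c("theoretical_coordinate", "unique_sequence",
              "carries_mutation", "binding_le_cutoff"),
    count = c(n_coord, n_seq, n_mut, n_bind),
    stringsAsFactors = FALSE
  )
  list(candidates = bound, funnel = funnel)
}

#' Write a machine-readable run manifest
#'
#' Records the resolved configuration, seed, package version and MD5
#' checksums of the input files next to a run's outputs.
#'
#' @param path output JSON path.
#' @param config resolved configuration list.
#' @param inputs character vector of input file paths (checksummed).
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, config, inputs = character()) {
  manifest <- list(
    package = "proteasplice",
    version = as.character(utils::packageVersion("proteasplice")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    inputs = if (length(inputs)) {
      data.frame(path = inputs, md5 = tools::md5sum(inputs),
                 row.names = NULL)
    } else NULL
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
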