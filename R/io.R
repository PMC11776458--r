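# Reading and writing the standard tabular interfaces: the four EHR-style
# input tables as TSV, and scenario configuration from YAML or JSON.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated two-sample dataset as TSV tables
#'
#' Writes `sample1/` (subjects, prescriptions, diagnoses) and `sample2/`
#' (subjects, prescriptions, index_dates, genus) under `dir`, plus a
#' `diseases.tsv` mapping disease names to their ICD-10 prefixes.
#'
#' @param sim an `abivr_simdata` object from [simulate_two_samples()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_simdata <- function(sim, dir) {
  stopifnot(inherits(sim, "abivr_simdata"))
  d1 <- file.path(dir, "sample1")
  d2 <- file.path(dir, "sample2")
  dir.create(d1, showWarnings = FALSE, recursive = TRUE)
  dir.create(d2, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sim$sample1$subjects, file.path(d1, "subjects.tsv"))
  write_tsv(sim$sample1$prescriptions, file.path(d1, "prescriptions.tsv"))
  write_tsv(sim$sample1$diagnoses, file.path(d1, "diagnoses.tsv"))
  write_tsv(sim$sample2$subjects, file.path(d2, "subjects.tsv"))
  write_tsv(sim$sample2$prescriptions, file.path(d2, "prescriptions.tsv"))
  write_tsv(sim$sample2$index_dates, file.path(d2, "index_dates.tsv"))
  write_tsv(sim$sample2$genus, file.path(d2, "genus.tsv"))
  codes <- scenario_icd_codes(sim$scenario)
  write_tsv(data.frame(disease = names(codes),
                       icd10_prefixes = vapply(codes, paste, "",
                                               collapse = ","),
                       stringsAsFactors = FALSE),
            file.path(dir, "diseases.tsv"))
  invisible(dir)
}

#' Read a sample directory written by [write_simdata()]
#'
#' @param dir directory containing `subjects.tsv`, `prescriptions.tsv`
#'   and optionally `diagnoses.tsv`, `index_dates.tsv`, `genus.tsv`.
#' @return list suitable as `sample1`/`sample2` input to [abivr()].
#' @export
read_sample_dir <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- list(subjects = rd("subjects.tsv"),
              prescriptions = rd("prescriptions.tsv"),
              diagnoses = rd("diagnoses.tsv"),
              index_dates = rd("index_dates.tsv"),
              genus = rd("genus.tsv"))
  out[!vapply(out, is.null, logical(1))]
}

#' Read disease definitions from a TSV or YAML file
#'
#' TSV files need columns `disease` and `icd10_prefixes`
#' (comma-separated); YAML files map disease names to prefix lists.
#'
#' @param path file path.
#' @return named list of ICD-10 prefix vectors.
#' @export
read_disease_codes <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed to read YAML files", call. = FALSE)
    }
    raw <- yaml::read_yaml(path)
    return(lapply(raw, as.character))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(strsplit(tab$icd10_prefixes, ","), tab$disease)
}

#' Read a simulation scenario from YAML or JSON
#'
#' The file holds arguments of [sim_scenario()]; unspecified fields keep
#' their defaults.  Dates may be ISO-8601 strings.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an `abivr_scenario` object.
#' @export
read_scenario <- function(path) {
  if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the 'jsonlite' package is needed to read JSON files",
           call. = FALSE)
    }
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed to read YAML files", call. = FALSE)
    }
    raw <- yaml::read_yaml(path)
  }
  if (!is.null(raw$disease_specs)) {
    raw$disease_specs <- as.data.frame(raw$disease_specs,
                                       stringsAsFactors = FALSE)
  }
  for (f in c("index_date_s1", "followup_end")) {
    if (!is.null(raw[[f]])) raw[[f]] <- as.Date(raw[[f]])
  }
  if (!is.null(raw$index_window_s2)) {
    raw$index_window_s2 <- as.Date(unlist(raw$index_window_s2))
  }
  if (!is.null(raw$class_split)) raw$class_split <- unlist(raw$class_split)
  do.call(sim_scenario, raw)
}
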