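# Microbiome exposure: the log Prevotella/Bacteroides ratio.
#
# The P/B ratio is a one-dimensional summary of gut community state along
# the enterotype axis.  Zeros are imputed with a pseudocount equal to half
# the minimal non-zero relative abundance observed anywhere in the genus
# table; the ratio itself is unit-invariant, so percent vs proportion
# input only affects reporting.

#' Compute the log Prevotella/Bacteroides ratio
#'
#' Imputes zeros in the Prevotella and Bacteroides columns with a
#' pseudocount equal to half the minimal non-zero relative abundance
#' observed across the whole genus table (all persons, all genera), then
#' returns the natural log of the Prevotella/Bacteroides ratio per
#' person.
#'
#' @param table genus-level relative-abundance table: a data frame with a
#'   `person_id` column (or person ids as row names) and one numeric
#'   column per genus, including `Prevotella` and `Bacteroides`.
#' @param units abundance units: `"auto"` (detected from row sums:
#'   near 100 means percent, near 1 means proportion), `"percent"` or
#'   `"proportion"`.  Recorded as an attribute; the log-ratio does not
#'   depend on it.
#' @param int if `TRUE`, also return the rank-based inverse-normal
#'   transform of the log ratio in column `log_pb_int` (see
#'   [rank_inverse_normal()]).
#' @return data frame of class `abivr_mbfeature` with columns
#'   `person_id`, `log_pb` and optionally `log_pb_int`; attributes
#'   `pseudocount` and `units`.
#' @examples
#' tab <- data.frame(person_id = c("a", "b"),
#'                   Prevotella = c(0, 30), Bacteroides = c(30, 30),
#'                   Faecalibacterium = c(70, 40))
#' compute_log_pb(tab)
#' @export
compute_log_pb <- function(table, units = c("auto", "percent", "proportion"),
                           int = FALSE) {
  units <- match.arg(units)
  if (is.matrix(table)) table <- as.data.frame(table)
  if ("person_id" %in% names(table)) {
    ids <- as.character(table$person_id)
    mat <- as.matrix(table[setdiff(names(table), "person_id")])
  } else {
    ids <- rownames(table)
    mat <- as.matrix(table)
  }
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("genus table needs unique person ids", call. = FALSE)
  }
  for (g in c("Prevotella", "Bacteroides")) {
    if (!g %in% colnames(mat)) stop("column '", g, "' missing", call. = FALSE)
  }
  if (!is.numeric(mat) || any(mat < 0)) {
    stop("abundances must be non-negative numbers", call. = FALSE)
  }
  nz <- mat[mat > 0]
  if (length(nz) == 0L) stop("all abundances are zero", call. = FALSE)
  pseudo <- min(nz) / 2

  if (units == "auto") {
    rs <- stats::median(rowSums(mat))
    units <- if (abs(rs - 100) < abs(rs - 1)) "percent" else "proportion"
  }

  p <- mat[, "Prevotella"]
  b <- mat[, "Bacteroides"]
  p[p == 0] <- pseudo
  b[b == 0] <- pseudo
  out <- data.frame(person_id = ids, log_pb = log(p / b),
                    stringsAsFactors = FALSE)
  if (int) out$log_pb_int <- rank_inverse_normal(out$log_pb)
  attr(out, "pseudocount") <- pseudo
  attr(out, "units") <- units
  class(out) <- c("abivr_mbfeature", "data.frame")
  out
}

#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles by rank:
#' `qnorm((rank - offset) / (n + 1 - 2 * offset))`, with average ranks
#' for ties.  The default offset 3/8 is the Blom offset, matching the
#' common convention for inverse-normal transformation of skewed or
#' multi-modal traits.
#'
#' @param values numeric vector, length at least 2, not all equal.
#' @param offset rank offset in `[0, 0.5]` (default 3/8).
#' @return numeric vector of transformed values, order-preserving.
#' @examples
#' rank_inverse_normal(c(3, 1, 2))
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  if (diff(range(values)) == 0) {
    # all ties: average ranks map everything to the median quantile (0)
    warning("constant vector: inverse-normal transform is degenerate",
            call. = FALSE)
  }
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (length(values) + 1 - 2 * offset))
}

#' Read a genus-level relative-abundance table
#'
#' Reads a wide TSV with either persons as rows (first column
#' `person_id`, genera as columns) or MetaPhlAn-style taxa as rows
#' (first column the genus name, persons as columns), transposing the
#' latter.  Genus labels of the form `k__...|g__Prevotella` are reduced
#' to the genus name.
#'
#' @param path path to the TSV file.
#' @param orientation `"auto"` (default), `"persons"` (persons as rows)
#'   or `"taxa"` (taxa as rows).
#' @return data frame with `person_id` plus one numeric column per genus.
#' @export
read_genus_table <- function(path, orientation = c("auto", "persons", "taxa")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (orientation == "auto") {
    orientation <- if (tolower(names(raw)[1]) %in%
                       c("person_id", "sample_id", "id")) "persons" else "taxa"
  }
  if (orientation == "taxa") {
    taxa <- sub("^.*g__", "", as.character(raw[[1]]))
    mat <- t(as.matrix(raw[-1]))
    colnames(mat) <- taxa
    out <- data.frame(person_id = rownames(mat), mat, check.names = FALSE,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  } else {
    out <- raw
    names(out)[1] <- "person_id"
    out$person_id <- as.character(out$person_id)
  }
  out
}
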