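# Readers and writers for the pinned TSV dialect: tab-delimited, UTF-8,
# '.' decimal, no quoting, '#' starts a comment line. Gene identifiers are
# opaque case-sensitive strings; no identifier mapping is attempted.

#' Read a network edge list (TSV or SIF)
#'
#' Two-column TSV (gene_a TAB gene_b) or three-column SIF
#' (gene_a TAB relation TAB gene_b, relation ignored); '#' comment lines
#' are skipped.
#'
#' @param path Input path.
#' @return A \code{gene_network} (via \code{\link{build_network}}).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty network")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf == 3L)) {
    edges <- t(vapply(fields, function(f) f[c(1L, 3L)], character(2)))
  } else if (all(nf == 2L)) {
    edges <- t(vapply(fields, function(f) f[1:2], character(2)))
  } else {
    stop(sprintf("edge list line %d has %d field(s); expected 2 (TSV) or 3 (SIF)",
                 which(!(nf %in% c(2L, 3L)))[1L],
                 nf[!(nf %in% c(2L, 3L))][1L]))
  }
  build_network(edges)
}

#' Read a seed gene file (one gene per line)
#'
#' @param path Input path.
#' @return Character vector of seed genes.
#' @export
read_seeds <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0L) stop("empty seed file")
  unique(x)
}

#' Read a numeric gene x sample matrix from TSV
#'
#' First column holds gene identifiers, header row holds sample identifiers.
#' Duplicate gene rows are collapsed by their mean with a warning; ragged
#' rows and non-numeric cells are errors. Also used for gene x sample
#' copy-number tables.
#'
#' @param path Input path.
#' @param unit Unit tag attached to the result (default
#'   \code{"normalized"}).
#' @return Numeric matrix with dimnames and a \code{unit} attribute.
#' @export
read_matrix <- function(path, unit = "normalized") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#",
                            quote = "")
  if (length(unique(nf)) > 1L) {
    stop(sprintf("ragged row %d: %d fields, expected %d",
                 which(nf != nf[1L])[1L], nf[nf != nf[1L]][1L], nf[1L]))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", quote = "",
                          check.names = FALSE, colClasses = "character")
  genes <- df[[1L]]
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, colnames(df)[-1L]))
  if (any(is.na(vals) & !is.na(as.matrix(df[-1L])))) {
    bad <- which(apply(is.na(vals), 1L, any))[1L]
    stop(sprintf("non-numeric cell in data row %d", bad))
  }
  if (anyDuplicated(genes)) {
    warning("duplicate gene rows collapsed by mean")
    sums <- rowsum(vals, genes)
    counts <- as.vector(table(genes)[rownames(sums)])
    vals <- sums / counts
    colnames(vals) <- colnames(df)[-1L]
  } else {
    rownames(vals) <- genes
  }
  attr(vals, "unit") <- unit
  vals
}

#' Write a numeric matrix as TSV (genes as rows)
#'
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the identifier column, default "gene".
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(mat, path, id_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample score table (sample TAB value)
#'
#' @param path Input path.
#' @return Named numeric vector.
#' @export
read_sample_scores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", quote = "",
                          check.names = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Read a response label table (sample, response[, timing])
#'
#' @param path Input path.
#' @return Data frame with columns \code{sample}, \code{response} and
#'   (if present) \code{timing}.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", quote = "",
                          check.names = FALSE,
                          stringsAsFactors = FALSE)
  colnames(df)[1:2] <- c("sample", "response")
  if (ncol(df) >= 3L) colnames(df)[3L] <- "timing"
  bad <- setdiff(unique(df$response), c("response", "non-response"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown response label(s): %s (expected 'response'/'non-response')",
                 paste(bad, collapse = ", ")))
  }
  df
}

#' Write a generic data frame as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse RECIST categories into binary response labels
#'
#' CR and PR collapse to "response"; SD and PD to "non-response".
#'
#' @param recist Character vector of RECIST categories.
#' @return Character vector of binary labels.
#' @export
recist_to_response <- function(recist) {
  up <- toupper(trimws(recist))
  bad <- setdiff(unique(up), c("CR", "PR", "SD", "PD"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown RECIST categories: %s", paste(bad, collapse = ", ")))
  }
  ifelse(up %in% c("CR", "PR"), "response", "non-response")
}

#' Write a run manifest
#'
#' Records the command, parameter map, input-file MD5 checksums, package
#' version and timestamp as JSON, sufficient to reproduce the run given the
#' same inputs.
#'
#' @param path Output path (JSON).
#' @param command Command or stage name.
#' @param params Named list of parameters (seeds, gamma, tau, ...).
#' @param inputs Named character vector of input file paths to checksum.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, params = list(),
                           inputs = character()) {
  checksums <- lapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  })
  manifest <- list(
    command = command,
    params = params,
    input_checksums = checksums,
    package = "netmias",
    version = as.character(utils::packageVersion("netmias")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
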