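#' Create a gene set
#'
#' @param name Gene set name.
#' @param members Character vector of member genes (deduplicated).
#' @param description Optional free-text description.
#' @return A \code{gene_set} list with \code{name}, \code{description},
#'   \code{members}.
#' @export
gene_set <- function(name, members, description = "") {
  members <- unique(as.character(members))
  members <- members[members != "" & !is.na(members)]
  if (length(members) == 0L) stop("gene set must be nonempty")
  structure(list(name = as.character(name),
                 description = as.character(description),
                 members = members),
            class = "gene_set")
}

#' Create a gene set collection
#'
#' @param sets A list of \code{gene_set} objects with unique names.
#' @return A \code{gene_set_collection} (named list of gene sets).
#' @export
gene_set_collection <- function(sets) {
  stopifnot(all(vapply(sets, inherits, logical(1), "gene_set")))
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate gene set names")
  names(sets) <- nm
  structure(sets, class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Blank and duplicate members on a line are dropped with a message.
#'
#' @param path Path to a GMT file.
#' @return A \code{gene_set_collection}.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    }
    members <- f[-(1:2)]
    members <- members[nzchar(trimws(members))]
    if (anyDuplicated(members)) {
      message(sprintf("read_gmt: duplicate members in set '%s' deduplicated",
                      f[1L]))
    }
    sets[[i]] <- gene_set(f[1L], members, f[2L])
  }
  gene_set_collection(sets)
}

#' Write gene sets to a GMT file
#'
#' @param collection A \code{gene_set_collection}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else "na",
            s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
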