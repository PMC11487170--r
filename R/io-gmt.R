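#' Read a GMT gene-set collection
#'
#' One set per line: set name, description, then member symbols, all
#' tab-separated. Members are de-duplicated preserving first-seen order.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (one per set), with the
#'   descriptions in attribute `descriptions` and `path` in `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1],
         " has fewer than 3 fields (a set needs >= 1 member)")
  }
  names_ <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set name: ", names_[duplicated(names_)][1])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  attr(sets, "descriptions") <- setNames(vapply(fields, `[`, character(1), 2),
                                         names_)
  attr(sets, "source") <- path
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions; defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must have unique names")
  }
  if (any(lengths(sets) == 0)) stop("every gene set must be non-empty")
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
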