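#' Construct a one-to-one ortholog map
#'
#' A validated table of one-to-one gene pairs between two species. Cross-
#' species projection and symbol mapping only ever use this correspondence.
#'
#' @param species_a,species_b species labels.
#' @param gene_a,gene_b character vectors of paired gene identifiers.
#' @return an `ortholog_map`: data.frame with columns `gene_a`, `gene_b` and
#'   attributes `species_a`, `species_b`.
#' @export
ortholog_map <- function(species_a, species_b, gene_a, gene_b) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (length(gene_a) != length(gene_b)) stop("gene_a and gene_b lengths differ")
  if (any(!nzchar(gene_a)) || any(!nzchar(gene_b)) ||
      any(is.na(gene_a)) || any(is.na(gene_b))) {
    stop("ortholog pair with an empty identifier")
  }
  if (anyDuplicated(gene_a)) {
    stop("one-to-one violation: gene '", gene_a[duplicated(gene_a)][1],
         "' appears in more than one pair on side '", species_a, "'")
  }
  if (anyDuplicated(gene_b)) {
    stop("one-to-one violation: gene '", gene_b[duplicated(gene_b)][1],
         "' appears in more than one pair on side '", species_b, "'")
  }
  out <- data.frame(gene_a = gene_a, gene_b = gene_b,
                    stringsAsFactors = FALSE)
  attr(out, "species_a") <- as.character(species_a)
  attr(out, "species_b") <- as.character(species_b)
  class(out) <- c("ortholog_map", "data.frame")
  out
}

#' Read one-to-one orthologs from OMA standalone output
#'
#' Consumes the `OrthologousMatrix.txt` / `Map-SeqNum-ID.txt` pair emitted by
#' OMA standalone. The matrix file may start with `#` comment lines, then has
#' a header of species labels and rows of integer entry numbers where 0 means
#' the species lacks an ortholog in that group. The map file has rows of
#' (species label, entry number, sequence id). Species are located by header
#' label, never by column position.
#'
#' @param matrix_path path to OrthologousMatrix.txt.
#' @param map_path path to Map-SeqNum-ID.txt.
#' @param species_a,species_b header labels of the two species to extract.
#' @return an [ortholog_map()] with the pairs where both species have a
#'   non-zero entry, translated to sequence ids.
#' @export
read_oma_orthologs <- function(matrix_path, map_path, species_a, species_b) {
  lines <- readLines(matrix_path)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) stop("empty OrthologousMatrix file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  for (sp in c(species_a, species_b)) {
    if (!sp %in% header) {
      stop("species '", sp, "' not found in OrthologousMatrix header")
    }
  }
  body <- lines[-1]
  ia <- match(species_a, header)
  ib <- match(species_b, header)
  entries <- lapply(strsplit(body, "\t", fixed = TRUE), function(f) {
    suppressWarnings(as.integer(f[c(ia, ib)]))
  })
  ea <- vapply(entries, `[`, integer(1), 1)
  eb <- vapply(entries, `[`, integer(1), 2)
  if (any(is.na(ea)) || any(is.na(eb))) {
    stop("non-integer entry in OrthologousMatrix body")
  }
  keep <- ea != 0L & eb != 0L

  map <- read.table(map_path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "#",
                    col.names = c("species", "entry", "id"))
  lookup <- function(species, entry_nums) {
    sub <- map[map$species == species, , drop = FALSE]
    idx <- match(entry_nums, sub$entry)
    if (anyNA(idx)) {
      stop("entry number ", entry_nums[which(is.na(idx))[1]],
           " for species '", species, "' has no Map-SeqNum-ID record")
    }
    sub$id[idx]
  }
  ortholog_map(species_a, species_b,
               lookup(species_a, ea[keep]),
               lookup(species_b, eb[keep]))
}

#' Write an ortholog map in the OMA standalone dialect
#'
#' Emits a synthetic `OrthologousMatrix.txt` / `Map-SeqNum-ID.txt` pair that
#' [read_oma_orthologs()] reads back to the same pair set.
#'
#' @param map an [ortholog_map()].
#' @param matrix_path,map_path output paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_oma_orthologs <- function(map, matrix_path, map_path) {
  stopifnot(inherits(map, "ortholog_map"))
  sa <- attr(map, "species_a")
  sb <- attr(map, "species_b")
  n <- nrow(map)
  con <- file(matrix_path, open = "wb")
  writeLines(c("# synthetic OMA standalone output",
               paste(sa, sb, sep = "\t"),
               paste(seq_len(n), seq_len(n), sep = "\t")),
             con, sep = "\n")
  close(con)
  con <- file(map_path, open = "wb")
  writeLines(c(paste(sa, seq_len(n), map$gene_a, sep = "\t"),
               paste(sb, seq_len(n), map$gene_b, sep = "\t")),
             con, sep = "\n")
  close(con)
  invisible(c(matrix_path, map_path))
}

#' Convert a Trinity gene_trans_map into an OMA splice file
#'
#' The Trinity `gene_trans_map` is two tab-separated columns (gene id,
#' transcript id), one row per transcript. The OMA splice dialect lists, one
#' line per gene, the transcript ids of genes with two or more isoforms,
#' joined by `"; "` in first-seen order; single-isoform genes are omitted
#' (OMA treats unlisted genes as single-variant).
#'
#' @param path path to a gene_trans_map file.
#' @param out optional output path; when given, lines are also written there.
#' @return character vector of splice-file lines.
#' @export
gene_trans_map_to_splice <- function(path, out = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2)) {
    stop("malformed gene_trans_map row at line ", which(nf != 2)[1],
         " (expected 2 tab-separated columns)")
  }
  genes <- vapply(fields, `[`, character(1), 1)
  txs <- vapply(fields, `[`, character(1), 2)
  if (anyDuplicated(txs)) {
    stop("duplicate transcript id: ", txs[duplicated(txs)][1])
  }
  by_gene <- split(txs, factor(genes, levels = unique(genes)))
  multi <- by_gene[lengths(by_gene) >= 2]
  splice <- vapply(multi, paste, character(1), collapse = "; ")
  splice <- unname(splice)
  if (!is.null(out)) {
    con <- file(out, open = "wb")
    on.exit(close(con))
    if (length(splice)) writeLines(splice, con, sep = "\n")
  }
  splice
}
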