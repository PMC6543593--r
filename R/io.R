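# Readers/writers for FASTA, Newick and TSV matrices, plus the shared
# tabular sequence representation used across the pipeline.
#
# Sequences are carried as tibbles with columns `id`, `desc`, `seq`,
# `alphabet` ("nucleotide" or "protein"); trees are ape `phylo` objects;
# distance and pan-matrices are base matrices with dimnames.

.NUC_CHARS <- "ACGTN-"
.PROT_CHARS <- "ACDEFGHIKLMNPQRSTVWYX-"

.clean_residues <- function(x, alphabet) {
  x <- toupper(x)
  allowed <- if (alphabet == "nucleotide") .NUC_CHARS else .PROT_CHARS
  repl <- if (alphabet == "nucleotide") "N" else "X"
  pat <- paste0("[^", allowed, "]")
  n_bad <- sum(vapply(gregexpr(pat, x), function(m) sum(m > 0), integer(1)))
  if (n_bad > 0) {
    warn(sprintf("%d residues outside the %s alphabet replaced by %s",
                 n_bad, alphabet, repl))
    x <- gsub(pat, repl, x)
  }
  x
}

#' Read sequences from a FASTA file
#'
#' Parses a (possibly multi-record) FASTA file into a tibble, one row per
#' record. Residues are uppercased; characters outside the declared alphabet
#' are replaced by `N` (nucleotide) or `X` (protein) with a warning, since
#' public marker-gene data is frequently dirty.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A tibble with columns `id`, `desc`, `seq`, `alphabet`. Record
#'   order is preserved.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(id = character(), desc = character(),
                  seq = character(), alphabet = character()))
  }
  if (!startsWith(lines[[1]], ">")) {
    abort(sprintf("malformed FASTA: line 1 of %s does not start with '>'", path))
  }
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- .clean_residues(as.character(ss), alphabet)
  if (any(!nzchar(seqs))) abort("empty sequence record in FASTA")
  tibble(id = unname(ids), desc = unname(descs), seq = unname(seqs),
         alphabet = alphabet)
}

#' Write sequences to a FASTA file
#'
#' @param records A sequence tibble as returned by [read_fasta()] (columns
#'   `id`, `seq`, optionally `desc`).
#' @param path Output path.
#' @param line_width Residues per sequence line (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 70) {
  stopifnot(line_width >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records) == 0) return(invisible(path))
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[[i]])) paste(records$id[[i]], desc[[i]]) else records$id[[i]]
    s <- records$seq[[i]]
    starts <- seq(1, nchar(s), by = line_width)
    writeLines(c(paste0(">", hdr),
                 substring(s, starts, pmin(starts + line_width - 1, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that
#' validate the result and preserve branch lengths to 10 significant digits
#' on a round trip.
#'
#' @param path Path to a Newick file.
#' @return `read_newick()`: an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) abort(paste0("Newick parse error in ", path,
                                                  ": ", conditionMessage(e))))
  if (is.null(tr)) abort(paste0("Newick parse error in ", path))
  tr
}

#' @rdname read_newick
#' @param tree An [ape::phylo] object.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Write / read a labelled numeric matrix as TSV
#'
#' Used for distance matrices and gene-family-by-genome pan-matrices. Reals
#' are written at 6 decimals; undefined cells become the literal `NA`.
#' The first column holds row labels under the header `label`.
#'
#' @param m A numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_tsv_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  vals <- if (is.integer(m) || all(m == round(m), na.rm = TRUE)) {
    format(m, trim = TRUE, scientific = FALSE)
  } else {
    formatC(m, digits = 6, format = "f")
  }
  vals[is.na(m)] <- "NA"
  out <- cbind(label = rownames(m), vals)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @return `read_tsv_matrix()`: a numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
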