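# ANIb-style average nucleotide identity. The BLASTN step of classical ANIb
# is replaced by an in-package k-mer seeded aligner (Biostrings local
# alignment on the best seed window), which at desk scale is insensitive to
# aligner details. Fragmentation and the 30%/70% acceptance rule follow the
# ANIb convention.

#' Fragment a genome into consecutive windows
#'
#' Cuts every contig into consecutive non-overlapping windows of
#' `fragment_length` bp (ANIb convention: 1,020 bp). A trailing fragment is
#' kept iff it is at least half the window length.
#'
#' @param genome Sequence tibble of nucleotide contigs, or a single character
#'   string.
#' @param fragment_length Window size in bp (>= 100).
#' @return A tibble: `fragment_id`, `contig`, `start`, `end`, `seq`.
#' @export
fragment_genome <- function(genome, fragment_length = 1020) {
  stopifnot(fragment_length >= 100)
  if (is.character(genome)) {
    genome <- tibble(id = paste0("contig", seq_along(genome)), seq = genome)
  }
  if (nrow(genome) == 0 || all(!nzchar(genome$seq))) abort("empty genome")
  out <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    L <- nchar(genome$seq[i])
    if (L < fragment_length / 2) return(NULL)
    starts <- seq(1, L, by = fragment_length)
    ends <- pmin(starts + fragment_length - 1, L)
    keep <- (ends - starts + 1) >= fragment_length / 2
    tibble(contig = genome$id[i], start = starts[keep], end = ends[keep],
           seq = substring(genome$seq[i], starts[keep], ends[keep]))
  })
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(fragment_id = character(), contig = character(),
                  start = integer(), end = integer(), seq = character()))
  }
  out$fragment_id <- sprintf("frag%04d", seq_len(nrow(out)))
  out[, c("fragment_id", "contig", "start", "end", "seq")]
}

# k-mer index of a subject sequence set: list kmer -> positions in the
# concatenated subject (contigs separated by runs of N so no seed spans two).
.build_subject_index <- function(subject_seqs, k = 11) {
  concat <- paste(subject_seqs, collapse = strrep("N", k))
  L <- nchar(concat)
  if (L < k) abort("subject too short for k-mer indexing")
  starts <- seq_len(L - k + 1)
  kmers <- substring(concat, starts, starts + k - 1)
  valid <- !grepl("N", kmers, fixed = TRUE)
  list(concat = concat, k = k,
       index = split(starts[valid], kmers[valid]))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.NUC_SUBST <- NULL  # built lazily; scoring match +1 / mismatch -1

.nuc_subst_matrix <- function() {
  if (is.null(.NUC_SUBST)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
    utils::assignInMyNamespace(".NUC_SUBST", m)
  }
  .NUC_SUBST
}

# Align one fragment against an indexed subject on one strand.
.seed_and_align <- function(frag, sidx, min_seeds = 3, pad = 60) {
  k <- sidx$k
  Lf <- nchar(frag)
  if (Lf < k) return(NULL)
  fstarts <- seq(1, Lf - k + 1, by = 4)  # sample every 4th k-mer as seed
  fk <- substring(frag, fstarts, fstarts + k - 1)
  hits <- sidx$index[fk]
  nh <- lengths(hits)
  if (sum(nh) == 0) return(NULL)
  diag <- unlist(hits, use.names = FALSE) - rep(fstarts, nh)
  # cluster diagonals within a small band
  band <- round(diag / 20)
  tab <- table(band)
  best <- as.integer(names(tab)[which.max(tab)])
  if (max(tab) < min_seeds) return(NULL)
  d0 <- stats::median(diag[band == best])
  ws <- max(1, d0 + 1 - pad)
  we <- min(nchar(sidx$concat), d0 + Lf + pad)
  window <- substring(sidx$concat, ws, we)
  aln <- Biostrings::pairwiseAlignment(
    pattern = frag, subject = window, type = "local",
    substitutionMatrix = .nuc_subst_matrix(),
    gapOpening = 5, gapExtension = 2)
  cols <- Biostrings::nchar(aln)  # alignment columns (local: no terminal gaps)
  if (cols == 0) return(NULL)
  aligned_frag <- BiocGenerics::end(Biostrings::pattern(aln)) -
    BiocGenerics::start(Biostrings::pattern(aln)) + 1
  list(identity = 100 * Biostrings::nmatch(aln) / cols,
       frag_coverage = aligned_frag / Lf,
       score = Biostrings::score(aln))
}

#' Align a fragment against a subject genome
#'
#' k-mer seeded (default k = 11) local alignment of one query fragment
#' against a subject genome, both strands, returning the best-scoring hit.
#' Scoring: match +1, mismatch -1, gap open -5, gap extend -2.
#'
#' @param fragment A nucleotide string.
#' @param subject Sequence tibble of subject contigs, character vector, or a
#'   prebuilt index from `anib()` internals.
#' @param k Seed k-mer length.
#' @return A list `identity` (percent over alignment columns),
#'   `frag_coverage` (aligned fraction of the fragment), `strand`; or `NULL`
#'   when no hit is found.
#' @export
align_fragment <- function(fragment, subject, k = 11) {
  sidx <- if (is.list(subject) && !is.null(subject$index)) subject
          else .build_subject_index(if (is.character(subject)) subject else subject$seq, k)
  fwd <- .seed_and_align(fragment, sidx)
  rev <- .seed_and_align(.revcomp(fragment), sidx)
  if (is.null(fwd) && is.null(rev)) return(NULL)
  if (is.null(rev) || (!is.null(fwd) && fwd$score >= rev$score)) {
    c(fwd[c("identity", "frag_coverage")], strand = "+")
  } else {
    c(rev[c("identity", "frag_coverage")], strand = "-")
  }
}

#' ANIb-style average nucleotide identity (one direction)
#'
#' Fragments the query genome, aligns each fragment to the subject, and
#' averages percent identity over fragments whose best hit reaches
#' `min_identity` percent identity over at least `min_frag_coverage` of the
#' fragment length. ANI is direction-dependent; see [ani_matrix()] for both
#' directions.
#'
#' @param query,subject Sequence tibbles (or character vectors) of genome
#'   contigs.
#' @param fragment_length Fragment window (default 1,020 bp).
#' @param min_identity Minimum percent identity for a fragment hit (30).
#' @param min_frag_coverage Minimum aligned fraction of the fragment (0.70).
#' @param query_id,subject_id Labels for the output row.
#' @return A one-row tibble: `query_id`, `subject_id`, `ani` (percent, `NA`
#'   when no fragment is accepted), `fragments_total`, `fragments_accepted`.
#' @export
anib <- function(query, subject, fragment_length = 1020,
                 min_identity = 30, min_frag_coverage = 0.70,
                 query_id = "query", subject_id = "subject") {
  frags <- fragment_genome(query, fragment_length)
  if (nrow(frags) == 0) abort("query genome produced no fragments")
  subj_seqs <- if (is.character(subject)) subject else subject$seq
  if (length(subj_seqs) == 0 || all(!nzchar(subj_seqs))) abort("empty subject genome")
  sidx <- .build_subject_index(subj_seqs, k = 11)
  ids <- vapply(frags$seq, function(f) {
    hit <- align_fragment(f, sidx)
    if (is.null(hit)) return(NA_real_)
    if (hit$identity >= min_identity && hit$frag_coverage >= min_frag_coverage) {
      hit$identity
    } else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
  acc <- sum(!is.na(ids))
  tibble(query_id = query_id, subject_id = subject_id,
         ani = if (acc >= 1) mean(ids, na.rm = TRUE) else NA_real_,
         fragments_total = nrow(frags), fragments_accepted = acc)
}

#' Pairwise ANI table for a set of genomes
#'
#' Runs [anib()] in both directions for every ordered genome pair (asymmetry
#' is surfaced, not hidden) and adds the per-unordered-pair mean.
#'
#' @param genomes Named list of genome sequence tibbles.
#' @param ... Passed to [anib()].
#' @return A tibble with one row per ordered pair plus a `pair_mean` column.
#' @export
ani_matrix <- function(genomes, ...) {
  stopifnot(is.list(genomes), !is.null(names(genomes)))
  ids <- names(genomes)
  rows <- purrr::map_dfr(ids, function(q) {
    purrr::map_dfr(setdiff(ids, q), function(s) {
      anib(genomes[[q]], genomes[[s]], query_id = q, subject_id = s, ...)
    })
  })
  key <- purrr::map2_chr(rows$query_id, rows$subject_id,
                         ~ paste(sort(c(.x, .y)), collapse = "|"))
  rows %>%
    mutate(pair = key) %>%
    group_by(.data$pair) %>%
    mutate(pair_mean = mean(.data$ani)) %>%
    ungroup() %>%
    select(-"pair")
}

#' Species-delineation call from ANI
#'
#' Applies the conventional 95% ANI species threshold: `same_species` iff
#' ANI >= threshold; undefined ANI gives an undefined call.
#'
#' @param ani_result A tibble with an `ani` column (e.g. from [anib()]).
#' @param threshold Percent ANI threshold (default 95).
#' @return The input with a `species_call` column
#'   (`same_species` / `different_species` / `undefined`).
#' @export
species_call <- function(ani_result, threshold = 95) {
  ani_result %>%
    mutate(species_call = dplyr::case_when(
      is.na(.data$ani) ~ "undefined",
      .data$ani >= threshold ~ "same_species",
      TRUE ~ "different_species"))
}
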