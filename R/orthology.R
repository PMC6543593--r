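# MGE flagging, protein percent identity, greedy centroid ortholog
# clustering at a 50% identity cutoff, and the core/accessory/unique
# pan-genome partition.

.MGE_KEYWORDS <- c("transposase", "integrase", "insertion sequence",
                   "IS family", "phage", "prophage", "recombinase")

#' Flag mobile-genetic-element genes by product keywords
#'
#' Case-insensitive substring match of annotation product strings against a
#' keyword set (transposase, integrase, insertion sequence, IS family, phage,
#' prophage, recombinase by default). Flagged genes are excluded from
#' ortholog clustering input, since lineage-specific MGE expansions distort
#' gene-family statistics.
#'
#' @param annotations Tibble with `gene_id` and `product` columns.
#' @param keyword_set Character vector of keywords.
#' @return Character vector of flagged `gene_id`s.
#' @export
flag_mge <- function(annotations, keyword_set = .MGE_KEYWORDS) {
  if (nrow(annotations) == 0) return(character())
  prod <- tolower(annotations$product)
  hit <- Reduce(`|`, lapply(tolower(keyword_set), function(k) {
    grepl(k, prod, fixed = TRUE)
  }))
  annotations$gene_id[hit]
}

.BLOSUM62 <- NULL

.blosum62 <- function() {
  if (is.null(.BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    utils::assignInMyNamespace(".BLOSUM62", as.matrix(e$BLOSUM62))
  }
  .BLOSUM62
}

# identity/coverage from a (possibly vectorized) PairwiseAlignments object.
# nchar() on the alignment counts alignment columns excluding terminal gaps,
# the identity denominator used throughout; coverage is aligned residue
# pairs over the shorter sequence length (always <= 1).
.aln_stats <- function(aln, len_shorter) {
  cols <- Biostrings::nchar(aln)
  matches <- Biostrings::nmatch(aln)
  pairs <- matches + Biostrings::nmismatch(aln)
  list(identity = ifelse(cols > 0, 100 * matches / cols, 0),
       coverage = pairs / len_shorter)
}

#' Global percent identity between two proteins
#'
#' Needleman-Wunsch global alignment with affine gaps (BLOSUM62, gap open
#' -10, gap extend -0.5). Identity is matches over alignment columns
#' excluding terminal gaps (identity definitions differ between tools, so
#' the denominator is stated); coverage is aligned residue pairs over the
#' shorter sequence length, hence always in [0, 1].
#'
#' @param prot_a,prot_b Protein sequence strings.
#' @return A list `identity` (percent) and `coverage`.
#' @export
pairwise_identity <- function(prot_a, prot_b) {
  if (!nzchar(prot_a) || !nzchar(prot_b)) abort("empty protein sequence")
  aln <- Biostrings::pairwiseAlignment(
    pattern = prot_a, subject = prot_b, type = "global",
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 0.5)
  st <- .aln_stats(aln, min(nchar(prot_a), nchar(prot_b)))
  list(identity = st$identity, coverage = st$coverage)
}

.kmer_set <- function(seq, k = 4) {
  L <- nchar(seq)
  if (L < k) return(character())
  unique(substring(seq, 1:(L - k + 1), k:L))
}

#' Greedy centroid clustering of proteomes into orthogroups
#'
#' USEARCH/BPGA-style greedy clustering: all proteins (MGE-flagged genes
#' removed first) are sorted by length descending (ties broken by gene id);
#' each protein joins the first existing centroid reaching
#' `identity_cutoff` percent identity and `coverage_cutoff` coverage of the
#' shorter sequence, else founds a new family with itself as centroid. The
#' global length sort makes the result independent of genome input order.
#'
#' A shared-tetramer prefilter (candidates must share at least
#' `min_shared_kmers` 4-mers with the centroid) skips hopeless alignments;
#' at the identity regimes that matter (>= 40%) it is lossless. Set
#' `min_shared_kmers = 0` to disable.
#'
#' @param proteomes Named list of protein sequence tibbles (one per genome).
#' @param identity_cutoff Percent identity threshold (default 50).
#' @param coverage_cutoff Minimum aligned coverage of the shorter sequence
#'   (default 0.5; behavioral stand-in for a BLAST E-value cutoff).
#' @param exclude Gene ids to drop before clustering (e.g. from
#'   [flag_mge()]).
#' @param min_shared_kmers Tetramer prefilter threshold (default 2).
#' @return A tibble: `family_id`, `genome_id`, `gene_id`, `representative`
#'   (the family centroid's gene id).
#' @export
cluster_orthogroups <- function(proteomes, identity_cutoff = 50,
                                coverage_cutoff = 0.5, exclude = NULL,
                                min_shared_kmers = 2) {
  stopifnot(is.list(proteomes), !is.null(names(proteomes)))
  prot <- purrr::map_dfr(names(proteomes), function(g) {
    p <- proteomes[[g]]
    tibble(genome_id = g, gene_id = p$id, seq = p$seq)
  })
  if (!is.null(exclude)) prot <- prot[!prot$gene_id %in% exclude, , drop = FALSE]
  if (nrow(prot) == 0) {
    return(tibble(family_id = character(), genome_id = character(),
                  gene_id = character(), representative = character()))
  }
  prot$len <- nchar(prot$seq)
  prot <- prot[order(-prot$len, prot$gene_id), , drop = FALSE]

  cent_seq <- character(); cent_rep <- character()
  # inverted index: tetramer -> integer vector of centroid indices
  kidx <- new.env(hash = TRUE, parent = emptyenv())
  assignment <- integer(nrow(prot))
  for (i in seq_len(nrow(prot))) {
    s <- prot$seq[i]
    km <- .kmer_set(s)
    if (min_shared_kmers > 0) {
      hits <- unlist(mget(km, envir = kidx, ifnotfound = list(integer())),
                     use.names = FALSE)
      shared <- tabulate(hits, nbins = length(cent_seq))
      cand <- which(shared >= min_shared_kmers)
    } else {
      cand <- seq_along(cent_seq)
    }
    placed <- FALSE
    if (length(cand)) {
      alns <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAStringSet(cent_seq[cand]), subject = s,
        type = "global", substitutionMatrix = .blosum62(),
        gapOpening = 10, gapExtension = 0.5)
      st <- .aln_stats(alns, pmin(nchar(cent_seq[cand]), prot$len[i]))
      ok <- which(st$identity >= identity_cutoff &
                  st$coverage >= coverage_cutoff)
      if (length(ok)) {  # first (oldest) qualifying centroid
        assignment[i] <- cand[ok[1]]
        placed <- TRUE
      }
    }
    if (!placed) {
      cent_seq <- c(cent_seq, s)
      cent_rep <- c(cent_rep, prot$gene_id[i])
      ci <- length(cent_seq)
      for (kk in km) assign(kk, c(kidx[[kk]], ci), envir = kidx)
      assignment[i] <- ci
    }
  }
  fam_ids <- sprintf("OG%05d", seq_along(cent_seq))
  tibble(family_id = fam_ids[assignment],
         genome_id = prot$genome_id, gene_id = prot$gene_id,
         representative = cent_rep[assignment]) %>%
    arrange(.data$family_id, .data$genome_id, .data$gene_id)
}

#' Gene-family-by-genome count matrix
#'
#' @param orthogroups Tibble from [cluster_orthogroups()].
#' @param genome_ids Genome order for the columns; every member genome must
#'   appear here.
#' @return Integer matrix (families x genomes) of member counts.
#' @export
build_pan_matrix <- function(orthogroups, genome_ids) {
  missing <- setdiff(unique(orthogroups$genome_id), genome_ids)
  if (length(missing)) {
    abort(paste0("member genomes absent from genome_ids: ",
                 paste(missing, collapse = ", ")))
  }
  fams <- sort(unique(orthogroups$family_id))
  m <- matrix(0L, length(fams), length(genome_ids),
              dimnames = list(fams, genome_ids))
  tab <- table(orthogroups$family_id, orthogroups$genome_id)
  m[rownames(tab), colnames(tab)] <- as.integer(tab)
  m
}

#' Core / accessory / unique pan-genome partition
#'
#' Families present (count >= 1) in all genomes are core; in >= 2 but not
#' all, accessory; in exactly one, unique to that genome.
#'
#' @param pan_matrix Families x genomes count matrix.
#' @return A list of class `pan_partition`: `core`, `accessory` (character
#'   vectors of family ids), `unique` (tibble: `genome_id`,
#'   `n_unique_families`), `per_genome` (tibble with per-genome family totals
#'   and core proportion), `n_families`.
#' @export
partition_pangenome <- function(pan_matrix) {
  pres <- pan_matrix >= 1
  n_genomes <- ncol(pres)
  n_pres <- rowSums(pres)
  core <- rownames(pres)[n_pres == n_genomes]
  unique_f <- rownames(pres)[n_pres == 1]
  accessory <- rownames(pres)[n_pres >= 2 & n_pres < n_genomes]
  uniq_genome <- if (length(unique_f)) {
    colnames(pres)[apply(pres[unique_f, , drop = FALSE], 1, which.max)]
  } else character()
  uniq_tbl <- tibble(genome_id = colnames(pres)) %>%
    left_join(tibble(genome_id = uniq_genome) %>% count(.data$genome_id),
              by = "genome_id") %>%
    mutate(n_unique_families = ifelse(is.na(.data$n), 0L, .data$n)) %>%
    select("genome_id", "n_unique_families")
  per_genome <- tibble(genome_id = colnames(pres),
                       n_families = colSums(pres),
                       core_proportion = length(core) / colSums(pres))
  structure(list(core = core, accessory = accessory, unique = uniq_tbl,
                 per_genome = per_genome, n_families = nrow(pres)),
            class = "pan_partition")
}

#' @export
print.pan_partition <- function(x, ...) {
  cat(sprintf(paste0("Pan-genome partition: %d families = %d core + %d ",
                     "accessory + %d unique\n"),
              x$n_families, length(x$core), length(x$accessory),
              sum(x$unique$n_unique_families)))
  invisible(x)
}

#' @method glance pan_partition
#' @export
glance.pan_partition <- function(x, ...) {
  tibble(n_families = x$n_families, n_core = length(x$core),
         n_accessory = length(x$accessory),
         n_unique = sum(x$unique$n_unique_families))
}
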