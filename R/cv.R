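# Composition-vector (CVTree-style) alignment-free phylogeny: K-tuple
# frequencies of whole proteomes, a (K-2)-order Markov background
# expectation, normalized deviations, and cosine-based distances.

.tuples_of <- function(seqs, K) {
  out <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < K) return(character())
    substring(s, 1:(L - K + 1), K:L)
  })
  unlist(out, use.names = FALSE)
}

#' K-tuple counts of a proteome
#'
#' Counts all length-`K` windows over every protein of a genome; windows
#' never span protein boundaries (CVTree convention).
#'
#' @param proteome Sequence tibble of proteins, or a character vector of
#'   protein strings.
#' @param K Tuple length.
#' @return A tibble: `tuple`, `count`, `freq` (count over total windows).
#' @export
ktuple_counts <- function(proteome, K) {
  seqs <- if (is.character(proteome)) proteome else proteome$seq
  tup <- .tuples_of(seqs, K)
  if (length(tup) == 0) abort(sprintf("all proteins shorter than K = %d", K))
  tab <- table(tup)
  tibble(tuple = names(tab), count = as.integer(tab),
         freq = as.integer(tab) / length(tup))
}

#' Markov background expectation for K-tuple frequencies
#'
#' The (K-2)-order Markov prediction
#' `f0(a1..aK) = f(a1..a(K-1)) * f(a2..aK) / f(a2..a(K-1))`, with `f0 = 0`
#' where the denominator marginal is unobserved.
#'
#' @param counts_K,counts_Km1,counts_Km2 Count tibbles from
#'   [ktuple_counts()] at orders K, K-1 and K-2 of the same proteome.
#' @return A tibble: `tuple`, `f` (observed frequency), `f0` (expected).
#' @export
markov_expected <- function(counts_K, counts_Km1, counts_Km2) {
  K <- nchar(counts_K$tuple[1])
  fK1 <- stats::setNames(counts_Km1$freq, counts_Km1$tuple)
  fK2 <- stats::setNames(counts_Km2$freq, counts_Km2$tuple)
  pre <- substring(counts_K$tuple, 1, K - 1)
  suf <- substring(counts_K$tuple, 2, K)
  mid <- substring(counts_K$tuple, 2, K - 1)
  num <- unname(fK1[pre]) * unname(fK1[suf])
  den <- unname(fK2[mid])
  f0 <- ifelse(is.na(den) | den == 0, 0,
               ifelse(is.na(num), 0, num / den))
  tibble(tuple = counts_K$tuple, f = counts_K$freq, f0 = f0)
}

#' Composition vector of a proteome
#'
#' The sparse vector of normalized deviations
#' `a(t) = (f(t) - f0(t)) / f0(t)` over K-tuples with `f0 > 0` (by
#' convention `a = 0` where `f0 = 0`). The subtraction of the Markov
#' background suppresses mutation-independent compositional signal and
#' highlights shared ancestry.
#'
#' @param proteome Sequence tibble or character vector of proteins.
#' @param K Tuple length (default 6, the standard whole-proteome choice;
#'   must be >= 3 since K-1 and K-2 marginals are needed).
#' @param genome_id Label carried on the vector.
#' @return A list of class `composition_vector`: `genome_id`, `K`, `tuple`,
#'   `a` (parallel vectors).
#' @export
cv_vector <- function(proteome, K = 6, genome_id = "genome") {
  if (K < 3) abort("K must be >= 3 (K-1 and K-2 marginals are required)")
  cK <- ktuple_counts(proteome, K)
  cK1 <- ktuple_counts(proteome, K - 1)
  cK2 <- ktuple_counts(proteome, K - 2)
  me <- markov_expected(cK, cK1, cK2)
  a <- ifelse(me$f0 > 0, (me$f - me$f0) / me$f0, 0)
  keep <- a != 0
  structure(list(genome_id = genome_id, K = K,
                 tuple = me$tuple[keep], a = a[keep]),
            class = "composition_vector")
}

#' @export
print.composition_vector <- function(x, ...) {
  cat(sprintf("Composition vector of %s: K = %d, %d non-zero components\n",
              x$genome_id, x$K, length(x$a)))
  invisible(x)
}

#' Cosine distance matrix between composition vectors
#'
#' `d(u, v) = (1 - C(u, v)) / 2` with `C` the cosine of the angle between
#' the two vectors over the union of their tuples, giving distances in
#' [0, 1] (0 identical direction, 0.5 orthogonal, 1 anti-parallel).
#'
#' @param vectors List of [cv_vector()] results with equal `K`.
#' @return A symmetric distance matrix, suitable for [nj_tree()].
#' @export
cv_distance_matrix <- function(vectors) {
  if (length(vectors) < 2) abort("need >= 2 composition vectors")
  Ks <- vapply(vectors, function(v) v$K, numeric(1))
  if (length(unique(Ks)) != 1) abort("composition vectors have differing K")
  ids <- vapply(vectors, function(v) v$genome_id, character(1))
  if (anyDuplicated(ids)) abort("duplicate genome ids")
  norms <- vapply(vectors, function(v) sqrt(sum(v$a^2)), numeric(1))
  if (any(norms == 0)) {
    abort(paste0("zero-norm composition vector: ",
                 paste(ids[norms == 0], collapse = ", ")))
  }
  n <- length(vectors)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    u <- vectors[[i]]; v <- vectors[[j]]
    common <- match(u$tuple, v$tuple)
    hit <- !is.na(common)
    C <- sum(u$a[hit] * v$a[common[hit]]) / (norms[i] * norms[j])
    m[i, j] <- m[j, i] <- (1 - C) / 2
  }
  m
}

#' Composition-vector phylogeny of a set of proteomes
#'
#' Convenience wrapper: [cv_vector()] for every genome, [cv_distance_matrix()],
#' [nj_tree()], and optional [root_by_outgroup()].
#'
#' @param proteomes Named list of protein sequence tibbles.
#' @param K Tuple length (default 6).
#' @param outgroup Optional tip label to root on.
#' @return A list: `tree` ([ape::phylo]), `distances` (matrix).
#' @export
cv_phylogeny <- function(proteomes, K = 6, outgroup = NULL) {
  vecs <- purrr::imap(proteomes, function(p, g) cv_vector(p, K, genome_id = g))
  d <- cv_distance_matrix(unname(vecs))
  tr <- nj_tree(d)
  if (!is.null(outgroup)) tr <- root_by_outgroup(tr, outgroup)
  list(tree = tr, distances = d)
}
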