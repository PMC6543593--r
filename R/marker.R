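# 16S marker pipeline: length/duplicate filtering, TN93 distances with the
# substitution-saturation check, neighbor-joining and outgroup rooting.

#' Filter marker-gene sequences by length and redundancy
#'
#' Keeps records whose ungapped length lies inside the inclusive window
#' `[min_len, max_len]` (defaults match the conventional near-full-length 16S
#' window of 1,300-1,550 bp) and removes exact duplicate sequences, keeping
#' the first occurrence.
#'
#' @param records Sequence tibble (see [read_fasta()]).
#' @param min_len,max_len Inclusive length bounds in bp.
#' @return The filtered tibble; attribute `"filter_counts"` holds a tibble of
#'   kept/dropped counts by reason.
#' @export
filter_marker_sequences <- function(records, min_len = 1300, max_len = 1550) {
  if (min_len > max_len) abort("min_len must be <= max_len")
  if (nrow(records) == 0) {
    out <- records
    attr(out, "filter_counts") <- tibble(reason = character(), n = integer())
    return(out)
  }
  len <- nchar(gsub("-", "", records$seq, fixed = TRUE))
  in_window <- len >= min_len & len <= max_len
  kept <- records[in_window, , drop = FALSE]
  dup <- duplicated(kept$seq)
  out <- kept[!dup, , drop = FALSE]
  attr(out, "filter_counts") <- tibble(
    reason = c("kept", "length_out_of_window", "duplicate_sequence"),
    n = c(nrow(out), sum(!in_window), sum(dup)))
  out
}

#' Pairwise substitution proportions between two aligned sequences
#'
#' Counts, over sites with an unambiguous base in both sequences (pairwise
#' deletion of gaps and N), the proportions of A<->G differences (`P1`),
#' C<->T differences (`P2`) and transversion differences (`Q`), plus base
#' frequencies averaged over both sequences at the usable sites.
#'
#' @param seq_a,seq_b Equal-length aligned nucleotide strings.
#' @return A list with `P1`, `P2`, `Q`, `base_freqs` (A, C, G, T) and
#'   `sites_used`.
#' @export
substitution_proportions <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) abort("sequences must be aligned (equal length)")
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0) abort("no comparable sites (all gapped or ambiguous)")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  pair <- paste0(pmin(a, b), pmax(a, b))
  P1 <- sum(diff & pair == "AG") / n
  P2 <- sum(diff & pair == "CT") / n
  Q <- sum(diff & !(pair %in% c("AG", "CT"))) / n
  freq <- (table(factor(a, c("A", "C", "G", "T"))) +
           table(factor(b, c("A", "C", "G", "T")))) / (2 * n)
  list(P1 = P1, P2 = P2, Q = Q,
       base_freqs = stats::setNames(as.numeric(freq), c("A", "C", "G", "T")),
       sites_used = n)
}

#' Tamura-Nei (1993) distance from substitution proportions
#'
#' Closed-form TN93 estimator with separate purine- and pyrimidine-transition
#' terms. When any logarithm argument is non-positive the estimator is
#' saturated and the undefined sentinel `NA` is returned (with the reason as
#' an attribute), never silently dropped.
#'
#' @param summary A list as returned by [substitution_proportions()].
#' @return A non-negative distance (substitutions/site), or `NA` if the
#'   estimator is undefined.
#' @export
tn93_distance <- function(summary) {
  p <- summary$base_freqs
  pA <- p[["A"]]; pC <- p[["C"]]; pG <- p[["G"]]; pT <- p[["T"]]
  if (any(c(pA, pC, pG, pT) <= 0)) {
    out <- NA_real_
    attr(out, "reason") <- "zero base frequency"
    return(out)
  }
  pR <- pA + pG; pY <- pC + pT
  P1 <- summary$P1; P2 <- summary$P2; Q <- summary$Q
  w1 <- 1 - pR * P1 / (2 * pA * pG) - Q / (2 * pR)
  w2 <- 1 - pY * P2 / (2 * pC * pT) - Q / (2 * pY)
  w3 <- 1 - Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "saturated (non-positive log argument)"
    return(out)
  }
  k1 <- 2 * pA * pG / pR
  k2 <- 2 * pC * pT / pY
  k3 <- 2 * (pR * pY - pA * pG * pY / pR - pC * pT * pR / pY)
  d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  max(d, 0)
}

#' Pairwise TN93 distance matrix for an alignment
#'
#' @param aln Sequence tibble of aligned nucleotide sequences.
#' @return A symmetric matrix of TN93 distances with zero diagonal; saturated
#'   pairs are `NA`.
#' @export
tn93_distance_matrix <- function(aln) {
  n <- nrow(aln)
  if (n < 2) abort("need >= 2 sequences")
  m <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- tn93_distance(substitution_proportions(aln$seq[i], aln$seq[j]))
    m[i, j] <- m[j, i] <- as.numeric(d)
  }
  m
}

#' Substitution-saturation assessment
#'
#' For every sequence pair computes the transition proportion `s = P1 + P2`,
#' the transversion proportion `v = Q`, and the TN93 distance. A pair is
#' saturated when transversions reach transitions (`v >= s`, with identical
#' pairs at `s = v = 0` counted as unsaturated); the alignment verdict is
#' `"not_saturated"` when fewer than half of pairs are saturated. This
#' operationalizes the visual transition/transversion-versus-distance test.
#'
#' @param aln Sequence tibble of aligned nucleotide sequences (>= 2).
#' @return A list of class `saturation_report`: `pairs` (tibble: `id_a`,
#'   `id_b`, `s`, `v`, `d`, `saturated`), `saturated_fraction`, `verdict`.
#' @export
saturation_assessment <- function(aln) {
  n <- nrow(aln)
  if (n < 2) abort("need >= 2 sequences")
  rows <- purrr::map_dfr(seq_len(n - 1), function(i) {
    purrr::map_dfr((i + 1):n, function(j) {
      sp <- substitution_proportions(aln$seq[i], aln$seq[j])
      tibble(id_a = aln$id[i], id_b = aln$id[j],
             s = sp$P1 + sp$P2, v = sp$Q,
             d = as.numeric(tn93_distance(sp)))
    })
  })
  rows$saturated <- rows$v >= rows$s & !(rows$s == 0 & rows$v == 0)
  frac <- mean(rows$saturated)
  structure(list(pairs = rows, saturated_fraction = frac,
                 verdict = if (frac < 0.5) "not_saturated" else "saturated"),
            class = "saturation_report")
}

#' @export
print.saturation_report <- function(x, ...) {
  cat(sprintf("Substitution saturation: %d pairs, %.1f%% saturated -> %s\n",
              nrow(x$pairs), 100 * x$saturated_fraction, x$verdict))
  invisible(x)
}

#' @method glance saturation_report
#' @export
glance.saturation_report <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), saturated_fraction = x$saturated_fraction,
         verdict = x$verdict)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]); exactly recovers
#' any additive distance matrix. Negative branch lengths, which NJ can
#' produce on non-additive input, are clamped to zero with a warning.
#'
#' @param m Symmetric distance matrix with >= 3 labelled taxa and no
#'   undefined (`NA`) entries.
#' @return An unrooted [ape::phylo].
#' @export
nj_tree <- function(m) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 3) abort("need >= 3 taxa")
  if (anyNA(m)) {
    bad <- rownames(m)[apply(is.na(m), 1, any)]
    abort(paste0("distance matrix has undefined entries; drop taxa: ",
                 paste(bad, collapse = ", ")))
  }
  tr <- ape::nj(m)
  if (any(tr$edge.length < 0)) {
    warn(sprintf("%d negative NJ branch lengths clamped to 0",
                 sum(tr$edge.length < 0)))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Root a tree on an outgroup
#'
#' Roots the tree on the edge subtending `outgroup_label`, placing the root
#' at the midpoint of that edge.
#'
#' @param tree An [ape::phylo].
#' @param outgroup_label A tip label.
#' @return A rooted binary `phylo` in which the outgroup is sister to
#'   everything else.
#' @export
root_by_outgroup <- function(tree, outgroup_label) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup_label %in% tree$tip.label) {
    abort(paste0("outgroup not a leaf of the tree: ", outgroup_label))
  }
  rooted <- ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  # split the outgroup edge at its midpoint
  ntip <- length(rooted$tip.label)
  root_node <- ntip + 1L
  root_edges <- which(rooted$edge[, 1] == root_node)
  if (length(root_edges) == 2 && !is.null(rooted$edge.length)) {
    total <- sum(rooted$edge.length[root_edges])
    rooted$edge.length[root_edges] <- total / 2
  }
  rooted
}
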