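# Clustering of candidate DMIs: interface topology (profile-mapped
# contact positions) and combined domain+peptide sequence identity
# ("unrelated protein clusters", UPCs).

#' Translate contacting domain residues to profile columns
#'
#' Profile columns give family members a normalized numbering so that
#' interfaces on homologous domains become comparable. Residues outside
#' the map (insertions relative to the profile) are dropped with a
#' warning.
#'
#' @param dom_res seq_index vector of contacting domain residues.
#' @param profile_map data.frame with `seq_index`, `column` for this
#'   domain instance.
#' @return sorted integer vector of profile columns.
#' @export
interface_profile_positions <- function(dom_res, profile_map) {
  if (is.null(profile_map) || nrow(profile_map) == 0)
    stop("interface_profile_positions: empty profile map")
  idx <- match(dom_res, profile_map$seq_index)
  if (anyNA(idx))
    warning("dropping ", sum(is.na(idx)),
            " contact(s) at unmapped (insertion) residues")
  sort(unique(profile_map$column[idx[!is.na(idx)]]))
}

#' Topology distance between two interfaces
#'
#' Dice-style dissimilarity of the profile-column contact sets:
#' `1 - 2|A n B| / (nA + nB)`; 0 iff identical, 1 iff disjoint. If one
#' interface has more than double the contacts of the other the distance
#' is set to 1 outright (vastly different interface sizes are distinct
#' topologies regardless of overlap).
#'
#' @param pos_a,pos_b non-empty integer vectors of profile columns.
#' @return distance in `[0, 1]`.
#' @export
topology_distance <- function(pos_a, pos_b) {
  if (length(pos_a) == 0 || length(pos_b) == 0)
    stop("topology_distance: empty contact set")
  pos_a <- unique(pos_a); pos_b <- unique(pos_b)
  na <- length(pos_a); nb <- length(pos_b)
  if (max(na, nb) > 2 * min(na, nb)) return(1)
  1 - 2 * length(intersect(pos_a, pos_b)) / (na + nb)
}

#' Complete-linkage hierarchical clustering with a fixed cut
#'
#' Deterministic agglomerative complete-linkage clustering. At each step
#' the pair of clusters at minimal (maximum-pairwise) distance is
#' merged, ties broken by the lexicographically smallest pair of lowest
#' member indices. Merging stops at the cut: with `inclusive = FALSE`
#' (default) only merges strictly below `cut` are performed (a cut of 1
#' keeps fully disjoint interfaces apart); with `inclusive = TRUE`
#' merges at exactly `cut` are allowed (cluster diameter <= cut).
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param cut cut height.
#' @param inclusive allow merges at exactly the cut height.
#' @return integer cluster membership vector (1-based, in order of
#'   cluster founder index).
#' @export
complete_linkage <- function(d, cut, inclusive = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n == 0) return(integer(0))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-9)))
    stop("complete_linkage: distance matrix not symmetric")
  if (any(diag(d) != 0)) stop("complete_linkage: nonzero diagonal")
  clusters <- as.list(seq_len(n))
  repeat {
    m <- length(clusters)
    if (m == 1) break
    best <- NULL; best_d <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      dij <- max(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d - 1e-15) { best_d <- dij; best <- c(i, j) }
      # ties: keep the earlier (lexicographically smaller) pair, which
      # the loop order already visits first
    }
    ok <- if (inclusive) best_d <= cut else best_d < cut
    if (!ok) break
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  membership
}

#' Pairwise domain identity via the family profile
#'
#' Identity of two domain instances through their shared profile
#' columns: the fraction of columns mapped in both instances at which
#' the residues are identical, over the number of columns mapped in
#' both. Zero shared columns gives identity 0.
#'
#' @param seq_a,seq_b full chain sequences of the two instances.
#' @param map_a,map_b profile maps (`seq_index`, `column`) for the two
#'   instances.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity_domains <- function(seq_a, map_a, seq_b, map_b) {
  shared <- intersect(map_a$column, map_b$column)
  if (length(shared) == 0) return(0)
  ia <- map_a$seq_index[match(shared, map_a$column)]
  ib <- map_b$seq_index[match(shared, map_b$column)]
  ra <- substring(seq_a, ia, ia)
  rb <- substring(seq_b, ib, ib)
  mean(ra == rb)
}

#' Pairwise peptide-region identity by global alignment
#'
#' Needleman-Wunsch global alignment (match 1, mismatch 0, gap open 1,
#' gap extend 0.5) of two peptide-region sequences; identity is
#' identical positions over alignment length.
#'
#' @param seq_a,seq_b peptide-region sequences.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity_peptides <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) return(0)
  sub <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = sub,
                                       gapOpening = 1, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Combined domain+peptide sequence distance
#'
#' `1 - (sd + sp) / 2`, the mean of the two identities turned into a
#' distance; a cut of 0.1 corresponds to 90% combined identity.
#'
#' @param sd domain identity in `[0, 1]`.
#' @param sp peptide identity in `[0, 1]`.
#' @return distance in `[0, 1]`.
#' @export
combined_distance <- function(sd, sp) {
  stopifnot(all(sd >= 0 & sd <= 1), all(sp >= 0 & sp <= 1))
  1 - (sd + sp) / 2
}

#' Topology clusters for the candidates of one family
#'
#' @param positions list of profile-column vectors, one per candidate.
#' @param cut cut height, default 1 (strict: merges only below 1).
#' @return integer membership vector.
#' @export
topology_clusters <- function(positions, cut = 1) {
  n <- length(positions)
  if (n == 0) return(integer(0))
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- topology_distance(positions[[i]], positions[[j]])
    }
  }
  complete_linkage(d, cut = cut, inclusive = FALSE)
}

#' Sequence clusters (UPCs) for the candidates of one family
#'
#' Complete-linkage clustering on the combined domain+peptide distance,
#' cut inclusively at `cut` (default 0.1, i.e. 90% combined identity
#' diameter). Peptide identity is computed on peptide-containing-region
#' sequences so that overlapping windows cannot inflate motif support.
#'
#' @param region_seqs peptide-region sequences, one per candidate.
#' @param domain_seqs chain sequences of the binding-domain instances.
#' @param domain_maps profile maps of the binding-domain instances.
#' @param cut cut height, default 0.1.
#' @return integer membership vector (UPC ids).
#' @export
sequence_clusters <- function(region_seqs, domain_seqs, domain_maps,
                              cut = 0.1) {
  n <- length(region_seqs)
  if (n == 0) return(integer(0))
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sd <- pairwise_identity_domains(domain_seqs[[i]], domain_maps[[i]],
                                      domain_seqs[[j]], domain_maps[[j]])
      sp <- pairwise_identity_peptides(region_seqs[[i]], region_seqs[[j]])
      d[i, j] <- d[j, i] <- combined_distance(sd, sp)
    }
  }
  complete_linkage(d, cut = cut, inclusive = TRUE)
}
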