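# Interface filters: contact, area, stoichiometry, intrachain context,
# homomer exclusion.

#' Residue contacts between a peptide and a domain
#'
#' Heavy-atom contact map: residue pairs with any inter-atom distance at
#' or below `cutoff` (default 5 Angstrom) are recorded symmetrically.
#'
#' @param struct a `dmi_structure`.
#' @param pep_chain,pep_start,pep_end peptide span.
#' @param dom_chain,dom_start,dom_end domain span.
#' @param cutoff heavy-atom distance cutoff (Angstrom).
#' @return list with `pep_res` and `dom_res` (sorted seq_index vectors of
#'   contacting residues), `pairs` (data.frame of contacting residue
#'   pairs) and `cutoff`.
#' @export
residue_contacts <- function(struct, pep_chain, pep_start, pep_end,
                             dom_chain, dom_start, dom_end, cutoff = 5.0) {
  pa <- span_atoms(struct, pep_chain, pep_start, pep_end)
  da <- span_atoms(struct, dom_chain, dom_start, dom_end)
  if (nrow(pa$xyz) == 0 || nrow(da$xyz) == 0)
    return(list(pep_res = integer(0), dom_res = integer(0),
                pairs = data.frame(pep = integer(0), dom = integer(0)),
                cutoff = cutoff))
  d2 <- outer(rowSums(pa$xyz^2), rowSums(da$xyz^2), "+") -
    2 * pa$xyz %*% t(da$xyz)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  pairs <- unique(data.frame(pep = pa$seq_index[hit[, 1]],
                             dom = da$seq_index[hit[, 2]]))
  list(pep_res = sort(unique(pairs$pep)), dom_res = sort(unique(pairs$dom)),
       pairs = pairs[order(pairs$pep, pairs$dom), , drop = FALSE],
       cutoff = cutoff)
}

#' Domain-contact filter for a candidate peptide
#'
#' A motif forms one connected interface with its binding domain. The
#' filter passes iff at least `min_frac` (default 60%) of the peptide
#' residues contact the domain AND no run of consecutive non-contacting
#' peptide residues is longer than `max_gap` (default 4), terminal runs
#' included.
#'
#' @param contact_pep_res seq_index vector of contacting peptide residues.
#' @param pep_start,pep_end peptide span.
#' @param min_frac minimum contacting fraction, default 0.6.
#' @param max_gap maximum non-contacting run length, default 4.
#' @return TRUE (pass) or FALSE (fail).
#' @export
domain_contact_filter <- function(contact_pep_res, pep_start, pep_end,
                                  min_frac = 0.6, max_gap = 4) {
  len <- pep_end - pep_start + 1
  inb <- contact_pep_res[contact_pep_res >= pep_start & contact_pep_res <= pep_end]
  if (length(inb) / len < min_frac) return(FALSE)
  touched <- (pep_start:pep_end) %in% inb
  runs <- rle(touched)
  gaps <- runs$lengths[!runs$values]
  !(length(gaps) > 0 && max(gaps) > max_gap)
}

#' Iterative interface size/ratio (stoichiometry) filter
#'
#' With N domains currently bound to the peptide, every domain whose
#' interface ratio `r_d = A_dp / A_full` is below `0.5 / N` is dropped;
#' N is updated and the rule re-applied until no domain is removed
#' (convergence in at most N rounds). The candidate is accepted iff the
#' retained domains jointly cover at least `min_total_ratio` of the full
#' interface, each retained ratio meets `min_total_ratio / N`, and each
#' retained domain-peptide interface area meets `min_area`.
#'
#' @param areas_dp named numeric vector of per-domain interface areas
#'   A_dp (Angstrom^2), names = domain ids.
#' @param area_full full protein-protein (or domain vs rest-of-chain)
#'   interface area A_full (Angstrom^2); must be positive.
#' @param min_area per-domain area floor, default 150 Angstrom^2.
#' @param min_total_ratio joint coverage requirement, default 0.5.
#' @return list: `accepted` (logical), `retained` (domain ids),
#'   `dropped` (domain ids), `ratios` (retained ratios), `rounds`.
#' @export
interface_ratio_filter <- function(areas_dp, area_full,
                                   min_area = 150, min_total_ratio = 0.5) {
  if (is.na(area_full) || area_full <= 0)
    stop("interface_ratio_filter: no inter-protein interface (A_full <= 0)")
  ratios <- pmin(pmax(areas_dp / area_full, 0), 1)
  retained <- names(ratios)
  if (is.null(retained)) retained <- as.character(seq_along(ratios))
  names(ratios) <- retained
  rounds <- 0L
  repeat {
    n <- length(ratios)
    if (n == 0) break
    drop <- ratios < min_total_ratio / n
    if (!any(drop)) break
    ratios <- ratios[!drop]
    rounds <- rounds + 1L
  }
  n <- length(ratios)
  ok <- n > 0 &&
    sum(ratios) >= min_total_ratio &&
    all(ratios >= min_total_ratio / n) &&
    all(areas_dp[names(ratios)] >= min_area)
  list(accepted = ok, retained = names(ratios),
       dropped = setdiff(retained, names(ratios)),
       ratios = ratios, rounds = rounds)
}

#' Intrachain context filters
#'
#' For intrachain candidates: fail if the peptide lies within any
#' structure-defined (CATH-like) domain span (such peptides are usually
#' artefacts of sequence- vs structure-based domain assignment), and
#' fail if the sequence separation between the peptide and its binding
#' domain is below `min_seq_dist` residues (separation exactly
#' `min_seq_dist` passes).
#'
#' @param pep_start,pep_end peptide span.
#' @param binding_domains data.frame of binding-domain spans on the same
#'   chain, columns `start`, `end`.
#' @param structure_domains data.frame of structure-defined spans on the
#'   same chain, columns `start`, `end`; may have zero rows.
#' @param min_seq_dist minimum peptide/binding-domain separation, default 10.
#' @return TRUE (pass) or FALSE (fail).
#' @export
intrachain_filters <- function(pep_start, pep_end, binding_domains,
                               structure_domains = NULL, min_seq_dist = 10) {
  if (!is.null(structure_domains) && nrow(structure_domains) > 0) {
    inside <- structure_domains$start <= pep_start &
      structure_domains$end >= pep_end
    if (any(inside)) return(FALSE)
  }
  if (nrow(binding_domains) > 0) {
    for (k in seq_len(nrow(binding_domains))) {
      ds <- binding_domains$start[k]; de <- binding_domains$end[k]
      gap <- if (de < pep_start) pep_start - de
             else if (ds > pep_end) ds - pep_end
             else 0L  # overlap
      if (gap < min_seq_dist) return(FALSE)
    }
  }
  TRUE
}

# Global-alignment identity over the shorter sequence (fraction 0..1).
chain_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0)
    stop("chain_identity: empty sequence")
  sub <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = sub,
                                       gapOpening = 1, gapExtension = 0.5)
  Biostrings::nmatch(aln) / min(nchar(seq_a), nchar(seq_b))
}

#' Homomer filter for interchain candidates
#'
#' Peptide-mediated interactions are usually heterologous; interactions
#' within homomers are rejected. The domain-containing and
#' peptide-containing chains are globally aligned and the candidate
#' fails iff their identity over the shorter sequence reaches
#' `identity_threshold` (default 0.98).
#'
#' @param domain_chain_seq,peptide_chain_seq one-letter chain sequences.
#' @param identity_threshold identity fraction at/above which the pair
#'   is treated as a homomer.
#' @return TRUE (pass, heteromer) or FALSE (fail, homomer).
#' @export
homomer_filter <- function(domain_chain_seq, peptide_chain_seq,
                           identity_threshold = 0.98) {
  chain_identity(domain_chain_seq, peptide_chain_seq) < identity_threshold
}
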