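# Consensus-motif derivation per topology cluster: pattern enumeration
# over non-redundant peptide sets, binomial significance against a
# background amino-acid model, with a correction for the size of the
# enumerable pattern space.

#' Select topology clusters eligible for motif derivation
#'
#' A cluster is searched for consensus motifs only if it has at least
#' `min_upcs` non-redundant sequence clusters (UPCs), at least one
#' interchain member, and at least one member whose protein pair has no
#' known domain-domain interaction (a DMI should occur independently of
#' a DDI).
#'
#' @param members data.frame with one row per candidate DMI: columns
#'   `topo_cluster`, `upc`, `interchain` (logical), `has_ddi` (logical).
#' @param min_upcs minimum number of UPCs, default 3.
#' @return vector of eligible `topo_cluster` ids.
#' @export
select_eligible_clusters <- function(members, min_upcs = 3) {
  ok <- vapply(split(members, members$topo_cluster), function(m) {
    length(unique(m$upc)) >= min_upcs && any(m$interchain) && any(!m$has_ddi)
  }, logical(1))
  ids <- names(ok)[ok]
  if (is.numeric(members$topo_cluster)) ids <- as.numeric(ids)
  ids
}

#' Required modified positions for a cluster
#'
#' If a particular aligned position is modified in more than half of the
#' peptides in a cluster, the modification is required for the motif.
#'
#' @param mod_positions data.frame with `peptide` (id), `position`
#'   (aligned position), `residue` (one-letter code of the modified
#'   residue); zero rows allowed.
#' @param n_peptides number of peptides in the cluster.
#' @return data.frame of required positions: `position`, `residue`,
#'   `n_modified`.
#' @export
required_modifications <- function(mod_positions, n_peptides) {
  empty <- data.frame(position = integer(), residue = character(),
                      n_modified = integer(), stringsAsFactors = FALSE)
  if (is.null(mod_positions) || nrow(mod_positions) == 0) return(empty)
  out <- lapply(split(mod_positions, mod_positions$position), function(m) {
    nm <- length(unique(m$peptide))
    if (nm > n_peptides / 2) {
      data.frame(position = m$position[1],
                 residue = names(sort(table(m$residue), decreasing = TRUE))[1],
                 n_modified = nm, stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

#' Is a cluster in helical mode?
#'
#' TRUE iff strictly more than half of the member peptides have a
#' helical modal class (H, G or I). Helical clusters constrain motif
#' positions to helix-face spacings.
#'
#' @param ss_classes modal DSSP class per member peptide.
#' @return logical.
#' @export
helical_mode <- function(ss_classes) {
  mean(ss_classes %in% c("H", "G", "I")) > 0.5
}

# Defined-position layouts: offset vectors starting at 0, k defined
# positions, total span <= max_span. Helical layouts restrict offsets to
# the helix-face spacings {0, 3, 4, 7}.
motif_layouts <- function(min_defined = 2, max_defined = 5, max_span = 8,
                          helical = FALSE) {
  layouts <- list()
  if (helical) {
    face <- c(3, 4, 7)
    for (k in (min_defined:max_defined) - 1) {
      if (k < 1 || k > length(face)) next
      cmb <- combn(face, k)
      for (c in seq_len(ncol(cmb))) layouts[[length(layouts) + 1]] <-
          c(0, cmb[, c])
    }
    return(layouts)
  }
  for (k in min_defined:max_defined) {
    for (span in k:max_span) {
      if (k == 1) next
      interior <- span - 2
      pick <- k - 2
      if (pick > interior) next
      if (pick == 0) {
        layouts[[length(layouts) + 1]] <- c(0, span - 1)
      } else {
        cmb <- combn(seq_len(interior), pick)
        for (c in seq_len(ncol(cmb))) layouts[[length(layouts) + 1]] <-
            c(0, cmb[, c], span - 1)
      }
    }
  }
  layouts
}

# Size of the enumerable fixed-pattern space for a layout set.
motif_space_size <- function(layouts, n_alphabet = 20) {
  sum(vapply(layouts, function(l) n_alphabet^length(l), numeric(1)))
}

# Size of the pattern space with exactly one ambiguous (pair or triple)
# position; ambiguous patterns are corrected against this larger space.
motif_space_size_amb <- function(layouts, n_alphabet = 20) {
  classes <- choose(n_alphabet, 2) + choose(n_alphabet, 3)
  sum(vapply(layouts, function(l) {
    k <- length(l)
    k * classes * n_alphabet^(k - 1)
  }, numeric(1)))
}

# Tokenize a pattern string into per-position tokens: ".", "X" or "[XY]".
pattern_tokens <- function(pattern) {
  toks <- character(0)
  i <- 1L
  n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(pattern, i, n), fixed = TRUE)
      if (j < 0) stop("unbalanced bracket in pattern: ", pattern)
      toks <- c(toks, substr(pattern, i, i + j - 1))
      i <- i + j
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

#' Single-position match probability and per-sequence match probability
#'
#' `pattern_match_prob` gives the probability that a pattern matches at
#' a fixed position of an i.i.d. background sequence (product over
#' defined positions of the background frequencies; bracket classes sum
#' their members; wildcards contribute 1), and from it the probability
#' of at least one match in a sequence of length `len`.
#'
#' @param pattern motif pattern (fixed residues, bracket classes, `.`).
#' @param background named amino-acid frequency vector summing to 1.
#' @param len sequence length (residues); if `NULL` only the
#'   per-position probability is returned.
#' @return list with `p_pos`, `span`, and (if `len` given) `p_seq`.
#' @export
pattern_match_prob <- function(pattern, background, len = NULL) {
  toks <- pattern_tokens(pattern)
  p_pos <- 1
  for (t in toks) {
    if (t == ".") next
    if (startsWith(t, "[")) {
      aas <- strsplit(gsub("\\[|\\]", "", t), "")[[1]]
      p_pos <- p_pos * sum(background[aas])
    } else {
      p_pos <- p_pos * unname(background[t])
    }
  }
  span <- length(toks)
  out <- list(p_pos = unname(p_pos), span = span)
  if (!is.null(len))
    out$p_seq <- 1 - (1 - out$p_pos)^max(0, len - span + 1)
  out
}

#' Binomial tail probability of motif support
#'
#' Probability that at least `support` of `n_upcs` unrelated sequence
#' clusters contain a match by chance, given the per-UPC probability `q`
#' of at least one match.
#'
#' @param support observed number of supporting UPCs.
#' @param n_upcs number of UPCs searched.
#' @param q per-UPC match probability.
#' @return upper binomial tail `P(X >= support)`.
#' @export
motif_pvalue <- function(support, n_upcs, q) {
  if (support > n_upcs) stop("support exceeds number of UPCs")
  if (support <= 0) return(1)
  pbinom(support - 1, n_upcs, q, lower.tail = FALSE)
}

#' Derive consensus motifs from a non-redundant peptide set
#'
#' Enumerates candidate patterns (2-`max_defined` defined positions,
#' total span at most `max_span`, fixed-length wildcards between)
#' occurring in the sequences; support is counted at most once per UPC.
#' Ambiguity classes (brackets of 2-3 residues) are formed from
#' single-position variants whose union is seen in at least 2 UPCs.
#' Raw binomial tail p-values (per-UPC match probability from the
#' background frequencies and sequence lengths) are corrected for the
#' size of the enumerable pattern space (Sidak), and patterns at or
#' below `p_threshold` are returned ranked by corrected p-value. No
#' terminal anchoring is ever inferred: structure fragments are often
#' truncated, so an apparent terminus need not be one in vivo.
#'
#' In helical mode defined positions are restricted to helix-face
#' spacings (offsets 0, 3, 4, 7 from the anchor). If required modified
#' residues are given, only patterns containing each of them as a fixed
#' position are reported.
#'
#' @param sequences peptide-region sequences (one or more per UPC).
#' @param upcs integer/character UPC id per sequence.
#' @param background named amino-acid frequency vector (sums to 1);
#'   default uniform.
#' @param required_mods character vector of residue letters that must
#'   appear fixed in any reported pattern (from
#'   [required_modifications()]).
#' @param helical restrict layouts to helix-face spacings.
#' @param min_defined,max_defined,max_span pattern shape bounds.
#' @param p_threshold report patterns with corrected p at or below this.
#' @param min_support minimum supporting UPCs for a reported pattern.
#' @return data.frame ranked by p: `pattern`, `support`, `n_defined`,
#'   `span`, `q`, `p_raw`, `p`, `rank`.
#' @export
find_motifs <- function(sequences, upcs, background = NULL,
                        required_mods = NULL, helical = FALSE,
                        min_defined = 2, max_defined = 5, max_span = 8,
                        p_threshold = 0.05, min_support = 2) {
  n_upcs <- length(unique(upcs))
  if (n_upcs < 3) stop("find_motifs requires at least 3 UPCs")
  if (is.null(background))
    background <- setNames(rep(1 / length(AA20), length(AA20)), AA20)
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  layouts <- motif_layouts(min_defined, max_defined, max_span, helical)
  n_space <- motif_space_size(layouts)
  n_space_amb <- n_space + motif_space_size_amb(layouts)

  # enumerate all occurring fixed patterns, recorded with their UPC
  pat <- character(0); pup <- character(0)
  for (s in seq_along(sequences)) {
    seq <- sequences[s]
    len <- nchar(seq)
    chars <- strsplit(seq, "")[[1]]
    for (l in layouts) {
      span <- max(l) + 1
      if (len < span) next
      starts <- 1:(len - span + 1)
      cols <- vector("list", span)
      ok <- rep(TRUE, length(starts))
      for (pos in 0:(span - 1)) {
        if (pos %in% l) {
          v <- chars[starts + pos]
          ok <- ok & v %in% AA20
          cols[[pos + 1]] <- v
        } else {
          cols[[pos + 1]] <- rep(".", length(starts))
        }
      }
      p <- do.call(paste0, cols)
      pat <- c(pat, p[ok]); pup <- c(pup, rep(as.character(upcs[s]), sum(ok)))
    }
  }
  if (length(pat) == 0) return(motif_result_frame())
  occ <- unique(data.frame(pattern = pat, upc = pup, stringsAsFactors = FALSE))
  support <- table(occ$pattern)
  cand <- data.frame(pattern = names(support),
                     support = as.integer(support),
                     stringsAsFactors = FALSE)
  cand <- cand[cand$support >= min_support, , drop = FALSE]

  # ambiguity classes: single-position variants joined into brackets
  if (nrow(cand) > 1) {
    amb <- derive_ambiguous(cand$pattern, occ)
    if (nrow(amb) > 0) cand <- rbind(cand, amb)
  }
  if (nrow(cand) == 0) return(motif_result_frame())

  # per-UPC lengths for the match probability
  upc_lengths <- split(nchar(sequences), as.character(upcs))
  cand$span <- vapply(cand$pattern,
                      function(p) length(pattern_tokens(p)), numeric(1))
  cand$n_defined <- vapply(cand$pattern, function(p)
    sum(pattern_tokens(p) != "."), numeric(1))
  cand$q <- vapply(cand$pattern, function(p) {
    pm <- pattern_match_prob(p, background)
    qs <- vapply(upc_lengths, function(ls)
      1 - prod((1 - pm$p_pos)^pmax(0, ls - pm$span + 1)), numeric(1))
    mean(qs)
  }, numeric(1))
  cand$p_raw <- mapply(motif_pvalue, cand$support,
                       MoreArgs = list(n_upcs = n_upcs), q = cand$q)
  # Sidak correction for the size of the pattern space searched;
  # bracket patterns are charged for the (much larger) ambiguous space
  space <- ifelse(grepl("[", cand$pattern, fixed = TRUE),
                  n_space_amb, n_space)
  cand$p <- -expm1(space * log1p(-pmin(cand$p_raw, 1 - 1e-16)))
  cand$p[cand$p_raw >= 1] <- 1

  if (!is.null(required_mods) && length(required_mods) > 0) {
    keep <- vapply(cand$pattern, function(p) {
      toks <- pattern_tokens(p)
      all(required_mods %in% toks)
    }, logical(1))
    cand <- cand[keep, , drop = FALSE]
  }
  cand <- cand[cand$p <= p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) return(motif_result_frame())
  cand <- cand[order(cand$p, -cand$n_defined, cand$pattern), , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand[, c("pattern", "support", "n_defined", "span", "q", "p_raw", "p", "rank")]
}

motif_result_frame <- function() {
  data.frame(pattern = character(), support = integer(),
             n_defined = numeric(), span = numeric(), q = numeric(),
             p_raw = numeric(), p = numeric(), rank = integer(),
             stringsAsFactors = FALSE)
}

# Bracket classes from fixed patterns differing at one defined position.
derive_ambiguous <- function(patterns, occ, max_class = 3) {
  out <- list()
  toks_list <- lapply(patterns, pattern_tokens)
  span <- vapply(toks_list, length, integer(1))
  for (sp in unique(span)) {
    idx <- which(span == sp)
    if (length(idx) < 2) next
    tk <- do.call(rbind, toks_list[idx])
    defined <- tk != "."
    layout_key <- apply(defined, 1, paste, collapse = "")
    for (lk in unique(layout_key)) {
      rows <- idx[layout_key == lk]
      if (length(rows) < 2) next
      tkr <- do.call(rbind, toks_list[rows])
      dpos <- which(tkr[1, ] != ".")
      for (d in dpos) {
        key <- apply(tkr[, -d, drop = FALSE], 1, paste, collapse = "")
        for (g in unique(key[duplicated(key)])) {
          members <- rows[key == g]
          res <- sort(unique(vapply(toks_list[members], function(t) t[d],
                                    character(1))))
          if (length(res) < 2 || length(res) > max_class) next
          toks <- toks_list[[members[1]]]
          toks[d] <- paste0("[", paste(res, collapse = ""), "]")
          bp <- paste(toks, collapse = "")
          u <- unique(occ$upc[occ$pattern %in% patterns[members]])
          if (length(u) < 2) next
          out[[bp]] <- data.frame(pattern = bp, support = length(u),
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(pattern = character(), support = integer(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' Export sequences and UPC grouping in SLiMFinder-compatible form
#'
#' Writes a FASTA file of the peptide-region sequences and a grouping
#' file listing one UPC per line (tab-separated sequence ids), for users
#' who want to run an external motif finder on the same input.
#'
#' @param sequences peptide-region sequences.
#' @param upcs UPC id per sequence.
#' @param fasta_path,upc_path output paths.
#' @param ids optional sequence ids; default `seq1..seqN`.
#' @return invisibly, the two paths.
#' @export
write_slimfinder_input <- function(sequences, upcs, fasta_path, upc_path,
                                   ids = NULL) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  writeLines(paste0(">", ids, "\n", sequences), fasta_path)
  groups <- vapply(split(ids, as.character(upcs)), paste,
                   character(1), collapse = "\t")
  writeLines(groups, upc_path)
  invisible(c(fasta_path, upc_path))
}
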