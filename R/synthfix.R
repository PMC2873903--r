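# Deterministic synthetic fixtures: ideal peptide geometries, toy
# domain-peptide complexes, planted-motif sequence sets and
# planted-enrichment interactome networks. All generators are seeded
# and emit the same containers/formats the pipeline consumes.

# Deterministic pseudo-backbone around a CA trace: N, C, O, CB offsets
# in a local frame (chain tangent + stable normal). Geometrically
# plausible heavy-atom cloud for contacts and SASA; not energetically
# meaningful.
backbone_atoms <- function(ca, chain = "A", start_index = 1) {
  n <- nrow(ca)
  t <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- if (i == 1) ca[1, ] else ca[i - 1, ]
    b <- if (i == n) ca[n, ] else ca[i + 1, ]
    v <- b - a
    t[i, ] <- v / max(sqrt(sum(v^2)), 1e-9)
  }
  ref <- c(0, 0, 1)
  out <- list()
  for (i in seq_len(n)) {
    u <- ref - sum(ref * t[i, ]) * t[i, ]
    if (sqrt(sum(u^2)) < 1e-6) u <- c(0, 1, 0) - sum(c(0, 1, 0) * t[i, ]) * t[i, ]
    u <- u / sqrt(sum(u^2))
    w <- c(t[i, 2] * u[3] - t[i, 3] * u[2],
           t[i, 3] * u[1] - t[i, 1] * u[3],
           t[i, 1] * u[2] - t[i, 2] * u[1])
    pos <- rbind(CA = ca[i, ],
                 N = ca[i, ] - 1.2 * t[i, ] + 0.5 * u,
                 C = ca[i, ] + 1.2 * t[i, ] + 0.4 * u,
                 O = ca[i, ] + 1.4 * t[i, ] + 1.4 * u,
                 CB = ca[i, ] - 0.5 * u - 1.2 * w)
    out[[i]] <- data.frame(chain = chain, seq_index = start_index + i - 1,
                           elety = rownames(pos),
                           element = c("C", "N", "C", "O", "C"),
                           x = pos[, 1], y = pos[, 2], z = pos[, 3],
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Ideal peptide backbone coordinates
#'
#' Generates C-alpha traces (plus a deterministic pseudo-backbone) for
#' the three geometric classes a bound peptide can take:
#' * `helix`: ideal alpha-helix, rise 1.5 A/residue, radius 2.3 A,
#'   100 degrees/residue (short and non-linear);
#' * `strand`: extended pleated trace, 3.8 A C-alpha steps alternating
#'   +/-5 degrees about the axis with small seeded jitter (long and
#'   flat: linearity stays below 0.5 A);
#' * `coil`: self-avoiding random walk with 3.8 A steps.
#'
#' @param kind `"helix"`, `"strand"` or `"coil"`.
#' @param n number of residues, 4..20.
#' @param seed RNG seed (used by `strand` jitter and `coil`).
#' @return list with `ca` (n x 3 matrix) and `atoms` (data.frame of
#'   heavy atoms: chain, seq_index, elety, element, x, y, z).
#' @export
ideal_peptide_coords <- function(kind = c("helix", "strand", "coil"),
                                 n, seed = 1) {
  kind <- match.arg(kind)
  if (n < 4 || n > 20) stop("peptide length must be 4..20 residues")
  set.seed(seed)
  if (kind == "helix") {
    i <- seq_len(n) - 1
    ang <- i * 100 * pi / 180
    ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  } else if (kind == "strand") {
    theta <- (5 + runif(n - 1, -1, 1)) * pi / 180 * rep_len(c(1, -1), n - 1)
    steps <- cbind(3.8 * cos(theta), 3.8 * sin(theta), 0)
    ca <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
  } else {
    ca <- matrix(0, n, 3)
    for (i in 2:n) {
      repeat {
        dir <- rnorm(3)
        cand <- ca[i - 1, ] + 3.8 * dir / sqrt(sum(dir^2))
        if (i <= 3) break
        dmin <- min(sqrt(rowSums(sweep(ca[1:(i - 2), , drop = FALSE],
                                       2, cand)^2)))
        if (dmin > 3.5) break
      }
      ca[i, ] <- cand
    }
  }
  list(ca = ca, atoms = backbone_atoms(ca))
}

# Compact snake-lattice CA trace: nx*ny*nz block, 3.8 A spacing,
# chain-contiguous ordering.
lattice_domain_ca <- function(nx, ny, nz) {
  ca <- matrix(0, nx * ny * nz, 3)
  k <- 1
  for (iz in 0:(nz - 1)) {
    ys <- if (iz %% 2 == 0) 0:(ny - 1) else (ny - 1):0
    for (iy in ys) {
      xs <- if ((iz + iy) %% 2 == 0) 0:(nx - 1) else (nx - 1):0
      for (ix in xs) {
        ca[k, ] <- c(ix, iy, iz) * 3.8
        k <- k + 1
      }
    }
  }
  ca
}

build_structure_from_atoms <- function(id, chains, is_biological_unit = TRUE) {
  # chains: list of list(atoms = df, sequence = chr vector, chain = id)
  atoms <- do.call(rbind, lapply(chains, function(ch) {
    a <- ch$atoms
    a$resno <- a$seq_index
    a$resid <- names(AA321)[match(ch$sequence[a$seq_index - min(a$seq_index) + 1],
                                  AA321)]
    a$o <- 1
    a
  }))
  res <- do.call(rbind, lapply(chains, function(ch) {
    a <- ch$atoms
    ca <- a[a$elety == "CA", , drop = FALSE]
    data.frame(chain = ch$chain, seq_index = ca$seq_index, resno = ca$seq_index,
               aa = ch$sequence, ca_x = ca$x, ca_y = ca$y, ca_z = ca$z,
               incomplete = FALSE, ss = NA_character_, acc = NA_real_,
               modified = NA_character_, stringsAsFactors = FALSE)
  }))
  rownames(atoms) <- rownames(res) <- NULL
  atoms <- atoms[, c("chain", "seq_index", "resno", "resid", "elety",
                     "element", "x", "y", "z", "o")]
  new_dmi_structure(id, atoms, res, is_biological_unit)
}

random_sequence <- function(n, background = NULL) {
  if (is.null(background))
    background <- setNames(rep(1 / length(AA20), length(AA20)), AA20)
  sample(names(background), n, replace = TRUE, prob = background)
}

#' Toy domain-peptide complex
#'
#' A compact lattice "domain" (chain A) with a peptide (chain B) either
#' placed in contact along a flat face (every peptide residue within
#' heavy-atom contact distance, satisfying the 60%/gap-4 rule by
#' construction) or translated far away. With `extra_segment = TRUE`
#' the peptide chain carries a second, domain-annotated segment that
#' also contacts the domain, so the peptide's share of the full
#' interface drops below 50% (ratio-filter rejection fixture).
#'
#' @param domain_size residues in the domain (lattice block), default 48.
#' @param peptide_kind geometry of the peptide, default `"strand"`.
#' @param peptide_len residues in the peptide, default 8.
#' @param bound place the peptide in contact (TRUE) or 60 A away.
#' @param extra_segment add a second contacting, domain-masked segment
#'   on the peptide chain.
#' @param peptide_seq optional peptide sequence (length `peptide_len`).
#' @param id structure id.
#' @param seed RNG seed.
#' @return list with `structure` (a `dmi_structure`), `annotations`
#'   (data.frame as from [load_annotations()]), `peptide` (chain, start,
#'   end), `profile_map` (profile columns 1..domain_size for chain A).
#' @export
toy_complex <- function(domain_size = 48, peptide_kind = "strand",
                        peptide_len = 8, bound = TRUE,
                        extra_segment = FALSE, peptide_seq = NULL,
                        id = "toy", seed = 1) {
  set.seed(seed)
  nx <- max(peptide_len, 4)
  rem <- ceiling(domain_size / nx)
  ny <- max(2, ceiling(sqrt(rem)))
  nz <- max(1, ceiling(rem / ny))
  ca_dom <- lattice_domain_ca(nx, ny, nz)[seq_len(domain_size), , drop = FALSE]
  dom_seq <- random_sequence(domain_size)
  chains <- list(list(chain = "A", atoms = backbone_atoms(ca_dom, "A"),
                      sequence = dom_seq))

  pep <- ideal_peptide_coords(peptide_kind, peptide_len, seed = seed + 1)
  ca_pep <- pep$ca
  # orient the peptide long axis along x, centred on the y = 0 face
  ca_pep <- sweep(ca_pep, 2, colMeans(ca_pep))
  span_x <- (peptide_len - 1) * 3.8
  ca_pep[, 1] <- ca_pep[, 1] + span_x / 2 + (nx - 1) * 3.8 / 2 - span_x / 2
  yoff <- if (bound) -5.2 else -60
  ca_pep[, 2] <- ca_pep[, 2] + yoff
  ca_pep[, 3] <- ca_pep[, 3] + 0
  if (is.null(peptide_seq)) peptide_seq <- paste(random_sequence(peptide_len),
                                                 collapse = "")
  pep_seq <- strsplit(peptide_seq, "")[[1]]
  stopifnot(length(pep_seq) == peptide_len)
  pep_atoms <- backbone_atoms(ca_pep, "B")
  b_sequence <- pep_seq
  ann <- data.frame(structure = id, chain = "A", family = "TOYFAM",
                    start = 1, end = domain_size,
                    kind = c("sequence", "structure"),
                    stringsAsFactors = FALSE)
  if (extra_segment) {
    # two close-packed strands against the opposite face, burying more
    # area than the peptide itself so its interface share falls below 50%
    seg_len <- 2 * peptide_len
    seg1 <- ideal_peptide_coords("strand", peptide_len, seed = seed + 2)$ca
    seg2 <- ideal_peptide_coords("strand", peptide_len, seed = seed + 3)$ca
    center_face <- function(m, zoff) {
      m <- sweep(m, 2, colMeans(m))
      m[, 1] <- m[, 1] + (nx - 1) * 3.8 / 2
      m[, 2] <- m[, 2] + (ny - 1) * 3.8 + 4.8  # opposite face, close
      m[, 3] <- m[, 3] + zoff
      m
    }
    ca_seg <- rbind(center_face(seg1, -2.4), center_face(seg2, 2.4))
    seg_atoms <- backbone_atoms(ca_seg, "B", start_index = peptide_len + 1)
    pep_atoms <- rbind(pep_atoms, seg_atoms)
    b_sequence <- c(pep_seq, random_sequence(seg_len))
    ann <- rbind(ann, data.frame(structure = id, chain = "B",
                                 family = "MASKFAM",
                                 start = peptide_len + 1,
                                 end = peptide_len + seg_len,
                                 kind = "sequence", stringsAsFactors = FALSE))
  }
  chains[[2]] <- list(chain = "B", atoms = pep_atoms, sequence = b_sequence)
  struct <- build_structure_from_atoms(id, chains)
  pmap <- data.frame(family = "TOYFAM", structure = id, chain = "A",
                     seq_index = seq_len(domain_size),
                     column = seq_len(domain_size), stringsAsFactors = FALSE)
  list(structure = struct, annotations = ann,
       peptide = list(chain = "B", start = 1, end = peptide_len),
       profile_map = pmap)
}

# Instantiate a motif pattern into a concrete sequence fragment.
instantiate_pattern <- function(pattern, background = NULL) {
  if (is.null(background))
    background <- setNames(rep(1 / length(AA20), length(AA20)), AA20)
  toks <- pattern_tokens(pattern)
  vapply(toks, function(t) {
    if (t == ".") sample(names(background), 1, prob = background)
    else if (startsWith(t, "[")) {
      aas <- strsplit(gsub("\\[|\\]", "", t), "")[[1]]
      sample(aas, 1)
    } else t
  }, character(1), USE.NAMES = FALSE)
}

#' Planted-motif sequence set
#'
#' One sequence per UPC: background-distributed flanks around one
#' instance of the planted pattern at a random offset. With
#' `planted_pattern = NULL` a pure background (null) set is generated.
#'
#' @param n_upcs number of UPCs (>= 3).
#' @param planted_pattern motif pattern to plant, or NULL for a null set.
#' @param flank_len flank length on each side, default 12.
#' @param background named amino-acid frequencies; default uniform.
#' @param seed RNG seed.
#' @return list with `sequences` (character vector) and `upcs`
#'   (integer vector `1..n_upcs`).
#' @export
synth_motif_set <- function(n_upcs, planted_pattern = "DE.F",
                            flank_len = 12, background = NULL, seed = 1) {
  if (n_upcs < 3) stop("n_upcs must be >= 3")
  set.seed(seed)
  span <- if (is.null(planted_pattern)) 0 else
    length(pattern_tokens(planted_pattern))
  total <- 2 * flank_len + max(span, 0)
  if (span > total) stop("pattern longer than sequence")
  seqs <- vapply(seq_len(n_upcs), function(k) {
    chars <- random_sequence(total, background)
    if (!is.null(planted_pattern)) {
      off <- sample.int(total - span + 1, 1)
      chars[off:(off + span - 1)] <- instantiate_pattern(planted_pattern,
                                                         background)
    }
    paste(chars, collapse = "")
  }, character(1))
  list(sequences = seqs, upcs = seq_len(n_upcs))
}

#' Planted-enrichment interactome network
#'
#' Random network of `p` proteins with Bernoulli domain carriage and
#' motif-match insertion whose rate depends on interactor status
#' (a protein is an interactor if it has at least one domain-carrying
#' neighbour). Equal rates give a null network; a higher interactor
#' rate plants enrichment.
#'
#' @param p number of proteins (>= 20).
#' @param domain_frac fraction of proteins carrying the domain.
#' @param match_prob_interactor,match_prob_other match-insertion rates.
#' @param mean_degree average node degree, default 4.
#' @param seq_len protein sequence length, default 60.
#' @param pattern motif pattern inserted into matching proteins.
#' @param family domain family name.
#' @param seed RNG seed.
#' @return a `dmi_interactome`.
#' @export
synth_interactome <- function(p = 1000, domain_frac = 0.1,
                              match_prob_interactor = 0.15,
                              match_prob_other = 0.05,
                              mean_degree = 4, seq_len = 60,
                              pattern = "DE.F", family = "FAM1", seed = 1) {
  if (p < 20) stop("p must be >= 20")
  stopifnot(match_prob_interactor >= 0, match_prob_interactor <= 1,
            match_prob_other >= 0, match_prob_other <= 1)
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(p))
  n_edges <- round(p * mean_degree / 2)
  a <- sample.int(p, 2 * n_edges, replace = TRUE)
  b <- sample.int(p, 2 * n_edges, replace = TRUE)
  keep <- a != b
  lo <- pmin(a, b)[keep]; hi <- pmax(a, b)[keep]
  dup <- duplicated(paste(lo, hi))
  lo <- lo[!dup][seq_len(min(n_edges, sum(!dup)))]
  hi <- hi[!dup][seq_len(min(n_edges, sum(!dup)))]
  carrier <- runif(p) < domain_frac
  if (!any(carrier)) carrier[sample.int(p, max(1, round(domain_frac * p)))] <- TRUE
  interactor <- ids %in% c(ids[lo][carrier[hi]], ids[hi][carrier[lo]])
  dom_len <- 20L
  rate <- ifelse(interactor, match_prob_interactor, match_prob_other)
  matched <- runif(p) < rate
  span <- length(pattern_tokens(pattern))
  seqs <- vapply(seq_len(p), function(k) {
    chars <- random_sequence(seq_len)
    if (matched[k]) {
      lo_pos <- if (carrier[k]) dom_len + 1L else 1L
      off <- sample(lo_pos:(seq_len - span + 1), 1)
      chars[off:(off + span - 1)] <- instantiate_pattern(pattern)
    }
    paste(chars, collapse = "")
  }, character(1))
  prot <- data.frame(id = ids, species = "synth", sequence = seqs,
                     domains = ifelse(carrier,
                                      sprintf("%s:1-%d", family, dom_len), ""),
                     stringsAsFactors = FALSE)
  edges <- data.frame(protA = ids[lo], protB = ids[hi],
                      stringsAsFactors = FALSE)
  doms <- parse_domain_strings(prot$id, prot$domains)
  new_interactome(prot, edges, doms)
}
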