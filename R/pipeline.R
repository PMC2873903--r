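# End-to-end discovery orchestration and the leave-one-domain-out
# benchmark.

#' Pipeline configuration
#'
#' All tunable thresholds of the discovery pipeline, with the defaults
#' used throughout: peptide lengths 4-20, heavy-atom contact cutoff
#' 5 A, 60% contacting residues with non-contact runs of at most 4,
#' per-domain interface floor 150 A^2, joint interface ratio 0.5 (0.5/N
#' per domain), minimum intrachain peptide/domain separation 10
#' residues, homomer identity 0.98, topology cut 1.0, sequence cut 0.1,
#' minimum 3 UPCs, motif p <= 0.05, enrichment p <= 0.025.
#'
#' @param ... overrides for any default.
#' @return named list of settings.
#' @export
dmi_config <- function(...) {
  cfg <- list(lmin = 4, lmax = 20, contact_cutoff = 5.0,
              contact_min_frac = 0.6, contact_max_gap = 4,
              min_interface_area = 150, min_total_ratio = 0.5,
              min_seq_dist = 10, homomer_identity = 0.98,
              topo_cut = 1.0, seq_cut = 0.1, min_upcs = 3,
              motif_p = 0.05, enrichment_p = 0.025,
              max_defined = 5, max_span = 8,
              sasa_points = 960, probe_radius = 1.4, seed = 1)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Amino-acid background frequencies from a structure set
#'
#' @param structures list of `dmi_structure`.
#' @return named frequency vector over the 20 standard residues.
#' @export
aa_frequencies <- function(structures) {
  aa <- unlist(lapply(structures, function(s) s$residues$aa))
  aa <- aa[aa %in% AA20]
  tab <- table(factor(aa, levels = AA20))
  freq <- as.numeric(tab) / sum(tab)
  setNames(freq, AA20)
}

# Ensure SS and accessibility are filled.
prepare_structure <- function(struct, cfg) {
  if (anyNA(struct$residues$ss))
    struct <- assign_secondary_structure(struct)
  if (anyNA(struct$residues$acc[!struct$residues$incomplete]))
    struct <- compute_accessibility(struct, probe_radius = cfg$probe_radius,
                                    n_points = cfg$sasa_points)
  struct
}

#' Run the candidate-DMI discovery pipeline
#'
#' Executes, in order: peptide enumeration outside sequence-domain
#' masks, SVM classification, domain-contact filtering, covered-peptide
#' removal, intrachain context filters, homomer filtering, interface
#' size/ratio filtering, topology and sequence clustering, eligibility
#' selection and motif derivation. Structures flagged as
#' non-biological-unit are excluded up front. Per-stage survivor counts
#' are reported; every (peptide, domain) pair carries its filter
#' provenance.
#'
#' @param structures list of `dmi_structure`.
#' @param annotations domain annotation data.frame
#'   (see [load_annotations()]).
#' @param model a trained `dmi_svm`.
#' @param config a [dmi_config()] list.
#' @param profile_maps optional profile-map data.frame
#'   (see [load_profile_map()]).
#' @param modified optional modified-residue data.frame.
#' @param ddi_pairs optional DDI family-pair data.frame (`familyA`,
#'   `familyB`).
#' @param background optional amino-acid frequency vector; default
#'   computed from `structures`.
#' @return list: `peptides`, `candidates`, `regions`, `clusters`,
#'   `motifs`, `counts` (per-stage survivors).
#' @export
run_discovery <- function(structures, annotations, model, config = dmi_config(),
                          profile_maps = NULL, modified = NULL,
                          ddi_pairs = NULL, background = NULL) {
  cfg <- config
  structures <- Filter(function(s) isTRUE(s$is_biological_unit), structures)
  names(structures) <- vapply(structures, `[[`, character(1), "id")
  if (is.null(background)) background <- aa_frequencies(structures)
  counts <- c(enumerated = 0, svm_accepted = 0, contact_pass = 0,
              after_covered = 0, context_pass = 0, interface_pass = 0)

  all_pep <- list(); all_cand <- list()
  for (sid in names(structures)) {
    st <- prepare_structure(structures[[sid]], cfg)
    structures[[sid]] <- st
    ann <- annotations[annotations$structure == sid, , drop = FALSE]
    seq_dom <- ann[ann$kind == "sequence", , drop = FALSE]
    str_dom <- ann[ann$kind == "structure", , drop = FALSE]

    pep <- do.call(rbind, lapply(unique(st$residues$chain), function(ch) {
      enumerate_peptides(st, ch,
                         masks = seq_dom[seq_dom$chain == ch, , drop = FALSE],
                         lmin = cfg$lmin, lmax = cfg$lmax)
    }))
    if (is.null(pep) || nrow(pep) == 0) next
    counts["enumerated"] <- counts["enumerated"] + nrow(pep)
    pep <- classify_peptides(model, pep)
    acc <- pep[pep$accepted, , drop = FALSE]
    counts["svm_accepted"] <- counts["svm_accepted"] + nrow(acc)
    all_pep[[sid]] <- pep
    if (nrow(acc) == 0) next

    # contact filter against every sequence-defined domain
    keep <- logical(nrow(acc))
    cmaps <- vector("list", nrow(acc))
    for (k in seq_len(nrow(acc))) {
      maps <- list()
      for (d in seq_len(nrow(seq_dom))) {
        if (seq_dom$chain[d] == acc$chain[k] &&
            !(seq_dom$end[d] < acc$start[k] || seq_dom$start[d] > acc$end[k]))
          next  # a peptide cannot bind a domain it overlaps
        cm <- residue_contacts(st, acc$chain[k], acc$start[k], acc$end[k],
                               seq_dom$chain[d], seq_dom$start[d],
                               seq_dom$end[d], cutoff = cfg$contact_cutoff)
        if (length(cm$pep_res) == 0) next
        if (domain_contact_filter(cm$pep_res, acc$start[k], acc$end[k],
                                  cfg$contact_min_frac, cfg$contact_max_gap))
          maps[[length(maps) + 1]] <- c(list(domain_row = d), cm)
      }
      if (length(maps) > 0) { keep[k] <- TRUE; cmaps[[k]] <- maps }
    }
    acc <- acc[keep, , drop = FALSE]; cmaps <- cmaps[keep]
    counts["contact_pass"] <- counts["contact_pass"] + nrow(acc)
    if (nrow(acc) == 0) next

    red <- remove_covered_peptides(acc)
    cmaps <- cmaps[match(paste(red$chain, red$start, red$end),
                         paste(acc$chain, acc$start, acc$end))]
    acc <- red
    counts["after_covered"] <- counts["after_covered"] + nrow(acc)

    for (k in seq_len(nrow(acc))) {
      for (cm in cmaps[[k]]) {
        d <- cm$domain_row
        dom <- seq_dom[d, ]
        intra <- dom$chain == acc$chain[k]
        provenance <- c("svm=pass", "contact=pass")
        ok <- TRUE
        if (intra) {
          pass <- intrachain_filters(
            acc$start[k], acc$end[k],
            binding_domains = dom[, c("start", "end")],
            structure_domains = str_dom[str_dom$chain == acc$chain[k],
                                        c("start", "end"), drop = FALSE],
            min_seq_dist = cfg$min_seq_dist)
          provenance <- c(provenance,
                          paste0("intrachain=", if (pass) "pass" else "fail"))
          ok <- ok && pass
        } else {
          pass <- homomer_filter(chain_sequence(st, dom$chain),
                                 chain_sequence(st, acc$chain[k]),
                                 cfg$homomer_identity)
          provenance <- c(provenance,
                          paste0("homomer=", if (pass) "pass" else "fail"))
          ok <- ok && pass
        }
        all_cand[[length(all_cand) + 1]] <- data.frame(
          structure = sid, pep_chain = acc$chain[k],
          pep_start = acc$start[k], pep_end = acc$end[k],
          sequence = acc$sequence[k], ss = acc$ss[k],
          dom_chain = dom$chain, dom_start = dom$start, dom_end = dom$end,
          family = dom$family, interchain = !intra,
          dom_contacts = paste(cm$dom_res, collapse = ","),
          context_pass = ok,
          provenance = paste(provenance, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  peptides <- if (length(all_pep)) do.call(rbind, all_pep) else NULL
  empty <- list(peptides = peptides, candidates = NULL, regions = NULL,
                clusters = NULL, motifs = NULL, counts = counts)
  if (length(all_cand) == 0) return(empty)
  cand <- do.call(rbind, all_cand)
  rownames(cand) <- NULL
  counts["context_pass"] <- sum(cand$context_pass)
  cand <- cand[cand$context_pass, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  # interface size/ratio filter per (structure, peptide, partner chain)
  cand$grp <- paste(cand$structure, cand$pep_chain, cand$pep_start,
                    cand$pep_end, cand$dom_chain, sep = "\r")
  keep_rows <- logical(nrow(cand))
  cand$ratio <- NA_real_; cand$area_dp <- NA_real_; cand$area_full <- NA_real_
  for (g in unique(cand$grp)) {
    rows <- which(cand$grp == g)
    st <- structures[[cand$structure[rows[1]]]]
    pch <- cand$pep_chain[rows[1]]; dch <- cand$dom_chain[rows[1]]
    ps <- cand$pep_start[rows[1]]; pe <- cand$pep_end[rows[1]]
    pa <- span_atoms(st, pch, ps, pe)
    areas <- vapply(rows, function(k) {
      da <- span_atoms(st, dch, cand$dom_start[k], cand$dom_end[k])
      interface_area(pa$xyz, pa$radii, da$xyz, da$radii,
                     probe_radius = cfg$probe_radius,
                     n_points = cfg$sasa_points)
    }, numeric(1))
    names(areas) <- as.character(rows)
    a_full <- if (pch != dch) {
      ca <- span_atoms(st, pch); cb <- span_atoms(st, dch)
      interface_area(ca$xyz, ca$radii, cb$xyz, cb$radii,
                     probe_radius = cfg$probe_radius,
                     n_points = cfg$sasa_points)
    } else {
      # intrachain: binding-domain span vs the rest of the chain
      du <- span_atoms(st, dch, min(cand$dom_start[rows]),
                       max(cand$dom_end[rows]))
      rest_idx <- setdiff(st$atoms$seq_index[st$atoms$chain == dch],
                          seq(min(cand$dom_start[rows]),
                              max(cand$dom_end[rows])))
      ra <- st$atoms[st$atoms$chain == dch &
                       st$atoms$seq_index %in% rest_idx, , drop = FALSE]
      interface_area(du$xyz, du$radii,
                     as.matrix(ra[, c("x", "y", "z")]),
                     vdw_radius(ra$element),
                     probe_radius = cfg$probe_radius,
                     n_points = cfg$sasa_points)
    }
    res <- tryCatch(
      interface_ratio_filter(areas, a_full, cfg$min_interface_area,
                             cfg$min_total_ratio),
      error = function(e) list(accepted = FALSE, retained = character(0),
                               ratios = numeric(0)))
    cand$area_dp[rows] <- areas
    cand$area_full[rows] <- a_full
    cand$ratio[rows] <- areas / max(a_full, 1e-9)
    if (res$accepted) keep_rows[as.integer(res$retained)] <- TRUE
  }
  cand$interface_pass <- keep_rows
  cand$provenance <- paste0(cand$provenance, ";interface=",
                            ifelse(keep_rows, "pass", "fail"))
  counts["interface_pass"] <- sum(keep_rows)
  survivors <- cand[keep_rows, , drop = FALSE]
  survivors$grp <- NULL
  if (nrow(survivors) == 0) {
    empty$candidates <- cand
    return(empty)
  }

  # peptide-containing regions per structure/chain from surviving peptides
  pep_for_regions <- unique(survivors[, c("structure", "pep_chain",
                                          "pep_start", "pep_end")])
  names(pep_for_regions) <- c("structure", "chain", "start", "end")
  regions <- build_peptide_regions(pep_for_regions)
  rkey <- function(s, ch, pos) {
    hit <- regions$structure == s & regions$chain == ch &
      regions$start <= pos & regions$end >= pos
    which(hit)[1]
  }
  survivors$region <- mapply(rkey, survivors$structure, survivors$pep_chain,
                             survivors$pep_start)
  survivors$region_seq <- vapply(survivors$region, function(rg) {
    st <- structures[[regions$structure[rg]]]
    r <- st$residues
    sel <- r$chain == regions$chain[rg] & r$seq_index >= regions$start[rg] &
      r$seq_index <= regions$end[rg]
    paste(r$aa[sel], collapse = "")
  }, character(1))

  # clustering per family
  clusters <- list(); motifs <- list()
  for (fam in unique(survivors$family)) {
    rows <- which(survivors$family == fam)
    sv <- survivors[rows, , drop = FALSE]
    pmap_fam <- if (!is.null(profile_maps))
      profile_maps[profile_maps$family == fam, , drop = FALSE] else NULL
    positions <- lapply(seq_len(nrow(sv)), function(k) {
      dres <- as.integer(strsplit(sv$dom_contacts[k], ",")[[1]])
      if (!is.null(pmap_fam) && nrow(pmap_fam) > 0) {
        pm <- pmap_fam[pmap_fam$structure == sv$structure[k] &
                         pmap_fam$chain == sv$dom_chain[k], , drop = FALSE]
        if (nrow(pm) > 0)
          return(interface_profile_positions(dres, pm))
      }
      dres  # raw numbering when no profile map is available
    })
    topo <- topology_clusters(positions, cut = cfg$topo_cut)
    dom_seqs <- lapply(seq_len(nrow(sv)), function(k)
      chain_sequence(structures[[sv$structure[k]]], sv$dom_chain[k]))
    dom_maps <- lapply(seq_len(nrow(sv)), function(k) {
      if (!is.null(pmap_fam) && nrow(pmap_fam) > 0) {
        pm <- pmap_fam[pmap_fam$structure == sv$structure[k] &
                         pmap_fam$chain == sv$dom_chain[k], , drop = FALSE]
        if (nrow(pm) > 0) return(pm[, c("seq_index", "column")])
      }
      data.frame(seq_index = sv$dom_start[k]:sv$dom_end[k],
                 column = seq_len(sv$dom_end[k] - sv$dom_start[k] + 1))
    })
    upc <- sequence_clusters(sv$region_seq, dom_seqs, dom_maps,
                             cut = cfg$seq_cut)
    has_ddi <- vapply(seq_len(nrow(sv)), function(k) {
      if (is.null(ddi_pairs) || nrow(ddi_pairs) == 0) return(FALSE)
      st <- structures[[sv$structure[k]]]
      ann <- annotations[annotations$structure == sv$structure[k] &
                           annotations$chain == sv$pep_chain[k] &
                           annotations$kind == "sequence", , drop = FALSE]
      pep_fams <- unique(ann$family)
      key <- c(paste(fam, pep_fams, sep = "\r"),
               paste(pep_fams, fam, sep = "\r"))
      any(key %in% paste(ddi_pairs$familyA, ddi_pairs$familyB, sep = "\r"))
    }, logical(1))
    cl <- data.frame(family = fam, candidate = rows, topo_cluster = topo,
                     upc = upc, interchain = sv$interchain,
                     has_ddi = has_ddi, stringsAsFactors = FALSE)
    clusters[[fam]] <- cl
    eligible <- select_eligible_clusters(cl, min_upcs = cfg$min_upcs)
    for (tc in eligible) {
      sel <- which(cl$topo_cluster == tc)
      # one sequence per region; UPC of the region = UPC of its members
      reg_idx <- !duplicated(sv$region[sel])
      seqs <- sv$region_seq[sel][reg_idx]
      upcs <- cl$upc[sel][reg_idx]
      hel <- helical_mode(sv$ss[sel])
      mots <- find_motifs(seqs, upcs, background = background,
                          helical = hel, max_defined = cfg$max_defined,
                          max_span = cfg$max_span,
                          p_threshold = cfg$motif_p)
      if (nrow(mots) > 0) {
        mots$family <- fam; mots$topo_cluster <- tc; mots$helical <- hel
        motifs[[length(motifs) + 1]] <- mots
      }
    }
  }
  list(peptides = peptides, candidates = cand,
       regions = regions, clusters = do.call(rbind, clusters),
       motifs = if (length(motifs)) do.call(rbind, motifs) else NULL,
       counts = counts)
}

#' Synthetic leave-one-domain-out benchmark set
#'
#' `n_families` domain families, each with `n_structures` toy complexes
#' whose bound strand peptides carry a family-specific planted motif in
#' otherwise random sequence (so each family yields at least 3
#' non-redundant peptides), plus background features from helical and
#' coil peptides for SVM training negatives.
#'
#' @param n_families number of families, default 3.
#' @param n_structures toy complexes per family, default 3.
#' @param peptide_len peptide length, default 8.
#' @param seed RNG seed.
#' @return list with `families` (per family: `pattern`, `complexes`,
#'   `annotations`, `profile_maps`) and `negative_features`.
#' @export
synth_benchmark_set <- function(n_families = 3, n_structures = 3,
                                peptide_len = 8, seed = 1) {
  set.seed(seed)
  patterns <- replicate(n_families,
                        paste(sample(setdiff(AA20, "X"), 4), collapse = ""))
  families <- list()
  for (f in seq_len(n_families)) {
    fam <- sprintf("FAM%d", f)
    complexes <- list()
    for (s in seq_len(n_structures)) {
      flank <- random_sequence(peptide_len - 4)
      off <- sample.int(peptide_len - 4 + 1, 1)
      pseq <- append(flank, strsplit(patterns[f], "")[[1]], after = off - 1)
      cx <- toy_complex(peptide_len = peptide_len, bound = TRUE,
                        peptide_seq = paste(pseq, collapse = ""),
                        id = sprintf("%s_s%d", fam, s),
                        seed = seed * 1000 + f * 100 + s)
      cx$annotations$family[cx$annotations$family == "TOYFAM"] <- fam
      cx$profile_map$family <- fam
      complexes[[s]] <- cx
    }
    families[[fam]] <- list(pattern = patterns[f], complexes = complexes)
  }
  # background features: helical and coil peptides (globular-like decoys)
  neg <- list()
  for (k in 1:30) {
    n <- sample(5:12, 1)
    kind <- if (k %% 2 == 0) "helix" else "coil"
    g <- ideal_peptide_coords(kind, n, seed = seed * 500 + k)
    neg[[k]] <- data.frame(length = n, elongation = elongation(g$ca),
                           linearity = linearity(g$ca),
                           ss = if (kind == "helix") "H" else "-",
                           acc = 80, stringsAsFactors = FALSE)
  }
  list(families = families, negative_features = do.call(rbind, neg))
}

# Feature rows for the known peptide spans of a family's complexes.
known_peptide_features <- function(complexes, cfg) {
  out <- list()
  for (cx in complexes) {
    st <- prepare_structure(cx$structure, cfg)
    r <- st$residues
    sel <- r$chain == cx$peptide$chain & r$seq_index >= cx$peptide$start &
      r$seq_index <= cx$peptide$end
    out[[length(out) + 1]] <- window_features(r[sel, , drop = FALSE])
  }
  do.call(rbind, out)
}

#' Leave-one-domain-out benchmark
#'
#' For each family: retrain the SVM without that family's peptides, run
#' the full discovery pipeline on the family's structures, and score
#' the family positive iff an accepted peptide overlaps a known test
#' peptide in at least `min_overlap` (default 3) positions and a
#' significant consensus pattern is derived for its cluster. Families
#' with fewer than the minimum number of non-redundant sequences are
#' reported as ignored, not as false negatives. Negative (helical /
#' coil) feature sets are classified with each fold's SVM; accepted
#' negatives count against specificity.
#'
#' @param benchmark a [synth_benchmark_set()]-shaped list.
#' @param config a [dmi_config()].
#' @param min_overlap minimum positional overlap with a test peptide.
#' @return list: `per_family` data.frame (family, n_test, n_recovered,
#'   sensitivity, ignored), `sensitivity` (over scored families),
#'   `negatives_accepted` (count over all folds).
#' @export
run_loo_benchmark <- function(benchmark, config = dmi_config(),
                              min_overlap = 3) {
  fams <- names(benchmark$families)
  if (length(fams) < 2) stop("benchmark needs at least 2 domain families")
  cfg <- config
  res <- list(); neg_accepted <- 0
  for (f in fams) {
    train_fams <- setdiff(fams, f)
    pos <- do.call(rbind, lapply(train_fams, function(g)
      known_peptide_features(benchmark$families[[g]]$complexes, cfg)))
    model <- train_svm(pos, benchmark$negative_features, seed = cfg$seed)
    neg_dec <- classify_peptides(model, benchmark$negative_features)
    neg_accepted <- neg_accepted + sum(neg_dec$accepted)

    cxs <- benchmark$families[[f]]$complexes
    structures <- lapply(cxs, `[[`, "structure")
    annotations <- do.call(rbind, lapply(cxs, `[[`, "annotations"))
    pmap <- do.call(rbind, lapply(cxs, `[[`, "profile_map"))
    disc <- run_discovery(structures, annotations, model, cfg,
                          profile_maps = pmap)
    n_test <- length(cxs); n_rec <- 0; ignored <- FALSE
    if (is.null(disc$clusters) ||
        length(unique(disc$clusters$upc)) < cfg$min_upcs) {
      ignored <- TRUE
    } else {
      sig_clusters <- if (!is.null(disc$motifs))
        unique(disc$motifs$topo_cluster) else integer(0)
      for (cx in cxs) {
        sv <- disc$candidates[disc$candidates$interface_pass &
                                disc$candidates$structure == cx$structure$id, ,
                              drop = FALSE]
        hit <- FALSE
        if (nrow(sv) > 0 && length(sig_clusters) > 0) {
          ov <- pmin(sv$pep_end, cx$peptide$end) -
            pmax(sv$pep_start, cx$peptide$start) + 1
          hit <- any(ov >= min_overlap)
        }
        n_rec <- n_rec + as.integer(hit)
      }
    }
    res[[f]] <- data.frame(family = f, n_test = n_test, n_recovered = n_rec,
                           sensitivity = if (ignored) NA_real_ else n_rec / n_test,
                           ignored = ignored, stringsAsFactors = FALSE)
  }
  per_family <- do.call(rbind, res)
  rownames(per_family) <- NULL
  scored <- per_family[!per_family$ignored, , drop = FALSE]
  list(per_family = per_family,
       sensitivity = if (nrow(scored)) sum(scored$n_recovered) /
         sum(scored$n_test) else NA_real_,
       negatives_accepted = neg_accepted)
}
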