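# Peptide enumeration, SVM classification, overlap reduction.

#' Enumerate candidate peptide windows on a chain
#'
#' All contiguous residue windows of `lmin`..`lmax` residues lying
#' wholly outside every sequence-defined domain span, with structural
#' features computed. Windows containing residues without C-alpha
#' coordinates are skipped. Secondary structure and accessibility must
#' already be assigned (see [assign_secondary_structure()],
#' [compute_accessibility()]).
#'
#' @param struct a `dmi_structure`.
#' @param chain chain identifier.
#' @param masks data.frame of spans to exclude, columns `start`, `end`
#'   (the sequence-defined domain annotations of this chain); may have
#'   zero rows.
#' @param lmin,lmax window length bounds (residues), defaults 4 and 20.
#' @return data.frame, one row per peptide: `structure`, `chain`,
#'   `start`, `end`, `length`, `sequence`, `elongation`, `linearity`,
#'   `ss`, `acc`.
#' @export
enumerate_peptides <- function(struct, chain, masks = NULL, lmin = 4, lmax = 20) {
  r <- struct$residues
  r <- r[r$chain == chain, , drop = FALSE]
  r <- r[order(r$seq_index), , drop = FALSE]
  usable <- !r$incomplete
  if (!is.null(masks) && nrow(masks) > 0) {
    for (k in seq_len(nrow(masks)))
      usable <- usable & !(r$seq_index >= masks$start[k] &
                           r$seq_index <= masks$end[k])
  }
  out <- list()
  n <- nrow(r)
  for (i in seq_len(n)) {
    if (!usable[i]) next
    for (len in lmin:lmax) {
      j <- i + len - 1
      if (j > n) break
      if (!all(usable[i:j])) break
      win <- r[i:j, , drop = FALSE]
      f <- window_features(win)
      out[[length(out) + 1]] <- data.frame(
        structure = struct$id, chain = chain,
        start = win$seq_index[1], end = win$seq_index[len],
        sequence = paste(win$aa, collapse = ""), f,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(structure = character(), chain = character(),
                      start = integer(), end = integer(),
                      sequence = character(), length = integer(),
                      elongation = numeric(), linearity = numeric(),
                      ss = character(), acc = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Train the motif-likeness SVM
#'
#' Linear-kernel SVM on encoded peptide features with asymmetric class
#' cost: misclassified positives cost `cost_factor` times more than
#' misclassified negatives (class-weighted C), with error/margin
#' trade-off `tradeoff`. Features are z-scored with training statistics
#' that are stored in the model for reuse at prediction time.
#'
#' @param positives,negatives feature data.frames (columns `length`,
#'   `elongation`, `linearity`, `acc`, `ss`) for known motif peptides
#'   and background peptides.
#' @param cost_factor relative cost of positive-class errors, default 10.
#' @param tradeoff error/margin trade-off (the C parameter), default 0.1.
#' @param n_background optional cap on the number of negatives used,
#'   sampled deterministically under `seed`.
#' @param seed RNG seed for background subsampling.
#' @return an object of class `dmi_svm`: weight vector `w`, bias `b`,
#'   standardization `stats`, training metadata.
#' @export
train_svm <- function(positives, negatives, cost_factor = 10, tradeoff = 0.1,
                      n_background = NULL, seed = 1) {
  if (nrow(positives) == 0 || nrow(negatives) == 0)
    stop("train_svm needs at least one example per class")
  if (!is.null(n_background) && nrow(negatives) > n_background) {
    set.seed(seed)
    negatives <- negatives[sample.int(nrow(negatives), n_background), ,
                           drop = FALSE]
  }
  xr <- rbind(encode_features(positives), encode_features(negatives))
  stats <- feature_stats(xr)
  x <- standardize_features(xr, stats)
  y <- factor(rep(c("pos", "neg"), c(nrow(positives), nrow(negatives))),
              levels = c("pos", "neg"))
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                    cost = tradeoff,
                    class.weights = c(pos = cost_factor, neg = 1),
                    scale = FALSE, tolerance = 1e-6)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision function so the first training label is
  # positive; flip if needed so that decision > 0 means "pos".
  if (fit$labels[1] != 1) { w <- -w; b <- -b }
  structure(list(w = w, b = b, stats = stats,
                 cost_factor = cost_factor, tradeoff = tradeoff,
                 n_pos = nrow(positives), n_neg = nrow(negatives)),
            class = "dmi_svm")
}

#' @export
print.dmi_svm <- function(x, ...) {
  cat(sprintf("dmi_svm: linear, cost_factor=%g, tradeoff=%g, trained on %d pos / %d neg\n",
              x$cost_factor, x$tradeoff, x$n_pos, x$n_neg))
  invisible(x)
}

#' Decision values of the motif-likeness SVM
#'
#' @param model a `dmi_svm`.
#' @param features feature data.frame as in [train_svm()].
#' @return numeric decision values (affine in the encoded features).
#' @export
svm_decision <- function(model, features) {
  x <- encode_features(features, stats = model$stats)
  drop(x %*% model$w) + model$b
}

#' Classify peptides with a trained SVM
#'
#' Adds `decision` and `accepted` columns; a peptide is accepted iff its
#' decision value is strictly positive (ties at exactly zero rejected).
#'
#' @param model a `dmi_svm`.
#' @param peptides peptide data.frame from [enumerate_peptides()].
#' @return `peptides` with `decision` and `accepted` added.
#' @export
classify_peptides <- function(model, peptides) {
  need <- c("length", "elongation", "linearity", "acc", "ss")
  if (!all(need %in% names(peptides)) || anyNA(peptides[need]))
    stop("classify_peptides: missing features")
  peptides$decision <- if (nrow(peptides)) svm_decision(model, peptides) else numeric(0)
  peptides$accepted <- peptides$decision > 0
  peptides
}

#' Persist / restore an SVM model
#'
#' Plain-text (dput) persistence of weights, bias, standardization stats
#' and training metadata.
#'
#' @param model a `dmi_svm`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_svm <- function(model, path) {
  dput(unclass(model), file = path)
  invisible(path)
}

#' @rdname save_svm
#' @export
load_svm <- function(path) {
  structure(dget(path), class = "dmi_svm")
}

#' Remove completely covered peptides
#'
#' Drops every peptide whose span is a subset of another (longer or
#' identical) peptide's span on the same chain; partially overlapping
#' peptides are retained. Idempotent and order-independent.
#'
#' @param peptides data.frame with `chain`, `start`, `end` (one chain or
#'   several; coverage is evaluated within each chain).
#' @return the reduced data.frame.
#' @export
remove_covered_peptides <- function(peptides) {
  if (nrow(peptides) == 0) return(peptides)
  keep <- logical(nrow(peptides))
  for (ch in unique(peptides$chain)) {
    idx <- which(peptides$chain == ch)
    s <- peptides$start[idx]; e <- peptides$end[idx]
    # drop duplicates of identical spans (keep first by span order)
    ord <- order(s, e)
    dup <- duplicated(paste(s, e))
    covered <- vapply(seq_along(idx), function(k) {
      any(s <= s[k] & e >= e[k] & (s < s[k] | e > e[k]))
    }, logical(1))
    keep[idx] <- !covered & !dup
  }
  peptides[keep, , drop = FALSE]
}

#' Build peptide-containing regions
#'
#' Connected components of the union of accepted peptide spans per
#' chain: spans sharing at least one residue are merged; mere adjacency
#' (no shared residue) does not merge. Regions partition exactly the
#' residues covered by one or more peptides.
#'
#' @param peptides data.frame with `structure`, `chain`, `start`, `end`.
#' @return data.frame of regions: `structure`, `chain`, `start`, `end`,
#'   `n_peptides`, `members` (semicolon-joined `start-end` spans).
#' @export
build_peptide_regions <- function(peptides) {
  if (nrow(peptides) == 0)
    return(data.frame(structure = character(), chain = character(),
                      start = integer(), end = integer(),
                      n_peptides = integer(), members = character(),
                      stringsAsFactors = FALSE))
  out <- list()
  for (key in unique(paste(peptides$structure, peptides$chain, sep = "\r"))) {
    p <- peptides[paste(peptides$structure, peptides$chain, sep = "\r") == key, ,
                  drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    cur_s <- p$start[1]; cur_e <- p$end[1]; mem <- 1L
    for (k in seq_len(nrow(p))[-1]) {
      if (p$start[k] <= cur_e) {  # shared residue => same region
        cur_e <- max(cur_e, p$end[k]); mem <- c(mem, k)
      } else {
        out[[length(out) + 1]] <- data.frame(
          structure = p$structure[1], chain = p$chain[1],
          start = cur_s, end = cur_e, n_peptides = length(mem),
          members = paste(paste0(p$start[mem], "-", p$end[mem]), collapse = ";"),
          stringsAsFactors = FALSE)
        cur_s <- p$start[k]; cur_e <- p$end[k]; mem <- k
      }
    }
    out[[length(out) + 1]] <- data.frame(
      structure = p$structure[1], chain = p$chain[1],
      start = cur_s, end = cur_e, n_peptides = length(mem),
      members = paste(paste0(p$start[mem], "-", p$end[mem]), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
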