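# Peptide-level structural descriptors: the quantities that make a bound
# linear motif recognisable in 3D (stretched, flat, exposed).

# Max distance of interior points from the line through first and last.
max_line_deviation <- function(ca) {
  n <- nrow(ca)
  if (n < 3) return(NA_real_)
  a <- ca[1, ]; b <- ca[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) return(NA_real_)
  u <- ab / len
  rel <- sweep(ca[2:(n - 1), , drop = FALSE], 2, a)
  proj <- as.vector(rel %*% u)
  perp <- rel - outer(proj, u)
  max(sqrt(rowSums(perp^2)))
}

#' Elongation of a peptide
#'
#' Euclidean distance (Angstrom) between the first and last C-alpha.
#' High values indicate a stretched peptide.
#'
#' @param ca n x 3 matrix of ordered C-alpha coordinates, n >= 2.
#' @return distance in Angstrom.
#' @export
elongation <- function(ca) {
  ca <- as.matrix(ca)
  if (nrow(ca) < 2) stop("elongation requires at least 2 points")
  sqrt(sum((ca[nrow(ca), ] - ca[1, ])^2))
}

#' Linearity of a peptide
#'
#' Maximum deviation (Angstrom) of any interior C-alpha from the line
#' through the first and last C-alpha. A low value indicates a very flat
#' or linear peptide; zero iff all points are collinear. If the terminal
#' C-alphas coincide the axis is undefined and an error is raised (a
#' closed hairpin is not "linear").
#'
#' @param ca n x 3 matrix of ordered C-alpha coordinates, n >= 3.
#' @return maximum point-to-line distance in Angstrom.
#' @export
linearity <- function(ca) {
  ca <- as.matrix(ca)
  if (nrow(ca) < 3) stop("linearity requires at least 3 points")
  if (sqrt(sum((ca[nrow(ca), ] - ca[1, ])^2)) == 0)
    stop("linearity undefined: first and last C-alpha coincide")
  max_line_deviation(ca)
}

#' Modal DSSP class of a peptide
#'
#' The secondary-structure class most frequent among the peptide's
#' residues. Ties are broken by the fixed priority H > E > G > I > B >
#' T > S > -, preferring the strong regular classes.
#'
#' @param classes character vector over the 8-letter DSSP alphabet.
#' @return single DSSP letter.
#' @export
peptide_ss_class <- function(classes) {
  if (length(classes) == 0) stop("empty secondary-structure vector")
  if (!all(classes %in% DSSP_CLASSES))
    stop("unknown DSSP class: ",
         paste(setdiff(unique(classes), DSSP_CLASSES), collapse = ", "))
  priority <- c("H", "E", "G", "I", "B", "T", "S", "-")
  counts <- table(factor(classes, levels = priority))
  names(counts)[which.max(counts)]  # which.max keeps first = highest priority
}

#' Mean residue accessibility of a peptide
#'
#' @param acc non-empty vector of per-residue accessible areas (Angstrom^2).
#' @return arithmetic mean.
#' @export
peptide_accessibility <- function(acc) {
  if (length(acc) == 0) stop("empty accessibility vector")
  if (anyNA(acc))
    stop("undefined accessibility at residue(s): ",
         paste(which(is.na(acc)), collapse = ", "))
  mean(acc)
}

#' Encode peptide features as a numeric vector
#'
#' 12 dimensions: length, elongation, linearity, accessibility, and a
#' one-hot encoding of the modal DSSP class over the 8-letter alphabet.
#' Optionally standardized (z-score) with training-set statistics stored
#' alongside the SVM model; dimensions with zero training variance (the
#' one-hot block, typically) are left unscaled.
#'
#' @param features data.frame with columns `length`, `elongation`,
#'   `linearity`, `acc`, `ss` (one row per peptide).
#' @param stats optional list with `center` and `scale` vectors.
#' @return numeric matrix, one row per peptide, 12 named columns.
#' @export
encode_features <- function(features, stats = NULL) {
  onehot <- matrix(0, nrow(features), length(DSSP_CLASSES),
                   dimnames = list(NULL, paste0("ss_", DSSP_CLASSES)))
  idx <- match(features$ss, DSSP_CLASSES)
  if (anyNA(idx)) stop("unknown DSSP class in features")
  onehot[cbind(seq_len(nrow(features)), idx)] <- 1
  m <- cbind(length = features$length, elongation = features$elongation,
             linearity = features$linearity, acc = features$acc, onehot)
  if (!is.null(stats)) m <- standardize_features(m, stats)
  m
}

feature_stats <- function(m) {
  center <- colMeans(m)
  scale <- apply(m, 2, sd)
  scale[scale == 0 | is.na(scale)] <- 1
  # one-hot block stays raw
  oh <- grepl("^ss_", colnames(m))
  center[oh] <- 0; scale[oh] <- 1
  list(center = center, scale = scale)
}

standardize_features <- function(m, stats) {
  sweep(sweep(m, 2, stats$center), 2, stats$scale, "/")
}

destandardize_features <- function(m, stats) {
  sweep(sweep(m, 2, stats$scale, "*"), 2, stats$center, "+")
}

# Feature row for one residue window of a chain (residue table subset).
window_features <- function(res) {
  ca <- as.matrix(res[, c("ca_x", "ca_y", "ca_z")])
  data.frame(length = nrow(res),
             elongation = elongation(ca),
             linearity = linearity(ca),
             ss = peptide_ss_class(res$ss),
             acc = peptide_accessibility(res$acc),
             stringsAsFactors = FALSE)
}
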