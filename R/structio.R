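# Structure input/output and per-residue annotation.
#
# A `dmi_structure` is a light container over two data frames:
#   $atoms    : chain, seq_index, resno, resid, elety, element, x, y, z, o
#   $residues : chain, seq_index, resno, aa, ss, acc, modified, incomplete,
#               ca_x, ca_y, ca_z
# seq_index is a 1-based, strictly increasing internal numbering per chain
# (author numbering and insertion codes are collapsed; resno keeps the
# author number as metadata).

AA321 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
           GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
           MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
           SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y",
           MSE = "M", SEC = "U", PYL = "O")

# van der Waals radii (Angstrom) by element; unknown heavy atoms get carbon.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, SE = 1.90)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

new_dmi_structure <- function(id, atoms, residues, is_biological_unit = TRUE) {
  if (anyDuplicated(unique(residues$chain)))
    stop("chain identifiers must be unique within a structure")
  structure(list(id = id, atoms = atoms, residues = residues,
                 is_biological_unit = is_biological_unit),
            class = "dmi_structure")
}

#' @export
print.dmi_structure <- function(x, ...) {
  cat(sprintf("dmi_structure '%s': %d chain(s), %d residues, %d atoms%s\n",
              x$id, length(unique(x$residues$chain)), nrow(x$residues),
              nrow(x$atoms),
              if (isTRUE(x$is_biological_unit)) "" else " [not biological unit]"))
  invisible(x)
}

#' Read a protein structure from PDB or mmCIF
#'
#' Parses coordinates into a `dmi_structure`. Only polymer (ATOM) records
#' are kept; waters and hetero ligands are dropped. Alternate locations
#' are resolved by keeping the highest-occupancy conformer. Insertion
#' codes are collapsed into a strictly increasing 1-based `seq_index`
#' per chain; the author residue number is retained as `resno`.
#' Residues lacking a C-alpha atom are flagged `incomplete`.
#'
#' @param path file path.
#' @param format `"pdb"` or `"mmcif"`; default guessed from the extension.
#' @param id structure identifier; default the file base name.
#' @param is_biological_unit logical flag recording whether the model is a
#'   presumed biological assembly (candidates from non-biological-unit
#'   structures are excluded before any interface geometry is computed).
#' @return a `dmi_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           id = NULL, is_biological_unit = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE, multi = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE,
                                       multi = FALSE))
    },
    error = function(e) stop("cannot parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in '", path, "'")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc: keep highest-occupancy conformer per (chain, resno, insert, elety)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  at <- at[order(key, -at$o), , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]

  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  ord <- order(at$chain, at$resno, at$insert)
  at <- at[ord, , drop = FALSE]
  rkey <- rkey[ord]
  # strictly increasing seq_index per chain, insertion codes collapsed
  seq_index <- integer(nrow(at))
  for (ch in unique(at$chain)) {
    sel <- at$chain == ch
    seq_index[sel] <- match(rkey[sel], unique(rkey[sel]))
  }
  element <- if ("elesy" %in% names(at)) at$elesy else
    substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1)
  element[is.na(element) | element == ""] <-
    substr(at$elety[is.na(element) | element == ""], 1, 1)

  atoms <- data.frame(chain = at$chain, seq_index = seq_index,
                      resno = at$resno, resid = at$resid,
                      elety = at$elety, element = toupper(element),
                      x = at$x, y = at$y, z = at$z, o = at$o,
                      stringsAsFactors = FALSE)
  atoms <- atoms[atoms$element != "H", , drop = FALSE]

  rid <- !duplicated(paste(atoms$chain, atoms$seq_index, sep = "\r"))
  res <- atoms[rid, c("chain", "seq_index", "resno", "resid")]
  res$aa <- unname(AA321[res$resid])
  res$aa[is.na(res$aa)] <- "X"
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ckey <- paste(ca$chain, ca$seq_index, sep = "\r")
  idx <- match(paste(res$chain, res$seq_index, sep = "\r"), ckey)
  res$ca_x <- ca$x[idx]; res$ca_y <- ca$y[idx]; res$ca_z <- ca$z[idx]
  res$incomplete <- is.na(idx)
  res$ss <- NA_character_
  res$acc <- NA_real_
  res$modified <- NA_character_
  res$resid <- NULL
  rownames(res) <- NULL
  rownames(atoms) <- NULL
  new_dmi_structure(id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
                    atoms = atoms, residues = res,
                    is_biological_unit = is_biological_unit)
}

#' Write a structure to a PDB file
#'
#' Round-trip companion of [read_structure()] for the supported record
#' subset (polymer heavy atoms).
#'
#' @param struct a `dmi_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(struct, path) {
  a <- struct$atoms
  aa3 <- names(AA321)[match(struct$residues$aa[
    match(paste(a$chain, a$seq_index), paste(struct$residues$chain,
                                             struct$residues$seq_index))],
    AA321)]
  aa3[is.na(aa3)] <- "UNK"
  bio3d::write.pdb(file = path, xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)), resno = a$resno,
                   resid = aa3, eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, o = a$o, b = rep(0, nrow(a)))
  invisible(path)
}

chain_sequence <- function(struct, chain) {
  r <- struct$residues
  paste(r$aa[r$chain == chain], collapse = "")
}

#' Parse a classic DSSP output file
#'
#' Reads the fixed-column residue block of a DSSP (`mkdssp`) output file:
#' author residue number, chain, amino acid, 8-class secondary structure
#' and accessible surface area.
#'
#' @param path DSSP output file.
#' @return data.frame with `resno`, `chain`, `aa`, `ss`, `acc`.
#' @export
parse_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a DSSP file (no residue header): ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 38 & substr(body, 14, 14) != "!"]
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "-"
  data.frame(resno = as.integer(substr(body, 6, 10)),
             chain = trimws(substr(body, 12, 12)),
             aa = substr(body, 14, 14),
             ss = ss,
             acc = as.numeric(substr(body, 35, 38)),
             stringsAsFactors = FALSE)
}

# CA-geometry secondary-structure assignment for one chain.
# H: residue covered by an i..i+3 window with d(CA_i, CA_i+3) in the
#    helical range (4.2-6.0 A; ideal alpha-helix ~5.1 A).
# E: otherwise, residue covered by a 5-residue window whose CA trace is
#    nearly straight (max deviation from the end-to-end line < 1.0 A).
# -: everything else. A documented simplification of DSSP, used only
#    when no DSSP file is supplied.
ss_assign_ca <- function(ca) {
  n <- nrow(ca)
  ss <- rep("-", n)
  if (n >= 4) {
    d3 <- sqrt(rowSums((ca[1:(n - 3), , drop = FALSE] -
                        ca[4:n, , drop = FALSE])^2))
    helical_win <- which(d3 >= 4.2 & d3 <= 6.0)
    for (j in helical_win) ss[j:(j + 3)] <- "H"
  }
  if (n >= 5) {
    for (j in 1:(n - 4)) {
      idx <- j:(j + 4)
      if (any(ss[idx] == "H")) next
      dev <- max_line_deviation(ca[idx, , drop = FALSE])
      if (!is.na(dev) && dev < 1.0) ss[idx][ss[idx] == "-"] <- "E"
    }
  }
  ss
}

#' Assign per-residue secondary structure
#'
#' Fills the `ss` column of a structure's residue table. When a DSSP
#' output file is supplied it is column-parsed and matched to the
#' structure by chain and author residue number. Otherwise an internal
#' C-alpha-geometry assigner fills H/E/- per chain; each chain is
#' assigned with all other chains removed, mirroring per-protein DSSP
#' practice. The operation is idempotent.
#'
#' @param struct a `dmi_structure`.
#' @param dssp_path optional DSSP classic output file.
#' @return the structure with `ss` filled.
#' @export
assign_secondary_structure <- function(struct, dssp_path = NULL) {
  r <- struct$residues
  if (!is.null(dssp_path)) {
    d <- parse_dssp(dssp_path)
    idx <- match(paste(r$chain, r$resno), paste(d$chain, d$resno))
    if (anyNA(idx)) {
      miss <- r[is.na(idx), c("chain", "resno")]
      stop("DSSP/structure mismatch; unmatched residues: ",
           paste(paste0(miss$chain, ":", miss$resno), collapse = ", "))
    }
    r$ss <- d$ss[idx]
  } else {
    for (ch in unique(r$chain)) {
      sel <- which(r$chain == ch & !r$incomplete)
      ca <- as.matrix(r[sel, c("ca_x", "ca_y", "ca_z")])
      r$ss[sel] <- ss_assign_ca(ca)
    }
    r$ss[r$incomplete] <- "-"
  }
  stopifnot(all(r$ss %in% DSSP_CLASSES))
  struct$residues <- r
  struct
}

#' Compute per-residue solvent accessibility
#'
#' Shrake-Rupley accessible surface area with a deterministic Fibonacci
#' sphere point set. By default each chain is computed in isolation
#' (other chains removed), matching per-protein accessibility practice;
#' set `per_chain = FALSE` to use the full assembly context.
#'
#' @param struct a `dmi_structure`.
#' @param probe_radius probe sphere radius in Angstrom.
#' @param n_points sphere sample points per atom.
#' @param per_chain compute each chain in isolation (default TRUE).
#' @return the structure with the residue `acc` column filled (Angstrom^2).
#'   Residues without atoms keep `NA` accessibility.
#' @export
compute_accessibility <- function(struct, probe_radius = 1.4,
                                  n_points = 960, per_chain = TRUE) {
  a <- struct$atoms
  r <- struct$residues
  groups <- if (per_chain) unique(a$chain) else list(unique(a$chain))
  for (g in groups) {
    sel <- a$chain %in% g
    xyz <- as.matrix(a[sel, c("x", "y", "z")])
    area <- sasa_atoms(xyz, vdw_radius(a$element[sel]),
                       probe_radius = probe_radius, n_points = n_points)
    byres <- tapply(area, paste(a$chain[sel], a$seq_index[sel], sep = "\r"), sum)
    key <- paste(r$chain, r$seq_index, sep = "\r")
    hit <- key %in% names(byres)
    r$acc[hit] <- as.numeric(byres[key[hit]])
  }
  struct$residues <- r
  struct
}

#' Load domain annotations
#'
#' Tab-separated table with header columns `structure`, `chain`,
#' `family`, `start`, `end`, `kind`. `kind` is `"sequence"` (Pfam-like,
#' sequence-defined; these spans are the peptide-exclusion mask and the
#' candidate binding domains) or `"structure"` (CATH-like,
#' structure-defined; used by the intrachain coverage filter).
#'
#' @param path TSV file.
#' @return data.frame of validated annotations.
#' @export
load_annotations <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("structure", "chain", "family", "start", "end", "kind")
  if (!all(need %in% names(d)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  bad <- which(d$start > d$end)
  if (length(bad))
    stop("start > end in annotation row(s): ", paste(bad, collapse = ", "))
  if (!all(d$kind %in% c("sequence", "structure")))
    stop("unknown annotation kind: ",
         paste(setdiff(unique(d$kind), c("sequence", "structure")), collapse = ", "))
  d
}

#' Load modified-residue annotations
#'
#' TSV with header `structure`, `chain`, `seq_index`, `modification`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
load_modified_residues <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("structure", "chain", "seq_index", "modification")
  if (!all(need %in% names(d)))
    stop("modified-residue table must have columns: ",
         paste(need, collapse = ", "))
  d
}

#' Load a per-family profile map
#'
#' TSV with header `family`, `structure`, `chain`, `seq_index`, `column`
#' mapping domain residues to normalized profile (HMM match-state)
#' columns. The mapping must be injective per (family, structure, chain).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
load_profile_map <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "structure", "chain", "seq_index", "column")
  if (!all(need %in% names(d)))
    stop("profile map must have columns: ", paste(need, collapse = ", "))
  key <- paste(d$family, d$structure, d$chain, sep = "\r")
  for (k in unique(key)) {
    cols <- d$column[key == k]
    if (anyDuplicated(cols))
      stop("profile map not injective for ", gsub("\r", "/", k))
  }
  d
}
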