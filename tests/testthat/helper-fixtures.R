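# Fixtures built in code: straight-chain structures, minimal mmCIF/DSSP
# writers, random rigid motions, synthetic feature clouds.

# Straight CA trace chain (3.8 A spacing) as a dmi_structure, with ss
# and accessibility pre-filled so window features are cheap.
make_line_chain <- function(n, chain = "A", id = "line", ss = "E",
                            acc = 100, seq = NULL) {
  ca <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
  atoms <- dmiminer:::backbone_atoms(ca, chain)
  if (is.null(seq)) seq <- rep("A", n)
  st <- dmiminer:::build_structure_from_atoms(
    id, list(list(chain = chain, atoms = atoms, sequence = seq)))
  st$residues$ss <- ss
  st$residues$acc <- acc
  st
}

# Random proper rotation matrix.
random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_out)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_motion <- function(xyz, rot, shift) {
  sweep(as.matrix(xyz) %*% rot, 2, shift, "+")
}

# Minimal mmCIF atom_site writer for cross-format tests.
write_mmcif_fixture <- function(struct, path) {
  a <- struct$atoms
  aa3 <- names(dmiminer:::AA321)[match(
    struct$residues$aa[match(paste(a$chain, a$seq_index),
                             paste(struct$residues$chain,
                                   struct$residues$seq_index))],
    dmiminer:::AA321)]
  lines <- c(
    "data_fixture", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    sprintf("ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
            seq_len(nrow(a)), a$element, a$elety, aa3, a$chain,
            a$seq_index, a$x, a$y, a$z, a$resno, aa3, a$chain, a$elety),
    "#")
  writeLines(lines, path)
  invisible(path)
}

# Minimal classic-DSSP-format writer (header + fixed-column residue
# block) for parser-identity tests.
write_dssp_fixture <- function(df, path) {
  lines <- c(
    "==== Secondary Structure Definition, fixture ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    vapply(seq_len(nrow(df)), function(k) {
      sprintf("%5d%5d %s %s  %s%17s%4.0f",
              k, df$resno[k], df$chain[k], df$aa[k], df$ss[k], "",
              df$acc[k])
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

# Gaussian feature clouds for SVM tests: strand-like positives,
# helix-like negatives.
feature_cloud <- function(n, elong, lin, ss, acc = 100, len = 7) {
  data.frame(length = len,
             elongation = rnorm(n, elong, 1),
             linearity = abs(rnorm(n, lin, 0.2)),
             ss = ss, acc = rnorm(n, acc, 10),
             stringsAsFactors = FALSE)
}

# Brute-force hypergeometric upper tail from log-binomial coefficients
# (independent of stats::phyper).
fisher_tail_bruteforce <- function(i_m, i, m, p) {
  ks <- max(0, i + m - p):min(i, m)
  logterm <- lchoose(m, ks) + lchoose(p - m, i - ks) - lchoose(p, i)
  sel <- ks >= i_m
  if (!any(sel)) return(0)
  mx <- max(logterm[sel])
  exp(mx) * sum(exp(logterm[sel] - mx))
}
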