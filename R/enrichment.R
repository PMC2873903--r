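# Cross-validation of derived motifs on interactome networks:
# contingency tables, enrichment factors, one-sided Fisher tests.

#' Load an interactome network
#'
#' Edge list TSV (columns `protA`, `protB`) plus a protein table TSV
#' (columns `id`, `species`, `sequence`, `domains`; `domains` is a
#' semicolon-joined list of `family:start-end` spans, empty allowed).
#' Edges are undirected and deduplicated; edges between proteins of
#' different species are dropped (hybrid interactions); edges naming
#' unknown proteins are an error.
#'
#' @param edges_path,proteins_path TSV files.
#' @return object of class `dmi_interactome`: `proteins` data.frame,
#'   `edges` data.frame, `domains` data.frame (`id`, `family`, `start`,
#'   `end`).
#' @export
load_interactome <- function(edges_path, proteins_path) {
  prot <- read.delim(proteins_path, stringsAsFactors = FALSE)
  need <- c("id", "species", "sequence", "domains")
  if (!all(need %in% names(prot)))
    stop("protein table must have columns: ", paste(need, collapse = ", "))
  ed <- read.delim(edges_path, stringsAsFactors = FALSE)
  if (!all(c("protA", "protB") %in% names(ed)))
    stop("edge table must have columns protA, protB")
  unknown <- setdiff(unique(c(ed$protA, ed$protB)), prot$id)
  if (length(unknown))
    stop("edges reference unknown protein(s): ",
         paste(unknown, collapse = ", "))
  doms <- parse_domain_strings(prot$id, prot$domains)
  new_interactome(prot, ed, doms)
}

parse_domain_strings <- function(ids, strings) {
  out <- list()
  for (k in seq_along(ids)) {
    s <- strings[k]
    if (is.na(s) || s == "") next
    for (tok in strsplit(s, ";", fixed = TRUE)[[1]]) {
      m <- regmatches(tok, regexec("^([^:]+):(\\d+)-(\\d+)$", tok))[[1]]
      if (length(m) != 4) stop("bad domain span '", tok, "' for ", ids[k])
      out[[length(out) + 1]] <- data.frame(
        id = ids[k], family = m[2], start = as.integer(m[3]),
        end = as.integer(m[4]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(id = character(), family = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

new_interactome <- function(proteins, edges, domains) {
  sp <- setNames(proteins$species, proteins$id)
  same <- sp[edges$protA] == sp[edges$protB]
  if (any(!same))
    message("dropping ", sum(!same), " cross-species edge(s)")
  edges <- edges[same, , drop = FALSE]
  a <- pmin(edges$protA, edges$protB)
  b <- pmax(edges$protA, edges$protB)
  keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
  edges <- data.frame(protA = a[keep], protB = b[keep],
                      stringsAsFactors = FALSE)
  structure(list(proteins = proteins, edges = edges, domains = domains),
            class = "dmi_interactome")
}

#' @export
print.dmi_interactome <- function(x, ...) {
  cat(sprintf("dmi_interactome: %d proteins, %d edges, %d domain assignments\n",
              nrow(x$proteins), nrow(x$edges), nrow(x$domains)))
  invisible(x)
}

#' Remove edges explainable by known domain-domain interactions
#'
#' Drops every edge whose two proteins carry a family pair listed in the
#' DDI table (either orientation); the remaining edges are those whose
#' interaction cannot be explained by a domain-domain interface, so a
#' motif can take the credit.
#'
#' @param net a `dmi_interactome`.
#' @param ddi_pairs data.frame with columns `familyA`, `familyB`.
#' @return the reduced network.
#' @export
filter_ddi_edges <- function(net, ddi_pairs) {
  if (is.null(ddi_pairs) || nrow(ddi_pairs) == 0) return(net)
  fams <- split(net$domains$family, net$domains$id)
  ddik <- unique(c(paste(ddi_pairs$familyA, ddi_pairs$familyB, sep = "\r"),
                   paste(ddi_pairs$familyB, ddi_pairs$familyA, sep = "\r")))
  explained <- vapply(seq_len(nrow(net$edges)), function(k) {
    fa <- fams[[net$edges$protA[k]]]
    fb <- fams[[net$edges$protB[k]]]
    if (is.null(fa) || is.null(fb)) return(FALSE)
    any(outer(fa, fb, function(x, y) paste(x, y, sep = "\r")) %in% ddik)
  }, logical(1))
  net$edges <- net$edges[!explained, , drop = FALSE]
  net
}

#' Does a pattern match outside all domain spans?
#'
#' TRUE iff the sequence has at least one pattern match every position
#' of which lies outside all domain spans. A match straddling a domain
#' boundary counts as inside.
#'
#' @param protein_seq one-letter sequence.
#' @param domain_spans data.frame with `start`, `end` (zero rows allowed).
#' @param pattern regular-expression-like motif pattern.
#' @return logical.
#' @export
match_outside_domains <- function(protein_seq, domain_spans, pattern) {
  m <- gregexpr(pattern, protein_seq)[[1]]
  if (m[1] == -1) return(FALSE)
  if (is.null(domain_spans) || nrow(domain_spans) == 0) return(TRUE)
  lens <- attr(m, "match.length")
  for (k in seq_along(m)) {
    s <- m[k]; e <- m[k] + lens[k] - 1
    inside <- any(domain_spans$start <= e & domain_spans$end >= s)
    if (!inside) return(TRUE)
  }
  FALSE
}

# Vectorized match-outside-domains over a network's proteins.
network_matches <- function(net, pattern) {
  doms <- split(net$domains, net$domains$id)
  vapply(seq_len(nrow(net$proteins)), function(k) {
    id <- net$proteins$id[k]
    match_outside_domains(net$proteins$sequence[k], doms[[id]], pattern)
  }, logical(1))
}

#' Build the enrichment contingency counts
#'
#' Counts `(i_m, i, m, p)`: `i` proteins with at least one (retained)
#' neighbour carrying the family, `m` proteins with a pattern match
#' outside domains, `i_m` their intersection, `p` all proteins.
#'
#' @param net a `dmi_interactome` (already DDI-filtered if desired).
#' @param family binding-domain family name.
#' @param pattern motif pattern.
#' @return named integer vector `c(i_m, i, m, p)`.
#' @export
build_contingency <- function(net, family, pattern) {
  carriers <- unique(net$domains$id[net$domains$family == family])
  if (length(carriers) == 0)
    stop("family not present in network: ", family)
  nb_a <- net$edges$protA[net$edges$protB %in% carriers]
  nb_b <- net$edges$protB[net$edges$protA %in% carriers]
  interactors <- unique(c(nb_a, nb_b))
  matched <- net$proteins$id[network_matches(net, pattern)]
  c(i_m = length(intersect(interactors, matched)),
    i = length(interactors),
    m = length(matched),
    p = nrow(net$proteins))
}

#' Enrichment factor of a contingency table
#'
#' `(i_m / i) / (m / p)`: the match rate among interactors of
#' family-carrying proteins relative to the overall match rate.
#'
#' @param table named vector `c(i_m, i, m, p)`.
#' @return enrichment ratio.
#' @export
enrichment_factor <- function(table) {
  t <- as.numeric(table)
  if (t[2] <= 0 || t[3] <= 0)
    stop("enrichment_factor undefined for i = 0 or m = 0")
  (t[1] / t[2]) / (t[3] / t[4])
}

#' One-sided Fisher's exact test (upper tail)
#'
#' Hypergeometric upper-tail probability `P(X >= i_m)` given the margins
#' `(i, m, p)`: the probability of seeing at least the observed number
#' of matching interactors by chance.
#'
#' @param table either a named vector `c(i_m, i, m, p)` or a 2x2 matrix
#'   `rbind(c(i_m, i - i_m), c(m - i_m, p - i - m + i_m))`.
#' @return p-value.
#' @export
fisher_one_sided <- function(table) {
  if (is.matrix(table)) {
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
    t <- c(a, a + b, a + c, a + b + c + d)
  } else {
    t <- as.numeric(table)
  }
  i_m <- t[1]; i <- t[2]; m <- t[3]; p <- t[4]
  if (any(t < 0) || i_m > min(i, m) || i > p || m > p ||
      i_m < i + m - p)
    stop("fisher_one_sided: inconsistent margins")
  phyper(i_m - 1, m, p - m, i, lower.tail = FALSE)
}

#' Test a motif's enrichment in a network
#'
#' Convenience wrapper: DDI-filter, contingency, enrichment factor and
#' one-sided Fisher p-value for one (family, pattern) pair.
#'
#' @param net a `dmi_interactome`.
#' @param family binding-domain family.
#' @param pattern motif pattern.
#' @param ddi_pairs optional DDI family-pair table (see
#'   [filter_ddi_edges()]).
#' @param p_threshold significance threshold, default 0.025.
#' @return data.frame with counts, `enrichment`, `p_value`, `significant`.
#' @export
test_enrichment <- function(net, family, pattern, ddi_pairs = NULL,
                            p_threshold = 0.025) {
  net <- filter_ddi_edges(net, ddi_pairs)
  tab <- build_contingency(net, family, pattern)
  enr <- if (tab["i"] > 0 && tab["m"] > 0) enrichment_factor(tab) else NA_real_
  pv <- fisher_one_sided(tab)
  data.frame(family = family, pattern = pattern,
             i_m = tab["i_m"], i = tab["i"], m = tab["m"], p = tab["p"],
             enrichment = enr, p_value = pv,
             significant = pv <= p_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
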