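# Interactome loading, DDI filtering, pattern matching, contingency
# tables, enrichment factors and Fisher tests.

write_net_fixture <- function(dir = tempfile()) {
  dir.create(dir)
  prot <- file.path(dir, "proteins.tsv")
  edges <- file.path(dir, "edges.tsv")
  writeLines(c("id\tspecies\tsequence\tdomains",
               "P1\thuman\tMMMDEAFMMM\t",
               "P2\thuman\tMMMMMMMMMM\tSH3:1-5",
               "P3\thuman\tDEAFMMMMMM\tkinase:2-8",
               "P4\tyeast\tMMMMMMMMMM\t"), prot)
  writeLines(c("protA\tprotB", "P1\tP2", "P2\tP1", "P2\tP3", "P2\tP3",
               "P1\tP4"), edges)
  list(edges = edges, proteins = prot)
}

test_that("interactome loading deduplicates and drops cross-species edges", {
  fx <- write_net_fixture()
  expect_message(net <- load_interactome(fx$edges, fx$proteins),
                 "cross-species")
  # (P1,P2) duplicated in both orders, (P2,P3) duplicated, (P1,P4) hybrid
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$protA, net$edges$protB),
                  c("P1 P2", "P2 P3"))

  bad <- tempfile(); writeLines(c("protA\tprotB", "P1\tP9"), bad)
  expect_error(load_interactome(bad, fx$proteins), "P9")
})

test_that("DDI-explained edges are removed, matching a brute-force scan", {
  fx <- write_net_fixture()
  net <- suppressMessages(load_interactome(fx$edges, fx$proteins))
  ddi <- data.frame(familyA = "SH3", familyB = "kinase")
  red <- filter_ddi_edges(net, ddi)
  expect_equal(nrow(red$edges), 1)  # P2(SH3)-P3(kinase) removed
  expect_equal(paste(red$edges$protA, red$edges$protB), "P1 P2")
  # empty DDI table leaves the network unchanged
  expect_equal(nrow(filter_ddi_edges(net, ddi[0, ])$edges), nrow(net$edges))

  # brute-force recount on a random synthetic network
  net2 <- synth_interactome(p = 60, seed = 5)
  fams <- c("FAM1", "FAM2")
  net2$domains$family <- sample(fams, nrow(net2$domains), TRUE)
  ddi2 <- data.frame(familyA = "FAM1", familyB = "FAM2")
  red2 <- filter_ddi_edges(net2, ddi2)
  fam_of <- split(net2$domains$family, net2$domains$id)
  brute <- sum(vapply(seq_len(nrow(net2$edges)), function(k) {
    fa <- fam_of[[net2$edges$protA[k]]]; fb <- fam_of[[net2$edges$protB[k]]]
    !is.null(fa) && !is.null(fb) &&
      (("FAM1" %in% fa && "FAM2" %in% fb) || ("FAM2" %in% fa && "FAM1" %in% fb))
  }, logical(1)))
  expect_equal(nrow(net2$edges) - nrow(red2$edges), brute)
})

test_that("pattern matches must lie wholly outside domains", {
  spans <- data.frame(start = 3, end = 8)
  expect_false(match_outside_domains("MMDEAFMMMM", spans, "DE.F"))  # inside
  expect_true(match_outside_domains("MMMMMMMMMDEAF", spans, "DE.F"))  # linker
  expect_false(match_outside_domains("MMMMMMDEAF", spans, "DE.F"))  # straddle
  expect_true(match_outside_domains("DEAFMMMMMM", NULL, "DE.F"))
  expect_false(match_outside_domains("MMMMMMMMMM", NULL, "DE.F"))
  # one inside and one outside match: outside wins
  expect_true(match_outside_domains("MMDEAFMMMDEAF", spans, "DE.F"))
})

test_that("contingency counts match an exhaustive recount", {
  net <- synth_interactome(p = 20, domain_frac = 0.3,
                           match_prob_interactor = 0.5,
                           match_prob_other = 0.2, seed = 9)
  tab <- build_contingency(net, "FAM1", "DE.F")
  # brute force
  doms <- split(net$domains, net$domains$id)
  carriers <- unique(net$domains$id[net$domains$family == "FAM1"])
  inter <- unique(c(net$edges$protA[net$edges$protB %in% carriers],
                    net$edges$protB[net$edges$protA %in% carriers]))
  match_flag <- vapply(seq_len(20), function(k)
    match_outside_domains(net$proteins$sequence[k],
                          doms[[net$proteins$id[k]]], "DE.F"), logical(1))
  matched <- net$proteins$id[match_flag]
  expect_equal(unname(tab),
               c(length(intersect(inter, matched)), length(inter),
                 length(matched), 20))
  expect_error(build_contingency(net, "NOFAM", "DE.F"), "family")
})

test_that("enrichment factor formula and edge cases", {
  expect_equal(enrichment_factor(c(50, 593, 256, 7808)), 2.57,
               tolerance = 0.005 / 2.57)
  expect_equal(enrichment_factor(c(10, 100, 50, 500)), 1.0)
  expect_equal(enrichment_factor(c(0, 100, 50, 500)), 0.0)
  expect_error(enrichment_factor(c(0, 0, 50, 500)), "undefined")
  # sign consistency with the two rates
  set.seed(8)
  for (k in 1:50) {
    p <- sample(50:500, 1); m <- sample(1:p, 1); i <- sample(1:p, 1)
    i_m <- sample(max(0, i + m - p):min(i, m), 1)
    ef <- enrichment_factor(c(i_m, i, m, p))
    expect_equal(ef > 1, (i_m / i) > (m / p))
  }
})

test_that("one-sided Fisher matches known values and brute force", {
  expect_equal(fisher_one_sided(rbind(c(50, 543), c(206, 7009))),
               2.827e-10, tolerance = 1e-3)
  expect_equal(fisher_one_sided(rbind(c(0, 10), c(0, 100))), 1.0)
  expect_equal(fisher_one_sided(rbind(c(3, 7), c(1, 9))), 53768 / 184756)
  expect_error(fisher_one_sided(c(10, 5, 3, 20)), "margins")
  # agreement with stats::fisher.test one-sided
  ft <- fisher.test(rbind(c(50, 543), c(206, 7009)), alternative = "greater")
  expect_equal(fisher_one_sided(rbind(c(50, 543), c(206, 7009))),
               ft$p.value, tolerance = 1e-9)
})

test_that("test_enrichment wires filters, factor and test together", {
  net <- synth_interactome(p = 300, match_prob_interactor = 0.4,
                           match_prob_other = 0.05, seed = 4)
  res <- test_enrichment(net, "FAM1", "DE.F")
  expect_true(res$significant)
  expect_gt(res$enrichment, 2)
  expect_lte(res$i_m, min(res$i, res$m))
})
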