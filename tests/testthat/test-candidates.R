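# Peptide enumeration, SVM classification, overlap reduction, regions.

window_count <- function(free_lengths, lmin = 4, lmax = 20) {
  sum(vapply(free_lengths, function(n)
    sum(pmax(0, n - (lmin:lmax) + 1)), numeric(1)))
}

test_that("enumeration count equals the closed-form window count", {
  st <- make_line_chain(30)
  masks <- data.frame(start = 1, end = 20)
  pep <- enumerate_peptides(st, "A", masks, lmax = 10)
  expect_equal(nrow(pep), 28)                       # free region of 10, L 4..10
  expect_equal(nrow(pep), window_count(10, lmax = 10))

  st20 <- make_line_chain(20)
  pep20 <- enumerate_peptides(st20, "A")
  expect_equal(nrow(pep20), window_count(20))

  # free region below lmin yields nothing
  st3 <- make_line_chain(10)
  pep3 <- enumerate_peptides(st3, "A", data.frame(start = 4, end = 10))
  expect_equal(nrow(pep3), 0)

  # property: arbitrary mask configurations match the oracle
  set.seed(9)
  for (k in 1:5) {
    n <- sample(25:40, 1)
    st <- make_line_chain(n)
    a <- sort(sample(1:n, 2))
    masks <- data.frame(start = a[1], end = a[2])
    free <- c(a[1] - 1, n - a[2])
    expect_equal(nrow(enumerate_peptides(st, "A", masks)),
                 window_count(free[free > 0]))
  }
})

test_that("enumerated windows never overlap masks and carry features", {
  st <- make_line_chain(30)
  pep <- enumerate_peptides(st, "A", data.frame(start = 12, end = 15))
  expect_true(all(pep$end < 12 | pep$start > 15))
  expect_true(all(pep$length == pep$end - pep$start + 1))
  expect_true(all(!is.na(pep$elongation) & !is.na(pep$linearity)))
  expect_true(all(pep$ss == "E"))
})

test_that("SVM separates clean clouds and classification is strict at zero", {
  set.seed(1)
  pos <- feature_cloud(30, elong = 22, lin = 0.4, ss = "E")
  neg <- feature_cloud(60, elong = 10, lin = 3, ss = "H")
  m <- train_svm(pos, neg)
  cl <- classify_peptides(m, rbind(pos, neg))
  expect_equal(mean(cl$accepted == rep(c(TRUE, FALSE), c(30, 60))), 1)
  expect_true(all(cl$accepted == (cl$decision > 0)))

  # a decision value of exactly zero is rejected (strict >)
  m0 <- structure(list(w = c(length = 1, elongation = 0, linearity = 0,
                             acc = 0, setNames(rep(0, 8),
                                               paste0("ss_", c("H", "G", "I",
                                                               "E", "B", "T",
                                                               "S", "-")))),
                       b = -7,
                       stats = list(center = rep(0, 12), scale = rep(1, 12))),
                  class = "dmi_svm")
  on_boundary <- data.frame(length = 7, elongation = 20, linearity = 1,
                            ss = "E", acc = 100)
  cl0 <- classify_peptides(m0, on_boundary)
  expect_identical(cl0$decision, 0)
  expect_false(cl0$accepted)

  expect_error(train_svm(pos[0, ], neg), "class")
  expect_error(classify_peptides(m, pos[, -2]), "features")
})

test_that("cost-factor 10 does not lose positive recall vs cost-factor 1", {
  set.seed(5)
  pos <- feature_cloud(40, elong = 16, lin = 1.2, ss = "E")
  neg <- feature_cloud(200, elong = 13, lin = 1.8, ss = "E")  # overlapping
  m10 <- train_svm(pos, neg, cost_factor = 10)
  m1 <- train_svm(pos, neg, cost_factor = 1)
  rec10 <- mean(classify_peptides(m10, pos)$accepted)
  rec1 <- mean(classify_peptides(m1, pos)$accepted)
  expect_gte(rec10, rec1)
  expect_gt(rec10, 0.8)  # weighted loss protects the minority class
})

test_that("training is invariant to row order", {
  set.seed(2)
  pos <- feature_cloud(25, elong = 22, lin = 0.4, ss = "E")
  neg <- feature_cloud(50, elong = 10, lin = 3, ss = "H")
  m <- train_svm(pos, neg)
  perm_p <- sample(nrow(pos)); perm_n <- sample(nrow(neg))
  m2 <- train_svm(pos[perm_p, ], neg[perm_n, ])
  probe <- feature_cloud(20, elong = 15, lin = 1.5, ss = "E")
  expect_equal(svm_decision(m2, probe), svm_decision(m, probe),
               tolerance = 1e-6)
})

test_that("classification is invariant under rigid motion of the structure", {
  set.seed(11)
  pos <- feature_cloud(30, elong = 22, lin = 0.4, ss = "E")
  neg <- feature_cloud(60, elong = 10, lin = 3, ss = "H")
  m <- train_svm(pos, neg)
  st <- make_line_chain(15)
  pep <- classify_peptides(m, enumerate_peptides(st, "A"))
  st2 <- st
  keys <- c("x", "y", "z")
  rot <- random_rotation(); shift <- rnorm(3, sd = 30)
  st2$atoms[, keys] <- rigid_motion(st2$atoms[, keys], rot, shift)
  ca <- c("ca_x", "ca_y", "ca_z")
  st2$residues[, ca] <- rigid_motion(st2$residues[, ca], rot, shift)
  pep2 <- classify_peptides(m, enumerate_peptides(st2, "A"))
  expect_equal(pep2$decision, pep$decision, tolerance = 1e-6)
  expect_identical(pep2$accepted, pep$accepted)
})

test_that("covered-peptide removal keeps maximal spans only", {
  df <- function(...) {
    sp <- list(...)
    data.frame(chain = "A", start = sapply(sp, `[`, 1),
               end = sapply(sp, `[`, 2))
  }
  r1 <- remove_covered_peptides(df(c(1, 10), c(2, 8)))
  expect_equal(nrow(r1), 1); expect_equal(r1$start, 1); expect_equal(r1$end, 10)

  r2 <- remove_covered_peptides(df(c(1, 10), c(5, 14)))
  expect_equal(nrow(r2), 2)  # partial overlap retained

  r3 <- remove_covered_peptides(df(c(3, 9), c(3, 9)))
  expect_equal(nrow(r3), 1)  # identical duplicates collapse

  # idempotent and order-independent
  set.seed(4)
  spans <- lapply(1:12, function(k) sort(sample(1:30, 2)))
  d <- do.call(function(...) df(...), spans)
  once <- remove_covered_peptides(d)
  expect_equal(nrow(remove_covered_peptides(once)), nrow(once))
  shuf <- d[sample(nrow(d)), ]
  again <- remove_covered_peptides(shuf)
  expect_setequal(paste(once$start, once$end), paste(again$start, again$end))
  # no kept span strictly inside another kept span
  for (i in seq_len(nrow(once))) {
    inside <- once$start <= once$start[i] & once$end >= once$end[i] &
      (once$start < once$start[i] | once$end > once$end[i])
    expect_false(any(inside))
  }
})

test_that("regions merge on shared residues but not on adjacency", {
  d <- data.frame(structure = "s", chain = "A",
                  start = c(1, 5, 20), end = c(10, 14, 25))
  rg <- build_peptide_regions(d)
  expect_equal(rg$start, c(1, 20))
  expect_equal(rg$end, c(14, 25))

  one <- build_peptide_regions(data.frame(structure = "s", chain = "A",
                                          start = 7, end = 13))
  expect_equal(c(one$start, one$end), c(7, 13))

  adj <- build_peptide_regions(data.frame(structure = "s", chain = "A",
                                          start = c(1, 6), end = c(5, 10)))
  expect_equal(nrow(adj), 2)  # adjacency without shared coverage

  # regions partition exactly the covered residues
  set.seed(6)
  for (k in 1:5) {
    sp <- t(replicate(8, sort(sample(1:40, 2))))
    d <- data.frame(structure = "s", chain = "A", start = sp[, 1], end = sp[, 2])
    rg <- build_peptide_regions(d)
    covered <- sort(unique(unlist(Map(seq, d$start, d$end))))
    in_regions <- sort(unlist(Map(seq, rg$start, rg$end)))
    expect_identical(in_regions, covered)  # no residue lost or duplicated
  }
})
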