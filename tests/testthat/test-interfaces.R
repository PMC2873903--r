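# Contact, area, stoichiometry, intrachain and homomer filters.

test_that("residue contacts respect the distance cutoff exactly", {
  two_res <- function(gap) {
    ca <- rbind(c(0, 0, 0), c(gap, 0, 0))
    atoms <- data.frame(chain = c("A", "B"), seq_index = c(1, 1),
                        resno = c(1, 1), resid = "ALA", elety = "CA",
                        element = "C", x = ca[, 1], y = ca[, 2], z = ca[, 3],
                        o = 1)
    res <- data.frame(chain = c("A", "B"), seq_index = c(1, 1),
                      resno = c(1, 1), aa = "A",
                      ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                      incomplete = FALSE, ss = "-", acc = 0,
                      modified = NA_character_)
    dmiminer:::new_dmi_structure("two", atoms, res)
  }
  near <- residue_contacts(two_res(4.9), "A", 1, 1, "B", 1, 1)
  expect_equal(near$pep_res, 1)
  far <- residue_contacts(two_res(5.1), "A", 1, 1, "B", 1, 1)
  expect_length(far$pep_res, 0)
})

test_that("contact map equals a brute-force all-pairs scan", {
  cx <- toy_complex(seed = 8)
  st <- cx$structure
  cm <- residue_contacts(st, "B", 1, 8, "A", 1, 48)
  a <- st$atoms
  pep <- a[a$chain == "B", ]; dom <- a[a$chain == "A", ]
  brute <- unique(do.call(rbind, lapply(seq_len(nrow(pep)), function(i) {
    d <- sqrt((dom$x - pep$x[i])^2 + (dom$y - pep$y[i])^2 +
                (dom$z - pep$z[i])^2)
    if (any(d <= 5)) data.frame(pep = pep$seq_index[i],
                                dom = dom$seq_index[d <= 5])
    else NULL
  })))
  expect_setequal(paste(cm$pairs$pep, cm$pairs$dom),
                  paste(brute$pep, brute$dom))
})

test_that("60%/gap-4 contact rule reproduces hand-computed verdicts", {
  expect_true(domain_contact_filter(c(1, 2, 4, 5, 7, 8), 1, 10))   # 6/10, gaps <= 2
  expect_false(domain_contact_filter(c(1, 2, 3, 4, 5), 1, 10))     # 50% < 60%
  expect_false(domain_contact_filter(c(1:7, 13:19), 1, 20))        # run of 5 (8..12)
  expect_true(domain_contact_filter(c(1, 2, 3), 1, 5))             # 3/5 = 60%
  expect_false(domain_contact_filter(c(6:10), 1, 10))              # terminal run of 5
  expect_true(domain_contact_filter(1:10, 1, 10))                  # full coverage
})

test_that("interface area: zero when apart, symmetric, matches spherical caps", {
  a <- matrix(c(0, 0, 0), 1); b <- matrix(c(30, 0, 0), 1)
  expect_equal(interface_area(a, 1.7, b, 1.7), 0)

  cx <- toy_complex(seed = 3)
  pa <- dmiminer:::span_atoms(cx$structure, "B", 1, 4)
  da <- dmiminer:::span_atoms(cx$structure, "A", 1, 10)
  ab <- interface_area(pa$xyz, pa$radii, da$xyz, da$radii, n_points = 480)
  ba <- interface_area(da$xyz, da$radii, pa$xyz, pa$radii, n_points = 480)
  expect_equal(ab, ba, tolerance = 1e-9)

  # two overlapping extended spheres vs the closed-form cap burial
  r1 <- 1.7 + 1.4; r2 <- 1.52 + 1.4; d <- 4.0
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  analytic <- (2 * pi * r1 * h1 + 2 * pi * r2 * h2) / 2
  computed <- interface_area(matrix(c(0, 0, 0), 1), 1.7,
                             matrix(c(d, 0, 0), 1), 1.52,
                             n_points = 1920)
  expect_lt(abs(computed - analytic) / analytic, 0.03)
})

test_that("iterative stoichiometry rule reproduces worked cases", {
  # N=1: ratio 0.6, area 200 -> accept
  r1 <- interface_ratio_filter(c(d1 = 200), 333)
  expect_true(r1$accepted)

  # N=2: ratios 0.30/0.30 (each >= 0.25, sum 0.6) -> accept
  r2 <- interface_ratio_filter(c(d1 = 300, d2 = 300), 1000)
  expect_true(r2$accepted)
  expect_setequal(r2$retained, c("d1", "d2"))

  # N=2: 0.45/0.10 -> second dropped (0.10 < 0.25), then 0.45 < 0.5 -> reject
  r3 <- interface_ratio_filter(c(d1 = 450, d2 = 100), 1000)
  expect_false(r3$accepted)
  expect_true("d2" %in% r3$dropped)

  # N=3: 0.2/0.2/0.05 -> 0.05 < 1/6 dropped; 0.2 < 0.25 both dropped -> reject
  r4 <- interface_ratio_filter(c(a = 200, b = 200, c = 50), 1000)
  expect_false(r4$accepted)
  expect_length(r4$retained, 0)

  # area floor: ratio fine but A_dp below 150 -> reject; at 160 -> accept
  expect_false(interface_ratio_filter(c(d1 = 140), 200)$accepted)
  expect_true(interface_ratio_filter(c(d1 = 160), 250)$accepted)
  # multi-domain: every retained domain must meet the floor
  expect_false(interface_ratio_filter(c(d1 = 300, d2 = 140), 1000)$accepted)

  expect_error(interface_ratio_filter(c(d1 = 100), 0), "interface")
})

test_that("stoichiometry iteration terminates within N rounds", {
  set.seed(13)
  for (k in 1:20) {
    n <- sample(1:6, 1)
    areas <- setNames(runif(n, 50, 500), paste0("d", 1:n))
    res <- interface_ratio_filter(areas, sum(areas) * runif(1, 1, 3))
    expect_lte(res$rounds, n)
    if (res$accepted) {
      expect_gte(sum(res$ratios), 0.5)
      expect_true(all(res$ratios >= 0.5 / length(res$ratios)))
    }
  }
})

test_that("intrachain rules reproduce hand-computed verdicts", {
  no_cath <- data.frame(start = integer(), end = integer())
  dom <- data.frame(start = 105, end = 160)
  # peptide inside a structure-defined span fails
  expect_false(intrachain_filters(30, 40, dom,
                                  data.frame(start = 1, end = 80)))
  # peptide end 100, domain start 105: separation 5 < 10 fails
  expect_false(intrachain_filters(91, 100, dom, no_cath))
  # separation exactly 10 passes ("below 10" rejected)
  expect_true(intrachain_filters(80, 95, dom, no_cath))
  expect_false(intrachain_filters(80, 96, dom, no_cath))  # separation 9
  # domain before the peptide, separation 12 passes
  expect_true(intrachain_filters(200, 210, data.frame(start = 100, end = 188),
                                 no_cath))
  # overlap with the binding domain is separation 0
  expect_false(intrachain_filters(150, 170, dom, no_cath))
})

test_that("homomer filter rejects near-identical chains", {
  s <- paste(rep(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"), 10),
             collapse = "")
  expect_false(homomer_filter(s, s))                      # identical
  expect_true(homomer_filter(s, paste(rep("W", 100), collapse = "")))
  mutant <- s
  substr(mutant, 50, 50) <- "Y"                           # 99% identity
  expect_false(homomer_filter(s, mutant))
  expect_true(homomer_filter(s, mutant, identity_threshold = 0.995))
})
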