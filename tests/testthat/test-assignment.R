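test_that("candidate filtering reproduces the published partition", {
  d <- read_distance_table(fixture_path("distances"))
  part <- filter_candidates(d)
  expect_setequal(part$beyond_detection,
                  c("CYS-72-HA", "CYS-72-HB2", "CYS-74-HN", "CYS-74-HB3",
                    "CYS-83-HA", "CYS-83-HB2", "HIS-87-HN", "HIS-87-HB3",
                    "HIS-87-HE1"))
  expect_length(part$beyond_detection, 9L)
  expect_setequal(part$candidates,
                  c("CYS-72-HB3", "CYS-74-HB2", "CYS-83-HB3", "HIS-87-HD2"))
  # the exchangeable hyperfine signal can only be the His ring NH
  expect_identical(hyperfine_exchangeable(part), "HIS-87-HNE2")
  # the two-way ambiguity for the weakly shifted signal F is surfaced as
  # the bond-excluded pair
  expect_setequal(setdiff(part$bond_excluded, "HIS-87-HA"),
                  c("CYS-74-HA", "HIS-87-HB2"))
  expect_error(filter_candidates(d[0, ]), "empty")
})

test_that("candidate partition is exhaustive, disjoint, and matches a brute-force rule scan", {
  set.seed(19)
  for (k in 1:200) {
    n <- sample(3:15, 1)
    d <- data.frame(
      chain = "A", resnum = sample(1:99, n), resname = "CYS",
      atom = sample(c("HN", "HA", "HB2", "HB3", "HNE2"), n, replace = TRUE),
      fe_label = "FE1", r_angstrom = runif(n, 1, 12),
      bonds = sample(c(NA, 1:6), n, replace = TRUE),
      ring = sample(c(TRUE, FALSE), n, replace = TRUE))
    class(d) <- c("distance_table", "data.frame")
    part <- filter_candidates(d)
    groups <- part[c("beyond_detection", "exchange_constrained",
                     "bond_excluded", "candidates")]
    ids <- paste(d$resname, d$resnum, d$atom, sep = "-")
    expect_setequal(unlist(groups, use.names = FALSE), ids)
    expect_equal(sum(lengths(groups)), n)
    # brute-force re-application of the rules, row by row
    for (i in seq_len(n)) {
      expected <-
        if (d$r_angstrom[i] < 4) "beyond_detection"
        else if (grepl("^H?N", d$atom[i])) "exchange_constrained"
        else if (!is.na(d$bonds[i]) && d$bonds[i] > 3 && !d$ring[i])
          "bond_excluded"
        else "candidates"
      expect_true(ids[i] %in% part[[expected]])
    }
  }
})

test_that("distant protons are all candidates", {
  d <- data.frame(chain = "A", resnum = 1:3, resname = "ALA",
                  atom = c("HA", "HB1", "HB2"), fe_label = "FE1",
                  r_angstrom = c(11, 12, 13), bonds = NA_integer_,
                  ring = FALSE)
  class(d) <- c("distance_table", "data.frame")
  part <- filter_candidates(d)
  expect_length(part$candidates, 3L)
  expect_length(part$beyond_detection, 0L)
})

test_that("NOE partner prediction ranks the geminal companion first with r^-6 intensities", {
  toy <- make_toy_structure(toy_site_spec())
  pp <- predict_noe_partners(toy$structure, "PRB-101-H1")
  expect_equal(pp$partner_id[1], "PRB-101-G1")
  expect_equal(pp$r_angstrom[1], 1.75, tolerance = 1e-6)
  expect_equal(pp$intensity[1], 1)
  expect_error(predict_noe_partners(toy$structure, "PRB-999-HX"),
               "not found")
})

test_that("NOE intensity ratio for partners at 2 and 4 Angstrom is 64:1", {
  pdb <- c(
    "ATOM      1  H1  PRB A   1       0.000   0.000   0.000  1.00  0.00           H",
    "ATOM      2  H2  PRB A   2       2.000   0.000   0.000  1.00  0.00           H",
    "ATOM      3  H3  PRB A   3       4.000   0.000   0.000  1.00  0.00           H")
  pp <- predict_noe_partners(read_pdb(pdb), "PRB-1-H1")
  expect_equal(pp$intensity[1] / pp$intensity[2], 64)
})

test_that("one candidate, one signal, one matching NOE assigns with score 1", {
  res <- match_assignments(
    candidates = "CYS-1-HB2", signals = "A",
    observed = list(A = 3.02),
    predicted = list("CYS-1-HB2" = data.frame(shift_ppm = 3.0,
                                              intensity = 1)))
  expect_identical(unname(res$assignment[["A"]]), "CYS-1-HB2")
  expect_equal(res$score, 1)
  expect_false(res$ambiguous)
})

test_that("synthetic NOE round trip recovers the ground truth and is relabeling-invariant", {
  toy <- make_toy_structure(toy_site_spec())
  s <- toy$structure
  ids <- paste(toy$truth$resname, toy$truth$resnum, toy$truth$atom,
               sep = "-")
  allh <- s[s$element == "H", ]
  shifts <- setNames(seq(1, by = 0.7, length.out = nrow(allh)),
                     paste(allh$resname, allh$resnum, allh$atom, sep = "-"))
  truth <- setNames(ids[c(1, 3, 5)], c("A", "D", "E"))
  noe <- make_noe_observations(s, truth, shifts, dropout = 0)
  observed <- split(noe$peak_shift_ppm, noe$irradiated_label)
  predicted <- lapply(setNames(ids, ids), function(id) {
    pp <- predict_noe_partners(s, id)
    data.frame(shift_ppm = unname(shifts[pp$partner_id]),
               intensity = pp$intensity)
  })
  res <- match_assignments(ids, names(truth), observed, predicted)
  expect_identical(res$assignment[names(truth)], truth)
  # relabeling invariance of the score
  perm <- c(3, 1, 2)
  res2 <- match_assignments(ids, names(truth)[perm],
                            observed, predicted)
  expect_equal(res2$score, res$score)
  expect_identical(res2$assignment[names(truth)], truth)
  # full dropout leaves every signal ambiguous
  res0 <- match_assignments(ids, names(truth),
                            observed = list(), predicted = predicted)
  expect_true(res0$ambiguous)
  expect_true(all(is.na(res0$assignment)))
})

test_that("more signals than candidates yields a partial result", {
  preds <- list(c1 = data.frame(shift_ppm = 1, intensity = 1),
                c2 = data.frame(shift_ppm = 2, intensity = 1))
  res <- match_assignments(c("c1", "c2"), c("A", "B", "C"),
                           observed = list(A = 1, B = 2, C = 99),
                           predicted = preds)
  expect_identical(unname(res$assignment[["A"]]), "c1")
  expect_identical(unname(res$assignment[["B"]]), "c2")
  expect_true(is.na(res$assignment[["C"]]))
})

test_that("combined shift perturbation is a scaled Euclidean norm", {
  expect_equal(delta_HN(0, 0), 0)
  expect_equal(delta_HN(0.1, 0.5), sqrt(0.01 + 0.01))
  expect_equal(delta_HN(0, 1.0), 0.2)
  expect_error(delta_HN(NA, 1), "finite")
  # norm properties on random triples
  set.seed(5)
  for (k in 1:50) {
    a <- rnorm(2); b <- rnorm(2)
    expect_lte(delta_HN(a[1] + b[1], a[2] + b[2]),
               delta_HN(a[1], a[2]) + delta_HN(b[1], b[2]) + 1e-12)
    if (any(a != 0)) expect_gt(delta_HN(a[1], a[2]), 0)
  }
})

test_that("perturbation significance uses mean + 1 sd over residues", {
  set.seed(8)
  rec <- data.frame(residue = 1:30, d_H = rnorm(30, 0, 0.02),
                    d_N = rnorm(30, 0, 0.1))
  rec$d_H[5] <- 0.5   # one strongly perturbed residue
  out <- perturbation_significance(rec)
  thr <- mean(out$delta_HN) + sd(out$delta_HN)
  expect_equal(attr(out, "threshold_ppm"), thr)
  expect_identical(out$significant, out$delta_HN > thr)
  expect_true(out$significant[5])
})
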