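# Core scoring: PSSM construction, peptide scoring, IC50 transform.

uniform_bg <- setNames(rep(0.05, 20), AA20)

test_that("build_pssm reproduces the hand-evaluated log-odds", {
  p <- build_pssm(rep("AAAAAAAAA", 10), background = uniform_bg,
                  omega = omega_policy(fixed_value = 0.05))
  # F_A,i = 1, BG_A = 0.05, omega = 0.05 -> ln(1.05/0.05) = ln(21)
  expect_equal(unname(p$matrix["A", ]), rep(log(21), 9))
  # unobserved residues: ln(0.05/0.05) = 0
  expect_equal(unname(p$matrix["C", ]), rep(0, 9))
  expect_identical(p$length, 9L)
  expect_identical(p$n_training_binders, 10L)
})

test_that("a cell with F_ai = BG_a - omega has log-odds exactly zero", {
  # NOTE: F_ai = BG_a - omega cannot hold for every cell of a column at
  # once (column frequencies sum to 1 but the targets sum to 1 - 20*omega),
  # so the zero-log-odds identity is asserted cell-wise.
  bg <- setNames(c(0.21, rep(0.79 / 19, 19)), AA20)
  binders <- c(paste0("A", strrep("L", 8)), paste0("A", strrep("K", 8)),
               random_peptide(8, 9, prob = bg))
  substr(binders[3:10], 1, 1) <- "G"   # column 1: A twice, G eight times
  p <- build_pssm(binders, background = bg,
                  omega = omega_policy(fixed_value = 0.01))
  # F_A,1 = 0.2 = BG_A - omega = 0.21 - 0.01
  expect_lt(abs(p$matrix["A", 1]), 1e-12)
})

test_that("PSSM column argmax recovers a sharp generating profile", {
  withr::with_seed(1, {
    prof <- make_motif_profile(9, anchors = c(2, 9), dominance = 0.7,
                               background = uniprot_background())
    binders <- sample_binders(prof, 100)
  })
  p <- build_pssm(binders, omega = omega_policy(fixed_value = 0.01))
  counted <- count_profile(binders)
  for (i in which(apply(prof$columns, 2, max) >= 0.5)) {
    expect_identical(AA20[which.max(p$matrix[, i])],
                     AA20[which.max(prof$columns[, i])])
    # and the counting oracle agrees with F inside the log-odds
    expect_equal(AA20[which.max(counted[, i])],
                 AA20[which.max(p$matrix[, i])])
  }
})

test_that("build_pssm rejects bad input", {
  expect_error(build_pssm(character(0)), "empty")
  expect_error(build_pssm(c("AAAAAAAA", "AAAAAAAAA")), "mixed")
  expect_error(build_pssm(c("AAAAAAAX", "AAAAAAAA")), "non-canonical")
  expect_error(build_pssm(rep("AAAA", 10)), "length")
  expect_error(omega_policy(fixed_value = 0), "fixed_value")
})

test_that("construction is pure for fixed omega and seeded for dirichlet", {
  binders <- withr::with_seed(2, random_peptide(30, 9))
  p1 <- build_pssm(binders)
  p2 <- build_pssm(binders)
  expect_identical(p1$matrix, p2$matrix)
  d1 <- build_pssm(binders, omega = omega_policy("dirichlet", seed = 42))
  d2 <- build_pssm(binders, omega = omega_policy("dirichlet", seed = 42))
  d3 <- build_pssm(binders, omega = omega_policy("dirichlet", seed = 43))
  expect_identical(d1$matrix, d2$matrix)
  expect_false(identical(d1$matrix, d3$matrix))
  expect_true(all(is.finite(d1$matrix)))
})

test_that("score_peptides is the length-normalized lookup sum", {
  p <- build_pssm(rep("AAAAAAAAA", 10), background = uniform_bg,
                  omega = omega_policy(fixed_value = 0.05))
  expect_equal(score_peptides(p, "AAAAAAAAA"), log(21))
  expect_equal(score_peptides(p, "CCCCCCCCC"), 0)
  # constant matrix -> any peptide scores that constant
  p$matrix[] <- 0.31
  expect_equal(score_peptides(p, random_peptide(5, 9)), rep(0.31, 5))
  expect_error(score_peptides(p, "AAAA"),
               "expects 9.*observed 4")
})

test_that("the per-column argmax peptide is a maximizer", {
  binders <- withr::with_seed(7, random_peptide(60, 9))
  p <- build_pssm(binders)
  best <- paste(AA20[apply(p$matrix, 2, which.max)], collapse = "")
  rivals <- withr::with_seed(7, random_peptide(500, 9))
  expect_true(all(score_peptides(p, best) >= score_peptides(p, rivals)))
})

test_that("score_to_ic50 hits its analytic anchors and classify splits at 500/50", {
  tr <- ic50_transform()
  expect_identical(score_to_ic50(0.8, tr), 1)
  expect_identical(score_to_ic50(-0.8, tr), 50000)
  expect_equal(score_to_ic50(0, tr), sqrt(50000))
  # clamping
  expect_identical(score_to_ic50(5, tr), 1)
  expect_identical(score_to_ic50(-5, tr), 50000)
  expect_identical(classify_affinity(c(49.9, 50, 499.9, 500), tr),
                   c("strong_binder", "binder", "binder", "nonbinder"))
  expect_error(classify_affinity(0, tr), "positive")
  expect_error(ic50_transform(strong_cutoff = 600), NULL)
})

test_that("transform is monotone, invertible, and score>0 implies binder", {
  tr <- ic50_transform()
  s <- withr::with_seed(3, sort(runif(1000, -0.8, 0.8)))
  ic <- score_to_ic50(s, tr)
  expect_true(all(diff(ic) < 0))                    # strictly decreasing
  expect_equal(ic50_to_score(ic, tr), s, tolerance = 1e-9)
  pos <- s[s > 0]
  expect_true(all(score_to_ic50(pos, tr) < 224))
  expect_true(all(classify_affinity(score_to_ic50(pos, tr), tr) != "nonbinder"))
})
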