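# Neoantigen window enumeration and candidate filtering.

sub_at <- function(pos, ref, alt) {
  list(position = pos, kind = "substitution", ref_aa = ref, alt_aa = alt)
}

test_that("substitution windows match the closed-form counts", {
  prot <- withr::with_seed(71, paste(sample(AA20, 20, TRUE), collapse = ""))
  ref <- substr(prot, 10, 10)
  alt <- setdiff(AA20, ref)[1]
  win <- enumerate_windows(prot, sub_at(10, ref, alt), lengths = 8:13)
  expect_identical(nrow(win), 54L)  # 8+9+10+10+9+8
  per_len <- table(win$length)
  for (L in 8:13)
    expect_identical(unname(per_len[as.character(L)]),
                     window_count(20, 10, L))
  # every mutant window differs from its wild-type partner at exactly one
  # position
  d <- mapply(function(m, w) sum(strsplit(m, "")[[1]] != strsplit(w, "")[[1]]),
              win$mutant_peptide, win$wild_type_peptide)
  expect_true(all(d == 1))
  expect_false(any(duplicated(win$mutant_peptide)))
})

test_that("boundary and monotonicity behavior of enumeration", {
  prot8 <- "ACDEFGHI"
  win <- enumerate_windows(prot8, sub_at(1, "A", "V"), lengths = 8:13)
  expect_identical(nrow(win), 1L)
  expect_identical(win$mutant_peptide, "VCDEFGHI")
  expect_identical(win$wild_type_peptide, "ACDEFGHI")

  prot <- withr::with_seed(72, paste(sample(AA20, 40, TRUE), collapse = ""))
  ref <- substr(prot, 20, 20); alt <- setdiff(AA20, ref)[1]
  n_wide <- nrow(enumerate_windows(prot, sub_at(20, ref, alt), 8:13))
  n_narrow <- nrow(enumerate_windows(prot, sub_at(20, ref, alt), 9:11))
  expect_lte(n_narrow, n_wide)

  expect_error(enumerate_windows(prot, sub_at(20, setdiff(AA20, ref)[2], alt)),
               "ref_aa mismatch")
  expect_error(enumerate_windows(prot, sub_at(20, ref, ref)), "differing")
})

test_that("indel windows cover the altered region without wild-type pairing", {
  prot <- strrep("ACDEFGHIKL", 4)   # length 40
  ins <- enumerate_windows(prot, list(position = 20, kind = "insertion",
                                      ref_aa = "", alt_aa = "WW"),
                           lengths = 9)
  expect_true(nrow(ins) > 0)
  expect_true(all(is.na(ins$wild_type_peptide)))
  expect_true(all(grepl("W", ins$mutant_peptide)))   # overlap the insertion

  del <- enumerate_windows(prot, list(position = 11, kind = "deletion",
                                      ref_aa = "ACD", alt_aa = ""),
                           lengths = 9)
  expect_true(nrow(del) > 0)
  expect_true(all(is.na(del$wild_type_peptide)))
  # junction windows span positions 10|11 of the mutant sequence
  expect_true(all(del$start <= 11 & del$start + 9 - 1 >= 10))
})

test_that("call_neoantigens applies the binder and wild-type rules", {
  # one allele; matrix rewards residue W so mutant (with W) beats wild-type
  p_good <- build_pssm(rep("AAAAAAAAA", 10), allele = "A*9001")
  p_good$matrix[] <- 0
  p_good$matrix["W", ] <- 2
  lib <- pssm_library(list(p_good))
  win <- data.frame(mutant_peptide = "AAAAWAAAA",
                    wild_type_peptide = "AAAAQAAAA")
  res <- call_neoantigens(win, "A*9001", lib)
  # wt score 0 -> 223.6 nM; mutant score 2/9 -> ~49 nM: binder and smaller
  expect_true(res$pass)
  expect_identical(res$reason, "pass")
  expect_lt(res$ic50_mut, res$ic50_wt)

  # penalized mutant residue: still a binder, but worse than wild-type
  p_bad <- p_good
  p_bad$matrix["W", ] <- -0.5
  res2 <- call_neoantigens(win, "A*9001", pssm_library(list(p_bad)))
  expect_false(res2$pass)
  expect_identical(res2$reason, "fail_wt_comparison")

  # strongly penalized: not a binder at all
  p_worst <- p_good
  p_worst$matrix["W", ] <- -20
  res3 <- call_neoantigens(win, "A*9001", pssm_library(list(p_worst)))
  expect_identical(res3$reason, "fail_binder")

  # indel-style rows (no wild-type) pass on rule (i) alone
  win_na <- data.frame(mutant_peptide = "AAAAWAAAA",
                       wild_type_peptide = NA_character_)
  expect_true(call_neoantigens(win_na, "A*9001", lib)$pass)

  expect_error(call_neoantigens(win, "B*5701", lib), "no coverage")
})

test_that("consensus_ic50 applies the 2-of-N median rule", {
  m <- rbind(c(100, 400, 900),   # two binders -> consensus binder, median 400
             c(100, 900, 900),   # one binder  -> not consensus
             c(600, 700, 800))   # none
  out <- consensus_ic50(m)
  expect_identical(out$binder, c(TRUE, FALSE, FALSE))
  expect_identical(out$ic50, c(400, 900, 700))
  expect_identical(out$n_support, c(2, 1, 0))
  # single predictor degenerates to its own call
  out1 <- consensus_ic50(matrix(c(100, 600), ncol = 1))
  expect_identical(out1$binder, c(TRUE, FALSE))
})
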