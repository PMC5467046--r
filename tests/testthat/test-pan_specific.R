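# Pan-specific prediction: alignment weights, similarity library,
# weighted-mean IC50.

test_that("alignment_weight matches BLOSUM62 lookups and the DP oracle", {
  b62 <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  expect_identical(alignment_weight("ARND", "ARND"), 21)  # 4+5+6+6
  # no positive substitution against W-free residue set -> local score 0
  expect_identical(alignment_weight("AAAA", "W"), 0)
  expect_error(alignment_weight("", "ARND"), "empty")

  withr::with_seed(51, {
    for (i in 1:50) {
      x <- paste(sample(AA20, sample(5:12, 1), TRUE), collapse = "")
      y <- paste(sample(AA20, sample(5:12, 1), TRUE), collapse = "")
      expect_identical(alignment_weight(x, y), alignment_weight(y, x))
    }
    for (i in 1:20) {  # DP oracle on toy inputs
      x <- paste(sample(AA20, sample(3:8, 1), TRUE), collapse = "")
      y <- paste(sample(AA20, sample(3:8, 1), TRUE), collapse = "")
      expect_identical(alignment_weight(x, y),
                       brute_local_align(x, y, b62))
    }
  })
})

test_that("build_similarity_library pairs, merges, and ranks identity highest", {
  hla <- make_synthetic_hla_set(3, n_uncharacterized = 1, seed = 3,
                                mutation_rate = 0.02, copy_of = 2L)
  sim <- build_similarity_library(hla$sequences, hla$characterized)
  u <- hla$uncharacterized[1]
  expect_identical(nrow(sim), 3L)                      # 1 unchar x 3 char
  expect_true(all(sim$uncharacterized == u))
  expect_true(all(sim$source == "alignment"))
  # identical sequence gets the maximum weight
  best <- sim$characterized[which.max(sim$weight)]
  expect_identical(best, hla$characterized[2])

  # nearest-distance pairs merge with alignment precedence
  nd <- data.frame(uncharacterized = u,
                   characterized = hla$characterized[c(1, 3)])
  sim2 <- build_similarity_library(
    hla$sequences[c(u, hla$characterized[1:2])],  # char 3 has no sequence
    hla$characterized, nearest_pairs = nd, constant_weight = 7)
  expect_identical(nrow(sim2), 3L)
  row13 <- sim2[sim2$characterized == hla$characterized[3], ]
  expect_identical(row13$source, "nearest_distance")
  expect_identical(row13$weight, 7)
  row1 <- sim2[sim2$characterized == hla$characterized[1], ]
  expect_identical(row1$source, "alignment")           # alignment wins
  # TSV round-trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_library(sim2, f)
  back <- read_similarity_library(f)
  expect_equal(back$weight, sim2$weight)
  expect_identical(back$characterized, sim2$characterized)
})

test_that("predict_pan computes the weighted mean of neighbor IC50s", {
  lib <- pssm_library(list(constant_ic50_pssm("A*9001", 9, 100),
                           constant_ic50_pssm("A*9002", 9, 300)))
  pep <- "SIINFEKLM"
  sim1 <- data.frame(uncharacterized = "HLA-B*90:01",
                     characterized = "HLA-A*90:01", weight = 5,
                     source = "alignment")
  r1 <- predict_pan(pep, "B*9001", lib, sim1)
  expect_equal(r1$ic50_nM, 100)                        # mean of one
  expect_identical(r1$mode, "pan-specific")
  expect_identical(r1$n_neighbors, 1L)

  sim2 <- data.frame(uncharacterized = "HLA-B*90:01",
                     characterized = c("HLA-A*90:01", "HLA-A*90:02"),
                     weight = c(1, 1), source = "alignment")
  expect_equal(predict_pan(pep, "B*9001", lib, sim2)$ic50_nM, 200)

  sim2$weight <- c(1, 3)
  r3 <- predict_pan(pep, "B*9001", lib, sim2)
  expect_equal(r3$ic50_nM, 250)                        # (1*100+3*300)/4
  expect_identical(r3$class, "binder")

  # top_k = 1 keeps only the heaviest neighbor
  expect_equal(predict_pan(pep, "B*9001", lib, sim2, top_k = 1)$ic50_nM, 300)

  expect_error(predict_pan(pep, "A*9001", lib, sim2), "characterized")
  expect_error(predict_pan(pep, "C*0102", lib, sim2), "uncoverable")
  # neighbor PSSMs missing the peptide length -> uncoverable error
  expect_error(predict_pan("AAAAAAAAAA", "B*9001", lib, sim2),
               "peptide length")
})

test_that("weighted mean is bounded and weight-scale invariant", {
  withr::with_seed(61, {
    alleles <- sprintf("A*91:%02d", 1:5)
    ic50s <- runif(5, 5, 5000)
    lib <- pssm_library(lapply(1:5, function(i)
      constant_ic50_pssm(alleles[i], 9, ic50s[i])))
    for (rep in 1:50) {
      w <- runif(5, 0.1, 100)
      sim <- data.frame(uncharacterized = "HLA-B*91:01",
                        characterized = normalize_allele(alleles),
                        weight = w, source = "alignment")
      peps <- random_peptide(3, 9)
      r <- predict_pan(peps, "B*9101", lib, sim)
      expect_true(all(r$ic50_nM >= min(ic50s) - 1e-9 &
                        r$ic50_nM <= max(ic50s) + 1e-9))
      sim$weight <- w * runif(1, 0.01, 100)
      r2 <- predict_pan(peps, "B*9101", lib, sim)
      expect_equal(r2$ic50_nM, r$ic50_nM, tolerance = 1e-9)
    }
  })
})

test_that("predict_binding dispatches modes and degrades row-wise", {
  lib <- pssm_library(list(constant_ic50_pssm("A*9001", 9, 100)))
  sim <- data.frame(uncharacterized = "HLA-B*90:01",
                    characterized = "HLA-A*90:01", weight = 1,
                    source = "alignment")
  r <- predict_binding(c("SIINFEKLM", "SIINFEKLML"), "A*9001", lib)
  expect_identical(r$mode, rep("allele-specific", 2))
  expect_identical(r$status, c("ok", "no_model_for_length"))
  expect_equal(r$ic50_nM[1], 100)
  expect_true(is.na(r$ic50_nM[2]))
  expect_true(r$binder_by_score[1])      # ic50 100 < 223.6 nM <=> score > 0
  r2 <- predict_binding("SIINFEKLM", "B*9001", lib, sim = sim)
  expect_identical(r2$mode, "pan-specific")
  expect_equal(r2$ic50_nM, 100)
  expect_error(predict_binding("SIINFEKLM", "B*9001", lib), "similarity")
})
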