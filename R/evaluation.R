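# Evaluation: k-fold cross-validation with generated nonbinders, ROC AUC
# (Mann-Whitney pair counting) and confusion metrics at an IC50 cutoff.

#' Seeded k-fold assignment
#'
#' Random partition of `1..n` into k folds whose sizes differ by at most
#' one; reproducible per seed.
#'
#' @param n Number of items, `n >= k`.
#' @param k Number of folds, `k >= 2`.
#' @param seed Optional integer; `NULL` uses the ambient RNG stream.
#' @return Integer vector of fold ids in `1..k`, length `n`.
#' @export
kfold_split <- function(n, k = 10L, seed = NULL) {
  stopifnot(k >= 2L)
  if (n < k) stop("n (", n, ") must be at least k (", k, ")")
  with_seed_if(seed, sample(rep(seq_len(k), length.out = n)))
}

#' Generate random nonbinder peptides
#'
#' Samples peptides i.i.d. per position from background residue
#' frequencies. When a `screen` function is supplied (peptides -> IC50 nM),
#' candidates it predicts as binders (IC50 < `screen_cutoff`) are rejected
#' and resampled, up to `max_attempts * n` total draws.
#'
#' @param n Number of peptides.
#' @param length Peptide length in 8..25.
#' @param background Named background frequency vector.
#' @param screen Optional function mapping a character vector of peptides
#'   to predicted IC50 (nM).
#' @param screen_cutoff Rejection threshold (nM), default 500.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @param max_attempts Rejection budget as a multiple of `n`.
#' @return Character vector of `n` peptides.
#' @export
generate_nonbinders <- function(n, length, background = uniprot_background(),
                                screen = NULL, screen_cutoff = 500,
                                seed = NULL, max_attempts = 50L) {
  stopifnot(n >= 1L, length >= PEPTIDE_LENGTH_RANGE[1L],
            length <= PEPTIDE_LENGTH_RANGE[2L])
  background <- validate_background(background)
  with_seed_if(seed, {
    out <- character(0)
    drawn <- 0L
    budget <- max_attempts * n
    while (base::length(out) < n) {
      want <- n - base::length(out)
      batch <- min(max(want * 2L, 64L), budget - drawn)
      if (batch <= 0L)
        stop("nonbinder rejection budget exhausted: acceptance rate ",
             signif(base::length(out) / max(drawn, 1L), 3L),
             " after ", drawn, " draws")
      chars <- sample(AMINO_ACIDS, batch * length, replace = TRUE,
                      prob = background)
      cand <- apply(matrix(chars, nrow = batch), 1L, paste, collapse = "")
      drawn <- drawn + batch
      if (!is.null(screen)) cand <- cand[screen(cand) >= screen_cutoff]
      out <- c(out, cand)
    }
    out[seq_len(n)]
  })
}

#' ROC AUC by Mann-Whitney pair counting
#'
#' The fraction of (positive, negative) pairs in which the positive scores
#' strictly higher, ties counted one half — computed through average
#' ranks, which is algebraically identical to exhaustive pair counting.
#' Scores are in the "higher = more positive" orientation (use e.g.
#' `-log(ic50)` for IC50 predictions).
#'
#' @param scores Numeric vector.
#' @param labels Logical (or 0/1) vector; `TRUE` marks positives. Both
#'   classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.numeric(scores))
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts and derived metrics at an IC50 cutoff
#'
#' A positive call is `ic50 < cutoff` (strict). Derived metrics:
#' `ACC = (TP+TN)/(TP+FP+TN+FN)`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`; `precision = TP/(TP+FP)` is also reported.
#'
#' @param ic50 Predicted IC50 values (nM).
#' @param labels Logical (or 0/1) truth vector; `TRUE` = binder.
#' @param cutoff Positive IC50 cutoff in nM (default 500).
#' @return List of class `confusion`: `TP`, `FP`, `TN`, `FN`, `cutoff`,
#'   `acc`, `sensitivity`, `specificity`, `precision`.
#' @export
confusion_metrics <- function(ic50, labels, cutoff = 500) {
  if (length(ic50) != length(labels))
    stop("ic50 and labels lengths differ (", length(ic50), " vs ",
         length(labels), ")")
  stopifnot(cutoff > 0)
  labels <- as.logical(labels)
  call_pos <- ic50 < cutoff
  TP <- sum(call_pos & labels); FP <- sum(call_pos & !labels)
  TN <- sum(!call_pos & !labels); FN <- sum(!call_pos & labels)
  structure(list(
    TP = TP, FP = FP, TN = TN, FN = FN, cutoff = cutoff,
    acc = (TP + TN) / (TP + FP + TN + FN),
    sensitivity = if (TP + FN > 0L) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0L) TN / (TN + FP) else NA_real_,
    precision = if (TP + FP > 0L) TP / (TP + FP) else NA_real_),
    class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion @ %g nM: TP=%d FP=%d TN=%d FN=%d | ACC=%.3f Sen=%.3f Spe=%.3f\n",
              x$cutoff, x$TP, x$FP, x$TN, x$FN, x$acc, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' k-fold cross-validation of PSSM training
#'
#' For each (allele, length) binder group: randomly partitions the binders
#' into k folds, trains a PSSM on k-1 folds, and scores the held-out
#' binders together with an equal-count validation nonbinder set (freshly
#' generated from background frequencies, or drawn from a caller-supplied
#' per-group nonbinder pool that is itself k-folded). Fold predictions are
#' pooled per group before computing AUC and the confusion metrics at the
#' 500 nM cutoff ("pooled"); per-fold averaging is available as an option.
#' Groups with fewer than `min_binders` binders (default 12) are skipped
#' and reported.
#'
#' @param groups Named list of binder peptide vectors, names
#'   `"<allele>|<length>"` (see [group_for_training()]).
#' @param k Number of folds (default 10).
#' @param seed Integer seed driving fold assignment and nonbinder
#'   generation; the whole run is reproducible per seed.
#' @param background Background frequencies for training and nonbinder
#'   generation.
#' @param nonbinders Optional named list parallel to `groups` supplying a
#'   fixed nonbinder pool per group (used instead of generation).
#' @param screen Optional screen function passed to
#'   [generate_nonbinders()]; default none (the trained model itself
#'   systematically inflates scores of random peptides through the
#'   pseudocount, so self-screening is not the default).
#' @param min_binders Minimum binders per evaluated group (default 12).
#' @param pooling `"pooled"` (default) or `"per_fold"` metric aggregation.
#' @param omega,log_base,transform Model settings, as in [build_pssm()] /
#'   [score_to_ic50()].
#' @return Data frame of class `eval_summary` with one row per evaluated
#'   group: `allele`, `length`, `n_binders`, `n_nonbinders`, `auc`, `acc`,
#'   `sensitivity`, `specificity`; attributes `"macro"` (named vector of
#'   macro-averaged metrics) and `"skipped"` (under-threshold groups).
#' @export
cross_validate <- function(groups, k = 10L, seed = 1L,
                           background = uniprot_background(),
                           nonbinders = NULL, screen = NULL,
                           min_binders = 12L, pooling = c("pooled", "per_fold"),
                           omega = omega_policy(), log_base = exp(1),
                           transform = ic50_transform()) {
  pooling <- match.arg(pooling)
  stopifnot(is.list(groups), k >= 2L)
  with_seed_if(seed, {
    rows <- list(); skipped <- list()
    for (key in names(groups)) {
      binders <- groups[[key]]
      allele <- sub("\\|.*$", "", key)
      L <- nchar(binders[1L])
      if (length(binders) < max(min_binders, k)) {
        skipped[[key]] <- data.frame(allele = allele, length = L,
                                     n = length(binders))
        next
      }
      kk <- min(k, length(binders))
      fold <- kfold_split(length(binders), kk)
      pool <- nonbinders[[key]]
      pool_fold <- if (!is.null(pool)) kfold_split(length(pool), kk)
      ic50 <- numeric(0); truth <- logical(0)
      fold_auc <- fold_acc <- fold_sen <- fold_spe <- numeric(kk)
      n_nb_total <- 0L
      for (f in seq_len(kk)) {
        train <- binders[fold != f]
        val_b <- binders[fold == f]
        p <- build_pssm(train, background = background, omega = omega,
                        log_base = log_base, allele = allele)
        val_n <- if (!is.null(pool)) pool[pool_fold == f] else
          generate_nonbinders(length(val_b), L, background = background,
                              screen = screen)
        n_nb_total <- n_nb_total + length(val_n)
        ic50_f <- score_to_ic50(score_peptides(p, c(val_b, val_n)), transform)
        truth_f <- rep(c(TRUE, FALSE), c(length(val_b), length(val_n)))
        ic50 <- c(ic50, ic50_f); truth <- c(truth, truth_f)
        if (pooling == "per_fold") {
          fold_auc[f] <- auc(-ic50_f, truth_f)
          cm <- confusion_metrics(ic50_f, truth_f, transform$binder_cutoff)
          fold_acc[f] <- cm$acc; fold_sen[f] <- cm$sensitivity
          fold_spe[f] <- cm$specificity
        }
      }
      if (pooling == "pooled") {
        group_auc <- auc(-ic50, truth)
        cm <- confusion_metrics(ic50, truth, transform$binder_cutoff)
        met <- c(auc = group_auc, acc = cm$acc, sensitivity = cm$sensitivity,
                 specificity = cm$specificity)
      } else {
        met <- c(auc = mean(fold_auc), acc = mean(fold_acc),
                 sensitivity = mean(fold_sen), specificity = mean(fold_spe))
      }
      rows[[key]] <- data.frame(allele = allele, length = L,
                                n_binders = length(binders),
                                n_nonbinders = n_nb_total,
                                auc = met[["auc"]], acc = met[["acc"]],
                                sensitivity = met[["sensitivity"]],
                                specificity = met[["specificity"]])
    }
    summary <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
      else data.frame(allele = character(0), length = integer(0),
                      n_binders = integer(0), n_nonbinders = integer(0),
                      auc = numeric(0), acc = numeric(0),
                      sensitivity = numeric(0), specificity = numeric(0))
    skipped_df <- if (length(skipped)) do.call(rbind, c(skipped, make.row.names = FALSE))
      else data.frame(allele = character(0), length = integer(0),
                      n = integer(0))
    macro <- if (nrow(summary))
      colMeans(summary[c("auc", "acc", "sensitivity", "specificity")])
      else c(auc = NA_real_, acc = NA_real_, sensitivity = NA_real_,
             specificity = NA_real_)
    structure(summary, macro = macro, skipped = skipped_df,
              class = c("eval_summary", "data.frame"))
  })
}

#' Write an evaluation summary TSV
#'
#' @param summary An `eval_summary` from [cross_validate()].
#' @param path TSV path.
#' @export
write_eval_summary <- function(summary, path) {
  write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
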