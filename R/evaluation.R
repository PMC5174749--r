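## Scoring: one-vs-rest per-class P/R/F, the micro-average pooled over the
## positive classes only (the DDIExtraction 2013 official convention — the
## negative class is excluded so "overall" reflects interaction extraction,
## not the easy majority class), binary detection (DEC) metrics, and
## sentence-grouped cross-validation splits.

.prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(P = p, R = r, F = f)
}

#' Score predictions
#'
#' Computes one-vs-rest precision/recall/F per class (in percent), the
#' overall micro-averaged P/R/F with true/false positives pooled across the
#' positive classes only, and the binary interaction-detection (DEC) metrics
#' obtained by collapsing all positive classes into a single "interaction"
#' label.
#'
#' @param gold,pred equal-length character vectors of class labels.
#' @param classes full class set; defaults to the labels observed.
#' @param positive positive (interaction) classes; defaults to everything
#'   except `"negative"`.
#' @return An object of class `eval_report`: list with `per_class`
#'   (data.frame of P/R/F and support per class), `micro`, `dec` (named
#'   P/R/F vectors) and `support`.
#' @export
score_relations <- function(gold, pred, classes = NULL, positive = NULL) {
  if (length(gold) != length(pred)) {
    stop_validation("gold (%d) and predicted (%d) label sequences differ in length",
                    length(gold), length(pred))
  }
  classes <- classes %||% sort(unique(c(gold, pred)))
  positive <- positive %||% setdiff(classes, "negative")
  per <- t(vapply(classes, function(cl) {
    tp <- sum(gold == cl & pred == cl)
    fp <- sum(pred == cl & gold != cl)
    fn <- sum(gold == cl & pred != cl)
    c(.prf(tp, fp, fn), support = sum(gold == cl))
  }, numeric(4)))
  per_class <- data.frame(class = classes, P = per[, "P"], R = per[, "R"],
                          F = per[, "F"], support = as.integer(per[, "support"]),
                          row.names = NULL, stringsAsFactors = FALSE)
  tp <- sum(vapply(positive, function(cl) sum(gold == cl & pred == cl), numeric(1)))
  fp <- sum(vapply(positive, function(cl) sum(pred == cl & gold != cl), numeric(1)))
  fn <- sum(vapply(positive, function(cl) sum(gold == cl & pred != cl), numeric(1)))
  micro <- .prf(tp, fp, fn)
  gb <- ifelse(gold %in% positive, "interaction", "negative")
  pb <- ifelse(pred %in% positive, "interaction", "negative")
  dec <- .prf(sum(gb == "interaction" & pb == "interaction"),
              sum(pb == "interaction" & gb != "interaction"),
              sum(gb == "interaction" & pb != "interaction"))
  structure(list(per_class = per_class, micro = micro, dec = dec,
                 positive = positive, n = length(gold)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%-16s %7s %7s %7s %8s\n", "class", "P", "R", "F", "support"))
  for (i in seq_len(nrow(x$per_class))) {
    cat(sprintf("%-16s %7.2f %7.2f %7.2f %8d\n", x$per_class$class[i],
                x$per_class$P[i], x$per_class$R[i], x$per_class$F[i],
                x$per_class$support[i]))
  }
  cat(sprintf("%-16s %7.2f %7.2f %7.2f %8d\n", "Overall (micro)",
              x$micro["P"], x$micro["R"], x$micro["F"], x$n))
  cat(sprintf("%-16s %7.2f %7.2f %7.2f %8d\n", "Detection (DEC)",
              x$dec["P"], x$dec["R"], x$dec["F"], x$n))
  invisible(x)
}

#' Convert an evaluation report to a key-value list
#'
#' Flat machine-readable form suitable for JSON export.
#'
#' @param report an `eval_report`.
#' @return Named list of numbers.
#' @export
report_to_list <- function(report) {
  out <- list(micro_p = unname(report$micro["P"]),
              micro_r = unname(report$micro["R"]),
              micro_f = unname(report$micro["F"]),
              dec_p = unname(report$dec["P"]),
              dec_r = unname(report$dec["R"]),
              dec_f = unname(report$dec["F"]),
              n = report$n)
  for (i in seq_len(nrow(report$per_class))) {
    cl <- report$per_class$class[i]
    out[[paste0(cl, "_p")]] <- report$per_class$P[i]
    out[[paste0(cl, "_r")]] <- report$per_class$R[i]
    out[[paste0(cl, "_f")]] <- report$per_class$F[i]
  }
  out
}

#' Cross-validation splits grouped by sentence
#'
#' Partitions instances into `k` folds for cross-validation. Instances from
#' the same sentence always land in the same fold (pairs from one sentence
#' are near-duplicates; splitting them would leak), sentences are assigned
#' in seeded shuffled order to the currently smallest fold, and fold sizes
#' are as balanced as the grouping allows.
#'
#' @param instances list of `mccnn_instance` objects.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return List of `k` folds, each a list with integer index vectors
#'   `train` and `test` into `instances`; the `test` sets partition the
#'   instance set.
#' @export
cv_split <- function(instances, k = 10L, seed = 1L) {
  stopifnot(k >= 2L, length(instances) >= k)
  sids <- instance_sentence_ids(instances)
  usids <- unique(sids)
  if (k > length(usids)) {
    stop_validation("k = %d exceeds the number of distinct sentences (%d)",
                    k, length(usids))
  }
  order_sids <- with_seed(seed, sample(usids))
  fold_of <- integer(length(usids))
  names(fold_of) <- order_sids
  fold_sizes <- integer(k)
  for (s in order_sids) {
    f <- which.min(fold_sizes)
    fold_of[s] <- f
    fold_sizes[f] <- fold_sizes[f] + sum(sids == s)
  }
  inst_fold <- unname(fold_of[sids])
  lapply(seq_len(k), function(f) {
    list(train = which(inst_fold != f), test = which(inst_fold == f))
  })
}
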