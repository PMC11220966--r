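#' Count exact-match true/false positives and false negatives
#'
#' A predicted span is a true positive iff a gold span with the same
#' sentence, start, end and label exists; matching is one-to-one. Remaining
#' predictions are false positives, remaining gold spans false negatives.
#'
#' @param pred,gold lists of span data.frames (`start`, `end`, `label`), one
#'   element per sentence, in the same sentence order.
#' @return list with integers `TP`, `FP`, `FN`.
#' @export
count_matches <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  TP <- 0L; FP <- 0L; FN <- 0L
  for (i in seq_along(gold)) {
    p <- as_span_frame(pred[[i]]); g <- as_span_frame(gold[[i]])
    pk <- span_keys(p); gk <- span_keys(g)
    # one-to-one: count multiplicities via table intersection
    tp <- sum(pmin(table(factor(pk, levels = unique(c(pk, gk)))),
                   table(factor(gk, levels = unique(c(pk, gk))))))
    TP <- TP + tp
    FP <- FP + length(pk) - tp
    FN <- FN + length(gk) - tp
  }
  list(TP = TP, FP = FP, FN = FN)
}

span_keys <- function(df) {
  if (nrow(df) == 0L) return(character())
  paste(df$start, df$end, df$label, sep = "|")
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. A zero denominator
#' yields 0 and sets the `degenerate` flag.
#'
#' @param counts list with `TP`, `FP`, `FN`.
#' @return list with `precision`, `recall`, `f1` (proportions in [0,1]),
#'   `counts`, and `degenerate`.
#' @export
score <- function(counts) {
  degenerate <- FALSE
  div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  P <- div(counts$TP, counts$TP + counts$FP)
  R <- div(counts$TP, counts$TP + counts$FN)
  F1 <- if (P + R == 0) { degenerate <- degenerate || counts$TP + counts$FP +
    counts$FN > 0; 0 } else 2 * P * R / (P + R)
  list(precision = P, recall = R, f1 = F1, counts = counts,
       degenerate = degenerate)
}

#' Evaluate predicted spans against a gold corpus
#'
#' Micro-averaged overall scores plus a per-label breakdown; exact span +
#' label match, no partial credit.
#'
#' @param pred list of predicted span data.frames, one per sentence.
#' @param gold_corpus the gold `mrc_corpus`.
#' @return list with `micro` (a [score()] result) and `per_label` data.frame.
#' @export
evaluate_spans <- function(pred, gold_corpus) {
  gold <- gold_corpus$spans
  micro <- score(count_matches(pred, gold))
  per <- lapply(gold_corpus$labels, function(lab) {
    sel <- function(lst) lapply(lst, function(df)
      df[df$label == lab, , drop = FALSE])
    s <- score(count_matches(sel(pred), sel(gold)))
    data.frame(label = lab, TP = s$counts$TP, FP = s$counts$FP,
               FN = s$counts$FN, precision = s$precision, recall = s$recall,
               f1 = s$f1, stringsAsFactors = FALSE)
  })
  list(micro = micro, per_label = reset_rows(do.call(rbind, per)))
}

#' Aggregate F1 scores over repeated runs
#'
#' Arithmetic mean, sample (n-1) standard deviation and maximum — the
#' "Mean ± std" / "Max" aggregate used in results tables. A single run has
#' standard deviation 0.
#'
#' @param f1s non-empty numeric vector of per-run F1 values.
#' @return list with `mean`, `std`, `max`, `n`.
#' @export
aggregate_runs <- function(f1s) {
  if (length(f1s) == 0L) stop("aggregate_runs requires at least one run")
  list(mean = mean(f1s),
       std = if (length(f1s) == 1L) 0 else stats::sd(f1s),
       max = max(f1s), n = length(f1s))
}

#' Format an evaluation report as tab-separated text
#'
#' Percentages to two decimals, per-label rows then a micro total.
#'
#' @param report result of [evaluate_spans()].
#' @return character vector of lines.
#' @export
format_eval_report <- function(report) {
  fmt <- function(x) sprintf("%.2f", 100 * x)
  lines <- c("label\tTP\tFP\tFN\tP\tR\tF1")
  pl <- report$per_label
  for (i in seq_len(nrow(pl)))
    lines <- c(lines, sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%s", pl$label[i],
                              pl$TP[i], pl$FP[i], pl$FN[i],
                              fmt(pl$precision[i]), fmt(pl$recall[i]),
                              fmt(pl$f1[i])))
  m <- report$micro
  c(lines, sprintf("micro\t%d\t%d\t%d\t%s\t%s\t%s", m$counts$TP, m$counts$FP,
                   m$counts$FN, fmt(m$precision), fmt(m$recall), fmt(m$f1)))
}
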