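#' Evaluate detected complexes against a benchmark catalog
#'
#' Matching is existential and many-to-many: a detected complex is true when
#' some benchmark complex overlaps it with Jaccard `>= th`, and a benchmark
#' complex is recovered when some detected complex overlaps it likewise (no
#' one-to-one assignment). Precision is the fraction of detected complexes
#' that are true, recall the fraction of benchmark complexes recovered, and
#' F-1 their harmonic mean (0 when both are 0).
#'
#' @param detected A complex tibble (or list of protein vectors).
#' @param benchmark The reference complex tibble (or list); must be
#'   non-empty.
#' @param th Jaccard matching threshold in `(0, 1]`, default 0.25.
#' @return A `complex_eval` object; see [glance.complex_eval()] and
#'   [tidy.complex_eval()].
#' @export
evaluate_complexes <- function(detected, benchmark, th = 0.25) {
  if (!is.numeric(th) || length(th) != 1L || th <= 0 || th > 1) {
    stop("th must lie in (0, 1]", call. = FALSE)
  }
  det <- as_complex_tbl(detected)
  ben <- as_complex_tbl(benchmark)
  if (nrow(ben) == 0L) stop("benchmark complex set is empty", call. = FALSE)
  nd <- nrow(det); nb <- nrow(ben)
  J <- matrix(0, nrow = nd, ncol = nb)
  if (nd > 0L) {
    for (i in seq_len(nd)) {
      J[i, ] <- vapply(ben$proteins, jaccard, numeric(1), c1 = det$proteins[[i]])
    }
  }
  det_matched <- if (nd > 0L) apply(J >= th, 1L, any) else logical()
  ben_matched <- if (nd > 0L) apply(J >= th, 2L, any) else rep(FALSE, nb)
  precision <- if (nd == 0L) 0 else mean(det_matched)
  recall <- mean(ben_matched)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1, th = th,
                 n_detected = nd, n_benchmark = nb,
                 detected = det, benchmark = ben, jaccard = J,
                 det_matched = det_matched, ben_matched = ben_matched),
            class = "complex_eval")
}

#' @export
print.complex_eval <- function(x, ...) {
  cat(sprintf("Complex detection evaluation (th = %.2f)\n", x$th))
  cat(sprintf("  detected: %d   benchmark: %d\n", x$n_detected, x$n_benchmark))
  cat(sprintf("  precision %.3f   recall %.3f   F-1 %.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Per-complex match table for an evaluation
#'
#' One row per detected complex with its best-matching benchmark complex and
#' the corresponding Jaccard score.
#'
#' @param x A `complex_eval` object.
#' @param ... Unused.
#' @return A tibble: `complex_id`, `size`, `matched`, `best_benchmark`,
#'   `best_jaccard`.
#' @export
tidy.complex_eval <- function(x, ...) {
  if (x$n_detected == 0L) {
    return(tibble::tibble(complex_id = integer(), size = integer(),
                          matched = logical(), best_benchmark = integer(),
                          best_jaccard = numeric()))
  }
  best <- apply(x$jaccard, 1L, which.max)
  tibble::tibble(
    complex_id = x$detected$complex_id,
    size = x$detected$size,
    matched = x$det_matched,
    best_benchmark = as.integer(best),
    best_jaccard = x$jaccard[cbind(seq_len(x$n_detected), best)]
  )
}

#' One-row evaluation summary
#'
#' @param x A `complex_eval` object.
#' @param ... Unused.
#' @return A one-row tibble: `precision`, `recall`, `f1`, `th`,
#'   `n_detected`, `n_benchmark`.
#' @export
glance.complex_eval <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall, f1 = x$f1,
                 th = x$th, n_detected = x$n_detected,
                 n_benchmark = x$n_benchmark)
}
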