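## Defined-formula utilities for downstream result tables: fold-change
## bucketing of a miRNome profile, three-list intersection, and
## fluorescence-trace normalization.

#' Classify miRNA fold changes into modulation buckets
#'
#' Fold change is the treated/untreated expression ratio. A miRNA is
#' up-regulated when `fc >= threshold`, down-regulated when
#' `1/fc >= threshold`; down-regulated miRNAs are split into a
#' moderate bucket (`1/fc` between `threshold` and `high`, inclusive
#' of both ends) and a strong bucket (`1/fc > high`). Everything else
#' is not modulated. Boundary values fall in the more extreme bucket.
#'
#' @param fc Numeric vector of fold changes, all > 0.
#' @param ids Optional identifiers (recycled names for the output).
#' @param threshold Modulation cutoff (default 2: two-fold).
#' @param high Cutoff separating moderate from strong down-regulation
#'   (default 3).
#' @return A `fc_classification`: `bucket` (factor per record with
#'   levels `not_modulated`, `up`, `down_mid`, `down_high`), `counts`,
#'   and `fractions` (summing to 1).
#' @examples
#' classify_fold_changes(c(2.5, 1.1, 0.4, 0.2))
#' @export
classify_fold_changes <- function(fc, ids = NULL, threshold = 2,
                                  high = 3) {
  stopifnot(is.numeric(fc), length(fc) >= 1L, threshold > 1, high >= threshold)
  if (any(!is.finite(fc)) || any(fc <= 0))
    stop("fold changes must be finite and > 0")
  inv <- 1 / fc
  bucket <- rep("not_modulated", length(fc))
  bucket[fc >= threshold] <- "up"
  bucket[inv >= threshold & inv <= high] <- "down_mid"
  bucket[inv > high] <- "down_high"
  bucket <- factor(bucket, levels = c("not_modulated", "up",
                                      "down_mid", "down_high"))
  if (!is.null(ids)) names(bucket) <- ids
  counts <- table(bucket)
  structure(list(bucket = bucket,
                 counts = as.vector(counts),
                 fractions = as.vector(counts) / length(fc),
                 levels = levels(bucket),
                 threshold = threshold, high = high),
            class = "fc_classification")
}

#' @export
print.fc_classification <- function(x, ...) {
  n <- sum(x$counts)
  for (i in seq_along(x$levels))
    cat(sprintf("  %-13s %5d (%.1f%%)\n", x$levels[i], x$counts[i],
                100 * x$fractions[i]))
  cat(sprintf("  total %d (FC threshold %g, strong-down > %g)\n",
              n, x$threshold, x$high))
  invisible(x)
}

#' Identifiers common to all three lists
#'
#' Set intersection of three identifier lists, order-stable by the
#' first list. The canonical use is intersecting a differential
#' miRNome list with a disease-associated list and a target-prediction
#' list to nominate a shared regulator.
#'
#' @param list1,list2,list3 Character vectors.
#' @return Character vector of identifiers present in all three, in
#'   `list1` order, without duplicates.
#' @examples
#' common_to_all(c("a", "b"), c("b", "c"), c("b", "d"))
#' @export
common_to_all <- function(list1, list2, list3) {
  out <- unique(list1)
  out[out %in% list2 & out %in% list3]
}

#' Normalize a fluorescence quench trace
#'
#' Converts a raw trace to percent signal variation relative to the
#' value at the moment of iodide addition:
#' `Fx(t) = ((F(t) - Fo) / Fo) * 100`, where `Fo = F[t0_index]`. The
#' normalized value at `t0_index` is 0 by construction, and the result
#' is invariant under rescaling the raw trace by any positive
#' constant.
#'
#' @param F Numeric vector, raw fluorescence values.
#' @param t0_index Index of the iodide-addition time point (defines
#'   `Fo`). Default 1.
#' @return Numeric vector `Fx`, same length as `F`.
#' @export
fx_normalize <- function(F, t0_index = 1L) {
  stopifnot(is.numeric(F), length(F) >= 1L)
  t0_index <- as.integer(t0_index)
  if (t0_index < 1L || t0_index > length(F))
    stop("t0_index out of range")
  Fo <- F[t0_index]
  if (!is.finite(Fo) || Fo == 0)
    stop("Fo (value at t0_index) must be nonzero")
  (F - Fo) / Fo * 100
}
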