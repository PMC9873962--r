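#' Average a stack of technical-replicate scans
#'
#' Spot intensities are read several times per array; the analysis works
#' on their arithmetic mean. All matrices in the stack must share
#' identical row and column labels.
#'
#' @param stack List of numeric matrices (or a single matrix, returned
#'   as-is after checks) with identical dimnames.
#' @return A matrix of element-wise means.
#' @examples
#' m <- matrix(c(40, 60), 1, 2, dimnames = list("mir", c("a", "b")))
#' averageReplicates(list(m, m + 20))
#' @export
averageReplicates <- function(stack) {
  if (is.matrix(stack)) stack <- list(stack)
  stopifnot(length(stack) >= 1L, all(vapply(stack, is.matrix, logical(1))))
  ref <- stack[[1L]]
  for (i in seq_along(stack)) {
    m <- stack[[i]]
    if (!identical(rownames(m), rownames(ref)))
      stop("replicate ", i, ": row labels differ from replicate 1")
    if (!identical(colnames(m), colnames(ref)))
      stop("replicate ", i, ": column labels differ from replicate 1")
  }
  Reduce(`+`, stack) / length(stack)
}

#' Filter miRNAs below the intensity floor
#'
#' Keeps exactly the miRNAs whose intensity is at or above the floor in
#' *all* samples (the floor is inclusive: a row minimum of exactly 50
#' is retained under the default). Row order is preserved. Arrays report
#' unreliable signal near background, so rows that dip below the floor in
#' any sample are excluded from screening.
#'
#' @param x A [MirnaArraySet-class].
#' @param floor Intensity floor in fluorescence units (default 50).
#' @return The filtered [MirnaArraySet-class]; warns (not errors) when no
#'   row survives.
#' @examples
#' m <- matrix(c(50, 120, 49.9, 120), 2, 2, byrow = TRUE,
#'             dimnames = list(c("keep", "drop"), c("s1", "s2")))
#' x <- MirnaArraySet(m, group = c("NHF", "AMHF"))
#' rownames(filterFloor(x, floor = 50))
#' @export
filterFloor <- function(x, floor = 50) {
  stopifnot(is(x, "MirnaArraySet"), floor >= 0)
  m <- intensities(x)
  keep <- apply(m, 1L, min) >= floor
  message(sprintf("filterFloor: %d of %d miRNAs at or above %g in all samples",
                  sum(keep), nrow(m), floor))
  if (!any(keep))
    warning("no miRNA passed the intensity floor of ", floor)
  x[keep, ]
}

#' Median-normalize sample columns
#'
#' Scales each sample column multiplicatively so its median intensity
#' equals a common target — by default the global median of the
#' pre-normalization column medians. This is the standard single-channel
#' median normalization: it removes per-array brightness differences
#' while preserving within-sample rank order and non-negativity.
#'
#' @param x A [MirnaArraySet-class] with at least one row.
#' @param target Numeric target median, or `NULL` (default) for the
#'   median of the column medians.
#' @return The normalized [MirnaArraySet-class]; the target used is
#'   stored in `metadata(x)$normalization_target`.
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6), 3, 2,
#'             dimnames = list(paste0("mir", 1:3), c("s1", "s2")))
#' x <- medianNormalize(MirnaArraySet(m, group = c("NHF", "AMHF")))
#' apply(intensities(x), 2, median)
#' @export
medianNormalize <- function(x, target = NULL) {
  stopifnot(is(x, "MirnaArraySet"))
  m <- intensities(x)
  if (nrow(m) == 0L) stop("cannot normalize an empty matrix")
  meds <- apply(m, 2L, median)
  if (any(meds == 0))
    stop("column(s) with median 0 cannot be scaled: ",
         paste(colnames(m)[meds == 0], collapse = ", "))
  if (is.null(target)) target <- median(meds)
  stopifnot(is.numeric(target), length(target) == 1L, target > 0)
  m <- sweep(m, 2L, target / meds, `*`)
  out <- MirnaArraySet(m, group = groupLabels(x))
  metadata(out)$normalization_target <- target
  out
}

#' Run the full preprocessing stage
#'
#' Convenience wrapper chaining technical-replicate averaging (when a
#' stack is supplied), the inclusive intensity floor and per-sample
#' median normalization, in that order.
#'
#' @param x A [MirnaArraySet-class], or a list of replicate matrices plus
#'   `group` when averaging is needed.
#' @param floor Intensity floor (default 50).
#' @param target Normalization target; `NULL` for the global median.
#' @param group Group labels, required only when `x` is a replicate stack.
#' @return A preprocessed [MirnaArraySet-class].
#' @export
preprocess <- function(x, floor = 50, target = NULL, group = NULL) {
  if (is.list(x) && !is(x, "MirnaArraySet")) {
    stopifnot(!is.null(group))
    x <- MirnaArraySet(averageReplicates(x), group = group)
  }
  medianNormalize(filterFloor(x, floor = floor), target = target)
}
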