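#' Match predicted cells to reference cells
#'
#' Uses the Cell Tracking Challenge majority criterion: a predicted cell S
#' matches a reference cell R iff it covers a strict majority of R's
#' pixels, `|R intersect S| > 0.5 |R|`. Each reference matches at most one
#' prediction (the majority winner is unique), but one prediction may
#' cover several references — those extra references are the "split"
#' events the DET measure penalizes.
#'
#' @param reference,predicted Integer label masks of the same shape.
#' @return A list of class `cell_matching`: `pairs` (two-column integer
#'   matrix, reference label / predicted label), `unmatched_refs`,
#'   `unmatched_preds` (integer vectors), and the per-pair intersection
#'   and union pixel counts `inter`, `union`.
#' @export
match_cells <- function(reference, predicted) {
  if (!identical(dim(reference), dim(predicted))) {
    stop("reference and predicted masks differ in shape")
  }
  rlabs <- sort(unique(reference[reference > 0]))
  plabs <- sort(unique(predicted[predicted > 0]))
  rarea <- tabulate(reference[reference > 0], nbins = max(reference, 1))
  parea <- tabulate(predicted[predicted > 0], nbins = max(predicted, 1))
  both <- reference > 0 & predicted > 0
  pairs <- NULL
  inter <- integer(0)
  uni <- integer(0)
  if (any(both)) {
    tab <- table(ref = reference[both], pred = predicted[both])
    rr <- as.integer(rownames(tab))
    pp <- as.integer(colnames(tab))
    for (i in seq_along(rr)) {
      ov <- as.integer(tab[i, ])
      hit <- which(ov > 0.5 * rarea[rr[i]])
      if (length(hit) == 1L) {
        pairs <- rbind(pairs, c(rr[i], pp[hit]))
        inter <- c(inter, ov[hit])
        uni <- c(uni, rarea[rr[i]] + parea[pp[hit]] - ov[hit])
      }
    }
  }
  matched_r <- if (is.null(pairs)) integer(0) else pairs[, 1]
  matched_p <- if (is.null(pairs)) integer(0) else unique(pairs[, 2])
  structure(list(
    pairs = if (is.null(pairs)) matrix(integer(0), 0, 2) else pairs,
    unmatched_refs = setdiff(rlabs, matched_r),
    unmatched_preds = setdiff(plabs, matched_p),
    inter = inter, union = uni,
    n_ref = length(rlabs), n_pred = length(plabs)
  ), class = "cell_matching")
}

#' Segmentation accuracy (SEG)
#'
#' Mean Jaccard index over all reference cells: each reference scores
#' `|R intersect S| / |R union S|` against its majority-matched prediction,
#' or 0 when no prediction covers a strict majority of it.
#'
#' @param reference,predicted Integer label masks of the same shape.
#' @return Scalar in \[0, 1\].
#' @export
seg_score <- function(reference, predicted) {
  m <- match_cells(reference, predicted)
  if (m$n_ref == 0L) stop("SEG is undefined for an empty reference mask")
  sum(m$inter / m$union) / m$n_ref
}

#' Detection accuracy (DET, AOGM-D)
#'
#' Counts the weighted graph edits turning the predicted detection graph
#' into the reference one: adding a missed reference node (weight
#' `w_false_negative`), deleting a spurious prediction (`w_false_positive`),
#' and splitting a prediction that covers several references
#' (`w_split` per extra reference beyond the first). Normalized by
#' AOGM-D0, the cost of building the reference graph from empty:
#' `DET = 1 - min(AOGM-D, AOGM-D0) / AOGM-D0`. Default weights are the
#' Cell Tracking Challenge reference values (10 / 1 / 5).
#'
#' @param reference,predicted Integer label masks of the same shape.
#' @param w_false_negative,w_false_positive,w_split Positive edit weights.
#' @return Scalar in \[0, 1\].
#' @export
det_score <- function(reference, predicted, w_false_negative = 10,
                      w_false_positive = 1, w_split = 5) {
  stopifnot(w_false_negative > 0, w_false_positive > 0, w_split > 0)
  m <- match_cells(reference, predicted)
  if (m$n_ref == 0L) stop("DET is undefined for an empty reference mask")
  n_fn <- length(m$unmatched_refs)
  n_fp <- length(m$unmatched_preds)
  n_split <- 0L
  if (nrow(m$pairs) > 0L) {
    per_pred <- table(m$pairs[, 2])
    n_split <- sum(pmax(as.integer(per_pred) - 1L, 0L))
  }
  aogm <- w_false_negative * n_fn + w_false_positive * n_fp +
    w_split * n_split
  aogm0 <- w_false_negative * m$n_ref
  1 - min(aogm, aogm0) / aogm0
}

#' Score a set of mask pairs
#'
#' @param references,predictions Lists of paired label masks.
#' @param ids Optional identifiers (defaults to the index).
#' @return A tibble with one row per pair (`id`, `seg`, `det`) — average
#'   the columns for suite-level scores.
#' @export
evaluate_masks <- function(references, predictions, ids = NULL) {
  stopifnot(length(references) == length(predictions))
  if (is.null(ids)) ids <- seq_along(references)
  tibble::tibble(
    id = ids,
    seg = mapply(seg_score, references, predictions),
    det = mapply(det_score, references, predictions)
  )
}
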