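#' Inbreeding coefficient from detected segments
#'
#' Total segment span over total reference length. Across a contiguity
#' ladder the denominator is always the intact reference's length (gap
#' insertion preserves coordinates), keeping comparisons fixed-denominator.
#'
#' @param segs a `roh_segments` (typically filtered to > 500 kb).
#' @param ref a `roh_reference`, or a total length in bases.
#' @return F_ROH as a fraction.
#' @export
f_roh <- function(segs, ref) {
  total <- if (inherits(ref, "roh_reference")) ref_total_len(ref) else ref
  if (nrow(segs) == 0L) return(0)
  sum(segment_span(segs)) / total
}

#' Signed relative error of a detected inbreeding coefficient
#'
#' `(detected - real) / real`.
#'
#' @param detected detected F_ROH.
#' @param real true F_ROH (> 0).
#' @return Signed fraction.
#' @export
f_roh_error_ratio <- function(detected, real) {
  if (real <= 0) stop_config("real F_ROH must be > 0")
  (detected - real) / real
}

roh_class_breaks <- c(0.5, 1, 5, 10, 25, Inf) * 1e6
roh_class_labels <- c("(0.5,1]", "(1,5]", "(5,10]", "(10,25]", ">25")

#' Count ROH segments per length class
#'
#' Classes (0.5,1], (1,5], (5,10], (10,25] and >25 Mb, left-open and
#' right-closed (a 5 Mb segment belongs to (1,5]).
#'
#' @param segs a `roh_segments`; every span must exceed 500 kb (filter
#'   first).
#' @return Named integer vector of counts over the five classes.
#' @export
length_class_table <- function(segs) {
  spans <- segment_span(segs)
  if (any(spans <= 5e5))
    stop_config("segments of 500 kb or less present; apply filter_min_length first")
  cls <- cut(spans, breaks = roh_class_breaks, labels = roh_class_labels,
             right = TRUE)
  table(cls)
}

#' Per-class correct-detection ratio of truth segments
#'
#' A truth segment counts as correctly detected iff the detected segments
#' cover at least `overlap_q` of its bases AND the union of the detected
#' segments overlapping it extends beyond it by no more than
#' `(1 - overlap_q)` of its length (a reciprocal-overlap convention; the
#' threshold is a reported setting, not an inference).
#'
#' @param truth truth interval data.frame (`contig`, `start`, `end`).
#' @param segs detected `roh_segments` (post-merge) for the same
#'   individual.
#' @param overlap_q overlap fraction in (0, 1].
#' @return List with `by_class` (named detection ratios over the truth
#'   length classes), `overall`, and `n_truth`.
#' @export
detection_ratio <- function(truth, segs, overlap_q = 0.9) {
  if (overlap_q <= 0 || overlap_q > 1)
    stop_config("overlap_q must be in (0,1]")
  n <- nrow(truth)
  detected <- logical(n)
  for (i in seq_len(n)) {
    tlen <- truth$end[i] - truth$start[i]
    d <- segs[segs$contig == truth$contig[i] &
                segs$end > truth$start[i] & segs$start < truth$end[i], ,
              drop = FALSE]
    if (nrow(d) == 0L) next
    cov <- sum(pmin(d$end, truth$end[i]) - pmax(d$start, truth$start[i]))
    ext <- sum(d$end - d$start) - cov
    detected[i] <- cov >= overlap_q * tlen && ext <= (1 - overlap_q) * tlen
  }
  tl <- truth$end - truth$start
  cls <- cut(tl, breaks = roh_class_breaks, labels = roh_class_labels,
             right = TRUE)
  by_class <- tapply(detected, cls, mean)
  list(by_class = by_class,
       overall = if (n) mean(detected) else NA_real_,
       n_truth = n)
}

#' Base-level Jaccard similarity of two interval sets
#'
#' Intersection over union of the base sets covered by two interval
#' data.frames (`contig`, `start`, `end`); the headline score for
#' truth-versus-detected ROH comparisons.
#'
#' @param a,b interval data.frames (0-based half-open).
#' @return Jaccard index in `[0, 1]` (1 when both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  inter <- intersect_len(a, b)
  uni <- interval_total_len(a) + interval_total_len(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Summarise one individual under one condition
#'
#' All per-individual summaries reported by the benchmark: F_ROH and its
#' signed error ratio, segment count, mean segment length, length-class
#' counts, detection ratios against truth, and (when a call set is given)
#' the SNP error ratio.
#'
#' @param segs detected `roh_segments` (post-merge, post-filter).
#' @param truth truth interval data.frame for the individual.
#' @param ref a `roh_reference` or total length in bases.
#' @param called optional `roh_calls` for the SNP error ratio.
#' @param vs optional truth `roh_variants` (required with `called`).
#' @param individual sample name (required with `called`).
#' @param overlap_q detection-ratio threshold.
#' @return A one-row data.frame of class `roh_metrics`.
#' @export
metrics_report <- function(segs, truth, ref, called = NULL, vs = NULL,
                           individual = NULL, overlap_q = 0.9) {
  total <- if (inherits(ref, "roh_reference")) ref_total_len(ref) else ref
  f_det <- f_roh(segs, total)
  f_real <- sum(truth$end - truth$start) / total
  cls <- if (nrow(segs)) length_class_table(segs) else
    setNames(rep(0L, 5), roh_class_labels)
  det <- detection_ratio(truth, segs, overlap_q)
  err <- if (!is.null(called)) snp_error_ratio(called, vs, individual) else
    list(error_ratio = NA_real_, missing_rate = NA_real_)
  out <- data.frame(
    f_roh_true = f_real,
    f_roh_detected = f_det,
    f_roh_error_ratio = if (f_real > 0) (f_det - f_real) / f_real else NA_real_,
    n_segments = nrow(segs),
    n_truth_segments = nrow(truth),
    mean_roh_len = if (nrow(segs)) mean(segment_span(segs)) else NA_real_,
    mean_roh_len_true = if (nrow(truth))
      mean(truth$end - truth$start) else NA_real_,
    total_roh_len = sum(segment_span(segs)),
    snp_error_ratio = err$error_ratio,
    snp_missing_rate = err$missing_rate,
    detection_ratio = det$overall,
    stringsAsFactors = FALSE)
  for (k in seq_along(roh_class_labels))
    out[[paste0("n_class_", k)]] <- as.integer(cls[[k]])
  class(out) <- c("roh_metrics", "data.frame")
  out
}
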