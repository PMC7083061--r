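# Quantitative evaluation protocol: T2 landmark distances (T2LDs) between
# superimposition results, pairwise operator differences, consensus truth,
# accuracy against truth, and the paired t-test comparing the automated
# method with hand tracing. A T2LD is the Euclidean distance (in mm)
# between the positions of the same T2 landmark under two different
# superimpositions onto the T1 template.

# Landmarks measured per superimposition type (the reported row sets).
EVAL_LANDMARKS <- list(
  cranial_base = c("Pt", "PNS", "ANS", "A", "B", "Me", "Go", "Co"),
  maxilla      = c("PNS", "ANS", "A", "UIE", "UIA", "UM", "UMA"),
  mandible     = c("B", "Pg", "Me", "Go", "Co", "LIE", "LIA", "LM", "LMA")
)

#' Landmarks evaluated for a superimposition region
#'
#' @param region region name.
#' @return Character vector of landmark abbreviations whose T2LDs are
#'   reported for that region.
#' @export
evaluation_landmarks <- function(region) {
  region <- match.arg(region, names(EVAL_LANDMARKS))
  EVAL_LANDMARKS[[region]]
}

#' Superimposed T2 landmarks in the T1 frame
#'
#' One superimposition result: T2 landmark coordinates after transfer onto
#' the T1 template, labelled with their source (an operator id or
#' `"automated"`).
#'
#' @param points two-column matrix of `(x, y)` pixel coordinates with
#'   landmark names as row names.
#' @param source label, e.g. `"op1"` or `"automated"`.
#' @param region region name.
#' @param mm_per_px calibration of the T1 frame.
#' @return An object of class `superimposed_landmarks`.
#' @export
superimposed_landmarks <- function(points, source, region,
                                   mm_per_px = DEFAULT_MM_PER_PX) {
  region <- match.arg(region, names(EVAL_LANDMARKS))
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2, !is.null(rownames(pts)), all(is.finite(pts)),
            mm_per_px > 0)
  colnames(pts) <- c("x", "y")
  structure(list(points = pts, source = source, region = region,
                 mm_per_px = mm_per_px),
            class = "superimposed_landmarks")
}

#' @export
print.superimposed_landmarks <- function(x, ...) {
  cat(sprintf("<superimposed_landmarks> %s / %s: %d landmarks\n",
              x$source, x$region, nrow(x$points)))
  invisible(x)
}

#' T2 landmark distances between two superimpositions
#'
#' Euclidean pixel distance per shared landmark, converted to mm by the
#' common calibration.
#'
#' @param a,b [superimposed_landmarks] of the same region and calibration.
#' @return Named numeric vector of distances in mm.
#' @export
t2ld <- function(a, b) {
  stopifnot(inherits(a, "superimposed_landmarks"),
            inherits(b, "superimposed_landmarks"))
  if (a$region != b$region) {
    stop("superimpositions belong to different regions", call. = FALSE)
  }
  if (abs(a$mm_per_px - b$mm_per_px) > 1e-12) {
    stop("calibration mismatch between superimpositions", call. = FALSE)
  }
  shared <- intersect(rownames(a$points), rownames(b$points))
  if (length(shared) == 0) {
    stop("no shared landmarks between superimpositions", call. = FALSE)
  }
  only_one <- union(setdiff(rownames(a$points), shared),
                    setdiff(rownames(b$points), shared))
  if (length(only_one) > 0) {
    message(sprintf("landmarks present in only one superimposition excluded: %s",
                    paste(only_one, collapse = ", ")))
  }
  d <- sqrt(rowSums((a$points[shared, , drop = FALSE] -
                     b$points[shared, , drop = FALSE])^2))
  setNames(d * a$mm_per_px, shared)
}

#' Pairwise operator differences in T2LD
#'
#' For every case and every unordered pair of operators, the per-landmark
#' T2LDs are pooled; with k operators and c complete cases each landmark
#' row holds `c * k(k-1)/2` values (three operators and 28 cases give 84).
#'
#' @param cases list of cases; each case is a list of
#'   [superimposed_landmarks], one per operator.
#' @return Data frame with columns `landmark`, `n`, `mean_mm`, `sd_mm`
#'   (sample SD, n-1 denominator).
#' @export
pairwise_operator_differences <- function(cases) {
  stopifnot(length(cases) >= 1)
  values <- list()
  for (ci in seq_along(cases)) {
    ops <- cases[[ci]]
    if (length(ops) < 2) {
      warning(sprintf("case %d has fewer than 2 operators; skipped", ci))
      next
    }
    pairs <- utils::combn(length(ops), 2)
    for (p in seq_len(ncol(pairs))) {
      d <- t2ld(ops[[pairs[1, p]]], ops[[pairs[2, p]]])
      for (nm in names(d)) values[[nm]] <- c(values[[nm]], d[[nm]])
    }
  }
  summarize_t2ld(values, grouping = "operator-pairwise")
}

summarize_t2ld <- function(values, grouping) {
  out <- data.frame(
    landmark = names(values),
    n = vapply(values, length, integer(1)),
    mean_mm = vapply(values, mean, numeric(1)),
    sd_mm = vapply(values, function(v) if (length(v) > 1) sd(v) else NA_real_,
                   numeric(1)),
    row.names = NULL
  )
  attr(out, "grouping") <- grouping
  out
}

#' Consensus truth from multiple operators
#'
#' Per-landmark coordinate-wise arithmetic mean of the operators'
#' positions; the averaged coordinates are taken as the true values against
#' which both hand and automated accuracies are measured.
#'
#' @param operators list of [superimposed_landmarks] (>= 2).
#' @return A [superimposed_landmarks] with source `"truth"`.
#' @export
consensus_truth <- function(operators) {
  stopifnot(length(operators) >= 2)
  shared <- Reduce(intersect, lapply(operators, function(o) rownames(o$points)))
  if (length(shared) == 0) stop("no landmark shared by all operators", call. = FALSE)
  dropped <- setdiff(unique(unlist(lapply(operators, function(o) rownames(o$points)))),
                     shared)
  if (length(dropped) > 0) {
    message(sprintf("landmarks not shared by all operators excluded: %s",
                    paste(dropped, collapse = ", ")))
  }
  acc <- Reduce(`+`, lapply(operators, function(o) o$points[shared, , drop = FALSE]))
  superimposed_landmarks(acc / length(operators), source = "truth",
                         region = operators[[1]]$region,
                         mm_per_px = operators[[1]]$mm_per_px)
}

#' Accuracy of a superimposition against consensus truth
#'
#' @param method a [superimposed_landmarks] (automated or one operator).
#' @param truth the consensus truth from [consensus_truth].
#' @return Named numeric vector of per-landmark distances in mm.
#' @export
accuracy_vs_truth <- function(method, truth) {
  t2ld(method, truth)
}

#' Paired t-test
#'
#' Classical paired t on the differences `x - y`, with the two-sided p-value
#' from the t distribution with n-1 degrees of freedom. Zero-variance
#' differences with nonzero mean report p as 0 (below machine epsilon); all
#' differences zero gives t = 0, p = 1.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return List with `t`, `p`, `n`, `mean_diff`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("paired t-test needs at least 2 pairs", call. = FALSE)
  d <- x - y
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (md == 0) return(list(t = 0, p = 1, n = n, mean_diff = 0))
    return(list(t = sign(md) * Inf, p = 0, n = n, mean_diff = md))
  }
  tstat <- md / (sdd / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  list(t = tstat, p = p, n = n, mean_diff = md)
}

#' Full evaluation report for one region
#'
#' Mirrors the reporting layout of the study protocol: per landmark, (i)
#' pairwise operator differences (n = cases x k(k-1)/2), (ii) hand accuracy
#' against consensus truth (per case the mean of the operators' distances;
#' n = cases), (iii) automated accuracy against truth (n = cases), and (iv)
#' the paired t-test comparing hand and automated accuracy across cases.
#'
#' @param automated list (one per case) of [superimposed_landmarks] from the
#'   automated pipeline.
#' @param operators list (one per case) of lists of [superimposed_landmarks]
#'   from the simulated or digitized operators.
#' @param pooling `"per-case"` (default: hand accuracy per case is the mean
#'   over operators, paired n = cases) or `"operator-replicated"` (each
#'   operator's accuracy kept as its own observation, paired against the
#'   replicated automated accuracy, n = cases x operators).
#' @return List of data frames `pairwise`, `accuracy`, `ttest`.
#' @export
evaluation_report <- function(automated, operators,
                              pooling = c("per-case", "operator-replicated")) {
  pooling <- match.arg(pooling)
  stopifnot(length(automated) == length(operators), length(automated) >= 1)
  n_cases <- length(automated)

  pairwise <- pairwise_operator_differences(operators)

  landmarks <- NULL
  hand_acc <- list()   # per landmark: per-case hand accuracy values
  auto_acc <- list()
  for (ci in seq_len(n_cases)) {
    truth <- consensus_truth(operators[[ci]])
    per_op <- lapply(operators[[ci]], accuracy_vs_truth, truth = truth)
    auto <- accuracy_vs_truth(automated[[ci]], truth)
    shared <- Reduce(intersect, c(lapply(per_op, names), list(names(auto))))
    landmarks <- union(landmarks, shared)
    for (nm in shared) {
      ops_nm <- vapply(per_op, function(v) v[[nm]], numeric(1))
      if (pooling == "per-case") {
        hand_acc[[nm]] <- c(hand_acc[[nm]], mean(ops_nm))
        auto_acc[[nm]] <- c(auto_acc[[nm]], auto[[nm]])
      } else {
        hand_acc[[nm]] <- c(hand_acc[[nm]], ops_nm)
        auto_acc[[nm]] <- c(auto_acc[[nm]], rep(auto[[nm]], length(ops_nm)))
      }
    }
  }

  accuracy <- data.frame(
    landmark = landmarks,
    n_hand = vapply(landmarks, function(nm) length(hand_acc[[nm]]), integer(1)),
    hand_mean_mm = vapply(landmarks, function(nm) mean(hand_acc[[nm]]), numeric(1)),
    hand_sd_mm = vapply(landmarks, function(nm) sd(hand_acc[[nm]]), numeric(1)),
    n_automated = vapply(landmarks, function(nm) length(auto_acc[[nm]]), integer(1)),
    automated_mean_mm = vapply(landmarks, function(nm) mean(auto_acc[[nm]]), numeric(1)),
    automated_sd_mm = vapply(landmarks, function(nm) sd(auto_acc[[nm]]), numeric(1)),
    row.names = NULL
  )

  ttest <- do.call(rbind, lapply(landmarks, function(nm) {
    h <- hand_acc[[nm]]; a <- auto_acc[[nm]]
    if (length(h) < 2) {
      return(data.frame(landmark = nm, n = length(h), t = NA_real_,
                        p = NA_real_, mean_diff_mm = NA_real_))
    }
    tt <- paired_t_test(h, a)
    data.frame(landmark = nm, n = tt$n, t = tt$t, p = tt$p,
               mean_diff_mm = tt$mean_diff)
  }))

  list(pairwise = pairwise, accuracy = accuracy, ttest = ttest)
}

#' Transfer T2 landmarks into the T1 frame with a superimposition result
#'
#' Applies the recovered T2 -> T1 transform to the measured T2 landmarks of
#' the region and returns them as a `superimposed_landmarks` labelled
#' `"automated"`.
#'
#' @param result a `superimposition` from [superimpose].
#' @param lm2 the T2 [landmark_set].
#' @param mm_per_px calibration of the T1 frame.
#' @return A [superimposed_landmarks].
#' @export
transfer_landmarks <- function(result, lm2, mm_per_px = DEFAULT_MM_PER_PX) {
  stopifnot(inherits(result, "superimposition"))
  keep <- intersect(EVAL_LANDMARKS[[result$region]], rownames(lm2))
  pts <- apply_to_points(result$transform, lm2[keep, , drop = FALSE])
  superimposed_landmarks(pts, source = "automated", region = result$region,
                         mm_per_px = mm_per_px)
}
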