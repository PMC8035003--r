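#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted one half:
#' the probability that a randomly chosen positive outscores a randomly
#' chosen negative.  Operating points are computed at every distinct score,
#' with the positive call made for scores \emph{strictly above} the
#' threshold (the same convention as [detect_af()]).
#'
#' @param scores numeric score vector.
#' @param labels class labels, same length as `scores`.
#' @param positive the label treated as positive; both classes must be
#'   present.
#' @return a `roc_summary`: `auc` and a data frame `operating_points` with
#'   columns `threshold`, `sensitivity`, `specificity`, `accuracy`.
#' @export
roc_auc <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present in the cohort")
  r <- rank(scores)                      # mid-ranks: ties count 1/2
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores))
  op <- t(vapply(thr, function(t) {
    call_pos <- scores > t
    tp <- sum(call_pos & pos); fp <- sum(call_pos & !pos)
    c(sensitivity = tp / n1,
      specificity = (n0 - fp) / n0,
      accuracy = (tp + (n0 - fp)) / (n1 + n0))
  }, c(sensitivity = 0.0, specificity = 0.0, accuracy = 0.0)))
  structure(list(auc = auc,
                 operating_points = data.frame(threshold = thr, op)),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  best <- x$operating_points[which.max(x$operating_points$accuracy), ]
  cat(sprintf("<roc_summary> AUC = %.4f (best accuracy %.4f at threshold %.4g)\n",
              x$auc, best$accuracy, best$threshold))
  invisible(x)
}

#' Kruskal-Wallis test with Dunn-type pairwise comparisons
#'
#' Overall Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()])
#' followed by pairwise Dunn comparisons on the pooled mid-ranks: for groups
#' i and j the statistic is the difference of mean ranks, its standard error
#' is \deqn{SE = \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12 (N - 1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}
#' (the sum running over tie groups), and the p-value comes from the normal
#' approximation with Bonferroni adjustment over all pairs — the
#' statistic/standard-error layout of standard post-hoc pairwise output.
#'
#' @param scores numeric vector.
#' @param labels group labels (>= 2 groups, each non-empty).
#' @return list with `H`, `df`, `p_overall`, and data frame `pairs`
#'   (`pair`, `statistic` = mean-rank difference, `std_error`, `z`,
#'   `p_adj`).
#' @export
kruskal_pairwise <- function(scores, labels) {
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) == 0L)) stop("every group must be non-empty")
  kw <- kruskal.test(scores, g)

  r <- rank(scores)
  N <- length(scores)
  tie_tab <- table(scores)
  tie_term <- sum(tie_tab^3 - tie_tab)
  var_fac <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  mean_r <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)

  lev <- levels(g)
  cmb <- utils::combn(seq_along(lev), 2L)
  n_pairs <- ncol(cmb)
  pairs <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    i <- cmb[1L, k]; j <- cmb[2L, k]
    diff_r <- unname(mean_r[i] - mean_r[j])
    se <- unname(sqrt(var_fac * (1 / n_g[i] + 1 / n_g[j])))
    z <- diff_r / se
    data.frame(pair = paste(lev[i], lev[j], sep = "-"),
               statistic = diff_r, std_error = se, z = z,
               p_adj = min(1, 2 * pnorm(-abs(z)) * n_pairs),
               row.names = NULL)
  }))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_overall = kw$p.value, pairs = pairs)
}

#' Screen candidate PRV indexes by AUC
#'
#' Computes the AUC of each candidate index for separating the positive
#' group and ranks them.  For orientation-ambiguous indexes (by default the
#' cosine index `d_c`, a similarity rather than a distance) both
#' orientations are evaluated and the better one is reported, flagged in
#' the `orientation` column.
#'
#' @param scores named list (or data frame) of equal-length score vectors,
#'   one per candidate index.
#' @param labels common label vector.
#' @param positive positive-class label.
#' @param two_sided names of indexes whose orientation is ambiguous.
#' @return data frame `(index, auc, auc_as_is, orientation)` sorted by
#'   decreasing `auc`, with the winning index name as attribute `"winner"`.
#' @export
screen_indexes <- function(scores, labels, positive, two_sided = "d_c") {
  scores <- as.list(scores)
  if (is.null(names(scores)) || any(names(scores) == ""))
    stop("candidate indexes must be named")
  len <- lengths(scores)
  if (any(len != length(labels)))
    stop("all candidate score vectors must match the label vector length")
  rows <- lapply(names(scores), function(nm) {
    a <- roc_auc(scores[[nm]], labels, positive)$auc
    if (nm %in% two_sided && (1 - a) > a) {
      data.frame(index = nm, auc = 1 - a, auc_as_is = a, orientation = "reversed")
    } else {
      data.frame(index = nm, auc = a, auc_as_is = a, orientation = "as-is")
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "winner") <- out$index[1L]
  out
}

#' Run the PRV pipeline over a training set
#'
#' Applies [measure_prv()] to every sample of a [generate_training_set()]
#' cohort and collects the three limb-distance indexes per sample.
#'
#' @param tset a `prv_training_set` (or any list of elements with a
#'   `series` and a `group`).
#' @param config a [prv_config()].
#' @param on_error `"na"` (default) records `NA` indexes for samples on
#'   which the pipeline degenerates — typically an extreme jitter-to-cycle
#'   ratio pushing the smeared second peak off the averaging frame —
#'   instead of aborting the whole cohort; `"stop"` propagates the error.
#' @return data frame with one row per sample: `id`, `group`, `d_e`, `d_m`,
#'   `d_c`, `n`, `n_averaged`.
#' @export
compute_indexes <- function(tset, config = prv_config(),
                            on_error = c("na", "stop")) {
  on_error <- match.arg(on_error)
  rows <- lapply(tset, function(s) {
    r <- if (on_error == "stop") measure_prv(s$series, config) else
      tryCatch(measure_prv(s$series, config), error = function(e) e)
    if (inherits(r, "error"))
      return(data.frame(id = s$series$id, group = s$group, d_e = NA_real_,
                        d_m = NA_real_, d_c = NA_real_, n = NA_integer_,
                        n_averaged = NA_integer_))
    data.frame(id = r$id, group = s$group, d_e = r$d_e, d_m = r$d_m,
               d_c = r$d_c, n = r$n, n_averaged = r$n_averaged)
  })
  do.call(rbind, rows)
}
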