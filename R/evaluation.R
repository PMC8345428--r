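#' Streamed pixel confusion counts
#'
#' Compares a predicted label mask against ground truth for one positive
#' label (PTC = 2 by default; all other labels count as negative) by
#' streaming over tile-sized blocks, so the counting loop never touches more
#' than one block pair at a time. Counts are exact.
#'
#' @param pred,truth integer label matrices of identical dimensions.
#' @param positive_label the positive class (default 2, PTC).
#' @param block_px block side used for streaming (default 1024).
#' @return an object of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth, positive_label = 2L,
                             block_px = 1024L) {
  if (!all(dim(pred) == dim(truth)))
    stop("prediction and truth masks differ in dimensions (",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"), ")")
  acc <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  nr <- nrow(pred); nc <- ncol(pred)
  for (r0 in seq(1L, nr, by = block_px)) {
    r1 <- min(nr, r0 + block_px - 1L)
    for (c0 in seq(1L, nc, by = block_px)) {
      c1 <- min(nc, c0 + block_px - 1L)
      p <- pred[r0:r1, c0:c1, drop = FALSE]
      t <- truth[r0:r1, c0:c1, drop = FALSE]
      storage.mode(p) <- "integer"; storage.mode(t) <- "integer"
      acc <- acc + confusion_block_cpp(p, t, as.integer(positive_label))
    }
  }
  structure(as.list(acc), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> tp=%g fp=%g fn=%g tn=%g (total %g px)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Segmentation metrics from confusion counts
#'
#' Accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`, recall `tp/(tp+fn)`,
#' F1 `2PR/(P+R)`, and Jaccard index `tp/(tp+fp+fn)`. Conventions for empty
#' denominators: when truth and prediction both contain zero positives
#' (a perfectly predicted all-background slide) precision, recall, F1 and
#' Jaccard are all 1; any other empty denominator yields 0. The identity
#' `f1 = 2 * jaccard / (1 + jaccard)` holds whenever both are defined.
#'
#' @param counts a [confusion_counts()] object (or list with tp/fp/fn/tn).
#' @param slide_id optional identifier carried into the record.
#' @return one-row data frame: `slide_id`, `accuracy`, `precision`,
#'   `recall`, `f1`, `jaccard`.
#' @export
seg_metrics <- function(counts, slide_id = NA_character_) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total <= 0) stop("no pixels to evaluate")
  if (tp + fp + fn == 0) {
    prec <- rec <- f1 <- jac <- 1
  } else {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec  <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1   <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    jac  <- tp / (tp + fp + fn)
  }
  data.frame(slide_id = slide_id, accuracy = (tp + tn) / total,
             precision = prec, recall = rec, f1 = f1, jaccard = jac,
             stringsAsFactors = FALSE)
}

#' Fisher's least-significant-difference test
#'
#' Post-hoc pairwise comparisons after a one-way ANOVA: the pooled
#' mean-square error with `N - k` degrees of freedom feeds unadjusted
#' pairwise t tests, `t = (m_I - m_J) / sqrt(MSE * (1/n_I + 1/n_J))`, with
#' two-sided p values and 95% confidence intervals
#' `diff +/- t(0.975, df) * SE`. Swapping a pair negates the difference and
#' mirrors the interval but leaves p unchanged.
#'
#' @param values numeric vector of per-slide metric values.
#' @param groups factor or character vector of method labels, same length.
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return data frame with one row per ordered method pair `(I, J)`,
#'   `I != J`: `group_i`, `group_j`, `mean_diff`, `std_error`, `t`, `df`,
#'   `p_value`, `ci_low`, `ci_high`. Attribute `degenerate` is `TRUE` when
#'   the pooled MSE is zero (p is then 0/1 by sign of the difference).
#' @examples
#' lsd_test(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
#' @export
lsd_test <- function(values, groups, conf_level = 0.95) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs at least two values")
  if (length(values) != length(groups))
    stop("values and groups differ in length")
  fit <- aov(values ~ groups)
  atab <- suppressWarnings(anova(fit))  # F-test warnings irrelevant; only MSE is used
  mse <- atab["Residuals", "Mean Sq"]
  df <- atab["Residuals", "Df"]
  degenerate <- mse <= .Machine$double.eps
  if (degenerate)
    warning("zero within-group variance; LSD p values are degenerate")
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  lev <- levels(groups)
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  rows <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (i == j) next
    diff <- means[[i]] - means[[j]]
    se <- sqrt(mse * (1 / ns[[i]] + 1 / ns[[j]]))
    tval <- if (se > 0) diff / se else ifelse(diff == 0, 0, sign(diff) * Inf)
    p <- if (se > 0) 2 * pt(-abs(tval), df) else ifelse(diff == 0, 1, 0)
    rows[[length(rows) + 1L]] <- data.frame(
      group_i = lev[i], group_j = lev[j], mean_diff = diff, std_error = se,
      t = tval, df = df, p_value = p,
      ci_low = diff - tcrit * se, ci_high = diff + tcrit * se,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "degenerate") <- degenerate
  out
}

#' Evaluate a cohort of segmentations
#'
#' Computes per-slide metrics for one or several methods, macro-averaged
#' summaries (per-slide metrics averaged across slides) overall and, when a
#' slide-type vector is given, stratified by type (e.g. FNA vs TP), plus the
#' Fisher's-LSD comparison table across methods for every metric.
#'
#' @param pred_sets either a named list of masks (one method) or a named
#'   list of methods, each a named list `slide_id -> predicted mask`.
#' @param truth_masks named list `slide_id -> truth mask`.
#' @param slide_type optional named character vector `slide_id -> type`.
#' @param positive_label positive class (default 2, PTC).
#' @param micro if `TRUE`, summaries pool pixels across slides
#'   (micro average) instead of averaging per-slide metrics.
#' @return list with `per_slide`, `summary`, and `lsd` (NULL with fewer than
#'   two methods) data frames.
#' @export
evaluate_cohort <- function(pred_sets, truth_masks, slide_type = NULL,
                            positive_label = 2L, micro = FALSE) {
  if (length(pred_sets) && is.matrix(pred_sets[[1]]))
    pred_sets <- list(method = pred_sets)
  ids <- names(truth_masks)
  if (is.null(ids)) stop("truth_masks must be a named list of slide masks")
  per <- list(); counts <- list()
  for (m in names(pred_sets)) {
    preds <- pred_sets[[m]]
    missing <- setdiff(ids, names(preds))
    if (length(missing))
      stop("method ", m, " is missing predictions for slide(s): ",
           paste(missing, collapse = ", "))
    for (id in ids) {
      cc <- confusion_counts(preds[[id]], truth_masks[[id]], positive_label)
      counts[[paste(m, id, sep = "\r")]] <- cc
      row <- seg_metrics(cc, slide_id = id)
      row$method <- m
      row$type <- if (!is.null(slide_type)) slide_type[[id]] else NA_character_
      per[[length(per) + 1L]] <- row
    }
  }
  per_slide <- do.call(rbind, per)
  per_slide <- per_slide[, c("method", "slide_id", "type", "accuracy",
                             "precision", "recall", "f1", "jaccard")]
  metrics <- c("accuracy", "precision", "recall", "f1", "jaccard")
  summarize <- function(rows, keys) {
    if (micro) {
      tot <- list(tp = 0, fp = 0, fn = 0, tn = 0)
      for (k in keys) for (f in names(tot))
        tot[[f]] <- tot[[f]] + counts[[k]][[f]]
      seg_metrics(tot)[, metrics]
    } else {
      as.data.frame(lapply(rows[metrics], mean))
    }
  }
  summaries <- list()
  cohorts <- "All"
  if (!is.null(slide_type)) cohorts <- c(cohorts, unique(unlist(slide_type)))
  for (m in names(pred_sets)) {
    for (co in cohorts) {
      sel <- per_slide$method == m &
        (co == "All" | (!is.na(per_slide$type) & per_slide$type == co))
      if (!any(sel)) next
      keys <- paste(m, per_slide$slide_id[sel], sep = "\r")
      s <- summarize(per_slide[sel, ], keys)
      summaries[[length(summaries) + 1L]] <-
        cbind(data.frame(method = m, cohort = co, n_slides = sum(sel),
                         stringsAsFactors = FALSE), s)
    }
  }
  lsd <- NULL
  if (length(pred_sets) >= 2L && all(table(per_slide$method) >= 2L)) {
    lsd <- do.call(rbind, lapply(metrics, function(mt) {
      out <- lsd_test(per_slide[[mt]], per_slide$method)
      cbind(data.frame(metric = mt, stringsAsFactors = FALSE), out)
    }))
  }
  list(per_slide = per_slide, summary = do.call(rbind, summaries), lsd = lsd)
}
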