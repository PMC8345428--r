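#' Split a slide cohort into training and testing sets
#'
#' Draws a reproducible train/test split, optionally stratified by slide
#' type (largest-remainder apportionment unless exact per-type counts are
#' given), and reports set sizes with rounded percentages. With 131 slides
#' and 28 in training this reproduces the 21% / 79% bookkeeping of a
#' 28-train / 103-test design.
#'
#' @param slide_ids character or integer identifiers.
#' @param n_train total number of training slides, or a named vector of
#'   per-type counts when `type` is given.
#' @param type optional vector of slide types (e.g. `"FNA"` / `"TP"`),
#'   parallel to `slide_ids`.
#' @param seed integer seed for the draw.
#' @return list with `train`, `test` (id vectors) and `summary` (data frame
#'   `set`, `n`, `pct` with `pct = round(100 * n / total)`).
#' @export
cohort_split <- function(slide_ids, n_train, type = NULL, seed = 1L) {
  n <- length(slide_ids)
  if (n < 2L) stop("need at least two slides")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  if (is.null(type)) {
    if (sum(n_train) >= n) stop("n_train must be smaller than the cohort")
    train <- slide_ids[sort(sample.int(n, sum(n_train)))]
  } else {
    if (length(type) != n) stop("type must parallel slide_ids")
    lev <- unique(type)
    if (!is.null(names(n_train))) {
      per <- n_train[lev]
      if (any(is.na(per))) stop("n_train names must cover every type")
    } else {
      # largest-remainder apportionment of a single total across types
      quota <- sum(n_train) * table(type)[lev] / n
      per <- floor(quota)
      rem <- sum(n_train) - sum(per)
      if (rem > 0) {
        ord <- order(quota - per, decreasing = TRUE)
        per[ord[seq_len(rem)]] <- per[ord[seq_len(rem)]] + 1
      }
    }
    train <- character(0)
    for (lv in lev) {
      ids <- slide_ids[type == lv]
      if (per[[lv]] > length(ids))
        stop("per-type training count exceeds available slides for ", lv)
      train <- c(train, as.character(ids[sort(sample.int(length(ids),
                                                         per[[lv]]))]))
    }
    train <- slide_ids[as.character(slide_ids) %in% train]
  }
  test <- slide_ids[!(slide_ids %in% train)]
  summary <- data.frame(
    set = c("train", "test"),
    n = c(length(train), length(test)),
    pct = c(round(100 * length(train) / n), round(100 * length(test) / n)))
  list(train = train, test = test, summary = summary)
}
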