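#' Published Sahel case-study confusion counts
#'
#' One-vs-rest confusion counts (TP, FP, FN, TN) per land-cover class for the
#' Sahel (Burkina Faso) 250 m case study -- 695,532 pixels evaluated against
#' a 2021 Sentinel-2 land-cover map -- for three segment sources: STiSeBS
#' superpixels (`"stisebs"`), SLIC-on-components superpixels (`"eslic"`),
#' and 1000 m low-resolution pixels (`"lr"`). The `precision`,
#' `sensitivity`, `f1` and `mcc` columns are the published 3-decimal values;
#' they can be recomputed from the counts with
#' [confusion_metrics_from_counts()].
#'
#' @param method optional filter: `"stisebs"`, `"eslic"` or `"lr"`.
#' @return a data frame with columns `method`, `class`, `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `sensitivity`, `f1`, `mcc`.
#' @export
sahel_confusion_counts <- function(method = NULL) {
  path <- system.file("extdata", "sahel_confusion_counts.csv",
                      package = "stisebs", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(method)) {
    method <- match.arg(method, c("stisebs", "eslic", "lr"))
    df <- df[df$method == method, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
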