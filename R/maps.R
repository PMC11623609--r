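#' Benjamini-Hochberg FDR threshold
#'
#' Step-up FDR correction. `NA` p-values are excluded from the correction and
#' stay `NA`; a unit is significant when its adjusted q-value is at most `q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @param q FDR level.
#' @return List with `q_values` (monotone BH-adjusted values) and `sig`
#'   (logical; `FALSE` where p is `NA`).
#' @examples
#' fdr_threshold(c(0.001, 0.01, 0.02, 0.04, 0.9), q = 0.05)$sig
#' @export
fdr_threshold <- function(p_values, q = 0.05) {
  qv <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  qv[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  list(q_values = qv, sig = !is.na(qv) & qv <= q)
}

# assemble the standard per-searchlight map table
#' @keywords internal
#' @noRd
brain_map <- function(stat, p, q_threshold) {
  fdr <- fdr_threshold(p, q_threshold)
  structure(
    data.frame(searchlight_id = seq_along(stat), stat = stat, p = p,
               q = fdr$q_values, sig = fdr$sig),
    class = c("brain_map", "data.frame"), q_threshold = q_threshold)
}

#' Write a per-searchlight statistic map as TSV
#'
#' Columns: `searchlight_id`, `stat`, `p`, `q`, `sig`.
#' @param map A `brain_map` data frame.
#' @param path TSV path.
#' @export
write_brainmap_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
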