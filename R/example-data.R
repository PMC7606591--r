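#' Example vertex count tables
#'
#' Loads the packaged example of overlap and volume-decomposition vertex
#' counts for a two-group cortical morphometry comparison at three
#' cluster-significance thresholds, in the nested-list form accepted by
#' [overlap_table_from_counts()] and
#' [decomposition_table_from_counts()]. Useful for exercising the table
#' arithmetic without running a full analysis.
#'
#' @return list with elements `overlap` (per threshold, per hemisphere
#'   `ct_only` / `sa_only` / `both` counts) and `decomposition` (per
#'   threshold, per direction, per hemisphere `cv_total` / `ct_only` /
#'   `sa_only` / `ct_and_sa` counts).
#' @examples
#' counts <- example_count_tables()
#' overlap_table_from_counts(counts$overlap[["p<0.05"]])
#' @export
example_count_tables <- function() {
  ov <- utils::read.csv(system.file("extdata",
                                    "example_overlap_counts.csv",
                                    package = "surfmorph"),
                        check.names = FALSE)
  dc <- utils::read.csv(system.file("extdata",
                                    "example_decomposition_counts.csv",
                                    package = "surfmorph"),
                        check.names = FALSE)
  overlap <- lapply(split(ov, ov$threshold), function(d) {
    out <- lapply(seq_len(nrow(d)), function(i) {
      c(ct_only = d$ct_only[i], sa_only = d$sa_only[i], both = d$both[i])
    })
    stats::setNames(out, d$hemisphere)
  })
  decomposition <- lapply(split(dc, dc$threshold), function(d) {
    dirs <- lapply(split(d, d$direction), function(dd) {
      out <- lapply(seq_len(nrow(dd)), function(i) {
        c(cv_total = dd$cv_total[i], ct_only = dd$ct_only[i],
          sa_only = dd$sa_only[i], ct_and_sa = dd$ct_and_sa[i])
      })
      stats::setNames(out, dd$hemisphere)
    })
    dirs[c("case_lt_control", "case_gt_control")]
  })
  list(overlap = overlap, decomposition = decomposition)
}
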