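# Bundled example data.

#' Per-category small-RNA filter counts for six goat skin libraries
#'
#' Published per-category filtered-read counts for six cashmere-goat skin
#' small-RNA libraries (three telogen samples T1-T3, three anagen samples
#' A1-A3). Each row carries the raw read total and the six filter-category
#' counts; the surviving high-quality count is not stored -- it is derived
#' through the accounting identity by [filter_report()].
#'
#' @return data.frame with columns `sample`, `total_reads` and one column
#'   per filter category.
#' @export
goat_filter_counts <- function() {
  utils::read.delim(system.file("extdata", "goat_srna_filter_counts.tsv",
                                package = "mirpair"),
                    stringsAsFactors = FALSE)
}
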