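#' Reference AML differentiation-state hierarchy counts
#'
#' Cell counts of the five leukemic differentiation states in the
#' single-cell reference cohort used to annotate spot-level hierarchies:
#' primitive-like (HSC-like plus common myeloid progenitor/lymphoid-primed
#' multipotent progenitor-like), GMP-like, erythroid-like, lymphoid-like,
#' and committed-like (monocyte-, basophil- and dendritic-cell-like), along
#' with the total leukemic cell count. Shipped as a plain-text table under
#' `inst/extdata/`.
#'
#' @return list: `states` (data frame state, n_cells for the five subsets),
#'   `total` (the reported leukemic cell total).
#' @export
#' @examples
#' h <- aml_hierarchy_counts()
#' sum(h$states$n_cells) == h$total
aml_hierarchy_counts <- function() {
  path <- system.file("extdata", "aml_hierarchy_counts.csv",
                      package = "spotniche", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  total <- df$n_cells[df$state == "AML_total"]
  states <- df[df$state != "AML_total", , drop = FALSE]
  rownames(states) <- NULL
  list(states = states, total = total)
}

#' Check the hierarchy bookkeeping
#'
#' Verifies that the five differentiation-state subset sizes sum exactly to
#' the leukemic cell total of the reference cohort.
#'
#' @return list: `subset_sum`, `total`, `consistent` (logical).
#' @export
check_hierarchy_counts <- function() {
  h <- aml_hierarchy_counts()
  s <- sum(h$states$n_cells)
  list(subset_sum = s, total = h$total, consistent = s == h$total)
}
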