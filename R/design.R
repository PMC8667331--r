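#' Two-group cohort design
#'
#' Assigns each profiled sample to the `case` or `control` group.
#'
#' @param sample_id character vector of unique sample ids.
#' @param group character vector of `"case"` / `"control"` labels.
#' @return a `cohort_design` data.frame with columns `sample_id`, `group`.
#' @export
cohort_design <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group))
    stop("'sample_id' and 'group' lengths differ")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in design")
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (sum(group == "case") < 2 || sum(group == "control") < 2)
    stop("need at least 2 samples per group")
  out <- data.frame(sample_id = sample_id, group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_design", "data.frame")
  out
}

# sample ids of one group, restricted (in order) to a reference sample set
group_samples <- function(design, group, within = NULL) {
  ids <- design$sample_id[design$group == group]
  if (!is.null(within)) ids <- intersect(within, ids)
  ids
}

check_design_covers <- function(design, sample_ids) {
  miss <- setdiff(sample_ids, design$sample_id)
  if (length(miss))
    stop("samples missing from the cohort design: ",
         paste(head(miss, 5), collapse = ", "))
  invisible(TRUE)
}
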