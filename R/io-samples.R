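#' Load a sample-metadata table
#'
#' Reads a TSV with at least `sample_id` and `collection_year`; any further
#' columns (e.g. `path`, `extraction_method`, `infection`) are carried
#' through as factor/annotation columns. Sample age is derived as
#' `reference_year - collection_year`. Rows with a missing collection year
#' are rejected with a message naming them; an age of exactly zero is
#' allowed but triggers a warning because such samples are excluded from
#' the decay regression downstream.
#'
#' @param tsv_path path to the sample table.
#' @param reference_year calendar year ages are measured against.
#' @return Tibble with `sample_id`, `collection_year`, `age`, and any extra
#'   columns from the file.
#' @export
load_sample_table <- function(tsv_path, reference_year) {
  tab <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  required <- c("sample_id", "collection_year")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop_bad_arg(paste0("sample table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  bad <- is.na(tab$collection_year)
  if (any(bad)) {
    inform(paste0("rejecting ", sum(bad), " sample(s) with missing collection year: ",
                  paste(tab$sample_id[bad], collapse = ", ")))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (anyDuplicated(tab$sample_id)) {
    stop_bad_arg("duplicate sample_id in sample table")
  }
  if (any(tab$collection_year > reference_year)) {
    stop_bad_arg("collection_year later than reference_year")
  }
  tab$age <- reference_year - tab$collection_year
  if (any(tab$age == 0)) {
    warn(paste0(sum(tab$age == 0), " sample(s) have age 0; they will be ",
                "excluded from the decay-rate regression"))
  }
  dplyr::relocate(as_tibble(tab), "sample_id", "collection_year", "age")
}
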