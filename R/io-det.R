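#' Read a differential-expression table for one timepoint
#'
#' Expects a tab-separated file with a one-line header providing the columns
#' `gene`, `comparison` (`proband_vs_mother` / `proband_vs_father`),
#' `log2fc` and `adjusted_p`. Duplicate (gene, comparison) rows — e.g.
#' transcript-level records mapped to one gene — are collapsed keeping the
#' smallest adjusted p-value.
#'
#' @param path Path to the table.
#' @param timepoint Which differentiation timepoint the table describes
#'   (`"d0"` undifferentiated or `"d25"` differentiated).
#' @return Tibble with columns `gene`, `comparison`, `log2fc`, `adjusted_p`,
#'   `timepoint`.
#' @export
read_det_table <- function(path, timepoint = c("d0", "d25")) {
  timepoint <- match.arg(timepoint)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("gene", "comparison", "log2fc", "adjusted_p")
  miss <- setdiff(required, names(tbl))
  if (length(miss) > 0) {
    stop("DET table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_cmp <- setdiff(unique(tbl$comparison), c("proband_vs_mother", "proband_vs_father"))
  if (length(bad_cmp) > 0) {
    stop("Unknown comparison value(s): ", paste(bad_cmp, collapse = ", "), call. = FALSE)
  }
  if (any(tbl$adjusted_p < 0 | tbl$adjusted_p > 1, na.rm = TRUE)) {
    stop("adjusted_p outside [0, 1] in ", path, call. = FALSE)
  }
  tbl |>
    dplyr::group_by(.data$gene, .data$comparison) |>
    dplyr::slice_min(.data$adjusted_p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(timepoint = timepoint) |>
    dplyr::select("gene", "comparison", "log2fc", "adjusted_p", "timepoint")
}
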