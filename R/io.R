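#' Write and read the registered curve matrix as wide CSV
#'
#' Columns `participant`, `day`, `day_order`, then `t1..tT`; missing cells
#' are empty fields. The missingness summary is written alongside as JSON.
#'
#' @param rm A `"registered_matrix"` from [build_matrix()].
#' @param path CSV path; the summary goes to `<path>_missingness.json`.
#' @return Invisibly, the CSV path.
#' @export
write_matrix_csv <- function(rm, path) {
  stopifnot(inherits(rm, "registered_matrix"))
  values <- rm$values
  colnames(values) <- paste0("t", seq_len(ncol(values)))
  utils::write.csv(cbind(rm$index, values), path, row.names = FALSE)
  ms <- rm$missingness
  jsonlite::write_json(
    list(n_rows = ms$n_rows, per_bout = ms$per_bout,
         mean_unregistered_rate = ms$mean_unregistered_rate,
         overall_missing_rate = ms$overall_missing_rate),
    sub("\\.csv$", "", path, ignore.case = TRUE) |>
      paste0("_missingness.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @param B Maximum bout length of the stored grid.
#' @export
read_matrix_csv <- function(path, B = 60L) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcols <- grep("^t[0-9]+$", names(d))
  values <- as.matrix(d[tcols])
  dimnames(values) <- NULL
  mask <- !is.na(values)
  structure(list(values = values, mask = mask,
                 index = d[setdiff(names(d), names(d)[tcols])],
                 missingness = missingness_summary(mask, B = B)),
            class = "registered_matrix")
}

#' Export level-1 scores for the association stage
#'
#' @param model Fitted `"mfpca_model"`.
#' @return Data frame `participant`, `PC1`, ..., `PCN1`.
#' @export
level1_scores <- function(model) {
  stopifnot(inherits(model, "mfpca_model"))
  data.frame(participant = rownames(model$scores1), model$scores1,
             row.names = NULL, stringsAsFactors = FALSE)
}
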