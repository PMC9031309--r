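# Plain-text I/O: TSV tables for colony measurements, scores, chase and Ct
# data; JSON for candidate reports.

#' Read / write a colony-size measurement table
#'
#' Tab-separated, columns `plate, row, col, gene, plasmid, condition,
#' replicate, day, colony_px`. Exported colony tables from plate-imaging
#' macros in the same schema are accepted directly.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_plate_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("plate", "gene", "plasmid", "condition", "replicate", "colony_px")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(tbl$colony_px < 0)) stop("colony_px must be >= 0")
  tbl
}

#' @rdname read_plate_table
#' @param table Measurement tibble (or a `screen_sim`, whose measurements
#'   are written).
#' @export
write_plate_table <- function(table, path) {
  if (inherits(table, "screen_sim")) table <- table$measurements
  readr::write_tsv(table, path)
  invisible(path)
}

#' Write a screen score table as TSV
#' @param scores Output of [score_screen()] or
#'   [call_condition_candidates()].
#' @param path File path.
#' @export
write_score_table <- function(scores, path) {
  readr::write_tsv(scores, path)
  invisible(path)
}

#' Write a candidate report as JSON
#' @param report Output of [candidate_report()].
#' @param path File path.
#' @export
write_candidate_report <- function(report, path) {
  report$venn <- rapply(report$venn, function(x) x, how = "replace")
  jsonlite::write_json(report, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read / write chase band tables (TSV)
#' @param path File path.
#' @return Tibble.
#' @export
read_chase_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_chase_table
#' @param table Chase tibble (or a `chase_sim`).
#' @export
write_chase_table <- function(table, path) {
  if (inherits(table, "chase_sim")) table <- table$measurements
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read / write Ct tables (TSV)
#' @param path File path.
#' @return Tibble with columns `strain, primer, bio_rep, tech_rep, ct`.
#' @export
read_ct_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("strain", "primer", "bio_rep", "tech_rep", "ct")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  tbl
}

#' @rdname read_ct_table
#' @param table Ct tibble (or a `qpcr_sim`).
#' @export
write_ct_table <- function(table, path) {
  if (inherits(table, "qpcr_sim")) table <- table$ct
  readr::write_tsv(table, path)
  invisible(path)
}
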