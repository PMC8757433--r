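# Reading and writing template sets. The interchange format is a CSV with a
# reaction_id column and one or more template_<level> columns holding
# reaction-SMARTS strings; parsed templates serialize to JSON lines.

.TEMPLATE_COLUMNS <- paste0("template_", c("r0", "r1", "r2", "r3", "default"))

#' Read a template table from CSV
#'
#' Expects a `reaction_id` column plus any subset of `template_r0`,
#' `template_r1`, `template_r2`, `template_r3`, `template_default` (an
#' optional `reaction_smiles` column is carried through untouched).
#'
#' @param path CSV file path
#' @return data.frame
#' @export
read_templates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"reaction_id" %in% names(df))
    stop("template CSV must have a reaction_id column")
  if (!any(.TEMPLATE_COLUMNS %in% names(df)))
    stop(sprintf("template CSV needs at least one of: %s",
                 paste(.TEMPLATE_COLUMNS, collapse = ", ")))
  df
}

#' Parse one level of a template table into template objects
#'
#' @param df template table (see [read_templates()])
#' @param level `"r0"`, `"r1"`, `"r2"`, `"r3"` or `"default"`
#' @param direction template direction
#' @return list of `rxn_template`, one per row, carrying the row's
#'   `reaction_id` as provenance
#' @export
template_records <- function(df, level, direction = "retro") {
  col <- paste0("template_", level)
  if (!col %in% names(df)) stop(sprintf("column %s not present", col))
  lapply(seq_len(nrow(df)), function(i) {
    parse_template(df[[col]][i], direction = direction, radius_tag = level,
                   reaction_ids = df$reaction_id[i])
  })
}

#' Parse every available level of a template table
#'
#' @inheritParams template_records
#' @return named list level -> list of `rxn_template`, suitable for
#'   [correct_hierarchically()]
#' @export
template_records_all <- function(df, direction = "retro") {
  lv <- sub("template_", "", intersect(.TEMPLATE_COLUMNS, names(df)))
  stats::setNames(lapply(lv, function(l) template_records(df, l, direction)), lv)
}

#' Write templates as JSON lines
#'
#' One JSON object per template: `template`, `direction`, `radius_tag`,
#' `reaction_ids`.
#'
#' @param ts list of `rxn_template`
#' @param path output file
#' @export
write_templates_jsonl <- function(ts, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (t in ts) {
    writeLines(jsonlite::toJSON(list(
      template = t$raw_string,
      direction = t$direction,
      radius_tag = t$radius_tag,
      reaction_ids = as.list(t$reaction_ids)
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read templates from JSON lines
#'
#' @param path file written by [write_templates_jsonl()]
#' @return list of `rxn_template`
#' @export
read_templates_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    rec <- jsonlite::fromJSON(line)
    parse_template(rec$template, direction = rec$direction,
                   radius_tag = if (is.null(rec$radius_tag) ||
                                    is.na(rec$radius_tag)) NA_character_
                                else rec$radius_tag,
                   reaction_ids = unlist(rec$reaction_ids))
  })
}
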