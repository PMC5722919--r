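#' Age conventions used throughout the package
#'
#' Fixed constants tying the three age scales together: rat postnatal day 0
#' is embryonic day 22 (so rat postconceptional day, pcd, runs continuously
#' through birth), human ages are postconceptional weeks (pcw, gestational
#' weeks minus an obstetric offset), mouse timings are mapped onto the rat
#' scale with the published linear conversion
#' `rat_day = 1.24 * mouse_day - 1.26`, and neural tube closure in humans
#' (4 pcw) anchors the "onset of neurogenesis" read-out of every fitted
#' regression.
#'
#' @param gestational_offset_weeks Weeks subtracted from gestational age
#'   (counted from the last menses) to obtain postconceptional age. The
#'   standard obstetric convention of 2 weeks is the default.
#' @return A list of class `age_conventions` with components
#'   `rat_birth_pcd` (22), `gestational_offset_weeks`, `mouse_to_rat_slope`
#'   (1.24), `mouse_to_rat_intercept` (-1.26) and
#'   `human_neural_tube_closure_pcw` (4).
#' @examples
#' conv <- age_conventions()
#' conv$rat_birth_pcd
#' @export
age_conventions <- function(gestational_offset_weeks = 2) {
  structure(
    list(
      rat_birth_pcd = 22,
      gestational_offset_weeks = gestational_offset_weeks,
      mouse_to_rat_slope = 1.24,
      mouse_to_rat_intercept = -1.26,
      human_neural_tube_closure_pcw = 4
    ),
    class = "age_conventions"
  )
}

REQUIRED_COLUMNS <- c("event_id", "name", "region", "human_pcw", "rat_pcd",
                      "mouse_derived")

#' Construct a validated developmental event table
#'
#' The observation unit is one developmental event: a milestone (chemical
#' marker onset, fibre innervation, structural change) with a comparable
#' timing in the human foetus (`human_pcw`, postconceptional weeks) and in
#' the rat (`rat_pcd`, postconceptional days). Each event carries the brain
#' region it belongs to; regions are the latent clustering units of the
#' mixture model, so all events of a region share one group.
#'
#' @param df A data.frame with columns `event_id` (unique positive integer),
#'   `name` (free text), `region` (non-empty label), `human_pcw` (> 0),
#'   `rat_pcd` (> 0) and `mouse_derived` (logical; `TRUE` when the rat
#'   timing was obtained through the mouse-to-rat conversion).
#' @return The data.frame, validated and classed `event_table`.
#' @seealso [read_event_table()], [filter_events()], [region_index()]
#' @export
event_table <- function(df) {
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          "devtrans_format_error")
  }
  df <- as.data.frame(df)[, REQUIRED_COLUMNS]
  df$event_id <- as.integer(df$event_id)
  df$name <- as.character(df$name)
  df$region <- as.character(df$region)
  df$human_pcw <- as.numeric(df$human_pcw)
  df$rat_pcd <- as.numeric(df$rat_pcd)
  df$mouse_derived <- as.logical(df$mouse_derived)
  if (nrow(df) > 0) {
    bad_time <- which(!is.finite(df$human_pcw) | !is.finite(df$rat_pcd))
    if (length(bad_time) > 0) {
      abort(sprintf("non-numeric timing in row(s): %s",
                    paste(bad_time, collapse = ", ")),
            "devtrans_parse_error")
    }
    bad <- which(df$human_pcw <= 0 | df$rat_pcd <= 0)
    if (length(bad) > 0) {
      abort(sprintf("non-positive timing in row(s): %s",
                    paste(bad, collapse = ", ")),
            "devtrans_validation_error")
    }
    if (any(is.na(df$region) | !nzchar(df$region))) {
      abort("empty region label(s) present", "devtrans_validation_error")
    }
    dup <- unique(df$event_id[duplicated(df$event_id)])
    if (length(dup) > 0) {
      rows <- which(df$event_id %in% dup)
      abort(sprintf("duplicate event_id(s) %s in rows %s",
                    paste(dup, collapse = ", "),
                    paste(rows, collapse = ", ")),
            "devtrans_integrity_error")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  df
}

#' Region index of an event table
#'
#' @param table An [event_table()].
#' @return Named list mapping each region label to the integer `event_id`s
#'   it contains, in table order; exactly the partition of events by region.
#' @export
region_index <- function(table) {
  split(table$event_id, factor(table$region, levels = unique(table$region)))
}

#' Read a developmental event table from CSV/TSV
#'
#' @param path Path to a delimited file with header columns
#'   `event_id,name,region,human_pcw,rat_pcd,mouse_derived`.
#' @param dialect `"csv"` or `"tsv"`; default guessed from the file
#'   extension (`.tsv`/`.tab` mean tab-separated).
#' @return A validated [event_table()].
#' @export
read_event_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "devtrans_io_error")
  }
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- switch(match.arg(dialect, c("csv", "tsv")), csv = ",", tsv = "\t")
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", stringsAsFactors = FALSE,
                           encoding = "UTF-8", comment.char = "")
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          "devtrans_format_error")
  }
  if (nrow(raw) > 0) {
    num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
    for (col in c("human_pcw", "rat_pcd")) {
      bad <- which(is.na(num(col)))
      if (length(bad) > 0) {
        abort(sprintf("non-numeric %s in data row(s): %s", col,
                      paste(bad, collapse = ", ")),
              "devtrans_parse_error")
      }
    }
    raw$human_pcw <- num("human_pcw")
    raw$rat_pcd <- num("rat_pcd")
    raw$event_id <- as.integer(raw$event_id)
    raw$mouse_derived <- as.logical(raw$mouse_derived)
  }
  event_table(raw)
}

#' Write an event table to CSV/TSV
#'
#' Round-trips with [read_event_table()]: integer ids exactly, timings to
#' full double precision.
#'
#' @param table An [event_table()].
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(table, path, dialect = c("csv", "tsv")) {
  sep <- switch(match.arg(dialect), csv = ",", tsv = "\t")
  out <- as.data.frame(table)
  out$human_pcw <- formatC(out$human_pcw, digits = 17, format = "g")
  out$rat_pcd <- formatC(out$rat_pcd, digits = 17, format = "g")
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a mouse developmental day to the rat scale
#'
#' Published linear conversion `rat_day = 1.24 * mouse_day - 1.26`, used when
#' a rat timing is unavailable and the corresponding mouse timing stands in.
#'
#' @param mouse_pcd Mouse postconceptional day(s), > 0.
#' @param conventions An [age_conventions()] object.
#' @return Rat postconceptional day(s).
#' @examples
#' mouse_to_rat(10)   # 11.14
#' @export
mouse_to_rat <- function(mouse_pcd, conventions = age_conventions()) {
  if (any(mouse_pcd <= 0)) {
    abort("mouse_pcd must be positive", "devtrans_domain_error")
  }
  conventions$mouse_to_rat_slope * mouse_pcd + conventions$mouse_to_rat_intercept
}

#' Inverse of the mouse-to-rat day conversion
#' @param rat_pcd Rat postconceptional day(s).
#' @param conventions An [age_conventions()] object.
#' @return Mouse postconceptional day(s).
#' @export
rat_to_mouse <- function(rat_pcd, conventions = age_conventions()) {
  (rat_pcd - conventions$mouse_to_rat_intercept) / conventions$mouse_to_rat_slope
}

#' Convert rat embryonic/postnatal day notation to postconceptional days
#'
#' Rat postnatal day 0 is defined as embryonic day 22, so `P d` maps to
#' pcd `22 + d` while `E d` is already a pcd.
#'
#' @param day Non-negative day number(s).
#' @param convention `"E"` (embryonic, insemination = E0) or `"P"`
#'   (postnatal).
#' @param conventions An [age_conventions()] object.
#' @return Rat postconceptional day(s).
#' @examples
#' rat_age_to_pcd(0, "P")   # 22
#' rat_age_to_pcd(15, "E")  # 15
#' @export
rat_age_to_pcd <- function(day, convention = c("E", "P"),
                           conventions = age_conventions()) {
  if (any(day < 0)) abort("day must be non-negative", "devtrans_domain_error")
  switch(match.arg(convention),
         E = day,
         P = conventions$rat_birth_pcd + day)
}

#' Convert human gestational weeks to postconceptional weeks
#'
#' Gestational age is counted from the last menses; subtracting the
#' conception offset (default 2 weeks) gives postconceptional age.
#'
#' @param gestational_week Gestational age in weeks, greater than the offset.
#' @param conventions An [age_conventions()] object.
#' @return Postconceptional week(s).
#' @export
gestational_week_to_pcw <- function(gestational_week,
                                    conventions = age_conventions()) {
  off <- conventions$gestational_offset_weeks
  if (any(gestational_week <= off)) {
    abort(sprintf("gestational week must exceed the offset (%g weeks)", off),
          "devtrans_domain_error")
  }
  gestational_week - off
}

#' Filter an event table by id range and exclusion set
#'
#' The analysis excludes birth-related events and restricts clustering to a
#' contiguous id range; this returns the sub-table containing exactly the
#' events in `keep_range` (when given) minus `exclude_ids`, preserving row
#' order. Unknown ids in `exclude_ids` produce a warning, not an error, so
#' one configuration runs unchanged on synthetic tables of any size.
#'
#' @param table An [event_table()].
#' @param exclude_ids Integer vector of event ids to drop (default none).
#' @param keep_range Optional length-2 inclusive id interval to keep.
#' @return A filtered [event_table()].
#' @examples
#' tab <- generate_dataset(study_design_config())$table
#' nrow(filter_events(tab, exclude_ids = c(47, 94)))      # 92
#' nrow(filter_events(tab, keep_range = c(1, 79)))        # 79
#' @export
filter_events <- function(table, exclude_ids = integer(0), keep_range = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(keep_range)) {
    stopifnot(length(keep_range) == 2)
    keep <- table$event_id >= keep_range[1] & table$event_id <= keep_range[2]
  }
  if (length(exclude_ids) > 0) {
    unknown <- setdiff(exclude_ids, table$event_id)
    if (length(unknown) > 0) {
      warning(sprintf("ignoring unknown event id(s) in exclusions: %s",
                      paste(unknown, collapse = ", ")))
    }
    keep <- keep & !(table$event_id %in% exclude_ids)
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}
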