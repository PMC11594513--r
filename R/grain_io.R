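#' Read a long-format table of individual grain weights
#'
#' Reads a CSV or TSV file in which each row is one threshed grain, carrying
#' its group labels (cultivar, seeding rate in kg/ha, weeks after heading)
#' and the identifier of the head (spike) it came from, plus the grain mass
#' in milligrams. The long one-row-per-grain layout is the canonical input;
#' wide or per-head layouts are rejected rather than guessed.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map optional named character vector mapping the canonical
#'   names (`cultivar`, `seeding_rate`, `wah`, `head_id`, `weight`) to the
#'   column names actually present in the file, e.g.
#'   `c(weight = "grain_mg")`. Unmapped canonical names are looked up
#'   verbatim.
#' @param delim field delimiter; `NULL` (default) sniffs `","` vs `"\t"`
#'   from the header line.
#' @param quiet suppress the row-count message.
#'
#' @return a `data.frame` with columns `cultivar` (character),
#'   `seeding_rate` (numeric, kg seed/ha), `wah` (integer weeks after
#'   heading), `head_id` (character) and `weight` (numeric, mg), one row per
#'   grain, input row order preserved.
#'
#' @details Validation is strict: every weight must be a finite positive
#'   number, `wah` a non-negative integer, and no group label may be missing.
#'   The first offending row is reported by its data row number (excluding
#'   the header).
#' @export
read_grain_table <- function(path, column_map = NULL, delim = NULL,
                             quiet = TRUE) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path)
  }
  if (file.size(path) == 0) {
    stop("input file is empty (zero bytes): ", path)
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (nrow(raw) == 0L) {
    stop("input file has a header but no data rows: ", path)
  }

  canonical <- c("cultivar", "seeding_rate", "wah", "head_id", "weight")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(!nzchar(names(column_map)))) {
      stop("column_map must be a named character vector")
    }
    unknown <- setdiff(names(column_map), canonical)
    if (length(unknown)) {
      stop("column_map names must be among {",
           paste(canonical, collapse = ", "), "}; got: ",
           paste(unknown, collapse = ", "))
    }
    map[names(column_map)] <- unname(column_map)
  }
  missing_cols <- map[!(map %in% names(raw))]
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(sprintf("'%s' (for %s)", missing_cols, names(missing_cols)),
               collapse = ", "))
  }

  out <- data.frame(
    cultivar     = as.character(raw[[map[["cultivar"]]]]),
    seeding_rate = suppressWarnings(as.numeric(raw[[map[["seeding_rate"]]]])),
    wah          = suppressWarnings(as.numeric(raw[[map[["wah"]]]])),
    head_id      = as.character(raw[[map[["head_id"]]]]),
    weight       = suppressWarnings(as.numeric(raw[[map[["weight"]]]])),
    stringsAsFactors = FALSE
  )
  validate_grain_records(out)
  out$wah <- as.integer(out$wah)
  if (!quiet) message("read ", nrow(out), " grain records from ", path)
  out
}

# invariant checks shared by the reader and the simulator
validate_grain_records <- function(df) {
  bad_row <- function(cond) if (any(cond)) which(cond)[1L] else 0L

  r <- bad_row(is.na(df$weight) | !is.finite(df$weight))
  if (r) stop("row ", r, ": weight is missing or non-numeric")
  r <- bad_row(df$weight <= 0)
  if (r) stop("row ", r, ": weight must be > 0 mg (got ", df$weight[r], ")")
  r <- bad_row(is.na(df$wah) | df$wah < 0 | df$wah != round(df$wah))
  if (r) stop("row ", r, ": wah must be a non-negative integer")
  r <- bad_row(is.na(df$seeding_rate) | df$seeding_rate <= 0)
  if (r) stop("row ", r, ": seeding_rate must be a positive number")
  r <- bad_row(is.na(df$cultivar) | !nzchar(df$cultivar) |
                 is.na(df$head_id) | !nzchar(df$head_id))
  if (r) stop("row ", r, ": missing cultivar or head_id label")
  invisible(df)
}

#' Write a result table as CSV with fixed numeric precision
#'
#' Serialises descriptive, model-selection, or component tables with all
#' non-integer numeric columns printed at a fixed number of decimals, so
#' that repeated runs produce byte-identical files.
#'
#' @param df non-empty data.frame of homogeneous records.
#' @param path output file path.
#' @param digits decimal places for non-integer numeric columns (default 3).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, digits = 3) {
  if (!is.data.frame(df) || nrow(df) == 0L || ncol(df) == 0L) {
    stop("refusing to write an empty table to ", path)
  }
  fmt <- df
  for (j in seq_along(fmt)) {
    col <- fmt[[j]]
    if (is.double(col)) {
      fmt[[j]] <- sprintf(paste0("%.", digits, "f"), col)
    }
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(fmt, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Split grain records into treatment groups
#'
#' A group is one (cultivar, seeding rate, weeks-after-heading) cell — the
#' unit on which one weight distribution is fitted. Groups are returned in
#' lexicographic order of (cultivar, seeding_rate, wah) so that downstream
#' iteration (and its log output) is deterministic.
#'
#' @param records data.frame from [read_grain_table()].
#' @return named list of data.frames; names are the group labels from
#'   [group_label()].
#' @export
split_groups <- function(records) {
  key <- group_label(records$cultivar, records$seeding_rate, records$wah)
  groups <- split(records, key)
  ord <- order(names(groups))
  groups[ord]
}

#' Canonical label for one treatment group
#'
#' @param cultivar cultivar code.
#' @param seeding_rate seeding rate in kg/ha.
#' @param wah weeks after heading.
#' @return character label, e.g. `"GW_150kg_4WAH"`.
#' @export
group_label <- function(cultivar, seeding_rate, wah) {
  sprintf("%s_%03dkg_%dWAH", cultivar, as.integer(round(seeding_rate)),
          as.integer(wah))
}
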