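#' Read a counting sheet from CSV
#'
#' Counting sheets are plain comma-delimited text with a header, in either
#' of two dialects. Long: one row per increment with columns `sample_id`,
#' `sample_type`, `round`, `increment_index`, `positives`. Wide: one row
#' per record with columns `sample_id`, `sample_type`, `round` and
#' `inc_001`, `inc_002`, ... (trailing empty cells allowed for shorter
#' records). Validation is strict: positives must be integers in 0--10,
#' increment indices contiguous from 1 within each record, sample types
#' one of `core_biopsy` / `surgical`, and duplicated increments are an
#' integrity error; offending rows are named in the error message.
#'
#' @param path Path to the CSV file.
#' @param dialect `"auto"` (default; detected from the header), `"long"`,
#'   or `"wide"`.
#' @return List of [counting_record()] objects.
#' @export
read_counting_sheet <- function(path, dialect = c("auto", "long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (dialect == "auto") {
    dialect <- if ("increment_index" %in% names(df)) "long"
               else if (any(grepl("^inc_\\d+$", names(df)))) "wide"
               else stop("cannot detect counting-sheet dialect from header of ", path,
                         call. = FALSE)
  }
  if (dialect == "long") read_long_sheet(df, path) else read_wide_sheet(df, path)
}

check_sheet_cols <- function(df, needed, path) {
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

check_positives <- function(x, rows, path) {
  bad <- which(is.na(x) | x != floor(x) | x < 0 | x > 10)
  if (length(bad)) {
    stop("positives outside 0-10 in ", path, " at data row(s): ",
         paste(rows[bad], collapse = ", "), call. = FALSE)
  }
}

check_sample_type <- function(x, path) {
  bad <- !x %in% c("core_biopsy", "surgical")
  if (any(bad)) {
    stop("invalid sample_type in ", path, ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
}

read_long_sheet <- function(df, path) {
  check_sheet_cols(df, c("sample_id", "sample_type", "round",
                         "increment_index", "positives"), path)
  check_sample_type(df$sample_type, path)
  check_positives(df$positives, seq_len(nrow(df)), path)
  key <- interaction(df$sample_id, df$sample_type, df$round, drop = TRUE)
  dup <- duplicated(data.frame(key, df$increment_index))
  if (any(dup)) {
    stop("duplicate (sample_id, round, increment_index) in ", path,
         " at data row(s): ", paste(which(dup), collapse = ", "), call. = FALSE)
  }
  lapply(split(df, key), function(g) {
    g <- g[order(g$increment_index), ]
    if (!identical(as.integer(g$increment_index), seq_len(nrow(g)))) {
      stop("increment_index not contiguous from 1 for sample '",
           g$sample_id[1], "' round ", g$round[1], " in ", path, call. = FALSE)
    }
    counting_record(g$sample_id[1], g$sample_type[1], g$round[1], g$positives)
  })
}

read_wide_sheet <- function(df, path) {
  check_sheet_cols(df, c("sample_id", "sample_type", "round"), path)
  check_sample_type(df$sample_type, path)
  inc_cols <- grep("^inc_\\d+$", names(df), value = TRUE)
  if (!length(inc_cols)) stop("no inc_* columns in ", path, call. = FALSE)
  inc_cols <- inc_cols[order(as.integer(sub("^inc_", "", inc_cols)))]
  key <- interaction(df$sample_id, df$sample_type, df$round, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, sample_type, round) rows in ", path, call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, inc_cols])
    keep <- which(!is.na(v))
    if (length(keep) && anyNA(v[seq_len(max(keep))])) {
      stop("internal gap in increments for sample '", df$sample_id[i],
           "' in ", path, call. = FALSE)
    }
    v <- v[keep]
    check_positives(v, rep(i, length(v)), path)
    counting_record(df$sample_id[i], df$sample_type[i], df$round[i], v)
  })
}

#' Write counting records to CSV
#'
#' Inverse of [read_counting_sheet()]; round-trips are lossless in both
#' dialects. Counts are stored as per-increment positives, never as
#' cumulative totals.
#'
#' @param records List of [counting_record()] objects.
#' @param path Output path.
#' @param dialect `"long"` (default) or `"wide"`.
#' @return Invisibly, `path`.
#' @export
write_counting_sheet <- function(records, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(is.list(records), all(vapply(records, inherits, logical(1), "counting_record")))
  if (dialect == "long") {
    df <- do.call(rbind, lapply(records, function(r) {
      data.frame(sample_id = r$sample_id, sample_type = r$sample_type,
                 round = r$round,
                 increment_index = seq_along(r$increments),
                 positives = r$increments, stringsAsFactors = FALSE)
    }))
    if (is.null(df)) {
      df <- data.frame(sample_id = character(), sample_type = character(),
                       round = integer(), increment_index = integer(),
                       positives = integer())
    }
  } else {
    width <- max(c(1L, vapply(records, function(r) length(r$increments), integer(1))))
    df <- do.call(rbind, lapply(records, function(r) {
      inc <- c(r$increments, rep(NA_integer_, width - length(r$increments)))
      row <- data.frame(sample_id = r$sample_id, sample_type = r$sample_type,
                        round = r$round, stringsAsFactors = FALSE)
      row[sprintf("inc_%03d", seq_len(width))] <- as.list(inc)
      row
    }))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pair core-biopsy and surgical records by sample id
#'
#' @param records List of [counting_record()] objects.
#' @param round If given, keep only records from that evaluation round.
#' @return List of [sample_pair()] objects; sample ids lacking exactly one
#'   record of each type are skipped with a message.
#' @export
pair_records <- function(records, round = NULL) {
  stopifnot(is.list(records))
  if (!is.null(round)) {
    records <- Filter(function(r) r$round == round, records)
  }
  ids <- vapply(records, `[[`, character(1), "sample_id")
  pairs <- list()
  for (id in unique(ids)) {
    grp <- records[ids == id]
    b <- Filter(function(r) r$sample_type == "core_biopsy", grp)
    s <- Filter(function(r) r$sample_type == "surgical", grp)
    if (length(b) == 1L && length(s) == 1L) {
      pairs[[id]] <- sample_pair(id, b[[1]], s[[1]])
    } else {
      message("sample '", id, "' skipped: needs exactly one record of each type",
              if (!is.null(round)) paste0(" in round ", round) else "")
    }
  }
  if (!length(pairs)) stop("no complete biopsy/surgical pairs found", call. = FALSE)
  unname(pairs)
}

#' Export a rejection table to CSV
#'
#' Writes columns `n`, `k_low`, `k_high`, `frac_low`, `frac_high`; absent
#' bounds become empty fields. Commented header lines record the null
#' proportion, per-test level and two-sided convention so the file is
#' self-describing.
#'
#' @param table A [build_rejection_table()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_rejection_table <- function(table, path) {
  stopifnot(inherits(table, "rejection_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# p0=%g alpha=%g convention=%s conf_level=%g",
                     attr(table, "p0"), attr(table, "alpha"),
                     attr(table, "convention"), attr(table, "conf_level")), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an analysis report to disk
#'
#' `cohort_report` objects are written either as a tidy CSV of one
#' statistic per row (exact values) or as the human-readable text summary;
#' data frames of sequential decisions (from [classify_records()]) are
#' written as CSV. Every file starts with commented header lines recording
#' the conventions in force, for auditability.
#'
#' @param report A [cohort_report()] object or a decisions data frame.
#' @param path Output path.
#' @param format `"csv"` (default) or `"text"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("csv", "text")) {
  format <- match.arg(format)
  if (inherits(report, "cohort_report")) {
    if (format == "text") {
      con <- file(path, "w")
      on.exit(close(con))
      sink(con)
      on.exit(sink(), add = TRUE, after = FALSE)
      print(report)
      return(invisible(path))
    }
    rows <- cohort_report_rows(report)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# n_cells=%d cutoff=%g n_pairs=%d zero_policy=%s two_sided=%s cutoff_rule=%s",
                       report$n_cells, report$cutoff, report$n_pairs,
                       report$zero_policy, report$conventions$two_sided,
                       gsub(" ", "_", report$conventions$cutoff_rule)), con)
    utils::write.csv(rows, con, row.names = FALSE, na = "")
    return(invisible(path))
  }
  if (is.data.frame(report)) {
    utils::write.csv(report, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  stop("unsupported report type: ", paste(class(report), collapse = "/"),
       call. = FALSE)
}

cohort_report_rows <- function(x) {
  tab <- x$table2x2
  data.frame(
    statistic = c("t_linear_mean_diff", "t_linear_ci_low", "t_linear_ci_high",
                  "t_linear_p", "gm_ratio", "gm_ratio_ci_low", "gm_ratio_ci_high",
                  "t_log_p", "wilcoxon_p", "mcnemar_b", "mcnemar_c", "mcnemar_p",
                  "table_low_low", "table_low_high", "table_high_low",
                  "table_high_high", "ba_linear_bias", "ba_linear_lower",
                  "ba_linear_upper", "ba_log_bias", "ba_log_lower", "ba_log_upper"),
    value = c(x$t_linear$mean_diff, x$t_linear$ci95, x$t_linear$p,
              x$t_log$gm_ratio, x$t_log$ci95, x$t_log$p, x$wilcoxon_p,
              x$mcnemar$b, x$mcnemar$c, x$mcnemar$p,
              tab["low", "low"], tab["low", "high"], tab["high", "low"],
              tab["high", "high"],
              x$bland_altman_linear$bias, x$bland_altman_linear$lower,
              x$bland_altman_linear$upper, x$bland_altman_log$bias,
              x$bland_altman_log$lower, x$bland_altman_log$upper))
}
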