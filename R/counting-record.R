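#' Construct a counting record
#'
#' A counting record holds one sample's Ki67 counting sheet: the ordered
#' sequence of Ki67-positive nuclei counted in consecutive blocks of 10
#' tumor cells, starting in the hotspot (the region of visibly elevated
#' proliferation, which is scored first). Counting order is preserved
#' because the cumulative positive fraction typically falls as counting
#' leaves the hotspot (the dilution effect); all downstream analyses derive
#' cumulative counts from the increments, never the reverse.
#'
#' @param sample_id Character scalar identifying the sample (also used to
#'   match core biopsy / surgical pairs).
#' @param sample_type One of `"core_biopsy"` or `"surgical"`.
#' @param round Evaluation round index (1 or 2; duplicate reads of the same
#'   slide are stored as separate rounds).
#' @param increments Integer vector of positives per 10-cell block, each in
#'   0--10, at most 100 blocks (1000 cells).
#' @return An object of class `"counting_record"`.
#' @examples
#' rec <- counting_record("S01", "core_biopsy", 1, rep(2L, 100))
#' total_cells(rec)
#' @export
counting_record <- function(sample_id, sample_type = c("core_biopsy", "surgical"),
                            round = 1L, increments = integer()) {
  sample_type <- match.arg(sample_type)
  if (length(sample_id) != 1L || is.na(sample_id)) {
    stop("'sample_id' must be a single non-missing value", call. = FALSE)
  }
  round <- as.integer(round)
  if (length(round) != 1L || is.na(round) || round < 1L) {
    stop("'round' must be a positive integer", call. = FALSE)
  }
  if (anyNA(increments) || any(increments != floor(increments))) {
    stop("'increments' must be whole numbers without missing values", call. = FALSE)
  }
  increments <- as.integer(increments)
  if (any(increments < 0L) || any(increments > 10L)) {
    bad <- which(increments < 0L | increments > 10L)
    stop("increment counts outside 0-10 at position(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(increments) > 100L) {
    stop("a counting record holds at most 100 increments (1000 cells)", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), sample_type = sample_type,
         round = round, increments = increments),
    class = "counting_record"
  )
}

#' @export
print.counting_record <- function(x, ...) {
  n <- total_cells(x)
  cat(sprintf("<counting_record> %s (%s, round %d): %d cells, %d positive (%.1f%%)\n",
              x$sample_id, x$sample_type, x$round, n, sum(x$increments),
              if (n > 0) 100 * sum(x$increments) / n else NA_real_))
  invisible(x)
}

#' Cells and cumulative positives of a counting record
#'
#' `total_cells()` returns the number of tumor cells covered by complete
#' increments; `cumulative_positives()` the running total of positive nuclei
#' after each 10-cell increment.
#'
#' @param record A [counting_record()].
#' @return An integer scalar (`total_cells`) or vector (`cumulative_positives`).
#' @export
total_cells <- function(record) {
  stopifnot(inherits(record, "counting_record"))
  10L * length(record$increments)
}

#' @rdname total_cells
#' @export
cumulative_positives <- function(record) {
  stopifnot(inherits(record, "counting_record"))
  cumsum(record$increments)
}

#' Pair a core biopsy with its surgical sample
#'
#' @param pair_id Identifier shared by the two records (one tumor).
#' @param biopsy A [counting_record()] with `sample_type = "core_biopsy"`.
#' @param surgical A [counting_record()] with `sample_type = "surgical"`.
#' @return An object of class `"sample_pair"`.
#' @export
sample_pair <- function(pair_id, biopsy, surgical) {
  stopifnot(inherits(biopsy, "counting_record"), inherits(surgical, "counting_record"))
  if (biopsy$sample_type != "core_biopsy") {
    stop("'biopsy' must have sample_type \"core_biopsy\"", call. = FALSE)
  }
  if (surgical$sample_type != "surgical") {
    stop("'surgical' must have sample_type \"surgical\"", call. = FALSE)
  }
  if (biopsy$round != surgical$round) {
    stop("paired records must come from the same evaluation round", call. = FALSE)
  }
  structure(list(pair_id = as.character(pair_id), biopsy = biopsy, surgical = surgical),
            class = "sample_pair")
}

#' @export
print.sample_pair <- function(x, ...) {
  cat(sprintf("<sample_pair> %s: biopsy %d cells, surgical %d cells (round %d)\n",
              x$pair_id, total_cells(x$biopsy), total_cells(x$surgical),
              x$biopsy$round))
  invisible(x)
}

#' Ki67 proliferation value over the first n cells
#'
#' Computes the Ki67 index (percent positive nuclei) over the first
#' `n_cells` cells of a record, i.e. over the hotspot-first prefix of the
#' counting sheet. The clinically used window sizes are 200 cells (roughly
#' one hotspot) and 1000 cells (the full sheet).
#'
#' @param record A [counting_record()].
#' @param n_cells Number of cells, a positive multiple of 10 not exceeding
#'   the record length.
#' @return The positive fraction on the 0--100 percent scale.
#' @examples
#' rec <- counting_record("S01", "core_biopsy", 1, rep(2L, 20))
#' proliferation_at(rec, 200)  # 20%
#' @export
proliferation_at <- function(record, n_cells) {
  stopifnot(inherits(record, "counting_record"))
  if (length(n_cells) != 1L || n_cells <= 0 || n_cells %% 10 != 0) {
    stop("'n_cells' must be a positive multiple of 10", call. = FALSE)
  }
  m <- n_cells / 10
  if (length(record$increments) < m) {
    stop(sprintf("record '%s' has only %d cells; %d requested",
                 record$sample_id, total_cells(record), n_cells), call. = FALSE)
  }
  100 * sum(record$increments[seq_len(m)]) / n_cells
}
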