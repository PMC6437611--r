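#' Respondent-driven sampling survey records
#'
#' An `rds_sample` is a tibble with one row per participant, ordered by
#' enrollment, carrying the recruitment links and self-reported network sizes
#' that the successive-sampling size model consumes. Required columns:
#'
#' * `id` (character): unique participant identifier.
#' * `recruiter_id` (character or `NA`): the recruiter's `id`; `NA` marks a
#'   seed.
#' * `enrollment_index` (integer): 1-based order of enrollment; a permutation
#'   of `1..n`.
#' * `degree_known` (integer or `NA`): how many eligible alters the
#'   participant knows.
#' * `degree_seen` (integer or `NA`): how many of those they have seen
#'   recently (the more restrictive follow-up question); must not exceed
#'   `degree_known`.
#' * `coupons_issued` (integer): recruitment coupons handed out.
#'
#' Optional columns `enrollment_date` (Date) and any simulation ground truth
#' (for example `true_visibility`) are carried along. Validation enforces
#' that recruitment links form a forest rooted at the seeds (no cycles, every
#' recruiter enrolled strictly earlier) and that no recruiter has more
#' recruits than coupons issued. A `wave` column (seed = 0, recruit =
#' recruiter's wave + 1) is computed on construction.
#'
#' @param x a data frame with the columns above.
#' @param label optional character label (population/city/year) stored as an
#'   attribute.
#' @return a tibble of class `rds_sample`, sorted by `enrollment_index`, with
#'   a `wave` column.
#' @export
rds_sample <- function(x, label = NULL) {
  x <- tibble::as_tibble(x)
  required <- c("id", "recruiter_id", "enrollment_index",
                "degree_known", "degree_seen", "coupons_issued")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "rdsize_error_missing_column")
  }
  if (nrow(x) < 1) {
    rlang::abort("an RDS sample needs at least one participant",
                 class = "rdsize_error_empty_sample")
  }
  x$id <- as.character(x$id)
  x$recruiter_id <- as.character(x$recruiter_id)
  x$enrollment_index <- as.integer(x$enrollment_index)
  x$degree_known <- as.integer(x$degree_known)
  x$degree_seen <- as.integer(x$degree_seen)
  x$coupons_issued <- as.integer(x$coupons_issued)

  if (anyDuplicated(x$id)) {
    rlang::abort(
      paste0("duplicate participant id(s): ",
             paste(unique(x$id[duplicated(x$id)]), collapse = ", ")),
      class = "rdsize_error_duplicate_id")
  }
  n <- nrow(x)
  if (!setequal(x$enrollment_index, seq_len(n))) {
    rlang::abort("enrollment_index must be a permutation of 1..n",
                 class = "rdsize_error_enrollment_index")
  }
  x <- dplyr::arrange(x, .data$enrollment_index)

  bad_deg <- which(!is.na(x$degree_seen) & !is.na(x$degree_known) &
                     x$degree_seen > x$degree_known)
  if (length(bad_deg) > 0) {
    rlang::abort(
      paste0("degree_seen exceeds degree_known for participant(s): ",
             paste(x$id[bad_deg], collapse = ", ")),
      class = "rdsize_error_degree")
  }
  neg <- which(!is.na(x$degree_known) & x$degree_known < 0 |
                 !is.na(x$degree_seen) & x$degree_seen < 0)
  if (length(neg) > 0) {
    rlang::abort("degrees must be non-negative",
                 class = "rdsize_error_degree")
  }

  is_seed <- is.na(x$recruiter_id)
  rec_pos <- match(x$recruiter_id, x$id)
  unknown <- which(!is_seed & is.na(rec_pos))
  if (length(unknown) > 0) {
    rlang::abort(
      paste0("recruiter_id not found in sample for participant(s): ",
             paste(x$id[unknown], collapse = ", ")),
      class = "rdsize_error_unknown_recruiter")
  }
  # recruiter enrolled strictly earlier; rows are sorted by enrollment_index
  # so this also rules out cycles (any cycle would need a non-increasing step)
  late <- which(!is_seed & rec_pos >= seq_len(n))
  if (length(late) > 0) {
    cyc <- which(!is_seed & rec_pos == seq_len(n)) # self-recruitment
    msg <- if (length(cyc) > 0) "cyclic recruitment" else
      "recruiter enrolled at or after recruit"
    rlang::abort(
      paste0(msg, " for participant(s): ", paste(x$id[late], collapse = ", ")),
      class = "rdsize_error_recruitment_order")
  }

  n_recruits <- table(factor(x$recruiter_id[!is_seed], levels = x$id))
  over <- which(as.integer(n_recruits) > x$coupons_issued)
  if (length(over) > 0) {
    rlang::abort(
      paste0("more recruits than coupons issued for participant(s): ",
             paste(x$id[over], collapse = ", ")),
      class = "rdsize_error_coupons")
  }

  # rows are in enrollment order and every recruiter precedes their recruit,
  # so a single forward pass assigns waves
  wave <- integer(n)
  for (i in seq_len(n)) {
    if (!is_seed[i]) wave[i] <- wave[rec_pos[i]] + 1L
  }
  x$wave <- wave

  class(x) <- c("rds_sample", class(x))
  attr(x, "label") <- label %||% attr(x, "label") %||% ""
  x
}

#' @export
print.rds_sample <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<rds_sample> n =", nrow(x),
      "| seeds =", sum(is.na(x$recruiter_id)),
      "| max wave =", max(x$wave),
      if (nzchar(lab %||% "")) paste("|", lab) else "", "\n")
  NextMethod()
}

#' Effective self-reported degree
#'
#' The degree used by the size model is the more restrictive of the two-part
#' network size elicitation: the number of eligible alters *seen recently*
#' when reported, otherwise the number *known*. Participants with neither
#' reported get `NA`; the model imputes their visibility from enrollment
#' order alone.
#'
#' @param x an `rds_sample`, or a data frame with `degree_known` and
#'   `degree_seen` columns.
#' @return integer vector of effective degrees (with `NA` for fully missing).
#' @examples
#' effective_degree(data.frame(degree_known = c(20, 5, NA),
#'                             degree_seen = c(8, NA, NA)))
#' @export
effective_degree <- function(x) {
  stopifnot(all(c("degree_known", "degree_seen") %in% names(x)))
  as.integer(ifelse(!is.na(x$degree_seen), x$degree_seen, x$degree_known))
}

#' Read and write RDS survey CSV files
#'
#' The canonical on-disk format is a UTF-8 CSV with header columns `id`,
#' `recruiter_id`, `enrollment_date` (optional, ISO), `degree_known`,
#' `degree_seen`, `coupons_issued`, and optionally `enrollment_index`. When
#' `enrollment_index` is absent, order is derived from `enrollment_date` with
#' ties broken by file row order (the likelihood needs only the order, not
#' the dates); absent both, file row order is used. A `dialect` mapping
#' renames non-standard column headers, e.g.
#' `c(id = "uid", degree_known = "netsize")`.
#'
#' @param path file path.
#' @param dialect named character vector mapping canonical column names to
#'   the names used in the file.
#' @param label optional sample label.
#' @return `read_rds_csv` returns an `rds_sample`; `write_rds_csv` invisibly
#'   returns `path`. A write followed by a read round-trips losslessly.
#' @export
read_rds_csv <- function(path, dialect = NULL, label = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path),
                 class = "rdsize_error_io")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (dialect[[canon]] %in% names(df)) {
        names(df)[names(df) == dialect[[canon]]] <- canon
      }
    }
  }
  if (!"enrollment_index" %in% names(df)) {
    if ("enrollment_date" %in% names(df)) {
      ord <- order(df$enrollment_date) # ties keep file order (stable sort)
      df$enrollment_index <- integer(nrow(df))
      df$enrollment_index[ord] <- seq_len(nrow(df))
    } else {
      df$enrollment_index <- seq_len(nrow(df))
    }
  }
  if (!"degree_seen" %in% names(df)) df$degree_seen <- NA_integer_
  rds_sample(df, label = label)
}

#' @param sample an `rds_sample`.
#' @rdname read_rds_csv
#' @export
write_rds_csv <- function(sample, path) {
  stopifnot(inherits(sample, "rds_sample"))
  out <- tibble::as_tibble(sample)
  out$wave <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
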