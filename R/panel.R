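# Panel data: construction, CSV input/output, follow-up selection and
# descriptive tables.
#
# A panel dataset is a data.frame with one row per individual and columns
#   id, <domain>_t0 ..., <domain>_t1 ..., days_between
# where every cell of the domain columns is one of "poor"/"fair"/"healthy".
# The domain registry travels with the object as an attribute.

#' Construct a panel dataset
#'
#' @param baseline,followup data.frames (or matrices) of level labels with
#'   one column per domain, one row per individual.
#' @param id character vector of unique individual identifiers; defaults to
#'   row numbers.
#' @param days_between non-negative integer days between the two
#'   observations per individual (optional, `NA` allowed).
#' @param domains domain registry.
#' @return a `panel_df`: a data.frame with columns `id`, `<domain>_t0`,
#'   `<domain>_t1`, `days_between` and attribute `domains`.
#' @export
#' @examples
#' b <- data.frame(sleep = c("poor", "fair"), distress = c("fair", "healthy"))
#' f <- data.frame(sleep = c("fair", "fair"), distress = c("healthy", "healthy"))
#' panel_dataset(b, f, domains = c("sleep", "distress"))
panel_dataset <- function(baseline, followup, id = NULL, days_between = NA_integer_,
                          domains = default_domains()) {
  domains <- check_registry(domains)
  baseline <- as.data.frame(baseline, stringsAsFactors = FALSE)
  followup <- as.data.frame(followup, stringsAsFactors = FALSE)
  if (!all(domains %in% names(baseline)) || !all(domains %in% names(followup))) {
    stop("baseline and followup must have one column per registered domain",
         call. = FALSE)
  }
  n <- nrow(baseline)
  if (n < 1L) stop("a panel dataset needs at least one record", call. = FALSE)
  if (nrow(followup) != n) stop("baseline and followup row counts differ", call. = FALSE)
  if (is.null(id)) id <- as.character(seq_len(n))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate individual_id values", call. = FALSE)
  days_between <- rep_len(as.integer(days_between), n)
  if (any(!is.na(days_between) & days_between < 0L)) {
    stop("days_between must be non-negative", call. = FALSE)
  }
  norm <- function(df) {
    out <- lapply(domains, function(d) code_level(level_code(df[[d]])))
    stats::setNames(as.data.frame(out, stringsAsFactors = FALSE), domains)
  }
  b <- norm(baseline)
  f <- norm(followup)
  names(b) <- paste0(domains, "_t0")
  names(f) <- paste0(domains, "_t1")
  out <- cbind(data.frame(id = id, stringsAsFactors = FALSE), b, f,
               data.frame(days_between = days_between))
  rownames(out) <- NULL
  attr(out, "domains") <- domains
  class(out) <- c("panel_df", "data.frame")
  out
}

#' Domain registry of a panel
#'
#' @param panel a `panel_df`.
#' @return character vector of domain names.
#' @export
panel_domains <- function(panel) {
  d <- attr(panel, "domains")
  if (is.null(d)) stop("not a panel_df: missing domain registry", call. = FALSE)
  d
}

#' @export
print.panel_df <- function(x, ...) {
  cat("<panel_df> ", nrow(x), " individuals, ",
      length(panel_domains(x)), " domains x 2 time points\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' Read a panel CSV
#'
#' Expects one row per individual with columns `<domain>_t0` and
#' `<domain>_t1` for every registered domain, plus optional `id` and
#' `days_between` columns. Level labels are matched case-insensitively.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @param domains domain registry the file must cover.
#' @return a [panel_dataset()] with rows in file order.
#' @export
read_panel_csv <- function(path, domains = default_domains()) {
  domains <- check_registry(domains)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- c(paste0(domains, "_t0"), paste0(domains, "_t1"))
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("panel CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in need) {
    key <- tolower(trimws(raw[[col]]))
    bad <- which(!(key %in% LEVELS))
    if (length(bad) > 0L) {
      stop(sprintf("unknown level label '%s' in column '%s' at data row %d",
                   raw[[col]][bad[1L]], col, bad[1L]), call. = FALSE)
    }
  }
  id <- if ("id" %in% names(raw)) raw[["id"]] else NULL
  days <- if ("days_between" %in% names(raw)) {
    suppressWarnings(as.integer(raw[["days_between"]]))
  } else NA_integer_
  b <- raw[paste0(domains, "_t0")]
  f <- raw[paste0(domains, "_t1")]
  names(b) <- domains
  names(f) <- domains
  panel_dataset(b, f, id = id, days_between = days, domains = domains)
}

#' Write a panel CSV
#'
#' Writes the documented dialect (lower-case levels, header, UTF-8). A
#' written file read back with [read_panel_csv()] reproduces the panel.
#'
#' @param panel a `panel_df`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select baseline and follow-up visits from a visit log
#'
#' The first visit per individual is the baseline; the follow-up is the
#' earliest later visit whose gap from baseline lies within
#' `[min_days, max_days]` (defaults 7 and 183 days, i.e. one week to six
#' months). Individuals without such a visit are dropped.
#'
#' @param visits data.frame with columns `id`, `day` (integer day offset or
#'   anything coercible to numeric days) and one column per registered
#'   domain; rows must be sorted by `day` within each individual.
#' @param min_days,max_days inclusive window bounds in days.
#' @param domains domain registry.
#' @return list with elements `panel` (a [panel_dataset()]) and `dropped`
#'   (number of individuals without an eligible follow-up).
#' @export
#' @examples
#' v <- data.frame(id = c(1, 1, 1), day = c(0, 3, 55),
#'                 sleep = c("poor", "poor", "fair"),
#'                 distress = c("fair", "fair", "healthy"))
#' select_followup(v, domains = c("sleep", "distress"))$panel$days_between
select_followup <- function(visits, min_days = 7L, max_days = 183L,
                            domains = default_domains()) {
  domains <- check_registry(domains)
  if (!(min_days < max_days)) stop("min_days must be < max_days", call. = FALSE)
  need <- c("id", "day", domains)
  missing_cols <- setdiff(need, names(visits))
  if (length(missing_cols) > 0L) {
    stop("visit table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  visits$id <- as.character(visits$id)
  visits$day <- as.numeric(visits$day)
  ids <- unique(visits$id)
  base_rows <- list()
  fup_rows <- list()
  keep_ids <- character(0)
  gaps <- integer(0)
  dropped <- 0L
  for (who in ids) {
    v <- visits[visits$id == who, , drop = FALSE]
    if (is.unsorted(v$day, strictly = FALSE)) {
      stop("visits for individual '", who, "' are not sorted by day", call. = FALSE)
    }
    gap <- v$day - v$day[1L]
    ok <- which(gap >= min_days & gap <= max_days)
    if (length(ok) == 0L) {
      dropped <- dropped + 1L
      next
    }
    pick <- ok[1L] # earliest eligible visit wins
    keep_ids <- c(keep_ids, who)
    gaps <- c(gaps, as.integer(gap[pick]))
    base_rows[[length(base_rows) + 1L]] <- v[1L, domains, drop = FALSE]
    fup_rows[[length(fup_rows) + 1L]] <- v[pick, domains, drop = FALSE]
  }
  if (length(keep_ids) == 0L) {
    stop("no individual has a follow-up visit within the window", call. = FALSE)
  }
  panel <- panel_dataset(do.call(rbind, base_rows), do.call(rbind, fup_rows),
                         id = keep_ids, days_between = gaps, domains = domains)
  list(panel = panel, dropped = dropped)
}

#' Per-domain, per-slice category counts
#'
#' @param panel a `panel_df`.
#' @return data.frame with columns `domain`, `slice` (`"baseline"` or
#'   `"followup"`), `poor`, `fair`, `healthy`; counts sum to `nrow(panel)`
#'   within each row.
#' @export
category_table <- function(panel) {
  domains <- panel_domains(panel)
  rows <- list()
  for (d in domains) {
    for (slice in c("baseline", "followup")) {
      col <- paste0(d, if (slice == "baseline") "_t0" else "_t1")
      cnt <- table(factor(panel[[col]], levels = LEVELS))
      rows[[length(rows) + 1L]] <- data.frame(
        domain = d, slice = slice,
        poor = as.integer(cnt[["poor"]]),
        fair = as.integer(cnt[["fair"]]),
        healthy = as.integer(cnt[["healthy"]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Encode a panel as an ordinal numeric matrix
#'
#' Columns follow the fixed node order of [node_names()] (all baseline
#' domains, then all follow-up domains); values are the ordinal codes
#' 0 (poor) < 1 (fair) < 2 (healthy) as reals.
#'
#' @param panel a `panel_df` with at least two records.
#' @return numeric matrix of dimension `n x (2 * n_domains)` with column
#'   names from [node_names()].
#' @export
ordinal_encode <- function(panel) {
  domains <- panel_domains(panel)
  if (nrow(panel) < 2L) stop("ordinal_encode needs at least 2 records", call. = FALSE)
  cols <- c(paste0(domains, "_t0"), paste0(domains, "_t1"))
  m <- vapply(cols, function(col) as.numeric(level_code(panel[[col]])),
              numeric(nrow(panel)))
  colnames(m) <- node_names(domains)
  m
}

# Extract the baseline profile state of one panel row.
baseline_state <- function(panel, row) {
  domains <- panel_domains(panel)
  vals <- vapply(domains, function(d) panel[[paste0(d, "_t0")]][row], character(1))
  profile_state(stats::setNames(vals, domains), domains = domains)
}

#' Empirical distribution of baseline states
#'
#' Tabulates the observed baseline profile states of a panel; weights are
#' empirical frequencies (they sum to 1). Used to marginalize rankings over
#' the baseline-state distribution.
#'
#' @param panel a `panel_df`.
#' @return data.frame with one column per domain (baseline levels), a
#'   `weight` column, and attribute `domains`; ordered by decreasing weight.
#' @export
baseline_state_weights <- function(panel) {
  domains <- panel_domains(panel)
  cols <- paste0(domains, "_t0")
  key <- do.call(paste, c(unname(as.data.frame(panel)[cols]), sep = "\r"))
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- domains
  out$weight <- as.numeric(tab) / nrow(panel)
  out <- out[order(-out$weight, do.call(paste, out[domains])), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "domains") <- domains
  out
}
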