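# Domain registry, ordinal levels and profile states.

# Ordinal level vocabulary: poor < fair < healthy, coded 0 < 1 < 2.
LEVELS <- c("poor", "fair", "healthy")
LEVEL_CODES <- c(poor = 0L, fair = 1L, healthy = 2L)

#' Ordinal level labels
#'
#' The three ordinal health-domain categories in increasing order of health:
#' `"poor" < "fair" < "healthy"`, with integer codes 0, 1, 2.
#'
#' @return character vector of the three level labels in ordinal order.
#' @export
#' @examples
#' levels_ordinal()
levels_ordinal <- function() LEVELS

#' Convert level labels to ordinal codes and back
#'
#' Labels are matched case-insensitively and surrounding whitespace is
#' ignored; codes are integers in `{0, 1, 2}` with `poor = 0 < fair = 1 <
#' healthy = 2`.
#'
#' @param label character vector of level labels.
#' @param code integer vector of ordinal codes.
#' @return `level_code()` returns integer codes; `code_level()` returns
#'   lower-case labels.
#' @export
#' @examples
#' level_code(c("Healthy", "poor"))
#' code_level(0:2)
level_code <- function(label) {
  key <- tolower(trimws(as.character(label)))
  out <- LEVEL_CODES[key]
  if (anyNA(out)) {
    bad <- unique(label[is.na(out)])
    stop("unknown level label(s): ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(LEVELS, collapse = ", "), ")",
         call. = FALSE)
  }
  unname(out)
}

#' @rdname level_code
#' @export
code_level <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code) | code < 0L | code > 2L)) {
    stop("ordinal codes must be integers in {0, 1, 2}", call. = FALSE)
  }
  LEVELS[code + 1L]
}

# Canonical seven-domain registry. The order is fixed and is used for
# deterministic tie-breaking throughout the package.
DEFAULT_DOMAINS <- c("functioning", "distress", "nutrition", "activity",
                     "sleep", "social", "substance")

#' Default domain registry
#'
#' The canonical seven health and well-being domains (personal functioning,
#' psychological distress, nutrition, physical activity, sleep, social
#' support, substance use). The registry is an ordered character vector; the
#' order is fixed and used for deterministic tie-breaking in rankings. Any
#' other registry (different names or length) is accepted by all functions
#' that take a `domains` argument.
#'
#' @return character vector of domain names.
#' @export
#' @examples
#' default_domains()
default_domains <- function() DEFAULT_DOMAINS

check_registry <- function(domains) {
  domains <- as.character(domains)
  if (length(domains) < 1L) stop("domain registry must be non-empty", call. = FALSE)
  if (anyDuplicated(domains)) stop("domain names must be unique", call. = FALSE)
  if (any(!nzchar(domains))) stop("domain names must be non-empty strings", call. = FALSE)
  domains
}

#' Names of the temporal variables for a registry
#'
#' Each domain appears at two time slices: baseline (`_t0`) and follow-up
#' (`_t1`). Node order is all baseline nodes in registry order, then all
#' follow-up nodes in registry order; this order is fixed and used for all
#' matrices in the package.
#'
#' @param domains character vector of domain names.
#' @return character vector of `2 * length(domains)` node names.
#' @export
#' @examples
#' node_names(c("sleep", "distress"))
node_names <- function(domains = default_domains()) {
  domains <- check_registry(domains)
  c(paste0(domains, "_t0"), paste0(domains, "_t1"))
}

# slice membership of nodes in node_names() order: 0 = baseline, 1 = followup
node_slices <- function(n_domains) {
  rep(c(0L, 1L), each = n_domains)
}

#' Construct a profile state
#'
#' A profile state assigns one ordinal level to every registered domain at a
#' single time point.
#'
#' @param ... named level labels, one per domain (e.g. `sleep = "poor"`), or
#'   a single named character vector.
#' @param domains domain registry the state must cover.
#' @return named character vector of lower-case levels in registry order,
#'   with class `"profile_state"`.
#' @export
#' @examples
#' profile_state(functioning = "poor", distress = "poor", nutrition = "fair",
#'               activity = "healthy", sleep = "fair", social = "poor",
#'               substance = "healthy")
profile_state <- function(..., domains = default_domains()) {
  domains <- check_registry(domains)
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1L]]))) {
    vals <- args[[1L]]
  } else {
    vals <- unlist(args)
  }
  if (is.null(names(vals)) || !setequal(names(vals), domains) ||
      anyDuplicated(names(vals))) {
    stop("a profile state must name every registered domain exactly once",
         call. = FALSE)
  }
  lv <- code_level(level_code(vals[domains])) # validates + normalizes case
  out <- stats::setNames(lv, domains)
  class(out) <- "profile_state"
  out
}

#' Profile state with all domains at one level
#'
#' @param level a single level label.
#' @param domains domain registry.
#' @return a [profile_state()].
#' @export
#' @examples
#' uniform_state("healthy")
uniform_state <- function(level, domains = default_domains()) {
  domains <- check_registry(domains)
  profile_state(stats::setNames(rep(level, length(domains)), domains),
                domains = domains)
}

#' @export
print.profile_state <- function(x, ...) {
  cat("<profile_state> ", paste(names(x), unclass(x), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

state_codes <- function(state) level_code(unclass(state))
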