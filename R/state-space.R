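#' Define the expanded disability state space
#'
#' Builds the state space of a disability process subject to resolution: a
#' latent absorbing resolved state `R`, a transient temporary non-disability
#' state `D0`, and `n_severity` increasing disability states `D1`, ...,
#' `Dm`. Disability severity changes only through adjacent states; `D0`
#' connects to `D1` and (when `resolution = TRUE`) to `R`. `R` has no outgoing
#' transitions. Both `R` and `D0` present as the observed code `"0"` ("no
#' disability"), which is therefore ambiguous; every disability state has its
#' own unambiguous code.
#'
#' @param n_severity Number of disability severity states `D1..Dm`
#'   (non-negative integer; `0` gives the two-state chain `D0 -> R`).
#' @param resolution Should the `D0 -> R` transition be allowed? Setting
#'   `FALSE` keeps `R` in the state space but makes it unreachable, which is
#'   the null model of "no resolution" used by [boundary_lrt()].
#' @return An object of class `resolution_space`: a list with `states`
#'   (ordered labels, `R` first), `transitions` (tibble of allowed ordered
#'   pairs), `n_severity` and `resolution`.
#' @examples
#' sp <- state_space(2)
#' sp$states
#' sp$transitions
#' @export
state_space <- function(n_severity = 2, resolution = TRUE) {
  if (length(n_severity) != 1L || is.na(n_severity) || n_severity < 0 ||
      n_severity != round(n_severity)) {
    stop("`n_severity` must be a single non-negative integer.", call. = FALSE)
  }
  n_severity <- as.integer(n_severity)
  states <- c("R", paste0("D", 0:n_severity))
  from <- character(0)
  to <- character(0)
  if (resolution) {
    from <- "D0"
    to <- "R"
  }
  if (n_severity >= 1) {
    for (k in seq_len(n_severity)) {
      lo <- paste0("D", k - 1L)
      hi <- paste0("D", k)
      from <- c(from, lo, hi)
      to <- c(to, hi, lo)
    }
  }
  structure(
    list(
      states = states,
      transitions = tibble::tibble(from = from, to = to),
      n_severity = n_severity,
      resolution = resolution
    ),
    class = "resolution_space"
  )
}

#' @exportS3Method base::print
print.resolution_space <- function(x, ...) {
  cat("<resolution_space> states:", paste(x$states, collapse = " "), "\n")
  cat("  transitions:",
      paste(transition_labels(x), collapse = ", "), "\n")
  cat("  observed code \"0\" maps to {R, D0}; \"Dk\" maps to {Dk}\n")
  invisible(x)
}

#' Labels of the allowed transitions
#'
#' @param space A [state_space()] object.
#' @return Character vector like `"D0->R"`, `"D0->D1"`, in the order used
#'   throughout the package (parameter vectors, fitted results).
#' @export
transition_labels <- function(space) {
  paste0(space$transitions$from, "->", space$transitions$to)
}

#' Latent states consistent with an observed code
#'
#' The observed code `"0"` (no disability) is the disjoint union of resolved
#' and temporary non-disability, so it maps to the censored set `{R, D0}`.
#' A latent state label used as a code (as in completely observed data) maps
#' to itself.
#'
#' @param code Character vector of observed codes.
#' @param space A [state_space()] object.
#' @return For a single code, a character vector of latent states; for
#'   several, a list of such vectors.
#' @examples
#' code_states("0", state_space(2))
#' code_states("D2", state_space(2))
#' @export
code_states <- function(code, space) {
  one <- function(cd) {
    if (identical(cd, "0")) return(c("R", "D0"))
    if (cd %in% space$states) return(cd)
    stop("Unknown state code: \"", cd, "\". Valid codes: ",
         paste(c("0", space$states), collapse = ", "), call. = FALSE)
  }
  if (length(code) == 1L) one(code) else lapply(code, one)
}

#' Observed code for a latent state
#'
#' Masks the latent labels the way a clinic record does: both `R` and `D0`
#' present as the code `"0"`, disability states keep their own label.
#'
#' @param state Character vector of latent state labels.
#' @return Character vector of observed codes.
#' @examples
#' mask_resolution(c("D0", "D1", "R", "R"))
#' @export
mask_resolution <- function(state) {
  ifelse(state %in% c("R", "D0"), "0", state)
}

state_index <- function(states, space) {
  i <- match(states, space$states)
  if (anyNA(i)) {
    stop("Unknown state label(s): ",
         paste(states[is.na(i)], collapse = ", "), call. = FALSE)
  }
  i
}
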