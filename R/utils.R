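# Internal helpers: typed error conditions and mixed-radix event indexing.

bn_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("bnsynth_", class), "bnsynth_error")))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min)
    bn_stop("invalid_argument", "`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

#' Enumerate the joint event space of a set of discrete ancestors
#'
#' Given the arities (state counts) of an ordered list of ancestor variables,
#' returns the number of joint ancestor events and an enumeration of all joint
#' assignments in canonical mixed-radix order: the first ancestor is the most
#' significant digit, states are 0-based, and event 1 is the all-zero
#' assignment. A root node (empty ancestor list) has exactly one event, the
#' empty assignment.
#'
#' @param arities integer vector of ancestor arities (each >= 2); may be empty.
#' @return A list with `count` (product of arities, 1 for a root) and
#'   `assignments`, a `count` x `length(arities)` integer matrix whose row i is
#'   the 0-based joint assignment with event index i.
#' @examples
#' ancestor_event_space(c(2, 3))$count  # 6
#' @export
ancestor_event_space <- function(arities) {
  arities <- as.integer(arities)
  if (length(arities) && any(is.na(arities) | arities < 2L))
    bn_stop("invalid_argument", "all ancestor arities must be integers >= 2")
  m <- as.integer(prod(arities))
  list(count = m, assignments = event_decode(seq_len(m), arities))
}

# 1-based event index -> 0-based assignment matrix (rows = events).
# First variable most significant.
event_decode <- function(idx, arities) {
  k <- length(arities)
  out <- matrix(0L, nrow = length(idx), ncol = k)
  if (k == 0L) return(out)
  rad <- rev(cumprod(rev(c(arities[-1L], 1L))))  # place value of each digit
  rem <- idx - 1L
  for (j in seq_len(k)) {
    out[, j] <- as.integer(rem %/% rad[j])
    rem <- rem %% rad[j]
  }
  out
}

# 0-based assignment matrix (or vector) -> 1-based event index.
event_encode <- function(states, arities) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  k <- length(arities)
  if (ncol(states) != k)
    bn_stop("invalid_argument", "assignment has %d entries, expected %d",
            ncol(states), k)
  if (k == 0L) return(rep(1L, nrow(states)))
  rad <- rev(cumprod(rev(c(arities[-1L], 1L))))
  as.integer(states %*% rad) + 1L
}
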