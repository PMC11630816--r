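# Bout segmentation and call-type transition statistics.
#
# The inter-call gap is silence: next onset minus previous offset. Calls
# separated by gaps under `max_gap` (default 0.320 s) belong to the same
# bout; transition probabilities are conditional relative frequencies of the
# following call's type given the preceding call's type.

#' Segment one session's calls into bouts
#'
#' Greedy left-to-right grouping: a new bout starts whenever the silent gap
#' to the previous call is `>= max_gap` (membership requires a gap strictly
#' under `max_gap`).
#'
#' @param records onset-sorted, non-overlapping `call_table` of one session.
#' @param max_gap bout-breaking gap, seconds (default 0.320).
#' @return data.frame with one row per bout: `bout`, `start`, `end`,
#'   `n_calls`, and list-column `call_ids`.
#' @export
segment_bouts <- function(records, max_gap = 0.320) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n == 0) {
    return(data.frame(bout = integer(), start = numeric(), end = numeric(),
                      n_calls = integer()))
  }
  if (is.unsorted(records$onset)) {
    stop_usv("records must be sorted by onset", class = "usv44_validation_error")
  }
  offs <- records$onset + records$duration
  gaps <- records$onset[-1] - offs[-n]
  if (any(gaps < 0)) {
    stop_usv("overlapping calls at row %d", which(gaps < 0)[1] + 1L,
             class = "usv44_validation_error")
  }
  bout_id <- cumsum(c(1L, as.integer(gaps >= max_gap)))
  idx <- split(seq_len(n), bout_id)
  out <- data.frame(
    bout = seq_along(idx),
    start = vapply(idx, function(i) records$onset[i[1]], numeric(1)),
    end = vapply(idx, function(i) offs[i[length(i)]], numeric(1)),
    n_calls = lengths(idx)
  )
  out$call_ids <- unname(lapply(idx, function(i) records$call_id[i]))
  rownames(out) <- NULL
  out
}

#' Call-type transition counts and probabilities
#'
#' Counts ordered within-session pairs of consecutive calls and normalizes
#' rows: `probabilities[i, j] = counts[i, j] / sum_j counts[i, j]`. Sessions
#' are processed independently (no cross-session pairs); counts are pooled
#' across sessions. Calls of type `unknown` break pairs: neither the pair
#' into nor out of an unknown call is counted.
#'
#' @param records typed `call_table` (possibly many sessions; grouped by
#'   `session_id`).
#' @param scope `"all"` counts every consecutive pair; `"within_bout"` only
#'   pairs whose silent gap is strictly under `max_gap`.
#' @param max_gap bout gap threshold, seconds.
#' @param types label set defining matrix order.
#' @return a list of class `transition_matrix` with `types`, `counts`
#'   (from x to), `probabilities` (row-normalized; `NaN` rows where a type
#'   has no outgoing pairs), and `n_pairs`.
#' @export
transition_matrix <- function(records, scope = c("all", "within_bout"),
                              max_gap = 0.320,
                              types = c("long22", "short22", "fifty", "fortyfour")) {
  scope <- match.arg(scope)
  records <- as.data.frame(records)
  counts <- matrix(0L, length(types), length(types),
                   dimnames = list(from = types, to = types))
  if (nrow(records) >= 2) {
    for (idx in split(seq_len(nrow(records)), records$session_id)) {
      s <- records[idx, , drop = FALSE]
      s <- s[order(s$onset), , drop = FALSE]
      if (nrow(s) < 2) next
      from <- s$call_type[-nrow(s)]
      to <- s$call_type[-1]
      ok <- from %in% types & to %in% types
      if (scope == "within_bout") {
        gaps <- s$onset[-1] - (s$onset + s$duration)[-nrow(s)]
        ok <- ok & gaps < max_gap
      }
      if (any(ok)) {
        tab <- table(factor(from[ok], levels = types),
                     factor(to[ok], levels = types))
        counts <- counts + as.matrix(tab)
      }
    }
  }
  rs <- rowSums(counts)
  probs <- counts / rs  # rows with no outgoing pairs become NaN (0/0)
  structure(list(types = types, counts = counts, probabilities = probs,
                 n_pairs = sum(counts)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Call-type transition matrix (", x$n_pairs, " pairs)\n", sep = "")
  print(round(x$probabilities, 3))
  invisible(x)
}
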