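#' ATN group labels
#'
#' The eight ATN profiles in canonical order (A varies slowest, then T,
#' then N). Labels use ASCII hyphens internally ("A-T-N-"); see
#' [pretty_label()] for display with true minus signs.
#'
#' @return Character vector of the 8 group labels.
#' @export
#' @examples
#' atn_labels()
atn_labels <- function() {
  out <- character(8L)
  i <- 1L
  for (a in c("-", "+")) for (t in c("-", "+")) for (n in c("-", "+")) {
    out[i] <- paste0("A", a, "T", t, "N", n)
    i <- i + 1L
  }
  out
}

#' Compose an ATN group label from three status flags
#'
#' @param a_positive,t_positive,n_positive Logical abnormality flags.
#' @return A label such as "A+T-N-".
#' @export
atn_label <- function(a_positive, t_positive, n_positive) {
  sgn <- function(x) ifelse(x, "+", "-")
  paste0("A", sgn(a_positive), "T", sgn(t_positive), "N", sgn(n_positive))
}

#' Pretty-print ATN labels with Unicode minus
#'
#' @param label Character vector of ASCII labels ("A-T-N-").
#' @return Labels with U+2212 minus signs (display only).
#' @export
pretty_label <- function(label) gsub("-", "−", label, fixed = TRUE)

#' The four AD-continuum ATN groups in ACH order
#'
#' The amyloid-cascade ordering: amyloid converts first, then tau, then
#' neurodegeneration.
#'
#' @return Character vector of 4 labels.
#' @export
ad_continuum_states <- function() {
  c("A-T-N-", "A+T-N-", "A+T+N-", "A+T+N+")
}

#' Construct a progression sequence over ATN groups
#'
#' @param name Sequence name (e.g. "ACH", "TAN", "P07").
#' @param states Character vector of 4 distinct ATN group labels in
#'   hypothesized order of disease progression.
#' @return A `group_sequence` object.
#' @export
group_sequence <- function(name, states) {
  stopifnot(is.character(name), length(name) == 1L)
  states <- as.character(states)
  if (length(states) != 4L) {
    stop("a progression sequence must have exactly 4 states", call. = FALSE)
  }
  bad <- setdiff(states, atn_labels())
  if (length(bad)) {
    stop("invalid ATN group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(states)) {
    stop("sequence states must be pairwise distinct", call. = FALSE)
  }
  structure(list(name = name, states = states), class = "group_sequence")
}

#' @export
print.group_sequence <- function(x, ...) {
  cat(x$name, ": ", paste(pretty_label(x$states), collapse = " ➔ "),
      "\n", sep = "")
  invisible(x)
}

#' Construct a named set of candidate sequences
#'
#' @param sequences List of [group_sequence()] objects.
#' @param reference Name of the reference sequence (must be in the set).
#' @return A `sequence_set` object (named list plus reference attribute).
#' @export
sequence_set <- function(sequences, reference = "ACH") {
  nm <- vapply(sequences, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("sequence names must be unique", call. = FALSE)
  names(sequences) <- nm
  if (!reference %in% nm) {
    stop("reference sequence '", reference, "' not in set", call. = FALSE)
  }
  structure(sequences, class = "sequence_set", reference = reference)
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set of", length(x), "sequences (reference:",
      attr(x, "reference"), ")\n")
  for (s in x) print(s)
  invisible(x)
}

#' Expand a biomarker-conversion order into its 4-state sequence
#'
#' A conversion order such as "TAN" means: the tau category becomes
#' abnormal first, amyloid second, neurodegeneration last. The expansion
#' starts at A-T-N- and flips one category per step, ending at A+T+N+.
#'
#' @param order A 3-character permutation of "ATN".
#' @return A [group_sequence()] named after the order.
#' @export
#' @examples
#' expand_order("TAN")
expand_order <- function(order) {
  stopifnot(is.character(order), length(order) == 1L)
  chars <- strsplit(order, "")[[1L]]
  if (length(chars) != 3L || !setequal(chars, c("A", "T", "N")) ||
      anyDuplicated(chars)) {
    stop("order must be a permutation of \"ATN\", got \"", order, "\"",
         call. = FALSE)
  }
  flags <- c(A = FALSE, T = FALSE, N = FALSE)
  states <- atn_label(flags["A"], flags["T"], flags["N"])
  for (ch in chars) {
    flags[ch] <- TRUE
    states <- c(states, atn_label(flags["A"], flags["T"], flags["N"]))
  }
  group_sequence(order, states)
}

#' All 24 orderings of the AD-continuum groups
#'
#' Enumerates every permutation of the four AD-continuum states
#' (A-T-N-, A+T-N-, A+T+N-, A+T+N+). The ACH ordering is listed first and
#' is the reference; the 23 alternatives follow in lexicographic order of
#' their state indices and are named "P01".."P23". Two permutations
#' highlighted in the literature carry aliases: "AP1"
#' (A+T-N- > A+T+N- > A-T-N- > A+T+N+) and "AP2"
#' (A+T-N- > A-T-N- > A+T+N- > A+T+N+); the alias map is stored in the
#' `aliases` attribute.
#'
#' @return A [sequence_set()] of 24 sequences, reference "ACH".
#' @export
permutation_sequences <- function() {
  states <- ad_continuum_states()
  perms <- permutations_of(4L)          # lex order; first row is 1,2,3,4
  seqs <- vector("list", nrow(perms))
  alt <- 0L
  for (i in seq_len(nrow(perms))) {
    nm <- if (i == 1L) "ACH" else sprintf("P%02d", {alt <- alt + 1L; alt})
    seqs[[i]] <- group_sequence(nm, states[perms[i, ]])
  }
  out <- sequence_set(seqs, reference = "ACH")
  attr(out, "aliases") <- c(
    AP1 = find_sequence(out, states[c(2L, 3L, 1L, 4L)]),
    AP2 = find_sequence(out, states[c(2L, 1L, 3L, 4L)])
  )
  out
}

#' The 6 three-step conversion paths from no pathology to full pathology
#'
#' All conceivable ways to convert from A-T-N- to A+T+N+ flipping exactly
#' one biomarker category per step, named by conversion order:
#' ACH (= ATN order), ANT, TAN, TNA, NAT, NTA.
#'
#' @return A [sequence_set()] of 6 sequences, reference "ACH".
#' @export
conversion_paths <- function() {
  orders <- c("ATN", "ANT", "TAN", "TNA", "NAT", "NTA")
  seqs <- lapply(orders, expand_order)
  seqs[[1L]]$name <- "ACH"   # the ATN order is the amyloid-cascade path
  sequence_set(seqs, reference = "ACH")
}

#' Resolve a sequence set choice from configuration
#'
#' @param choice "permutations24", "paths6", or a [sequence_set()].
#' @return A [sequence_set()].
#' @export
resolve_sequences <- function(choice) {
  if (inherits(choice, "sequence_set")) return(choice)
  switch(as.character(choice),
    permutations24 = permutation_sequences(),
    paths6 = conversion_paths(),
    stop("unknown sequence set '", choice,
         "' (use \"permutations24\", \"paths6\", or a sequence_set)",
         call. = FALSE)
  )
}

#' Serialize a sequence set to JSON
#'
#' @param x A [sequence_set()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON text (invisibly when written to `path`).
#' @export
sequences_to_json <- function(x, path = NULL) {
  lst <- lapply(unname(x), function(s) list(name = s$name, states = s$states))
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# all permutations of 1..n in lexicographic order (n small)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# name of the sequence in `set` whose states equal `states`, or NA
find_sequence <- function(set, states) {
  for (s in set) if (identical(s$states, states)) return(s$name)
  NA_character_
}
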