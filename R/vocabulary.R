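#' Interaction vocabulary
#'
#' The controlled vocabulary of interaction terms understood by the simulator,
#' together with the effect, strength class and signed numeric weight each
#' term maps to. Activating edges carry positive weights, inhibitory edges
#' negative weights, and `binds` edges (physical association without an effect
#' on activity) carry weight zero. Strength classes map to weight magnitudes
#' weak = 0.5, standard = 1.0, strong = 1.5.
#'
#' @return A data frame with columns `term`, `effect`, `strength`, `weight`.
#' @export
#' @examples
#' interaction_vocabulary()
interaction_vocabulary <- function() {
  data.frame(
    term = c(
      "activates", "weakly activates", "strongly activates",
      "inhibits", "weakly inhibits", "strongly inhibits",
      "binds"
    ),
    effect = c(
      "activation", "activation", "activation",
      "inhibition", "inhibition", "inhibition",
      "neutral"
    ),
    strength = c(
      "standard", "weak", "strong",
      "standard", "weak", "strong",
      "none"
    ),
    weight = c(1, 0.5, 1.5, -1, -0.5, -1.5, 0),
    stringsAsFactors = FALSE
  )
}

# canonical form: lower case, trimmed, underscores treated as spaces,
# internal runs of whitespace collapsed
canonical_term <- function(term) {
  term <- tolower(trimws(term))
  term <- gsub("_", " ", term, fixed = TRUE)
  gsub("[[:space:]]+", " ", term)
}

#' Normalize an interaction term
#'
#' Maps free-text interaction terms onto the controlled vocabulary. Matching
#' is case-insensitive, surrounding whitespace is ignored, and underscore
#' forms (`"weakly_activates"`) are accepted as equivalents. Any term outside
#' the vocabulary falls back to `"activates"` (standard activation, weight
#' +1) and is flagged in the `substituted` column so callers can report the
#' replacement to the user; the map is therefore total over non-empty text.
#'
#' @param term Character vector of interaction terms.
#' @return A data frame with one row per term: `original_term`, canonical
#'   `term`, `effect` (`"activation"`, `"inhibition"` or `"neutral"`),
#'   `strength` (`"weak"`, `"standard"`, `"strong"` or `"none"`), signed
#'   `weight`, and logical `substituted`.
#' @export
#' @examples
#' normalize_interaction("weakly activates")
#' normalize_interaction("phosphorylates")  # outside the vocabulary
normalize_interaction <- function(term) {
  if (length(term) == 0L) stop("no interaction term supplied")
  term <- as.character(term)
  if (anyNA(term) || any(!nzchar(trimws(term)))) {
    stop("interaction terms must be non-empty text")
  }
  vocab <- interaction_vocabulary()
  canon <- canonical_term(term)
  idx <- match(canon, vocab$term)
  substituted <- is.na(idx)
  idx[substituted] <- match("activates", vocab$term)
  out <- vocab[idx, , drop = FALSE]
  out <- cbind(original_term = term, out, substituted = substituted)
  rownames(out) <- NULL
  out
}
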