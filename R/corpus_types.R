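#' Construct an entity mention
#'
#' An entity mention is a contiguous span of sentence text annotated with a
#' type (e.g. `"drug"`, `"protein"`). Character offsets follow the
#' DDIExtraction 2013 `charOffset` convention: 0-based, inclusive on both
#' ends, into the raw sentence string.
#'
#' @param id unique (within sentence) entity identifier.
#' @param surface the mention text; must equal the sentence substring at
#'   `[char_start, char_end]`.
#' @param char_start,char_end 0-based inclusive character offsets.
#' @param etype entity type label.
#' @return A one-row `data.frame` with columns
#'   `id, surface, char_start, char_end, etype`.
#' @export
entity_mention <- function(id, surface, char_start, char_end, etype = "drug") {
  if (char_start > char_end) {
    stop_validation("entity '%s': char_start (%d) > char_end (%d)",
                    id, char_start, char_end)
  }
  data.frame(id = as.character(id), surface = as.character(surface),
             char_start = as.integer(char_start),
             char_end = as.integer(char_end),
             etype = as.character(etype), stringsAsFactors = FALSE)
}

#' Construct a gold relation pair
#'
#' @param e1,e2 entity ids participating in the relation; must differ.
#' @param label class symbol, e.g. one of
#'   `advice, effect, mechanism, int, negative` for DDI or
#'   `positive, negative` for PPI.
#' @return A one-row `data.frame` with columns `e1, e2, label`.
#' @export
gold_pair <- function(e1, e2, label) {
  if (identical(as.character(e1), as.character(e2))) {
    stop_validation("gold pair references the same entity twice: '%s'", e1)
  }
  data.frame(e1 = as.character(e1), e2 = as.character(e2),
             label = as.character(label), stringsAsFactors = FALSE)
}

.empty_entities <- function() {
  data.frame(id = character(), surface = character(),
             char_start = integer(), char_end = integer(),
             etype = character(), stringsAsFactors = FALSE)
}

.empty_pairs <- function() {
  data.frame(e1 = character(), e2 = character(), label = character(),
             stringsAsFactors = FALSE)
}

#' Construct an annotated sentence
#'
#' The unit of corpus annotation: raw sentence text plus its entity mentions
#' and gold-labeled entity pairs. Offsets are validated against the text.
#'
#' @param id sentence identifier.
#' @param text raw sentence text (UTF-8).
#' @param entities `data.frame` of entity mentions (see [entity_mention()]),
#'   or a list of such one-row frames.
#' @param pairs `data.frame` of gold pairs (see [gold_pair()]).
#' @return An object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(id, text, entities = .empty_entities(),
                               pairs = .empty_pairs()) {
  if (is.list(entities) && !is.data.frame(entities)) {
    entities <- if (length(entities)) do.call(rbind, entities) else .empty_entities()
  }
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- if (length(pairs)) do.call(rbind, pairs) else .empty_pairs()
  }
  s <- structure(list(id = as.character(id), text = as.character(text),
                      entities = entities, pairs = pairs),
                 class = "annotated_sentence")
  validate_sentence(s)
  s
}

#' Validate an annotated sentence
#'
#' Checks that entity ids are unique, offsets lie inside the text, each
#' surface form equals the substring it points at, and every gold pair
#' references known entities.
#'
#' @param s an `annotated_sentence`.
#' @return `s`, invisibly, or an error naming the offending sentence.
#' @export
validate_sentence <- function(s) {
  e <- s$entities
  if (anyDuplicated(e$id)) {
    stop_validation("sentence '%s': duplicated entity ids", s$id)
  }
  n <- nchar(s$text)
  for (i in seq_len(nrow(e))) {
    if (e$char_start[i] < 0L || e$char_end[i] >= n) {
      stop_validation("sentence '%s': entity '%s' offsets [%d,%d] outside text (length %d)",
                      s$id, e$id[i], e$char_start[i], e$char_end[i], n)
    }
    sub <- substr(s$text, e$char_start[i] + 1L, e$char_end[i] + 1L)
    if (!identical(sub, e$surface[i])) {
      stop_validation("sentence '%s': entity '%s' surface '%s' != text span '%s'",
                      s$id, e$id[i], e$surface[i], sub)
    }
  }
  p <- s$pairs
  if (nrow(p)) {
    bad <- !(p$e1 %in% e$id) | !(p$e2 %in% e$id)
    if (any(bad)) {
      stop_validation("sentence '%s': pair references unknown entity id", s$id)
    }
  }
  invisible(s)
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat(sprintf("<annotated_sentence '%s': %d entities, %d pairs>\n  %s\n",
              x$id, nrow(x$entities), nrow(x$pairs), x$text))
  invisible(x)
}

#' Construct a candidate instance
#'
#' A blinded candidate pair ready for classification: the token sequence with
#' the two target entities replaced by `Entity1`/`Entity2` and every other
#' entity by `EntityOther`, plus the class label and provenance.
#'
#' @param sentence_id source sentence id.
#' @param e1,e2 target entity ids, in document order.
#' @param tokens character vector of blinded token symbols.
#' @param label class symbol.
#' @param filtered removal reason: `"none"`, `"rule1"` or `"rule2"`.
#' @return An object of class `mccnn_instance`.
#' @export
new_instance <- function(sentence_id, e1, e2, tokens, label,
                         filtered = "none") {
  if (!length(tokens)) stop_validation("instance with empty token list")
  if (!(filtered %in% c("none", "rule1", "rule2"))) {
    stop_validation("unknown filtered reason '%s'", filtered)
  }
  structure(list(sentence_id = as.character(sentence_id),
                 e1 = as.character(e1), e2 = as.character(e2),
                 tokens = as.character(tokens), label = as.character(label),
                 filtered = filtered),
            class = "mccnn_instance")
}

#' @export
print.mccnn_instance <- function(x, ...) {
  cat(sprintf("<instance %s (%s,%s) label=%s%s>\n  %s\n",
              x$sentence_id, x$e1, x$e2, x$label,
              if (x$filtered != "none") paste0(" filtered=", x$filtered) else "",
              paste(x$tokens, collapse = " ")))
  invisible(x)
}

#' Extract labels or sentence ids from an instance list
#'
#' @param instances list of `mccnn_instance` objects.
#' @return Character vector.
#' @export
instance_labels <- function(instances) {
  vapply(instances, function(i) i$label, character(1))
}

#' @rdname instance_labels
#' @export
instance_sentence_ids <- function(instances) {
  vapply(instances, function(i) i$sentence_id, character(1))
}
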